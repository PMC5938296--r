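test_that("identical ratings give kappa 1 and full agreement in both schemes", {
  x <- c(-2, -1, 0, 0, 1, 2, 1, -1)
  for (w in c("linear", "quadratic")) {
    k <- weighted_kappa(x, x, weights = w)
    expect_equal(k$kappa_w, 1, tolerance = 1e-12)
    expect_equal(k$percent_agreement, 100)
  }
})

test_that("weighted kappa matches the brute-force formula on a 3x3 table", {
  tab <- matrix(c(11, 3, 1,
                  2, 9, 4,
                  1, 2, 10), 3, 3, byrow = TRUE)
  x <- rep(rep(1:3, each = 3), times = as.vector(t(tab)))
  y <- rep(rep(1:3, times = 3), times = as.vector(t(tab)))
  for (w in c("linear", "quadratic")) {
    k <- weighted_kappa(x, y, weights = w, categories = 1:3)
    expect_equal(k$kappa_w, oracle_weighted_kappa(tab, w), tolerance = 1e-12)
  }
  # both weightings agree in sign on this fixture
  kl <- weighted_kappa(x, y, weights = "linear", categories = 1:3)$kappa_w
  kq <- weighted_kappa(x, y, weights = "quadratic", categories = 1:3)$kappa_w
  expect_equal(sign(kl), sign(kq))
})

test_that("independent raters land within 3 SE of zero", {
  set.seed(101)
  x <- sample(-2:2, 4000, replace = TRUE)
  y <- sample(-2:2, 4000, replace = TRUE)
  k <- weighted_kappa(x, y)
  expect_lt(abs(k$kappa_w), 3 * k$se)
})

test_that("degenerate rating inputs are handled explicitly", {
  expect_error(weighted_kappa(c(1, 2), c(1, 2, 3), categories = 1:3),
               "length")
  k <- weighted_kappa(rep(0, 10), rep(0, 10))
  expect_true(k$undefined)
  expect_true(is.na(k$kappa_w))
  expect_equal(k$percent_agreement, 100)
})

test_that("kappa is invariant under order-preserving relabelling", {
  set.seed(103)
  x <- sample(-2:2, 200, replace = TRUE, prob = c(1, 2, 4, 2, 1))
  y <- pmin(pmax(x + sample(-1:1, 200, replace = TRUE), -2), 2)
  k1 <- weighted_kappa(x, y)
  k2 <- weighted_kappa(x + 10, y + 10, categories = -2:2 + 10)
  expect_equal(k1$kappa_w, k2$kappa_w, tolerance = 1e-12)
  expect_equal(k1$percent_agreement, k2$percent_agreement)
  expect_lte(within_one_agreement(x, y), 100)
  expect_gte(within_one_agreement(x, y), k1$percent_agreement)
})

test_that("inter-observer summary covers every observer pair", {
  rec <- simulate_study(sim_config(n_patients = 20,
                                   criteria = vgr_criteria()[1],
                                   n_replicates = 0, seed = 107))
  s <- interobserver_summary(rec)
  expect_equal(nrow(s), choose(5, 2))
  expect_true(all(s$n == 20 * 12))
  rng <- attr(s, "range")
  expect_lte(rng$kappa_min, rng$kappa_max)
})

test_that("observer pairs with no shared patients are skipped with a notice", {
  rec <- make_records(12, seed = 109)
  rec$criterion <- 1L
  rec$observer_id <- "A"
  rec2 <- rec
  rec2$observer_id <- "B"
  rec2$patient_id <- paste0("Q", seq_len(nrow(rec2)))
  expect_message(s <- interobserver_summary(rbind(rec, rec2)), "skipped")
  expect_equal(nrow(s), 0L)
})

test_that("less heterogeneous observers agree more", {
  mean_kappa <- function(sig_o, seed) {
    cfg <- sim_config(n_patients = 25, criteria = vgr_criteria()[1],
                      sigma_observer = sig_o, n_replicates = 0, seed = seed)
    mean(interobserver_summary(simulate_study(cfg))$kappa_w)
  }
  expect_gt(mean_kappa(0, 113), mean_kappa(2, 113))
})

test_that("intra-observer kappa is 1 on verbatim-copied replicates", {
  rec <- make_records(12, seed = 115)
  rec$observer_id <- "A"
  rec$patient_id <- sprintf("P%02d", 1:12)   # unique hangings
  rec$score <- rep(c(-2, -1, 0, 1), 3)
  reps <- rec
  reps$replicate_index <- 1L
  s <- intraobserver_summary(rbind(rec, reps))
  expect_equal(nrow(s), 1L)
  expect_equal(s$kappa_w, 1, tolerance = 1e-12)
  expect_equal(s$percent_agreement, 100)
})

test_that("default replication yields 5 paired ratings per observer per criterion", {
  rec <- simulate_study(sim_config(seed = 117))  # n_replicates = 5
  s <- intraobserver_summary(rec)
  expect_equal(nrow(s), 5L)
  expect_true(all(s$n == 5L * 6L))  # 5 hangings x 6 criteria, pooled
})

test_that("records without replicates produce an empty result with a notice", {
  rec <- simulate_study(sim_config(n_patients = 5,
                                   criteria = vgr_criteria()[1],
                                   n_replicates = 0, seed = 119))
  expect_message(s <- intraobserver_summary(rec), "no replicated")
  expect_equal(nrow(s), 0L)
})

test_that("score distribution assigns scores to the condition's own side", {
  rec <- data.frame(
    patient_id = sprintf("P%d", 1:4), observer_id = "A", criterion = 1L,
    left_mAs = c(42, 98, 42, 98), left_algo = c("FBP", "IR3", "FBP", "IR3"),
    right_mAs = c(98, 42, 98, 42), right_algo = c("IR3", "FBP", "IR3", "FBP"),
    score = c(2L, -2L, 2L, -2L), replicate_index = 0L)
  d <- score_distribution(rec, 98, "IR3")
  expect_equal(d$percent, c(0, 0, 0, 0, 100))   # IR3\@98 always wins
  expect_equal(d$n, 4L)
  d2 <- score_distribution(rec, 42, "FBP")
  expect_equal(d2$percent, c(100, 0, 0, 0, 0))  # and FBP\@42 always loses
  expect_error(score_distribution(rec, 140, "IR5"), "absent")
})

test_that("score distributions are normalized and double-count each record", {
  rec <- simulate_study(sim_config(n_patients = 10,
                                   criteria = vgr_criteria()[1],
                                   n_replicates = 0, seed = 121))
  d <- default_design()
  conds <- unique(rbind(
    data.frame(mAs = d$left_mAs, algo = d$left_algo),
    data.frame(mAs = d$right_mAs, algo = d$right_algo)))
  total_n <- 0
  for (i in seq_len(nrow(conds))) {
    sd_ <- score_distribution(rec, conds$mAs[i], conds$algo[i])
    expect_equal(sum(sd_$percent), 100, tolerance = 1e-9)
    total_n <- total_n + sd_$n
  }
  expect_equal(total_n, 2L * nrow(rec))
})

test_that("a symmetric null study yields a symmetric score distribution", {
  cfg <- sim_config(n_patients = 60, true_a = 0, true_b = c(IR3 = 0, IR5 = 0),
                    sigma_patient = 0, sigma_observer = 0,
                    criteria = vgr_criteria()[1], n_replicates = 0, seed = 123)
  d <- score_distribution(simulate_study(cfg), 98, "IR3")
  p <- d$percent / 100
  se <- sqrt(p * (1 - p) / d$n) * 100
  expect_true(all(abs(d$percent - rev(d$percent)) <= 3 * (se + rev(se)) + 1))
})
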