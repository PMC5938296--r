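test_that("covariate coding follows the right-minus-left convention", {
  rec <- data.frame(
    patient_id = "P1", observer_id = "A", criterion = 1L,
    left_mAs = c(42, 98, 98), left_algo = c("FBP", "FBP", "IR3"),
    right_mAs = c(98, 98, 98), right_algo = c("FBP", "IR3", "FBP"),
    score = c(1L, 0L, -1L), replicate_index = 0L)
  mf <- prepare_covariates(rec, criterion = 1)
  expect_equal(mf$log_mAs[1], log(98 / 42), tolerance = 1e-12)
  expect_equal(mf$IR3, c(0, 1, -1))
  expect_equal(mf$y, rec$score + 3L)
  expect_equal(attr(mf, "reference"), "FBP")
})

test_that("dose-interval filtering drops exactly the out-of-interval rows", {
  rec <- make_records(20, seed = 8)
  rec$criterion <- 1L
  keep_hand <- rec$left_mAs <= 98 & rec$right_mAs <= 98
  mf <- prepare_covariates(rec, criterion = 1, dose_interval = c(42, 98))
  expect_equal(nrow(mf), sum(keep_hand))
})

test_that("fixed-effects fit agrees with an established ordinal regression", {
  cfg <- sim_config(n_patients = 20, observers = c("A", "B"),
                    criteria = vgr_criteria()[1], sigma_patient = 0,
                    sigma_observer = 0, n_replicates = 0, seed = 3)
  rec <- simulate_study(cfg)
  f <- fit_vgr(rec, criterion = 1, random_effects = NULL)
  mf <- prepare_covariates(rec, criterion = 1)
  pf <- MASS::polr(factor(y, ordered = TRUE) ~ log_mAs + IR3 + IR5,
                   data = mf, Hess = TRUE)
  expect_equal(unname(coef(f)), unname(coef(pf)), tolerance = 1e-3)
  expect_equal(unname(f$thresholds), unname(pf$zeta), tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(pf)), tolerance = 1e-4)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(pf))[1:3])),
               tolerance = 1e-3)
})

test_that("null data yield estimates within 3 SE of zero", {
  cfg <- sim_config(n_patients = 40, true_a = 0, true_b = c(IR3 = 0, IR5 = 0),
                    sigma_patient = 0, sigma_observer = 0,
                    criteria = vgr_criteria()[1], n_replicates = 0, seed = 5)
  f <- fit_vgr(simulate_study(cfg), criterion = 1, random_effects = NULL)
  expect_true(all(abs(coef(f)) < 3 * f$se))
})

test_that("degenerate and rank-deficient inputs raise informative errors", {
  rec <- make_records(30, seed = 2)
  rec$criterion <- 1L
  rec$score <- 0L
  expect_error(fit_vgr(rec, criterion = 1, random_effects = NULL),
               "degenerate")
  # a single pair type: dose column and IR3 indicator are collinear
  one <- data.frame(patient_id = sprintf("P%d", 1:30), observer_id = "A",
                    criterion = 1L, left_mAs = 42, left_algo = "FBP",
                    right_mAs = 98, right_algo = "IR3",
                    score = rep(c(-1L, 0L, 1L), 10), replicate_index = 0L)
  expect_error(fit_vgr(one, criterion = 1, random_effects = NULL),
               "rank deficient")
})

test_that("orientation flip leaves coefficients unchanged, reverses thresholds", {
  cfg <- sim_config(n_patients = 20, observers = c("A", "B"),
                    criteria = vgr_criteria()[1], sigma_patient = 0,
                    sigma_observer = 0, n_replicates = 0, seed = 3)
  rec <- simulate_study(cfg)
  ctl <- list(rel_tol = 1e-14)
  f1 <- fit_vgr(rec, criterion = 1, random_effects = NULL, control = ctl)
  f2 <- fit_vgr(flip_records(rec), criterion = 1, random_effects = NULL,
                control = ctl)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(unname(f1$thresholds), -rev(unname(f2$thresholds)),
               tolerance = 1e-6)
})

test_that("fitted likelihood dominates the generating parameters", {
  for (seed in c(13, 14, 15)) {
    cfg <- sim_config(n_patients = 15, observers = c("A", "B"),
                      criteria = vgr_criteria()[1], sigma_patient = 0,
                      sigma_observer = 0, n_replicates = 0, seed = seed)
    rec <- simulate_study(cfg)
    f <- fit_vgr(rec, criterion = 1, random_effects = NULL)
    mf <- prepare_covariates(rec, criterion = 1)
    # independent evaluation of the likelihood at the truth
    eta_true <- cfg$true_a * mf$log_mAs + cfg$true_b["IR3"] * mf$IR3 +
      cfg$true_b["IR5"] * mf$IR5
    th <- c(-Inf, cfg$thresholds, Inf)
    ll_true <- sum(log(plogis(th[mf$y + 1L] - eta_true) -
                         plogis(th[mf$y] - eta_true)))
    expect_gte(f$loglik, ll_true)
  }
})

test_that("predicted probabilities are valid distributions", {
  cfg <- sim_config(n_patients = 15, observers = c("A", "B"),
                    criteria = vgr_criteria()[1], n_replicates = 0, seed = 17)
  f <- fit_vgr(simulate_study(cfg), criterion = 1, random_effects = NULL)
  pr <- predict(f, default_design())
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-12)
  cum <- t(apply(pr, 1, cumsum))
  expect_true(all(diff(t(cum)) >= -1e-12))
})

test_that("mixed fit collapses to the fixed fit when variances vanish", {
  cfg <- sim_config(n_patients = 30, observers = c("A", "B", "C"),
                    criteria = vgr_criteria()[1], sigma_patient = 0,
                    sigma_observer = 0, n_replicates = 0, seed = 19)
  rec <- simulate_study(cfg)
  fm <- fit_vgr(rec, criterion = 1, dose_interval = c(42, 98))
  ff <- fit_vgr(rec, criterion = 1, random_effects = NULL,
                dose_interval = c(42, 98))
  expect_true(all(fm$sigma2 < 0.05))
  expect_equal(coef(fm), coef(ff), tolerance = 0.02)
})

test_that("an unidentifiable observer variance is pinned at zero with a note", {
  cfg <- sim_config(n_patients = 25, observers = "A",
                    criteria = vgr_criteria()[1], n_replicates = 0, seed = 23)
  f <- fit_vgr(simulate_study(cfg), criterion = 1,
               random_effects = c("patient", "observer"))
  expect_equal(unname(f$sigma2[["observer"]]), 0)
  expect_true(any(grepl("observer", f$warnings)))
})

test_that("per-algorithm tube-load effect recovers the dose dependence", {
  cfg <- sim_config(criteria = vgr_criteria()[1], n_replicates = 0, seed = 29)
  rec <- simulate_study(cfg)
  f <- tube_load_effect(rec, "IR3", c(42, 98), criterion = 1,
                        random_effects = NULL)
  expect_equal(names(coef(f)), "log_mAs")
  expect_gt(coef(f)[["log_mAs"]], 0)
  expect_lt(f$p_values[["log_mAs"]], 0.05)
  expect_error(tube_load_effect(rec, "SAFIRE", c(42, 98), criterion = 1),
               "no records")
})

test_that("Wald intervals for the tube-load effect reach nominal coverage", {
  truth <- 2.3
  covered <- logical(50)
  for (i in seq_along(covered)) {
    cfg <- sim_config(n_patients = 15, observers = paste0("O", 1:3),
                      criteria = vgr_criteria()[1], n_replicates = 0,
                      seed = 500 + i)
    f <- fit_vgr(simulate_study(cfg), criterion = 1,
                 dose_interval = c(42, 98))
    a <- coef(f)[["log_mAs"]]; se <- f$se[["log_mAs"]]
    covered[i] <- abs(a - truth) <= qnorm(0.975) * se
  }
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 1.0)
})
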