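# Latent-variable simulator for pairwise visual gradings.
#
# A grading of pair (L, R) is generated from the cumulative-logit model:
# the latent relative quality is
#   eta = a * (log mAs_R - log mAs_L) + b[algo_R] - b[algo_L] + u + v
# with patient intercept u and observer intercept v, plus a standard-logistic
# residual; thresholds theta_1..theta_4 cut the latent scale into the five
# ordered score categories -2..+2.

#' Simulation configuration
#'
#' Ground-truth parameters and study dimensions for [simulate_study()].
#' Defaults reproduce the structure and approximate effect magnitudes of a
#' full abdominal-CT grading study: 50 patients, 5 observers, 6 criteria,
#' the 12-pair design of [default_design()], tube-load effect `a = 2.3`,
#' algorithm effects `b(IR3) = 1.0`, `b(IR5) = 1.7` (reference FBP fixed at
#' 0), patient/observer intercept SDs 0.5, symmetric thresholds
#' (-3, -1, 1, 3) which concentrate mass on scores -1..+1, and five
#' replicated pair presentations per observer.
#'
#' @param n_patients Number of patients.
#' @param observers Observer labels.
#' @param criteria Registered criteria (named integer vector as in
#'   [vgr_criteria()]).
#' @param design A `vgr_design`.
#' @param true_a Latent effect per unit natural-log tube load.
#' @param true_b Named latent effects for non-reference algorithms; the
#'   design's reference algorithm is fixed at 0.
#' @param sigma_patient,sigma_observer Nonnegative SDs of the patient and
#'   observer random intercepts (drawn per criterion).
#' @param thresholds Nondecreasing length-4 vector of latent cutpoints.
#' @param n_replicates Pair presentations re-shown to each observer to
#'   support intra-observer reliability (replicate_index >= 1).
#' @param seed Integer seed making the simulation fully reproducible.
#' @return A list of class `vgr_sim_config`.
#' @export
sim_config <- function(n_patients = 50,
                       observers = paste0("Obs", 1:5),
                       criteria = vgr_criteria(),
                       design = default_design(),
                       true_a = 2.3,
                       true_b = c(IR3 = 1.0, IR5 = 1.7),
                       sigma_patient = 0.5,
                       sigma_observer = 0.5,
                       thresholds = c(-3, -1, 1, 3),
                       n_replicates = 5,
                       seed = 1L) {
  stopifnot(n_patients >= 1, length(observers) >= 1,
            length(criteria) >= 1, inherits(design, "vgr_design"),
            sigma_patient >= 0, sigma_observer >= 0,
            length(thresholds) == 4L, n_replicates >= 0)
  if (is.unsorted(thresholds))
    stop("thresholds must be nondecreasing", call. = FALSE)
  ref <- attr(design, "reference")
  nonref <- setdiff(attr(design, "algorithms"), ref)
  if (!all(names(true_b) %in% nonref))
    stop("true_b names must be non-reference algorithms (",
         paste(nonref, collapse = ", "), "); reference ", ref,
         " is fixed at 0", call. = FALSE)
  b <- stats::setNames(numeric(length(nonref)), nonref)
  b[names(true_b)] <- true_b
  structure(list(n_patients = n_patients, observers = observers,
                 criteria = criteria, design = design, true_a = true_a,
                 true_b = b, sigma_patient = sigma_patient,
                 sigma_observer = sigma_observer, thresholds = thresholds,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "vgr_sim_config")
}

# run code with a temporary RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# category probabilities from a latent shift eta (vectorized over eta)
.cat_probs <- function(eta, thresholds) {
  cum <- stats::plogis(outer(thresholds, eta, function(t, e) t - e))
  p <- rbind(cum, 1) - rbind(0, cum)   # (K x n)
  t(p)
}

#' Category probabilities for a comparison pair
#'
#' Probability of each score -2..+2 when grading `pair` under the latent
#' cumulative-logit model, optionally shifted by patient and observer random
#' intercepts. With latent mean
#' `eta = a * log(mAs_R / mAs_L) + b[algo_R] - b[algo_L] + u + v`,
#' `P(score <= s) = plogis(theta_s - eta)` and category probabilities are
#' consecutive differences of the logistic CDF.
#'
#' @param pair A design row (or list) with `left_mAs`, `left_algo`,
#'   `right_mAs`, `right_algo`.
#' @param config A `vgr_sim_config` supplying `true_a`, `true_b`,
#'   `thresholds`.
#' @param patient_effect,observer_effect Latent intercepts `u`, `v`.
#' @return Named probability 5-vector over scores -2..+2 (sums to 1).
#' @export
#' @examples
#' category_probabilities(list(left_mAs = 42, left_algo = "FBP",
#'                             right_mAs = 98, right_algo = "FBP"),
#'                        sim_config())
category_probabilities <- function(pair, config, patient_effect = 0,
                                   observer_effect = 0) {
  stopifnot(inherits(config, "vgr_sim_config"))
  ref <- attr(config$design, "reference")
  beff <- c(stats::setNames(0, ref), config$true_b)
  for (a in c(pair$left_algo, pair$right_algo))
    if (!a %in% names(beff))
      stop("unregistered algorithm '", a, "'", call. = FALSE)
  eta <- config$true_a * (log(pair$right_mAs) - log(pair$left_mAs)) +
    beff[[pair$right_algo]] - beff[[pair$left_algo]] +
    patient_effect + observer_effect
  stats::setNames(drop(.cat_probs(eta, config$thresholds)), -2:2)
}

#' Simulate a complete grading study
#'
#' Draws patient and observer random intercepts per criterion, randomizes the
#' left/right hanging of every (patient, pair) presentation once (all
#' observers see the same hanging, as on a reading workstation), samples one
#' ordinal score per (patient, observer, criterion, pair) from
#' [category_probabilities()], and appends `n_replicates` re-presented pairs
#' per observer (same hanging and intercepts, fresh residual draws,
#' `replicate_index = 1`). Fully reproducible from `config$seed`.
#'
#' @param config A `vgr_sim_config`.
#' @return Grading-record data frame (columns of [read_records()]).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 4, observers = c("A", "B"),
#'                   criteria = vgr_criteria()[1], n_replicates = 0)
#' nrow(simulate_study(cfg))  # 4 patients x 2 observers x 12 pairs
simulate_study <- function(config) {
  stopifnot(inherits(config, "vgr_sim_config"))
  .with_seed(config$seed, {
    design <- config$design
    n_pair <- nrow(design)
    patients <- sprintf("P%03d", seq_len(config$n_patients))
    observers <- config$observers
    criteria <- unname(config$criteria)
    nP <- length(patients); nO <- length(observers); nC <- length(criteria)

    # per-criterion random intercepts
    u <- matrix(stats::rnorm(nP * nC, 0, config$sigma_patient), nP, nC)
    v <- matrix(stats::rnorm(nO * nC, 0, config$sigma_observer), nO, nC)

    # one blinded hanging per (patient, pair)
    flip <- matrix(stats::runif(nP * n_pair) < 0.5, nP, n_pair)

    grid <- expand.grid(pair = seq_len(n_pair), patient = seq_len(nP),
                        observer = seq_len(nO), criterion = seq_len(nC),
                        KEEP.OUT.ATTRS = FALSE)
    fl <- flip[cbind(grid$patient, grid$pair)]
    lm <- ifelse(fl, design$right_mAs[grid$pair], design$left_mAs[grid$pair])
    rm_ <- ifelse(fl, design$left_mAs[grid$pair], design$right_mAs[grid$pair])
    la <- ifelse(fl, design$right_algo[grid$pair], design$left_algo[grid$pair])
    ra <- ifelse(fl, design$left_algo[grid$pair], design$right_algo[grid$pair])

    ref <- attr(design, "reference")
    beff <- c(stats::setNames(0, ref), config$true_b)
    eta <- config$true_a * (log(rm_) - log(lm)) +
      unname(beff[ra]) - unname(beff[la]) +
      u[cbind(grid$patient, grid$criterion)] +
      v[cbind(grid$observer, grid$criterion)]
    score <- .sample_scores(eta, config$thresholds)

    rec <- data.frame(
      patient_id = patients[grid$patient],
      observer_id = observers[grid$observer],
      criterion = criteria[grid$criterion],
      left_mAs = lm, left_algo = la, right_mAs = rm_, right_algo = ra,
      score = score, replicate_index = 0L)

    if (config$n_replicates > 0) {
      reps <- lapply(seq_len(nO), function(o) {
        idx <- sample.int(nP * n_pair, config$n_replicates)  # distinct hangings
        sel <- data.frame(patient = (idx - 1L) %% nP + 1L,
                          pair = (idx - 1L) %/% nP + 1L)
        g <- expand.grid(i = seq_len(config$n_replicates),
                         criterion = seq_len(nC), KEEP.OUT.ATTRS = FALSE)
        p <- sel$patient[g$i]; pr <- sel$pair[g$i]
        fl <- flip[cbind(p, pr)]  # same hanging as the original
        lm <- ifelse(fl, design$right_mAs[pr], design$left_mAs[pr])
        rm_ <- ifelse(fl, design$left_mAs[pr], design$right_mAs[pr])
        la <- ifelse(fl, design$right_algo[pr], design$left_algo[pr])
        ra <- ifelse(fl, design$left_algo[pr], design$right_algo[pr])
        eta <- config$true_a * (log(rm_) - log(lm)) +
          unname(beff[ra]) - unname(beff[la]) +
          u[cbind(p, g$criterion)] + v[cbind(rep(o, length(p)), g$criterion)]
        data.frame(patient_id = patients[p], observer_id = observers[o],
                   criterion = criteria[g$criterion],
                   left_mAs = lm, left_algo = la, right_mAs = rm_,
                   right_algo = ra,
                   score = .sample_scores(eta, config$thresholds),
                   replicate_index = 1L)
      })
      rec <- rbind(rec, do.call(rbind, reps))
    }
    rownames(rec) <- NULL
    rec
  })
}

# sample ordinal scores -2..+2 given latent shifts (logistic residual)
.sample_scores <- function(eta, thresholds) {
  z <- stats::rlogis(length(eta))
  score <- rowSums(outer(z + eta, thresholds, `>`)) - 2L
  as.integer(score)
}
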