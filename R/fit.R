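# Visual grading regression: cumulative-logit (proportional-odds) model for
# relative pairwise scores.
#
# Latent model for grading pair (L, R):
#   eta_i = a * (log mAs_R - log mAs_L) + sum_g b_g ([algo_R = g] - [algo_L = g])
#           + u_patient(i) + v_observer(i)
#   P(score_i <= s) = plogis(theta_s - eta_i)
# Fixed-effects fits maximize the cumulative-logit likelihood directly;
# mixed fits integrate the crossed patient/observer intercepts out by a
# Laplace approximation at the joint mode (crossed effects do not factorize,
# so adaptive quadrature is not applicable).

#' Build the VGR covariate table from grading records
#'
#' One row per record: the right-minus-left difference in natural-log tube
#' load, one signed indicator per non-reference algorithm
#' (`[right = g] - [left = g]`), patient and observer factors, and the score
#' recoded to ordered categories 1..5. This right-minus-left coding makes the
#' model invariant to presentation side and identifies the coefficients `a`
#' and `b` exactly as the dose-reduction equation `DR = 1 - exp(-b/a)`
#' requires.
#'
#' @param records Grading-record data frame.
#' @param criterion Criterion to keep; may be `NULL` if the records contain a
#'   single criterion.
#' @param dose_interval Optional length-2 tube-load interval; records with
#'   either side outside it are excluded (e.g. `c(42, 98)` to drop the
#'   nonlinear 98-140 mAs regime).
#' @param reference_algorithm Reference level for the algorithm contrasts;
#'   default `"FBP"` when present, otherwise the first algorithm.
#' @param covariates Fixed effects to include: `"dose"` (delta log mAs)
#'   and/or `"algorithm"`.
#' @return Data frame with columns `y` (1..5), `log_mAs`, one column per
#'   non-reference algorithm, `patient`, `observer`; attributes `reference`
#'   and `fixed_terms`.
#' @export
prepare_covariates <- function(records, criterion = NULL, dose_interval = NULL,
                               reference_algorithm = NULL,
                               covariates = c("dose", "algorithm")) {
  records <- as.data.frame(records)
  covariates <- match.arg(covariates, c("dose", "algorithm"), several.ok = TRUE)
  if (!is.null(criterion)) {
    records <- records[records$criterion %in% criterion, , drop = FALSE]
  } else if (length(unique(records$criterion)) > 1L) {
    stop("records contain several criteria; pass `criterion`", call. = FALSE)
  }
  if (!is.null(dose_interval)) {
    stopifnot(length(dose_interval) == 2L)
    lo <- min(dose_interval); hi <- max(dose_interval)
    keep <- records$left_mAs >= lo & records$left_mAs <= hi &
      records$right_mAs >= lo & records$right_mAs <= hi
    records <- records[keep, , drop = FALSE]
  }
  if (!nrow(records)) stop("no records left after filtering", call. = FALSE)
  if (any(!records$score %in% (-2:2)))
    stop("scores outside the -2..+2 scale; run validate_records()", call. = FALSE)
  algos <- sort(unique(c(records$left_algo, records$right_algo)))
  if (is.null(reference_algorithm))
    reference_algorithm <- if ("FBP" %in% algos) "FBP" else algos[1L]
  if (!reference_algorithm %in% algos)
    stop("reference algorithm '", reference_algorithm,
         "' absent from records", call. = FALSE)
  out <- data.frame(y = as.integer(records$score) + 3L)
  terms <- character()
  if ("dose" %in% covariates) {
    out$log_mAs <- log(records$right_mAs) - log(records$left_mAs)
    terms <- "log_mAs"
  }
  if ("algorithm" %in% covariates) {
    for (g in setdiff(algos, reference_algorithm)) {
      out[[g]] <- as.numeric(records$right_algo == g) -
        as.numeric(records$left_algo == g)
      terms <- c(terms, g)
    }
  }
  if (!length(terms)) stop("at least one fixed effect required", call. = FALSE)
  out$patient <- factor(records$patient_id)
  out$observer <- factor(records$observer_id)
  structure(out, reference = reference_algorithm, fixed_terms = terms)
}

# ---- cumulative-logit likelihood pieces --------------------------------

# thresholds from increment parameterization (enforces monotonicity)
.th_from_par <- function(tpar) {
  if (length(tpar) == 1L) tpar else cumsum(c(tpar[1L], exp(tpar[-1L])))
}

.logis_d1 <- stats::dlogis
.logis_d2 <- function(x) {           # f'(x) for the logistic density
  fx <- stats::dlogis(x)
  fx * (1 - 2 * stats::plogis(x))
}

# per-observation category prob and 1st/2nd derivatives of log prob wrt eta
.cl_obs <- function(eta, y, th, deriv = 2L) {
  thU <- c(th, Inf)[y]
  thL <- c(-Inf, th)[y]
  A <- thU - eta; B <- thL - eta
  p <- pmax(stats::plogis(A) - stats::plogis(B), 1e-300)
  out <- list(p = p, A = A, B = B)
  if (deriv >= 1L) {
    fA <- ifelse(is.finite(A), .logis_d1(A), 0)
    fB <- ifelse(is.finite(B), .logis_d1(B), 0)
    out$fA <- fA; out$fB <- fB
    out$g <- (fB - fA) / p
  }
  if (deriv >= 2L) {
    dA <- ifelse(is.finite(A), .logis_d2(A), 0)
    dB <- ifelse(is.finite(B), .logis_d2(B), 0)
    out$h <- (dA - dB) / p - out$g^2          # <= 0 (log-concavity)
  }
  out
}

# negative log-likelihood and analytic gradient, fixed-effects model
# par = c(threshold params (K-1), beta (p))
.cl_nll <- function(par, y, X, K) {
  th <- .th_from_par(par[seq_len(K - 1L)])
  beta <- par[-seq_len(K - 1L)]
  eta <- drop(X %*% beta)
  o <- .cl_obs(eta, y, th, deriv = 0L)
  -sum(log(o$p))
}

.cl_grad <- function(par, y, X, K) {
  th <- .th_from_par(par[seq_len(K - 1L)])
  beta <- par[-seq_len(K - 1L)]
  eta <- drop(X %*% beta)
  o <- .cl_obs(eta, y, th, deriv = 1L)
  gb <- -drop(crossprod(X, o$g))
  # accumulate d log p / d theta_k
  dth <- numeric(K - 1L)
  up <- o$fA / o$p           # theta_y is the upper cutpoint (y < K)
  lo <- o$fB / o$p           # theta_{y-1} is the lower cutpoint (y > 1)
  for (k in seq_len(K - 1L)) {
    dth[k] <- sum(up[y == k]) - sum(lo[y == k + 1L])
  }
  gt <- numeric(K - 1L)
  gt[1L] <- -sum(dth)
  if (K > 2L) {
    tpar <- par[seq_len(K - 1L)]
    for (j in 2L:(K - 1L)) gt[j] <- -exp(tpar[j]) * sum(dth[j:(K - 1L)])
  }
  c(gt, gb)
}

# threshold initialization from empirical cumulative frequencies
.th_init <- function(y, K) {
  pr <- tabulate(y, K) / length(y)
  cf <- pmin(pmax(cumsum(pr)[seq_len(K - 1L)], 1e-3), 1 - 1e-3)
  th0 <- stats::qlogis(cf)
  if (K == 2L) th0 else c(th0[1L], log(pmax(diff(th0), 1e-2)))
}

.vgr_control <- function(control = list()) {
  ctl <- list(iter_max = 200L, rel_tol = 1e-8, grad_tol = 1e-6,
              inner_iter = 50L, inner_tol = 1e-8, sigma_floor = 1e-4)
  ctl[names(control)] <- control
  ctl
}

#' Fit the visual grading regression model
#'
#' Fits the cumulative-logit model of relative pairwise scores on the
#' covariate differences built by [prepare_covariates()]. With
#' `random_effects = NULL` the plain likelihood is maximized
#' (quasi-Newton with analytic gradient; covariance from the inverse observed
#' information). With patient and/or observer random intercepts the marginal
#' likelihood is maximized under a Laplace approximation at the joint mode of
#' the crossed random effects.
#'
#' @inheritParams prepare_covariates
#' @param random_effects Character subset of `c("patient", "observer")`, or
#'   `NULL` for a fixed-effects fit.
#' @param control Optional list overriding convergence settings
#'   (`iter_max = 200`, `rel_tol = 1e-8`, `grad_tol = 1e-6`,
#'   `sigma_floor = 1e-4`).
#' @return An object of class `vgr_fit`: `coefficients` (named; `log_mAs` is
#'   the tube-load coefficient `a`, algorithm entries are the `b`s),
#'   `thresholds`, `vcov` (fixed-effect block), `se`, `p_values`, `sigma2`
#'   (random-intercept variances, mixed fits only), `loglik`, `converged`,
#'   `n_obs`, `warnings`.
#' @seealso [dose_reduction_ci()], [tube_load_effect()]
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 15, observers = c("A", "B"),
#'                   criteria = vgr_criteria()[1], n_replicates = 0, seed = 7)
#' fit <- fit_vgr(simulate_study(cfg), criterion = 1,
#'                random_effects = NULL, dose_interval = c(42, 98))
#' coef(fit)
fit_vgr <- function(records, criterion = NULL,
                    random_effects = c("patient", "observer"),
                    dose_interval = NULL, reference_algorithm = NULL,
                    covariates = c("dose", "algorithm"),
                    control = list()) {
  ctl <- .vgr_control(control)
  mf <- prepare_covariates(records, criterion = criterion,
                           dose_interval = dose_interval,
                           reference_algorithm = reference_algorithm,
                           covariates = covariates)
  terms <- attr(mf, "fixed_terms")
  X <- as.matrix(mf[terms])
  # collapse to observed categories (unobserved cutpoints are unidentifiable)
  cats <- sort(unique(mf$y))
  if (length(cats) < 2L)
    stop("degenerate response: all scores identical", call. = FALSE)
  y <- match(mf$y, cats)
  K <- length(cats)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- terms[setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])]
    stop("model matrix rank deficient; offending covariate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  warn <- character()
  crit <- if (!is.null(criterion)) criterion else NA

  if (is.null(random_effects) || !length(random_effects)) {
    res <- .fit_cl_fixed(y, X, K, ctl)
    method <- "fixed"
    sigma2 <- NULL
  } else {
    random_effects <- match.arg(random_effects, c("patient", "observer"),
                                several.ok = TRUE)
    pidx <- as.integer(mf$patient); nP <- nlevels(mf$patient)
    oidx <- as.integer(mf$observer); nO <- nlevels(mf$observer)
    use_p <- "patient" %in% random_effects
    use_o <- "observer" %in% random_effects
    if (use_p && nP < 2L) {
      warn <- c(warn, "patient variance pinned at 0: fewer than 2 patients")
      use_p <- FALSE
    }
    if (use_o && nO < 2L) {
      warn <- c(warn, "observer variance pinned at 0: fewer than 2 observers")
      use_o <- FALSE
    }
    if (!use_p && !use_o) {
      res <- .fit_cl_fixed(y, X, K, ctl)
      method <- "fixed"
      sigma2 <- stats::setNames(rep(0, length(random_effects)), random_effects)
    } else {
      res <- .fit_cl_laplace(y, X, K, pidx, nP, oidx, nO, use_p, use_o, ctl)
      method <- "laplace"
      sigma2 <- res$sigma2
      warn <- c(warn, res$warnings)
      # report pinned-but-requested variances as exact zeros
      for (re in random_effects) if (!re %in% names(sigma2))
        sigma2[re] <- 0
      sigma2 <- sigma2[random_effects]
    }
  }

  beta <- stats::setNames(res$beta, terms)
  se <- stats::setNames(sqrt(pmax(diag(res$vcov_beta), 0)), terms)
  pv <- 2 * stats::pnorm(-abs(beta / se))
  if (any(abs(beta) > 15))
    warn <- c(warn, paste0("possible separation: |coefficient| > 15 for ",
                           paste(terms[abs(beta) > 15], collapse = ", ")))
  structure(list(
    criterion = crit,
    coefficients = beta,
    thresholds = stats::setNames(res$th,
      paste0("theta_", utils::head(cats, -1L) - 3L, "|", cats[-1L] - 3L)),
    vcov = structure(res$vcov_beta, dimnames = list(terms, terms)),
    se = se, p_values = pv,
    sigma2 = sigma2,
    loglik = res$loglik, converged = res$converged,
    n_obs = length(y), method = method,
    reference = attr(mf, "reference"),
    categories = cats - 3L,
    random_effects = if (method == "laplace") res$ranef else NULL,
    warnings = warn), class = "vgr_fit")
}

#' @export
coef.vgr_fit <- function(object, ...) object$coefficients

#' @export
vcov.vgr_fit <- function(object, ...) object$vcov

#' @export
logLik.vgr_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              length(object$thresholds) + length(object$sigma2),
            class = "logLik")
}

#' @export
print.vgr_fit <- function(x, ...) {
  cat(sprintf("<VGR fit> %s, %d records, logLik %.3f%s\n",
              if (x$method == "laplace") "mixed (Laplace)" else "fixed effects",
              x$n_obs, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    p = signif(x$p_values, 3),
                    ` ` = significance_stars(x$p_values),
                    check.names = FALSE)
  print(tab, digits = 4)
  cat("thresholds:", paste(sprintf("%s=%.3f", names(x$thresholds),
                                   x$thresholds), collapse = " "), "\n")
  if (!is.null(x$sigma2))
    cat("random-intercept variances:",
        paste(sprintf("%s=%.4f", names(x$sigma2), x$sigma2), collapse = " "),
        "\n")
  for (w in x$warnings) cat("note:", w, "\n")
  invisible(x)
}

#' Significance stars
#'
#' Renders two-sided p-values at the conventional reporting levels:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, and a degree sign for
#' non-significant results.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "°")))
}

# ---- fixed-effects fit -------------------------------------------------

.fit_cl_fixed <- function(y, X, K, ctl) {
  p <- ncol(X)
  start <- c(.th_init(y, K), rep(0, p))
  opt <- stats::nlminb(start, .cl_nll, .cl_grad, y = y, X = X, K = K,
                       control = list(iter.max = ctl$iter_max,
                                      eval.max = 4L * ctl$iter_max,
                                      rel.tol = ctl$rel_tol))
  # Newton polish: quasi-Newton solutions at tight tolerances can stop with
  # a still-noticeable gradient; a few damped second-order steps finish the job
  par <- opt$par
  nv <- opt$objective
  for (it in seq_len(20L)) {
    gr <- .cl_grad(par, y, X, K)
    if (max(abs(gr)) < 1e-8 * (abs(nv) + 1)) break
    H <- stats::optimHess(par, .cl_nll, .cl_grad, y = y, X = X, K = K)
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step)) break
    tt <- 1
    repeat {
      cand <- par - tt * step
      v <- .cl_nll(cand, y, X, K)
      if (v <= nv + 1e-12 || tt < 1e-4) break
      tt <- tt / 2
    }
    if (v > nv + 1e-12) break
    par <- cand; nv <- v
  }
  gr <- .cl_grad(par, y, X, K)
  converged <- opt$convergence == 0 ||
    max(abs(gr)) < ctl$grad_tol * (abs(nv) + 1)
  if (!converged)
    stop("fixed-effects fit did not converge (", opt$message,
         "; max |gradient| = ", format(max(abs(gr))), ")", call. = FALSE)
  opt <- list(par = par, objective = nv)
  H <- stats::optimHess(opt$par, .cl_nll, .cl_grad, y = y, X = X, K = K)
  V <- tryCatch(solve(H), error = function(e)
    stop("observed information singular (separation or rank deficiency)",
         call. = FALSE))
  bi <- K:(K - 1L + p)
  list(th = .th_from_par(opt$par[seq_len(K - 1L)]),
       beta = opt$par[bi],
       vcov_beta = V[bi, bi, drop = FALSE],
       loglik = -opt$objective, converged = converged)
}

# ---- Laplace-approximated mixed fit ------------------------------------

# inner problem: joint mode of crossed random intercepts given outer params
.laplace_inner <- function(b0, y, X, K, th, beta, pidx, nP, oidx, nO,
                           use_p, use_o, sp2, so2, ctl) {
  q <- use_p * nP + use_o * nO
  b <- b0
  eta_fix <- drop(X %*% beta)
  split_b <- function(b) list(u = if (use_p) b[seq_len(nP)] else numeric(0),
                              v = if (use_o) b[use_p * nP + seq_len(nO)] else numeric(0))
  pen_ll <- function(b) {
    s <- split_b(b)
    eta <- eta_fix +
      (if (use_p) s$u[pidx] else 0) + (if (use_o) s$v[oidx] else 0)
    o <- .cl_obs(eta, y, th, deriv = 0L)
    sum(log(o$p)) - (if (use_p) sum(s$u^2) / (2 * sp2) else 0) -
      (if (use_o) sum(s$v^2) / (2 * so2) else 0)
  }
  ll <- pen_ll(b)
  for (it in seq_len(ctl$inner_iter)) {
    s <- split_b(b)
    eta <- eta_fix +
      (if (use_p) s$u[pidx] else 0) + (if (use_o) s$v[oidx] else 0)
    o <- .cl_obs(eta, y, th, deriv = 2L)
    W <- -o$h                                   # >= 0
    grad <- numeric(q); Hb <- matrix(0, q, q)
    if (use_p) {
      gu <- rowsum(o$g, pidx, reorder = TRUE)[, 1L] - s$u / sp2
      grad[seq_len(nP)] <- gu
      Hb[cbind(seq_len(nP), seq_len(nP))] <-
        rowsum(W, pidx, reorder = TRUE)[, 1L] + 1 / sp2
    }
    if (use_o) {
      off <- use_p * nP
      gv <- rowsum(o$g, oidx, reorder = TRUE)[, 1L] - s$v / so2
      grad[off + seq_len(nO)] <- gv
      Hb[cbind(off + seq_len(nO), off + seq_len(nO))] <-
        rowsum(W, oidx, reorder = TRUE)[, 1L] + 1 / so2
    }
    if (use_p && use_o) {
      cell <- (oidx - 1L) * nP + pidx
      cs <- rowsum(W, cell, reorder = TRUE)
      C <- matrix(0, nP, nO)
      C[as.integer(rownames(cs))] <- cs[, 1L]
      Hb[seq_len(nP), nP + seq_len(nO)] <- C
      Hb[nP + seq_len(nO), seq_len(nP)] <- t(C)
    }
    if (max(abs(grad)) < ctl$inner_tol) break
    R <- tryCatch(chol(Hb), error = function(e) NULL)
    if (is.null(R)) {  # ridge fallback; Hb is PD in exact arithmetic
      R <- chol(Hb + diag(1e-8, q))
    }
    delta <- backsolve(R, forwardsolve(t(R), grad))
    step <- 1
    repeat {
      b_new <- b + step * delta
      ll_new <- pen_ll(b_new)
      if (ll_new >= ll - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    if (ll_new < ll && step < 1e-4) break
    b <- b_new
    if (abs(ll_new - ll) < ctl$inner_tol * (abs(ll) + 1)) { ll <- ll_new; break }
    ll <- ll_new
  }
  # final curvature at the mode
  s <- split_b(b)
  eta <- eta_fix + (if (use_p) s$u[pidx] else 0) + (if (use_o) s$v[oidx] else 0)
  o <- .cl_obs(eta, y, th, deriv = 2L)
  W <- -o$h
  Hb <- matrix(0, q, q)
  if (use_p)
    Hb[cbind(seq_len(nP), seq_len(nP))] <-
      rowsum(W, pidx, reorder = TRUE)[, 1L] + 1 / sp2
  if (use_o) {
    off <- use_p * nP
    Hb[cbind(off + seq_len(nO), off + seq_len(nO))] <-
      rowsum(W, oidx, reorder = TRUE)[, 1L] + 1 / so2
  }
  if (use_p && use_o) {
    cell <- (oidx - 1L) * nP + pidx
    cs <- rowsum(W, cell, reorder = TRUE)
    C <- matrix(0, nP, nO)
    C[as.integer(rownames(cs))] <- cs[, 1L]
    Hb[seq_len(nP), nP + seq_len(nO)] <- C
    Hb[nP + seq_len(nO), seq_len(nP)] <- t(C)
  }
  R <- tryCatch(chol(Hb), error = function(e) chol(Hb + diag(1e-8, q)))
  list(b = b, pen_ll = pen_ll(b), logdet = 2 * sum(log(diag(R))))
}

.fit_cl_laplace <- function(y, X, K, pidx, nP, oidx, nO, use_p, use_o, ctl) {
  p <- ncol(X)
  q <- use_p * nP + use_o * nO
  # initialize from the fixed-effects fit
  fx <- .fit_cl_fixed(y, X, K, ctl)
  tpar0 <- if (K == 2L) fx$th else c(fx$th[1L], log(pmax(diff(fx$th), 1e-3)))
  n_sig <- use_p + use_o
  start <- c(tpar0, fx$beta, rep(log(0.3), n_sig))
  lb <- c(rep(-Inf, K - 1L + p), rep(log(ctl$sigma_floor), n_sig))
  warm <- new.env(parent = emptyenv())
  warm$b <- numeric(q)

  nll_m <- function(par) {
    th <- .th_from_par(par[seq_len(K - 1L)])
    beta <- par[K:(K - 1L + p)]
    ls <- par[(K + p):(K - 1L + p + n_sig)]
    sig <- exp(ls)
    sp2 <- if (use_p) sig[1L]^2 else NA
    so2 <- if (use_o) sig[n_sig]^2 else NA
    inner <- .laplace_inner(warm$b, y, X, K, th, beta, pidx, nP, oidx, nO,
                            use_p, use_o, sp2, so2, ctl)
    warm$b <- inner$b
    # marginal ll = pen_ll(bhat) - nP log sp - nO log so - 0.5 logdet(Hb)
    # (the 2*pi factors of the prior and the Laplace integral cancel)
    -(inner$pen_ll -
        (if (use_p) nP * log(sqrt(sp2)) else 0) -
        (if (use_o) nO * log(sqrt(so2)) else 0) -
        0.5 * inner$logdet)
  }

  opt <- stats::nlminb(start, nll_m, lower = lb,
                       control = list(iter.max = ctl$iter_max,
                                      eval.max = 10L * ctl$iter_max,
                                      rel.tol = ctl$rel_tol))
  if (!opt$convergence %in% c(0L, 1L) &&
      !grepl("converg", opt$message, ignore.case = TRUE))
    stop("mixed-model fit did not converge: ", opt$message, call. = FALSE)
  par <- opt$par
  ls_idx <- (K + p):(K - 1L + p + n_sig)
  pinned <- par[ls_idx] <= log(ctl$sigma_floor) + 1e-6
  warnings <- character()
  sig_names <- c(if (use_p) "patient", if (use_o) "observer")
  if (any(pinned))
    warnings <- paste0(sig_names[pinned],
                       " random-intercept variance pinned at 0 (boundary)")
  free <- c(rep(TRUE, K - 1L + p), !pinned)
  H <- stats::optimHess(par, nll_m)
  Vfree <- tryCatch(solve(H[free, free, drop = FALSE]), error = function(e) {
    warnings <<- c(warnings, "observed information singular; SEs from a ridged inverse")
    solve(H[free, free, drop = FALSE] + diag(1e-6, sum(free)))
  })
  bi_all <- K:(K - 1L + p)
  bi_free <- match(bi_all, which(free))
  vcov_beta <- Vfree[bi_free, bi_free, drop = FALSE]
  sigma2 <- stats::setNames(exp(2 * par[ls_idx]), sig_names)
  sigma2[pinned] <- 0
  # random-effect modes at the optimum (for inspection)
  ranef <- list()
  if (use_p) ranef$patient <- warm$b[seq_len(nP)]
  if (use_o) ranef$observer <- warm$b[use_p * nP + seq_len(nO)]
  list(th = .th_from_par(par[seq_len(K - 1L)]),
       beta = par[bi_all], vcov_beta = vcov_beta,
       sigma2 = sigma2, loglik = -opt$objective,
       converged = TRUE, ranef = ranef, warnings = warnings)
}

#' Predicted category probabilities for comparison pairs
#'
#' @param object A `vgr_fit`.
#' @param newdata Data frame with `left_mAs`, `left_algo`, `right_mAs`,
#'   `right_algo` (e.g. a `vgr_design`).
#' @param ... Unused.
#' @return Matrix (rows = pairs) of probabilities over the observed score
#'   categories; rows sum to 1.
#' @export
predict.vgr_fit <- function(object, newdata, ...) {
  beta <- object$coefficients
  eta <- numeric(nrow(newdata))
  if ("log_mAs" %in% names(beta))
    eta <- eta + beta[["log_mAs"]] *
      (log(newdata$right_mAs) - log(newdata$left_mAs))
  for (g in setdiff(names(beta), "log_mAs"))
    eta <- eta + beta[[g]] *
      (as.numeric(newdata$right_algo == g) - as.numeric(newdata$left_algo == g))
  pr <- .cat_probs(eta, unname(object$thresholds))
  colnames(pr) <- object$categories
  pr
}

#' Tube-load effect within one reconstruction algorithm
#'
#' Fits the log-tube-load-only VGR model on the subset of records comparing
#' the two given tube loads within a single algorithm — the per-algorithm
#' dose-dependence analysis.
#'
#' @inheritParams fit_vgr
#' @param algorithm Algorithm whose within-algorithm dose pairs are used.
#' @param dose_pair Length-2 vector of tube loads, e.g. `c(42, 98)`.
#' @return A `vgr_fit` with the single coefficient `log_mAs`.
#' @export
tube_load_effect <- function(records, algorithm, dose_pair = c(42, 98),
                             criterion = NULL,
                             random_effects = c("patient", "observer"),
                             control = list()) {
  records <- as.data.frame(records)
  dp <- sort(dose_pair)
  keep <- records$left_algo == algorithm & records$right_algo == algorithm &
    pmin(records$left_mAs, records$right_mAs) == dp[1L] &
    pmax(records$left_mAs, records$right_mAs) == dp[2L]
  sub <- records[keep, , drop = FALSE]
  if (!nrow(sub))
    stop("no records compare ", dp[1L], " vs ", dp[2L], " mAs within ",
         algorithm, call. = FALSE)
  fit_vgr(sub, criterion = criterion, random_effects = random_effects,
          covariates = "dose", control = control)
}
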