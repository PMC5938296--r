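# Potential dose reduction from VGR coefficients: DR = 1 - exp(-b/a), where
# a is the log-tube-load coefficient and b the algorithm coefficient. DR is
# the fraction by which tube load could be cut, when switching to the
# algorithm, at equal perceived image quality: the algorithm benefit b on
# the latent scale is traded against the dose benefit a per log mAs unit.

#' Potential dose reduction
#'
#' `DR = 1 - exp(-b/a)`. Negative when `b < 0` (the algorithm change would
#' *require* extra dose); strictly increasing in `b` for fixed `a > 0`; and
#' `DR < 1` for any finite ratio. Requires `a > 0`: when perceived quality
#' does not improve with tube load, trading quality for dose is undefined.
#'
#' @param a Regression coefficient for natural-log tube load (positive).
#' @param b Regression coefficient for the algorithm change (vectorized).
#' @return Dose reduction as a proportion.
#' @export
#' @examples
#' dose_reduction(2.28, 0.57)   # 0.2212 -> "22%"
#' dose_reduction(1.88, -0.98)  # -0.684 -> "-68%"
dose_reduction <- function(a, b) {
  if (any(a <= 0))
    stop("dose reduction undefined: `a` <= 0 means image quality does not ",
         "increase with tube load", call. = FALSE)
  1 - exp(-b / a)
}

#' Dose reduction as a rounded integer percentage
#'
#' Rendering helper matching how DR values are reported: nearest integer
#' per cent (half away from zero).
#'
#' @inheritParams dose_reduction
#' @return Integer percentage.
#' @export
dose_reduction_percent <- function(a, b) {
  dr <- 100 * dose_reduction(a, b)
  as.integer(sign(dr) * floor(abs(dr) + 0.5))
}

#' Confidence interval for a dose-reduction estimate
#'
#' Propagates the joint uncertainty of `(a, b)` from a fitted VGR model to
#' `DR = 1 - exp(-b/a)`. Three methods:
#' \describe{
#'   \item{delta}{first-order variance of the ratio `r = b/a`; the Wald
#'     interval on `r` is mapped through the monotone transform
#'     `1 - exp(-r)`, so the endpoints map directly.}
#'   \item{fieller}{exact ratio interval solving the Fieller quadratic in
#'     `r`, mapped likewise; when the denominator `a` is not significantly
#'     positive the interval is unbounded and reported as such (infinite
#'     endpoints), never silently truncated.}
#'   \item{bootstrap}{parametric resampling of `(a, b)` from the fitted
#'     Gaussian; percentile interval of DR; reproducible via `seed`.}
#' }
#'
#' @param fit A converged `vgr_fit` containing the `log_mAs` coefficient.
#' @param algorithm Which algorithm coefficient to use as `b`.
#' @param level Confidence level in (0, 1).
#' @param method `"delta"` (default), `"fieller"` or `"bootstrap"`.
#' @param n_boot Bootstrap draws.
#' @param seed Seed for the bootstrap.
#' @return A list of class `vgr_dr`: `dr`, `ci_low`, `ci_high`, `level`,
#'   `ci_method`, `algorithm`, `criterion`, `p_value` (Wald p of `b`) and
#'   `significant` (at 0.05; mirrors the reporting convention of suppressing
#'   DR for non-significant `b`).
#' @export
dose_reduction_ci <- function(fit, algorithm, level = 0.95,
                              method = c("delta", "fieller", "bootstrap"),
                              n_boot = 10000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "vgr_fit"), level > 0, level < 1)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  cf <- fit$coefficients
  if (!"log_mAs" %in% names(cf))
    stop("fit lacks the log tube-load coefficient", call. = FALSE)
  if (!algorithm %in% names(cf))
    stop("no coefficient for algorithm '", algorithm, "' in fit", call. = FALSE)
  a <- cf[["log_mAs"]]; b <- cf[[algorithm]]
  V <- fit$vcov[c("log_mAs", algorithm), c("log_mAs", algorithm)]
  va <- V[1L, 1L]; vb <- V[2L, 2L]; vab <- V[1L, 2L]
  if (method != "bootstrap" && a <= 0)
    stop("dose reduction undefined: `a` <= 0", call. = FALSE)
  dr <- dose_reduction(a, b)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    r <- b / a
    vr <- vb / a^2 + b^2 * va / a^4 - 2 * b * vab / a^3
    lo_r <- r - z * sqrt(max(vr, 0)); hi_r <- r + z * sqrt(max(vr, 0))
    ci <- c(1 - exp(-lo_r), 1 - exp(-hi_r))
  } else if (method == "fieller") {
    # (b - r a)^2 = z^2 (vb - 2 r vab + r^2 va), quadratic in r
    A <- a^2 - z^2 * va
    B <- -2 * (a * b - z^2 * vab)
    C <- b^2 - z^2 * vb
    disc <- B^2 - 4 * A * C
    if (A <= 0 || disc < 0) {
      ci <- c(-Inf, Inf)   # a not significantly positive: unbounded
    } else {
      roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
      ci <- 1 - exp(-roots)
    }
  } else {
    draws <- .with_seed(if (is.null(seed)) 1L else seed,
                        MASS::mvrnorm(n_boot, c(a, b), V))
    keep <- draws[, 1L] > 0
    if (!all(keep))
      warning(sum(!keep), " bootstrap draws with a <= 0 discarded")
    dr_draws <- 1 - exp(-draws[keep, 2L] / draws[keep, 1L])
    ci <- unname(stats::quantile(dr_draws, c((1 - level) / 2,
                                             1 - (1 - level) / 2)))
  }
  structure(list(dr = dr, ci_low = ci[1L], ci_high = ci[2L], level = level,
                 ci_method = method, algorithm = algorithm,
                 criterion = fit$criterion,
                 p_value = fit$p_values[[algorithm]],
                 significant = fit$p_values[[algorithm]] < 0.05),
            class = "vgr_dr")
}

#' @export
print.vgr_dr <- function(x, ...) {
  cat(sprintf("<dose reduction> %s: %.1f%% (%g%% CI %.1f%%; %.1f%%) [%s]%s\n",
              x$algorithm, 100 * x$dr, 100 * x$level, 100 * x$ci_low,
              100 * x$ci_high, x$ci_method,
              if (!x$significant) " — b not significant at 0.05" else ""))
  invisible(x)
}

#' Per-criterion table of VGR coefficients and dose reductions
#'
#' Fits the VGR model for each criterion on the configured dose interval and
#' tabulates the tube-load coefficient `a`, the algorithm coefficients `b`
#' with significance stars, and the corresponding dose-reduction estimates
#' with confidence intervals. DR cells whose `b` is not significant at 0.05
#' are suppressed in the rendered column (the customary long-dash convention)
#' while the numeric estimate stays available in the `dr_<algo>` column.
#'
#' @inheritParams fit_vgr
#' @param criteria Integer criteria to analyse (default: all present).
#' @param level Confidence level for the DR intervals.
#' @param ci_method CI method passed to [dose_reduction_ci()].
#' @return Data frame, one row per criterion, with attribute `errors` (named
#'   list of per-criterion fitting errors, which do not abort the rest).
#' @export
dr_table <- function(records, criteria = NULL,
                     random_effects = c("patient", "observer"),
                     dose_interval = c(42, 98), reference_algorithm = NULL,
                     level = 0.95, ci_method = "delta", control = list()) {
  records <- as.data.frame(records)
  if (is.null(criteria)) criteria <- sort(unique(records$criterion))
  crit_names <- vgr_criteria()
  errors <- list()
  rows <- lapply(criteria, function(cr) {
    fit <- tryCatch(
      fit_vgr(records, criterion = cr, random_effects = random_effects,
              dose_interval = dose_interval,
              reference_algorithm = reference_algorithm, control = control),
      error = function(e) e)
    if (inherits(fit, "error")) {
      errors[[as.character(cr)]] <<- conditionMessage(fit)
      return(NULL)
    }
    algos <- setdiff(names(fit$coefficients), "log_mAs")
    row <- data.frame(
      criterion = cr,
      label = if (cr %in% crit_names) names(crit_names)[match(cr, crit_names)]
              else as.character(cr),
      a = fit$coefficients[["log_mAs"]],
      a_stars = significance_stars(fit$p_values[["log_mAs"]]))
    for (g in algos) {
      est <- dose_reduction_ci(fit, g, level = level, method = ci_method)
      row[[paste0("b_", g)]] <- fit$coefficients[[g]]
      row[[paste0("b_", g, "_stars")]] <- significance_stars(fit$p_values[[g]])
      row[[paste0("dr_", g)]] <- est$dr
      row[[paste0("dr_", g, "_low")]] <- est$ci_low
      row[[paste0("dr_", g, "_high")]] <- est$ci_high
      row[[paste0("dr_", g, "_display")]] <- if (est$significant)
        sprintf("%d%% (%d%%; %d%%)", round(100 * est$dr),
                round(100 * est$ci_low), round(100 * est$ci_high))
      else "−"
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  attr(out, "errors") <- errors
  out
}

#' Reference VGR coefficients from a published abdominal-CT observer study
#'
#' Bundled coefficient sets from a published visual-grading study of
#' abdominal CT comparing filtered back projection with iterative
#' reconstruction (ADMIRE strengths 3 and 5) over the 42-98 quality-reference
#' mAs interval: the log-tube-load coefficient `a` and algorithm coefficient
#' `b` per criterion, for the IR-vs-FBP and IR5-vs-IR3 analyses. Useful as
#' worked examples for [dose_reduction()] without refitting.
#'
#' @return Data frame with columns `comparison` (`"IR_vs_FBP"` or
#'   `"IR5_vs_IR3"`), `criterion`, `label`, `algorithm`, `a`, `b`,
#'   `b_significant`.
#' @export
published_coefficients <- function() {
  path <- system.file("extdata", "admire_vgr_coefficients.csv",
                      package = "vgrkit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
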