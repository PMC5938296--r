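# Observer reliability: weighted kappa on the ordinal -2..+2 scale, for
# inter-observer (shared cells, original assessments) and intra-observer
# (original vs replicate presentations) comparisons.

#' Weighted kappa for two sets of ordered ratings
#'
#' Builds the square contingency table over the ordered categories,
#' applies disagreement weights `|i - j| / (K - 1)` (linear) or
#' `((i - j) / (K - 1))^2` (quadratic), and computes
#' `kappa_w = 1 - sum(w * observed) / sum(w * expected)` with expectation
#' under independence of the two margins. The confidence interval uses the
#' standard large-sample variance of the weighted kappa (Fleiss, Cohen &
#' Everitt); percent agreement is the exact-match fraction.
#'
#' @param x,y Equal-length vectors of ratings on the same ordered categorical
#'   scale.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @param categories The full ordered category set (positions on the scale
#'   matter for the weights); defaults to `-2:2`, the pairwise grading scale.
#' @param level Confidence level.
#' @return A list of class `vgr_kappa`: `kappa_w`, `ci_low`, `ci_high`,
#'   `se`, `percent_agreement`, `weights`, `n`, `undefined` (TRUE when both
#'   raters used fewer than 2 categories, where chance correction is
#'   undefined).
#' @export
#' @examples
#' weighted_kappa(c(-1, 0, 1, 2), c(-1, 0, 1, 2))  # kappa 1, agreement 100
weighted_kappa <- function(x, y, weights = c("linear", "quadratic"),
                           categories = -2:2, level = 0.95) {
  weights <- match.arg(weights)
  if (length(x) != length(y))
    stop("rating vectors differ in length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 paired ratings", call. = FALSE)
  if (!all(x %in% categories) || !all(y %in% categories))
    stop("ratings outside the category set", call. = FALSE)
  K <- length(categories)
  pos <- seq_len(K)
  dis <- abs(outer(pos, pos, `-`)) / (K - 1)
  if (weights == "quadratic") dis <- dis^2
  tab <- table(factor(x, levels = categories),
               factor(y, levels = categories)) / n
  pr <- rowSums(tab); pc <- colSums(tab)
  exp_tab <- outer(pr, pc)
  undefined <- (sum(pr > 0) < 2L) && (sum(pc > 0) < 2L)
  if (undefined) {
    kw <- NA_real_; se <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    kw <- 1 - sum(dis * tab) / sum(dis * exp_tab)
    # large-sample variance in the agreement-weight form
    w <- 1 - dis
    po <- sum(w * tab); pe <- sum(w * exp_tab)
    wr <- drop(w %*% pc)     # average agreement weight of row category i
    wc <- drop(t(w) %*% pr)  # and of column category j
    # Fleiss-Cohen-Everitt: sum p_ij [w_ij - (wr_i + wc_j)(1 - k)]^2 -
    #                       [k - pe(1 - k)]^2, all over n (1 - pe)^2
    inner <- (w - outer(wr, wc, `+`) * (1 - kw))^2
    var_k <- (sum(tab * inner) - (kw - pe * (1 - kw))^2) / (n * (1 - pe)^2)
    se <- sqrt(max(var_k, 0))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- kw + c(-1, 1) * z * se
  }
  structure(list(kappa_w = kw, ci_low = ci[1L], ci_high = ci[2L], se = se,
                 percent_agreement = 100 * mean(x == y), weights = weights,
                 n = n, level = level, undefined = undefined),
            class = "vgr_kappa")
}

#' @export
print.vgr_kappa <- function(x, ...) {
  if (x$undefined) {
    cat("<weighted kappa> undefined (fewer than 2 categories used by both raters);",
        sprintf("agreement %.1f%% on n = %d\n", x$percent_agreement, x$n))
  } else {
    cat(sprintf("<weighted kappa> %s weights: %.3f (%g%% CI %.3f; %.3f), agreement %.1f%%, n = %d\n",
                x$weights, x$kappa_w, 100 * x$level, x$ci_low, x$ci_high,
                x$percent_agreement, x$n))
  }
  invisible(x)
}

#' Within-one-category agreement
#'
#' Fraction of paired ratings differing by at most one category. Kept
#' separate from the exact-match percent agreement reported by
#' [weighted_kappa()]; the two are never conflated.
#'
#' @inheritParams weighted_kappa
#' @return Percentage in 0-100.
#' @export
within_one_agreement <- function(x, y) {
  if (length(x) != length(y))
    stop("rating vectors differ in length", call. = FALSE)
  100 * mean(abs(x - y) <= 1)
}

#' Inter-observer reliability summary
#'
#' Weighted kappa for every pair of observers on their shared
#' (patient, pair, criterion) cells, using original assessments only
#' (`replicate_index == 0`). Records are first brought to a canonical
#' left/right orientation (scores sign-flipped as needed) so that
#' differently-randomized hangings remain comparable. Observer pairs with no
#' shared cells are skipped with a notice.
#'
#' @param records Grading-record data frame.
#' @param weights Kappa weighting scheme.
#' @return Data frame (one row per observer pair: `observer_1`, `observer_2`,
#'   `n`, `kappa_w`, `ci_low`, `ci_high`, `percent_agreement`) with
#'   attributes `range` (min/max kappa and agreement) and `skipped`.
#' @export
interobserver_summary <- function(records, weights = "linear") {
  rec <- canonicalize_records(as.data.frame(records))
  rec <- rec[rec$replicate_index == 0, , drop = FALSE]
  obs <- sort(unique(rec$observer_id))
  if (length(obs) < 2L)
    stop("need at least 2 observers", call. = FALSE)
  rec$cell <- paste(rec$patient_id, rec$criterion,
                    .cond_key(rec$left_mAs, rec$left_algo),
                    .cond_key(rec$right_mAs, rec$right_algo), sep = "/")
  pairs <- utils::combn(obs, 2L)
  skipped <- character()
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    o1 <- pairs[1L, k]; o2 <- pairs[2L, k]
    r1 <- rec[rec$observer_id == o1, c("cell", "score")]
    r2 <- rec[rec$observer_id == o2, c("cell", "score")]
    m <- merge(r1, r2, by = "cell", suffixes = c("_1", "_2"))
    if (!nrow(m)) {
      skipped <<- c(skipped, paste(o1, o2, sep = " vs "))
      return(NULL)
    }
    kp <- weighted_kappa(m$score_1, m$score_2, weights = weights)
    data.frame(observer_1 = o1, observer_2 = o2, n = kp$n,
               kappa_w = kp$kappa_w, ci_low = kp$ci_low, ci_high = kp$ci_high,
               percent_agreement = kp$percent_agreement)
  })
  if (length(skipped))
    message("skipped observer pair(s) with no shared cells: ",
            paste(skipped, collapse = "; "))
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  ok <- nrow(out) > 0 && any(!is.na(out$kappa_w))
  attr(out, "range") <- if (ok) list(
    kappa_min = min(out$kappa_w, na.rm = TRUE),
    kappa_max = max(out$kappa_w, na.rm = TRUE),
    agreement_min = min(out$percent_agreement),
    agreement_max = max(out$percent_agreement)) else NULL
  attr(out, "skipped") <- skipped
  out
}

#' Intra-observer reliability summary
#'
#' Pairs each replicated presentation (`replicate_index >= 1`) with its
#' original (same patient, observer, pair, criterion) and computes a weighted
#' kappa and percent agreement per observer, pooled over criteria.
#'
#' @inheritParams interobserver_summary
#' @return Data frame (one row per observer with replicates: `observer`,
#'   `n`, `kappa_w`, `ci_low`, `ci_high`, `percent_agreement`). When no
#'   replicates exist, an empty data frame with a message.
#' @export
intraobserver_summary <- function(records, weights = "linear") {
  rec <- canonicalize_records(as.data.frame(records))
  rep_rows <- rec[rec$replicate_index >= 1, , drop = FALSE]
  if (!nrow(rep_rows)) {
    message("no replicated assessments (replicate_index >= 1) in records")
    return(data.frame())
  }
  orig <- rec[rec$replicate_index == 0, , drop = FALSE]
  key <- function(r) paste(r$patient_id, r$observer_id, r$criterion,
                           .cond_key(r$left_mAs, r$left_algo),
                           .cond_key(r$right_mAs, r$right_algo), sep = "/")
  orig$key <- key(orig); rep_rows$key <- key(rep_rows)
  m <- merge(orig[c("key", "observer_id", "score")],
             rep_rows[c("key", "score")], by = "key",
             suffixes = c("_orig", "_rep"))
  rows <- lapply(split(m, m$observer_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    kp <- weighted_kappa(d$score_orig, d$score_rep, weights = weights)
    data.frame(observer = d$observer_id[1L], n = kp$n, kappa_w = kp$kappa_w,
               ci_low = kp$ci_low, ci_high = kp$ci_high,
               percent_agreement = kp$percent_agreement)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Favourable-versus-unfavourable score distribution for one image condition
#'
#' For every record in which the condition appears, takes the score as
#' assigned *to that condition*: as-is when the condition was hung on the
#' right (positive scores favour the right image) and negated when on the
#' left. Tabulates the resulting percentages over scores -2..+2.
#'
#' @param records Grading-record data frame.
#' @param tube_load,algorithm The image condition.
#' @return A list of class `vgr_score_distribution`: `percent` (named
#'   5-vector summing to 100), `counts`, `n`, `tube_load`, `algorithm`.
#' @export
score_distribution <- function(records, tube_load, algorithm) {
  rec <- as.data.frame(records)
  on_right <- rec$right_mAs == tube_load & rec$right_algo == algorithm
  on_left <- rec$left_mAs == tube_load & rec$left_algo == algorithm
  if (!any(on_right | on_left))
    stop("condition ", tube_load, " mAs / ", algorithm,
         " absent from records", call. = FALSE)
  sc <- c(rec$score[on_right], -rec$score[on_left])
  counts <- table(factor(sc, levels = -2:2))
  structure(list(percent = 100 * as.numeric(counts) / length(sc),
                 counts = as.integer(counts), n = length(sc),
                 tube_load = tube_load, algorithm = algorithm,
                 scores = -2:2),
            class = "vgr_score_distribution")
}

#' @export
print.vgr_score_distribution <- function(x, ...) {
  cat(sprintf("<score distribution> %g mAs / %s (n = %d assessments)\n",
              x$tube_load, x$algorithm, x$n))
  print(stats::setNames(sprintf("%.1f%%", x$percent), x$scores), quote = FALSE)
  invisible(x)
}

#' @export
plot.vgr_score_distribution <- function(x, ...) {
  graphics::barplot(stats::setNames(x$percent, x$scores),
                    xlab = "score assigned to the image type",
                    ylab = "percentage of assessments",
                    main = sprintf("%g mAs / %s", x$tube_load, x$algorithm),
                    ...)
  invisible(x)
}
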