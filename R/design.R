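# Comparison design: which image conditions (tube load x reconstruction
# algorithm) are hung against each other for pairwise grading.

#' Image-quality grading criteria
#'
#' The six anatomical/technical criteria used in abdominal CT visual grading,
#' registered as integers 1-6 with display names. The set is configurable in
#' every function that takes a `criteria` argument; these are the defaults.
#'
#' @return Named integer vector; names are display labels.
#' @export
#' @examples
#' vgr_criteria()
vgr_criteria <- function() {
  stats::setNames(1:6, c(
    "Liver parenchyma",
    "Pancreatic contours",
    "Kidneys and proximal ureters",
    "Lymph nodes < 15 mm",
    "Image noise",
    "Overall image quality"
  ))
}

#' Construct an image condition
#'
#' An image condition labels one reconstructed image stack by its quality
#' reference tube load (Qref mAs) and reconstruction algorithm.
#'
#' @param tube_load Positive tube load in quality-reference mAs.
#' @param algorithm Algorithm label, e.g. `"FBP"`, `"IR3"`, `"IR5"`.
#' @param algorithms Registered algorithm set; `algorithm` must belong to it.
#' @param tube_loads Registered tube loads; used to derive `dose_fraction`
#'   (percent of the maximum registered tube load).
#' @return A list of class `vgr_condition` with fields `tube_load`,
#'   `algorithm` and `dose_fraction`.
#' @export
#' @examples
#' image_condition(98, "IR3")
image_condition <- function(tube_load, algorithm,
                            algorithms = c("FBP", "IR3", "IR5"),
                            tube_loads = c(42, 98, 140)) {
  if (!is.numeric(tube_load) || length(tube_load) != 1L || tube_load <= 0)
    stop("`tube_load` must be a single positive number", call. = FALSE)
  if (!algorithm %in% algorithms)
    stop("unregistered algorithm '", algorithm, "' (registered: ",
         paste(algorithms, collapse = ", "), ")", call. = FALSE)
  structure(
    list(tube_load = tube_load, algorithm = algorithm,
         dose_fraction = 100 * tube_load / max(tube_loads)),
    class = "vgr_condition")
}

#' @export
print.vgr_condition <- function(x, ...) {
  cat(sprintf("<image condition> %g mAs, %s (%.0f%% of full tube load)\n",
              x$tube_load, x$algorithm, x$dose_fraction))
  invisible(x)
}

# canonical string key for a condition, used for duplicate/mirror checks
.cond_key <- function(mAs, algo) sprintf("%012.4f|%s", mAs, algo)

#' Default 12-pair comparison design
#'
#' Builds the pairwise comparison design over three tube loads and three
#' reconstruction algorithms: for each algorithm the two adjacent dose pairs
#' (42 vs 98 and 98 vs 140 mAs), plus the three between-algorithm pairs
#' (FBP vs IR3, FBP vs IR5, IR3 vs IR5) at each of the two lower tube loads
#' — 12 pairs in total. Left/right presentation side is *not* part of the
#' design: blinding randomization happens at simulation/presentation time,
#' so the design object is deterministic.
#'
#' @param tube_loads Three increasing tube loads (quality-reference mAs).
#' @param algorithms Algorithm labels; first element is the reference level.
#' @return A data frame of class `vgr_design` with columns `left_mAs`,
#'   `left_algo`, `right_mAs`, `right_algo`; attributes `tube_loads`,
#'   `algorithms` and `reference`.
#' @export
#' @examples
#' d <- default_design()
#' nrow(d)  # 12
default_design <- function(tube_loads = c(42, 98, 140),
                           algorithms = c("FBP", "IR3", "IR5")) {
  stopifnot(length(tube_loads) == 3L, all(diff(tube_loads) > 0),
            length(algorithms) == 3L, !anyDuplicated(algorithms))
  lo <- tube_loads[1]; mid <- tube_loads[2]; hi <- tube_loads[3]
  within_algo <- do.call(rbind, lapply(algorithms, function(g)
    data.frame(left_mAs  = c(lo, mid), left_algo  = g,
               right_mAs = c(mid, hi), right_algo = g)))
  algo_pairs <- utils::combn(algorithms, 2L)
  cross_algo <- do.call(rbind, lapply(c(lo, mid), function(q)
    data.frame(left_mAs  = q, left_algo  = algo_pairs[1L, ],
               right_mAs = q, right_algo = algo_pairs[2L, ])))
  vgr_design(rbind(within_algo, cross_algo),
             tube_loads = tube_loads, algorithms = algorithms)
}

#' Construct and validate a comparison design
#'
#' @param pairs Data frame with columns `left_mAs`, `left_algo`, `right_mAs`,
#'   `right_algo`, one row per comparison pair.
#' @param tube_loads,algorithms Registered condition sets; every condition
#'   referenced by a pair must be registered. First algorithm is the
#'   reference level.
#' @return The validated `vgr_design` object.
#' @export
vgr_design <- function(pairs, tube_loads = sort(unique(c(pairs$left_mAs, pairs$right_mAs))),
                       algorithms = unique(c(pairs$left_algo, pairs$right_algo))) {
  need <- c("left_mAs", "left_algo", "right_mAs", "right_algo")
  if (!all(need %in% names(pairs)))
    stop("design needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  pairs <- as.data.frame(pairs)[need]
  if (any(pairs$left_mAs <= 0) || any(pairs$right_mAs <= 0))
    stop("tube loads must be positive", call. = FALSE)
  bad_algo <- setdiff(unique(c(pairs$left_algo, pairs$right_algo)), algorithms)
  if (length(bad_algo))
    stop("unregistered algorithm(s): ", paste(bad_algo, collapse = ", "), call. = FALSE)
  bad_load <- setdiff(unique(c(pairs$left_mAs, pairs$right_mAs)), tube_loads)
  if (length(bad_load))
    stop("unregistered tube load(s): ", paste(bad_load, collapse = ", "), call. = FALSE)
  lk <- .cond_key(pairs$left_mAs, pairs$left_algo)
  rk <- .cond_key(pairs$right_mAs, pairs$right_algo)
  if (any(lk == rk))
    stop("a comparison pair must differ in tube load, algorithm, or both",
         call. = FALSE)
  unordered <- paste(pmin(lk, rk), pmax(lk, rk))
  if (anyDuplicated(unordered))
    stop("duplicate pairs in design (a pair and its mirror count as one)",
         call. = FALSE)
  structure(pairs, class = c("vgr_design", "data.frame"),
            tube_loads = tube_loads, algorithms = algorithms,
            reference = algorithms[1L])
}

#' @export
print.vgr_design <- function(x, ...) {
  cat(sprintf("<comparison design> %d pairs over tube loads {%s} mAs x algorithms {%s} (reference %s)\n",
              nrow(x), paste(attr(x, "tube_loads"), collapse = ", "),
              paste(attr(x, "algorithms"), collapse = ", "),
              attr(x, "reference")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read / write a comparison design as YAML
#'
#' @param design A `vgr_design`.
#' @param path File path.
#' @return `read_design` returns a `vgr_design`; `write_design` returns
#'   `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "vgr_design"))
  yaml::write_yaml(list(
    tube_loads = attr(design, "tube_loads"),
    algorithms = as.list(attr(design, "algorithms")),
    pairs = lapply(seq_len(nrow(design)), function(i) list(
      left  = list(tube_load = design$left_mAs[i],  algorithm = design$left_algo[i]),
      right = list(tube_load = design$right_mAs[i], algorithm = design$right_algo[i])))),
    path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- yaml::read_yaml(path)
  pairs <- do.call(rbind, lapply(d$pairs, function(p) data.frame(
    left_mAs = p$left$tube_load, left_algo = p$left$algorithm,
    right_mAs = p$right$tube_load, right_algo = p$right$algorithm)))
  vgr_design(pairs, tube_loads = unlist(d$tube_loads),
             algorithms = unlist(d$algorithms))
}
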