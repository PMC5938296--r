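# Grading records: one row per (patient, observer, criterion, image pair)
# ordinal assessment on the relative -2..+2 scale, plus CSV serialization
# and structural validation against a design.

.record_cols <- c("patient_id", "observer_id", "criterion",
                  "left_mAs", "left_algo", "right_mAs", "right_algo",
                  "score", "replicate_index")

#' Read grading records from CSV
#'
#' Comma-separated, UTF-8, header required. Mandatory columns:
#' `patient_id`, `observer_id`, `criterion`, `left_mAs`, `left_algo`,
#' `right_mAs`, `right_algo`, `score`, `replicate_index`. Scores are parsed
#' as signed integers; any extra columns are preserved untouched.
#'
#' @param path Path to the CSV file.
#' @return Data frame of grading records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing <- setdiff(.record_cols, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  parse_int <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("malformed value '%s' in field '%s' at line %d of %s",
                   raw[[col]][bad[1L]], col, bad[1L] + 1L, path), call. = FALSE)
    v
  }
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("malformed value '%s' in field '%s' at line %d of %s",
                   raw[[col]][bad[1L]], col, bad[1L] + 1L, path), call. = FALSE)
    v
  }
  out <- raw
  out$criterion <- parse_int("criterion")
  out$score <- parse_int("score")
  out$replicate_index <- parse_int("replicate_index")
  out$left_mAs <- parse_num("left_mAs")
  out$right_mAs <- parse_num("right_mAs")
  out[c(.record_cols, setdiff(names(out), .record_cols))]
}

#' Write grading records to CSV
#'
#' Inverse of [read_records()]: `read_records(write_records(x, p))` is the
#' identity on valid records. Extra columns are written through.
#'
#' @param records Grading-record data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  missing <- setdiff(.record_cols, names(records))
  if (length(missing))
    stop("records lack mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate grading records against a design
#'
#' Reports (never raises) out-of-range scores, unknown criteria, pairs not in
#' the design (left/right mirror images of design pairs are accepted), and
#' per-cell completeness over patients x observers x pairs x criteria.
#' Original assessments (`replicate_index == 0`) define the completeness and
#' bookkeeping counts; replicates are counted separately.
#'
#' @param records Grading-record data frame.
#' @param design A `vgr_design` (default [default_design()]).
#' @param criteria Registered criterion set (default [vgr_criteria()]).
#' @return A list of class `vgr_validation`: `counts` (records, patients,
#'   observers, image pairs per observer, pair assessments across observers,
#'   replicate rows, missing cells) and `violations` (data frame with `row`,
#'   `field`, `problem`).
#' @export
validate_records <- function(records, design = default_design(),
                             criteria = vgr_criteria()) {
  records <- as.data.frame(records)
  n <- nrow(records)
  viol <- list()
  flag <- function(rows, field, problem) {
    if (length(rows))
      viol[[length(viol) + 1L]] <<- data.frame(row = rows, field = field,
                                               problem = problem)
  }
  if (n) {
    flag(which(!records$score %in% (-2:2)), "score",
         "score outside the 5-point scale -2..+2")
    flag(which(!records$criterion %in% criteria), "criterion",
         "criterion not in the registered set")
    flag(which(records$replicate_index < 0), "replicate_index",
         "negative replicate index")
    dk <- paste(pmin(.cond_key(design$left_mAs, design$left_algo),
                     .cond_key(design$right_mAs, design$right_algo)),
                pmax(.cond_key(design$left_mAs, design$left_algo),
                     .cond_key(design$right_mAs, design$right_algo)))
    lk <- .cond_key(records$left_mAs, records$left_algo)
    rk <- .cond_key(records$right_mAs, records$right_algo)
    rkey <- paste(pmin(lk, rk), pmax(lk, rk))
    flag(which(!rkey %in% dk), "pair",
         "comparison pair absent from the design (including its mirror)")
  }
  violations <- if (length(viol)) {
    v <- do.call(rbind, viol)
    v[order(v$row), , drop = FALSE]
  } else data.frame(row = integer(), field = character(), problem = character())

  orig <- records[n > 0 & records$replicate_index == 0, , drop = FALSE]
  pair_id <- if (nrow(orig)) paste(pmin(.cond_key(orig$left_mAs, orig$left_algo),
                                        .cond_key(orig$right_mAs, orig$right_algo)),
                                   pmax(.cond_key(orig$left_mAs, orig$left_algo),
                                        .cond_key(orig$right_mAs, orig$right_algo)))
             else character()
  # a "pair assessment" = one hanging graded by one observer (all criteria)
  pa <- if (nrow(orig)) unique(data.frame(patient = orig$patient_id,
                                          observer = orig$observer_id,
                                          pair = pair_id))
        else data.frame(patient = character(), observer = character(),
                        pair = character())
  per_obs <- if (nrow(pa)) table(pa$observer) else table(character())
  n_cells_expected <- length(unique(orig$patient_id)) *
    length(unique(orig$observer_id)) * nrow(design) * length(criteria)
  cell <- if (nrow(orig)) unique(paste(orig$patient_id, orig$observer_id,
                                       pair_id, orig$criterion))
          else character()
  structure(list(
    counts = list(
      n_records = n,
      n_original = nrow(orig),
      n_replicate_rows = n - nrow(orig),
      n_patients = length(unique(records$patient_id)),
      n_observers = length(unique(records$observer_id)),
      pairs_per_observer = per_obs,
      n_pair_assessments = nrow(pa),
      n_cells_expected = n_cells_expected,
      n_cells_present = length(cell),
      n_cells_missing = max(0L, n_cells_expected - length(cell))),
    violations = violations), class = "vgr_validation")
}

#' @export
print.vgr_validation <- function(x, ...) {
  cts <- x$counts
  cat("<grading-record validation>\n")
  cat(sprintf("  records: %d (%d original, %d replicate rows)\n",
              cts$n_records, cts$n_original, cts$n_replicate_rows))
  cat(sprintf("  patients: %d  observers: %d\n", cts$n_patients, cts$n_observers))
  if (length(cts$pairs_per_observer))
    cat(sprintf("  image pairs per observer: %s\n",
                paste(sprintf("%s=%d", names(cts$pairs_per_observer),
                              as.integer(cts$pairs_per_observer)), collapse = " ")))
  cat(sprintf("  pair assessments across observers: %d\n", cts$n_pair_assessments))
  cat(sprintf("  completeness: %d / %d cells present (%d missing)\n",
              cts$n_cells_present, cts$n_cells_expected, cts$n_cells_missing))
  if (nrow(x$violations)) {
    cat(sprintf("  violations: %d\n", nrow(x$violations)))
    print(utils::head(x$violations, 10L))
  } else cat("  violations: none\n")
  invisible(x)
}

# Canonical orientation: order the two conditions of each record by the
# deterministic condition key, negating the score when sides are swapped.
# Makes ratings from differently-randomized hangings comparable.
canonicalize_records <- function(records) {
  lk <- .cond_key(records$left_mAs, records$left_algo)
  rk <- .cond_key(records$right_mAs, records$right_algo)
  swap <- lk > rk
  out <- records
  out$left_mAs[swap] <- records$right_mAs[swap]
  out$left_algo[swap] <- records$right_algo[swap]
  out$right_mAs[swap] <- records$left_mAs[swap]
  out$right_algo[swap] <- records$left_algo[swap]
  out$score[swap] <- -records$score[swap]
  out
}
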