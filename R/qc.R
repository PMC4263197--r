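#' Hard-call genotypes from probability triplets
#'
#' Calls the most probable genotype class when its probability reaches
#' `threshold`, otherwise a missing call. Calls are returned as allele-A
#' dosages (2 = AA, 1 = AB, 0 = BB, NA = missing); use
#' [genotype_class()] for labels.
#'
#' @param probs Length-3 vector, a samples x 3 triplet matrix, or a
#'   [gen_data] object (returns a markers x samples matrix).
#' @param threshold Minimum probability for a call (default 0.9).
#' @return Integer dosage(s) with NA for no-calls.
#' @export
hard_call <- function(probs, threshold = 0.9) {
  if (inherits(probs, "gen_data")) {
    n_ind <- n_samples(probs)
    out <- vapply(seq_len(n_ind), function(s) {
      hard_call(probs$probs[, (3 * s - 2):(3 * s), drop = FALSE], threshold)
    }, integer(nrow(probs$markers)))
    if (!is.matrix(out)) out <- matrix(out, nrow = nrow(probs$markers))
    return(out)
  }
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 3, byrow = TRUE)
  if (nrow(probs) == 0) return(integer())
  best <- max.col(probs, ties.method = "first")
  pmax_ <- probs[cbind(seq_len(nrow(probs)), best)]
  call <- c(2L, 1L, 0L)[best]
  call[pmax_ < threshold] <- NA_integer_
  call
}

#' Genotype class labels for hard calls
#'
#' @param dosage Allele-A dosages from [hard_call()].
#' @return Character vector in `{"AA", "AB", "BB", NA}`.
#' @export
genotype_class <- function(dosage) {
  c("BB", "AB", "AA")[dosage + 1L]
}

#' Split an info table at an info-score threshold
#'
#' Keeps markers with info strictly above the threshold; the -1 sentinel
#' never passes. The alternative thresholds 0.3 (liberal) and 0.9
#' (conservative) are supported by the same argument.
#'
#' @param info Info tibble.
#' @param threshold Strict lower bound (default 0.7).
#' @return A list with `kept` and `dropped` info tibbles and a one-row
#'   `summary` ([threshold_summary] layout).
#' @export
filter_info <- function(info, threshold = 0.7) {
  validate_info_table(info)
  keep <- !is.na(info$info) & info$info > threshold
  list(kept = info[keep, , drop = FALSE],
       dropped = info[!keep, , drop = FALSE],
       summary = threshold_summary(sum(!keep), nrow(info), threshold))
}

# One ThresholdSummary row: dropped + remaining = total,
# prop_dropped + prop_remaining = 1 exactly.
threshold_summary <- function(n_dropped, n_total, threshold) {
  tibble::tibble(
    threshold = threshold,
    dropped = n_dropped,
    prop_dropped = if (n_total > 0) n_dropped / n_total else 0,
    remaining = n_total - n_dropped,
    prop_remaining = if (n_total > 0) (n_total - n_dropped) / n_total else 0)
}

#' Marker call-rate threshold table
#'
#' Hard-calls the probabilistic genotypes, computes each marker's call
#' rate (fraction of called samples) and summarizes, for each threshold,
#' how many markers would be dropped (call rate below the threshold) and
#' how many remain.
#'
#' @param gen A [gen_data] object.
#' @param thresholds Call-rate thresholds (default `c(0.95, 0.98, 0.99)`).
#' @param call_threshold Hard-call probability threshold (default 0.9).
#' @return A tibble with one [threshold_summary] row per threshold.
#' @export
marker_call_rate_table <- function(gen, thresholds = c(0.95, 0.98, 0.99),
                                   call_threshold = 0.9) {
  calls <- hard_call(gen, threshold = call_threshold)
  rates <- rowMeans(!is.na(calls))
  purrr::map_dfr(thresholds, function(t)
    threshold_summary(sum(rates < t), length(rates), t))
}

#' Sample call-rate threshold table
#'
#' Applies a marker call-rate filter first (markers below `marker_filter`
#' removed), then summarizes per-sample call rates at each threshold.
#' Samples are reported, not removed.
#'
#' @inheritParams marker_call_rate_table
#' @param marker_filter Marker call-rate filter applied first (default
#'   0.99).
#' @return A tibble with one [threshold_summary] row per threshold.
#' @export
sample_call_rate_table <- function(gen, thresholds = c(0.95, 0.98, 0.99),
                                   marker_filter = 0.99,
                                   call_threshold = 0.9) {
  calls <- hard_call(gen, threshold = call_threshold)
  keep <- rowMeans(!is.na(calls)) >= marker_filter
  calls <- calls[keep, , drop = FALSE]
  rates <- if (nrow(calls) > 0) colMeans(!is.na(calls)) else
    rep(1, ncol(calls))
  purrr::map_dfr(thresholds, function(t)
    threshold_summary(sum(rates < t), length(rates), t))
}

#' Minor-allele-frequency threshold table
#'
#' Reports the MAF distribution of the merged data after the info-score
#' and marker call-rate filters: markers failing `info > info_threshold`
#' or call rate `>= marker_filter` are removed first, monomorphic markers
#' (no copy of a minor allele) are excluded, then each MAF threshold
#' counts markers that would be dropped (`MAF < threshold`).
#'
#' @inheritParams marker_call_rate_table
#' @param info Optional info tibble aligned with `gen$markers` for the
#'   info-score filter.
#' @param thresholds MAF thresholds (default
#'   `c(0.05, 0.01, 0.005, 0.001, 0.0005, 0.0001)`).
#' @param info_threshold Strict info filter (default 0.7).
#' @param marker_filter Marker call-rate filter (default 0.99).
#' @param dosage_maf Compute MAF from expected dosages instead of hard
#'   calls (default `FALSE`).
#' @return A tibble with one [threshold_summary] row per threshold.
#' @export
maf_table <- function(gen, info = NULL,
                      thresholds = c(0.05, 0.01, 0.005, 0.001, 0.0005,
                                     0.0001),
                      info_threshold = 0.7, marker_filter = 0.99,
                      call_threshold = 0.9, dosage_maf = FALSE) {
  keep <- rep(TRUE, nrow(gen$markers))
  if (!is.null(info)) {
    keep <- keep & !is.na(info$info) & info$info > info_threshold
  }
  calls <- hard_call(gen, threshold = call_threshold)
  keep <- keep & rowMeans(!is.na(calls)) >= marker_filter
  mafs <- if (dosage_maf) {
    d <- t(vapply(seq_len(nrow(gen$markers)), function(i) {
      expected_dosage(matrix(gen$probs[i, ], ncol = 3, byrow = TRUE))
    }, numeric(n_samples(gen))))
    f <- rowMeans(d, na.rm = TRUE) / 2
    pmin(f, 1 - f)
  } else {
    f <- rowMeans(calls, na.rm = TRUE) / 2
    pmin(f, 1 - f)
  }
  mafs[is.nan(mafs)] <- 0
  mafs <- mafs[keep]
  mafs <- mafs[mafs > 0]   # at least one copy of a minor allele
  purrr::map_dfr(thresholds, function(t)
    threshold_summary(sum(mafs < t), length(mafs), t))
}

#' Full post-merge quality-control report
#'
#' Produces the standard best-practices summary for an imputed, merged
#' dataset: the info-score filter outcome and the marker call-rate,
#' sample call-rate and MAF threshold tables.
#'
#' @param merged A `merged_dataset` (or a list with `gen` and `info`).
#' @param info_threshold,call_threshold,marker_filter See the individual
#'   table functions.
#' @param json_path Optional path; when given (and the jsonlite package
#'   is available) a machine-readable JSON summary is written there.
#' @return A `qc_report` list of tibbles.
#' @export
qc_report <- function(merged, info_threshold = 0.7, call_threshold = 0.9,
                      marker_filter = 0.99, json_path = NULL) {
  gen <- merged$gen
  info <- merged$info
  fi <- filter_info(info, threshold = info_threshold)
  keep <- !is.na(info$info) & info$info > info_threshold
  gen_f <- gen_data(gen$markers[keep, , drop = FALSE],
                    gen$probs[keep, , drop = FALSE], samples = gen$samples)
  out <- list(
    info_filter = fi$summary,
    marker_call_rate = marker_call_rate_table(
      gen_f, call_threshold = call_threshold),
    sample_call_rate = sample_call_rate_table(
      gen_f, marker_filter = marker_filter,
      call_threshold = call_threshold),
    maf = maf_table(gen_f, info = NULL, marker_filter = marker_filter,
                    call_threshold = call_threshold),
    n_markers = nrow(gen$markers), n_samples = n_samples(gen))
  class(out) <- "qc_report"
  if (!is.null(json_path)) {
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(lapply(unclass(out), function(x)
        if (is.data.frame(x)) x else jsonlite::unbox(x)), json_path,
        digits = NA)
    } else {
      warning("jsonlite not available; JSON summary not written",
              call. = FALSE)
    }
  }
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_markers, " markers x ", x$n_samples,
      " samples\ninfo filter:\n", sep = "")
  print(x$info_filter)
  cat("marker call rate:\n"); print(x$marker_call_rate)
  cat("sample call rate:\n"); print(x$sample_call_rate)
  cat("MAF:\n"); print(x$maf)
  invisible(x)
}
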