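#' Mask genotyped markers ahead of re-imputation
#'
#' Removes a subset of genotyped markers from the study input so they can
#' be re-imputed as though they were never genotyped, retaining the
#' original genotypes as the truth store. Only genotyped (type-2) markers
#' are eligible; selection is reproducible under a fixed seed.
#'
#' @param study_haps Pre-phased study [hap_panel].
#' @param fraction Fraction of eligible markers to mask (in (0, 1));
#'   ignored when `markers` is given.
#' @param markers Explicit character vector of `rs_id`s to mask.
#' @param seed Seed for the random selection.
#' @return A list with `masked` (the study panel without the masked
#'   markers), `truth` (marker table of the masked markers) and
#'   `truth_geno` (hard allele-A dosage matrix, masked markers x samples).
#' @export
mask_markers <- function(study_haps, fraction = NULL, markers = NULL,
                         seed = NULL) {
  stopifnot(inherits(study_haps, "hap_panel"))
  mk <- study_haps$markers
  eligible <- if ("type" %in% names(mk) && any(!is.na(mk$type))) {
    which(!is.na(mk$type) & mk$type == 2L)
  } else {
    seq_len(nrow(mk))
  }
  if (!is.null(markers)) {
    sel <- which(mk$rs_id %in% markers)
    if (!all(sel %in% eligible)) {
      stop("only genotyped (type-2) markers can be masked", call. = FALSE)
    }
  } else {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1) {
      stop("fraction must lie strictly between 0 and 1", call. = FALSE)
    }
    n_mask <- floor(fraction * length(eligible))
    sel <- if (n_mask == 0) integer() else
      with_seed(seed, sort(sample(eligible, n_mask)))
  }
  keep <- setdiff(seq_len(nrow(mk)), sel)
  masked <- hap_panel(mk[keep, , drop = FALSE],
                      study_haps$haps[keep, , drop = FALSE],
                      study_haps$sample_ids)
  truth_geno <- hap_genotypes(study_haps)[sel, , drop = FALSE]
  list(masked = masked, truth = mk[sel, , drop = FALSE],
       truth_geno = truth_geno)
}

#' Expected allelic dosage of a genotype probability triplet
#'
#' `2 * P(AA) + 1 * P(AB) + 0 * P(BB)`: the probabilistic count of the
#' first (A) allele. The all-zero (missing) triplet yields `NA`.
#'
#' @param probs Length-3 vector, or a matrix with columns P(AA), P(AB),
#'   P(BB).
#' @return Dosage value(s) in \[0, 2\], `NA` for missing triplets.
#' @export
expected_dosage <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 3, byrow = TRUE)
  d <- 2 * probs[, 1] + probs[, 2]
  d[rowSums(probs) == 0] <- NA_real_
  d
}

#' Squared dosage correlation between truth and imputed genotypes
#'
#' Squared Pearson correlation between hard truth dosages (0/1/2) and
#' imputed expected dosages over individuals at one marker. Undefined
#' (`NA`) when fewer than 2 usable samples remain or either vector is
#' constant. Invariant under allele relabeling.
#'
#' @param truth Integer vector of truth allele-A dosages (NA = missing).
#' @param probs Imputed triplet matrix, samples x 3.
#' @return Squared correlation in \[0, 1\], or `NA`.
#' @seealso [allelic_r()] for the signed correlation.
#' @export
allelic_r2 <- function(truth, probs) {
  r <- allelic_r(truth, probs)
  if (is.na(r)) NA_real_ else r^2
}

#' Signed dosage correlation between truth and imputed genotypes
#'
#' @inheritParams allelic_r2
#' @return Pearson correlation in \[-1, 1\], or `NA` when undefined.
#' @export
allelic_r <- function(truth, probs) {
  d <- expected_dosage(probs)
  use <- !is.na(truth) & !is.na(d)
  if (sum(use) < 2) return(NA_real_)
  t_ <- truth[use]; d_ <- d[use]
  if (stats::sd(t_) == 0 || stats::sd(d_) == 0) return(NA_real_)
  stats::cor(t_, d_)
}

#' Best-guess genotype concordance at one marker
#'
#' Hard-calls each imputed triplet (argmax class if its maximum
#' probability reaches `call_threshold`, otherwise no-call) and reports
#' the fraction of called, non-missing-truth samples whose call matches
#' the truth genotype.
#'
#' @inheritParams allelic_r2
#' @param call_threshold Minimum probability for a hard call (default
#'   0.9).
#' @return Fraction in \[0, 1\], or `NA` when no sample is callable.
#' @export
concordance <- function(truth, probs, call_threshold = 0.9) {
  calls <- hard_call(probs, threshold = call_threshold)
  use <- !is.na(truth) & !is.na(calls)
  if (sum(use) == 0) return(NA_real_)
  mean(calls[use] == truth[use])
}

#' Masked re-imputation evaluation
#'
#' Masks a fraction (or explicit list) of genotyped markers, re-imputes
#' them with the nearest-haplotype imputer, and scores each masked marker:
#' truth minor-allele frequency, best-guess concordance, allelic R^2,
#' signed correlation, info score and usable sample count.
#'
#' @inheritParams mask_markers
#' @inheritParams impute_segment
#' @param call_threshold Hard-call threshold for concordance (default
#'   0.9).
#' @return A `masked_eval` object; `tidy()` returns the per-marker report,
#'   `glance()` the dataset-level summary and merge gate.
#' @export
run_masked_eval <- function(study_haps, ref_panel, fraction = 0.1,
                            markers = NULL, seed = 1, k = 5, flank = 50,
                            call_threshold = 0.9) {
  m <- mask_markers(study_haps, fraction = fraction, markers = markers,
                    seed = seed)
  if (nrow(m$truth) == 0) {
    stop("mask selected no markers; nothing to evaluate", call. = FALSE)
  }
  res <- impute_segment(m$masked, ref_panel, k = k, flank = flank)
  key <- paste(res$gen$markers$chrom, res$gen$markers$pos)
  idx <- match(paste(m$truth$chrom, m$truth$pos), key)
  if (anyNA(idx)) {
    stop("masked markers absent from imputation output", call. = FALSE)
  }
  n_ind <- n_samples(res$gen)
  report <- purrr::map_dfr(seq_len(nrow(m$truth)), function(i) {
    row <- res$gen$probs[idx[i], ]
    tr <- matrix(row, n_ind, 3, byrow = TRUE)
    truth <- m$truth_geno[i, ]
    # orient truth dosage to the imputer's output allele order
    if (m$truth$allele_a[i] != res$gen$markers$allele_a[idx[i]]) {
      truth <- 2L - truth
    }
    f <- mean(truth, na.rm = TRUE) / 2
    tibble::tibble(
      chrom = m$truth$chrom[i], pos = m$truth$pos[i],
      rs_id = m$truth$rs_id[i],
      maf = min(f, 1 - f),
      concordance = concordance(truth, tr, call_threshold),
      allelic_r2 = allelic_r2(truth, tr),
      allelic_r = allelic_r(truth, tr),
      info = res$info$info[idx[i]],
      n_samples = sum(!is.na(truth)))
  })
  structure(list(report = report, call_threshold = call_threshold,
                 n_masked = nrow(report)),
            class = "masked_eval")
}

#' @export
print.masked_eval <- function(x, ...) {
  cat("<masked_eval> ", x$n_masked, " masked markers; mean concordance ",
      sprintf("%.3f", mean(x$report$concordance, na.rm = TRUE)), "\n",
      sep = "")
  invisible(x)
}

#' Merge-eligibility gate on masked concordance
#'
#' A dataset is flagged mergeable when its mean masked concordance reaches
#' `min_concordance` (default 0.80).
#'
#' @param eval A `masked_eval` object.
#' @param min_concordance Gate threshold (default 0.8).
#' @return A one-row tibble with `mean_concordance`, `min_concordance`,
#'   `mergeable`.
#' @export
mask_gate <- function(eval, min_concordance = 0.8) {
  stopifnot(inherits(eval, "masked_eval"))
  mc <- mean(eval$report$concordance, na.rm = TRUE)
  tibble::tibble(mean_concordance = mc, min_concordance = min_concordance,
                 mergeable = !is.na(mc) & mc >= min_concordance)
}

#' Summarize masked-marker metrics by MAF bin
#'
#' Bins reports by truth minor-allele frequency into intervals
#' `[k * bin_width, (k + 1) * bin_width)` covering \[0, 0.5\] (a MAF of
#' exactly 0.5 lands in the top bin) and returns equally weighted per-bin
#' means with undefined values excluded, plus per-bin marker counts.
#'
#' @param reports Per-marker report tibble (from a `masked_eval` object or
#'   assembled by hand) with a `maf` column and any of `concordance`,
#'   `allelic_r2`, `info`.
#' @param bin_width Bin width (e.g. 0.1 or 0.01).
#' @return A tibble with `bin_lo`, `bin_hi`, `n_snps` and per-metric
#'   means.
#' @export
summarize_by_maf <- function(reports, bin_width = 0.1) {
  if (inherits(reports, "masked_eval")) reports <- reports$report
  if (nrow(reports) == 0) stop("no reports to summarize", call. = FALSE)
  k <- pmin(floor(reports$maf / bin_width),
            ceiling(0.5 / bin_width) - 1)
  reports$bin_lo <- k * bin_width
  out <- dplyr::summarise(
    dplyr::group_by(reports, .data$bin_lo),
    n_snps = dplyr::n(),
    dplyr::across(dplyr::any_of(c("concordance", "allelic_r2", "info")),
                  ~ mean(.x[.x != -1], na.rm = TRUE),
                  .names = "mean_{.col}"),
    .groups = "drop")
  out <- dplyr::mutate(out, bin_hi = .data$bin_lo + bin_width,
                       .after = "bin_lo")
  dplyr::arrange(out, .data$bin_lo)
}
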