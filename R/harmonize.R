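#' Complement alleles to the opposite strand
#'
#' Maps A<->T and C<->G per allele. Applying it twice is the identity.
#'
#' @param alleles Character vector of single-base alleles (A, C, G, T).
#' @return Character vector of complemented alleles.
#' @export
complement_alleles <- function(alleles) {
  ok <- is.na(alleles) | alleles %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stop("unsupported allele(s): ",
         paste(unique(alleles[!ok]), collapse = ", "),
         " (only A/C/G/T can be strand-complemented)", call. = FALSE)
  }
  chartr("ACGT", "TGCA", alleles)
}

#' Is an allele pair palindromic (strand-ambiguous)?
#'
#' A/T and C/G pairs read the same on both strands, so their orientation
#' cannot be resolved from allele labels alone.
#'
#' @param allele_a,allele_b Allele vectors.
#' @return Logical vector.
#' @export
is_palindromic <- function(allele_a, allele_b) {
  !is.na(allele_a) & !is.na(allele_b) &
    allele_b == chartr("ACGT", "TGCA", allele_a)
}

#' Apply a precomputed genome-build coordinate map
#'
#' Converts marker names, chromosomes and positions from an old genome
#' build to a new one using a precomputed conversion table (the product of
#' a batch coordinate-conversion run). Four steps, in order: markers with
#' indeterminate mappings (unknown chromosome and/or position) are removed;
#' names are updated; chromosomes are updated; positions are updated. The
#' output is re-sorted by (chrom, pos).
#'
#' @param markers Marker table keyed by the old build's
#'   (`chrom`, `pos`, `rs_id`).
#' @param map Conversion table with columns `old_chrom`, `old_pos`,
#'   `old_label`, `new_chrom`, `new_pos`, `new_label`, `status`
#'   (`"mapped"`/`"unmapped"`). Markers absent from the table count as
#'   unmapped.
#' @return A list with `markers` (converted, re-sorted) and `dropped`
#'   (input rows removed as unmappable).
#' @export
apply_coordinate_map <- function(markers, map) {
  validate_marker_table(markers)
  needed <- c("old_chrom", "old_pos", "old_label", "new_chrom", "new_pos",
              "new_label", "status")
  if (!all(needed %in% names(map))) {
    stop("coordinate map needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  map <- dplyr::mutate(tibble::as_tibble(map),
                       old_chrom = as.character(.data$old_chrom),
                       new_chrom = as.character(.data$new_chrom))
  joined <- dplyr::left_join(
    dplyr::mutate(markers, .row = dplyr::row_number()),
    map,
    by = c(chrom = "old_chrom", pos = "old_pos", rs_id = "old_label"))
  mappable <- !is.na(joined$status) & joined$status == "mapped" &
    !is.na(joined$new_chrom) & !is.na(joined$new_pos)
  dropped <- markers[joined$.row[!mappable], , drop = FALSE]
  out <- joined[mappable, , drop = FALSE]
  out$chrom <- out$new_chrom
  out$rs_id <- dplyr::coalesce(out$new_label, out$rs_id)
  out$pos <- as.integer(out$new_pos)
  out <- dplyr::select(out, -dplyr::any_of(c(".row", "new_chrom", "new_pos",
                                             "new_label", "status")))
  out <- sort_markers(out)
  key <- paste(out$chrom, out$pos,
               pmin(out$allele_a, out$allele_b),
               pmax(out$allele_a, out$allele_b))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    stop("coordinate map sends markers to identical (chrom, pos, alleles): ",
         paste(utils::head(out$rs_id[dup], 6), collapse = ", "),
         call. = FALSE)
  }
  list(markers = out, dropped = dropped)
}

#' Convert a whole study dataset to a new genome build
#'
#' Applies [apply_coordinate_map()] to the marker table of a [study_data]
#' object and reorders the genotype rows to match.
#'
#' @param study A [study_data] object in old-build coordinates.
#' @param map Coordinate conversion table (see [apply_coordinate_map()]).
#' @return A list with `study` (converted) and `dropped` (marker table of
#'   removed rows).
#' @export
liftover_study <- function(study, map) {
  stopifnot(inherits(study, "study_data"))
  res <- apply_coordinate_map(
    dplyr::mutate(study$markers, .orig = dplyr::row_number()), map)
  idx <- res$markers$.orig
  new_markers <- dplyr::select(res$markers, -".orig")
  list(
    study = study_data(new_markers, study$geno[idx, , drop = FALSE],
                       study$samples),
    dropped = dplyr::select(res$dropped, -dplyr::any_of(".orig")))
}

#' Pre-harmonization marker and sample quality filters
#'
#' Removes low call-rate samples, then low call-rate and low-MAF markers,
#' and optionally all palindromic markers, before strand checking.
#'
#' @param study A [study_data] object.
#' @param marker_call_rate Minimum fraction of non-missing genotypes per
#'   marker (default 0.95).
#' @param sample_call_rate Minimum fraction of non-missing genotypes per
#'   sample (default 0.95).
#' @param maf Minimum minor-allele frequency (default 0.05).
#' @param drop_palindromic Remove A/T and C/G markers outright (default
#'   `FALSE`).
#' @return A filtered [study_data] object.
#' @export
filter_study_qc <- function(study, marker_call_rate = 0.95,
                            sample_call_rate = 0.95, maf = 0.05,
                            drop_palindromic = FALSE) {
  stopifnot(inherits(study, "study_data"))
  g <- study$geno
  keep_s <- if (ncol(g) > 0 && nrow(g) > 0)
    colMeans(!is.na(g)) >= sample_call_rate else rep(TRUE, ncol(g))
  g <- g[, keep_s, drop = FALSE]
  cr <- if (ncol(g) > 0) rowMeans(!is.na(g)) else rep(1, nrow(g))
  f <- rowMeans(g, na.rm = TRUE) / 2
  mafs <- pmin(f, 1 - f)
  mafs[is.nan(mafs)] <- 0
  keep_m <- cr >= marker_call_rate & mafs >= maf
  if (drop_palindromic) {
    keep_m <- keep_m &
      !is_palindromic(study$markers$allele_a, study$markers$allele_b)
  }
  samples <- study$samples[keep_s, , drop = FALSE]
  samples$call_rate <- if (sum(keep_m) > 0)
    colMeans(!is.na(g[keep_m, , drop = FALSE])) else rep(NA_real_, nrow(samples))
  study_data(study$markers[keep_m, , drop = FALSE],
             g[keep_m, , drop = FALSE], samples)
}
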