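#' Build a marker table
#'
#' Markers are the central bookkeeping unit of the pipeline: one row per
#' biallelic variant, identified by chromosome, position and an allele pair.
#' The first allele (`allele_a`) and second allele (`allele_b`) follow the
#' Oxford GEN convention: genotype probability triplets are ordered
#' P(AA), P(AB), P(BB) and haplotype indicators use 0 for `allele_a`,
#' 1 for `allele_b`.
#'
#' @param chrom Chromosome labels (character or integer).
#' @param rs_id Marker labels (rs-style or platform identifiers).
#' @param pos 1-based base-pair positions.
#' @param allele_a,allele_b Allele strings; for SNVs one of A, C, G, T.
#' @param snp_id Secondary identifier column carried by GEN files; defaults
#'   to `"---"` as in IMPUTE2 output.
#' @param type Optional panel-membership code: 0/1 reference-only, 2
#'   genotyped in the study (the imputation basis), 3 study-only.
#' @return A tibble with columns `chrom`, `snp_id`, `rs_id`, `pos`,
#'   `allele_a`, `allele_b`, `type`.
#' @export
marker_table <- function(chrom, rs_id, pos, allele_a, allele_b,
                         snp_id = "---", type = NA_integer_) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    snp_id = as.character(snp_id),
    rs_id = as.character(rs_id),
    pos = as.integer(pos),
    allele_a = as.character(allele_a),
    allele_b = as.character(allele_b),
    type = as.integer(type)
  )
  validate_marker_table(out)
  out
}

validate_marker_table <- function(markers, require_sorted = FALSE) {
  stopifnot(is.data.frame(markers))
  needed <- c("rs_id", "pos", "allele_a", "allele_b")
  missing_cols <- setdiff(needed, names(markers))
  if (length(missing_cols) > 0) {
    stop("marker table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(markers$pos < 1L, na.rm = TRUE)) {
    stop("marker positions must be >= 1 (1-based coordinates)", call. = FALSE)
  }
  same <- !is.na(markers$allele_a) & !is.na(markers$allele_b) &
    markers$allele_a == markers$allele_b
  if (any(same)) {
    stop("markers with identical alleles: ",
         paste(utils::head(markers$rs_id[same], 5), collapse = ", "),
         call. = FALSE)
  }
  if (require_sorted && !marker_sorted(markers)) {
    stop("markers must be sorted by (chrom, pos)", call. = FALSE)
  }
  invisible(markers)
}

marker_sorted <- function(markers) {
  ord <- order(chrom_rank(markers$chrom), markers$pos)
  all(ord == seq_len(nrow(markers)))
}

# Numeric-aware chromosome ordering: 1..22 sort numerically, labels sort after.
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(n), 1e6 + as.numeric(factor(chrom)), n)
}

sort_markers <- function(markers) {
  markers[order(chrom_rank(markers$chrom), markers$pos), , drop = FALSE]
}

#' Genotype probability container
#'
#' Couples a marker table with a matrix of per-sample genotype probability
#' triplets, mirroring an Oxford GEN file plus its companion sample file.
#' Each marker row carries `3 * n_samples` probabilities laid out as
#' P(AA), P(AB), P(BB) blocks in sample order. The all-zero triplet encodes
#' a missing genotype; triplets are stored exactly as read, never
#' renormalized.
#'
#' @param markers A marker table (see [marker_table()]).
#' @param probs Numeric matrix, `nrow(markers)` rows by `3 * n_samples`
#'   columns.
#' @param samples Optional sample roster tibble with at least a `sample_id`
#'   column; may carry `dataset_id` and `call_rate`.
#' @return An object of class `gen_data`.
#' @export
gen_data <- function(markers, probs, samples = NULL) {
  validate_marker_table(markers)
  probs <- as.matrix(probs)
  if (nrow(markers) != nrow(probs)) {
    stop("probs must have one row per marker", call. = FALSE)
  }
  if (ncol(probs) %% 3 != 0) {
    stop("probs must have 3 columns per sample", call. = FALSE)
  }
  if (length(probs) > 0 && (anyNA(probs) || min(probs) < 0 || max(probs) > 1)) {
    stop("genotype probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(samples)) {
    stopifnot(is.data.frame(samples), "sample_id" %in% names(samples))
    if (nrow(samples) != ncol(probs) / 3) {
      stop("sample roster length (", nrow(samples),
           ") does not match probability width (", ncol(probs) / 3,
           " samples)", call. = FALSE)
    }
    samples <- tibble::as_tibble(samples)
  }
  structure(
    list(markers = tibble::as_tibble(markers), probs = unname(probs),
         samples = samples),
    class = "gen_data"
  )
}

#' @export
print.gen_data <- function(x, ...) {
  cat("<gen_data> ", nrow(x$markers), " markers x ", n_samples(x),
      " samples\n", sep = "")
  print(utils::head(x$markers, 5))
  invisible(x)
}

#' Number of samples in a genotype container
#' @param x A `gen_data` or `hap_panel` object.
#' @return Integer sample count.
#' @export
n_samples <- function(x) UseMethod("n_samples")

#' @export
n_samples.gen_data <- function(x) ncol(x$probs) %/% 3L

#' @export
n_samples.hap_panel <- function(x) ncol(x$haps) %/% 2L

#' Phased haplotype panel
#'
#' A marker table plus a 0/1 haplotype matrix with two columns per diploid
#' individual (0 = `allele_a`, 1 = `allele_b`). Used both for the phased
#' reference panel and for pre-phased study data.
#'
#' @param markers A marker table, sorted by (chrom, pos).
#' @param haps Integer matrix of 0/1 allele indicators,
#'   `nrow(markers)` x `2 * n_samples`.
#' @param sample_ids Character roster, one id per individual.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(markers, haps, sample_ids = NULL) {
  validate_marker_table(markers, require_sorted = TRUE)
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (nrow(markers) != nrow(haps)) {
    stop("haps must have one row per marker", call. = FALSE)
  }
  if (ncol(haps) %% 2 != 0) {
    stop("haplotype count must be even (two per diploid individual)",
         call. = FALSE)
  }
  if (length(haps) > 0 && !all(haps %in% c(0L, 1L))) {
    stop("haplotype entries must be 0 or 1", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(ncol(haps) / 2))
  }
  if (length(sample_ids) != ncol(haps) / 2) {
    stop("sample_ids length must equal half the haplotype count", call. = FALSE)
  }
  structure(
    list(markers = tibble::as_tibble(markers), haps = unname(haps),
         sample_ids = as.character(sample_ids)),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("<hap_panel> ", nrow(x$markers), " markers x ", ncol(x$haps),
      " haplotypes (", n_samples(x), " individuals)\n", sep = "")
  invisible(x)
}

#' Diploid allele-A dosages from a haplotype panel
#'
#' Collapses haplotype pairs into hard genotype dosages counting
#' `allele_a` copies (2 = AA, 1 = AB, 0 = BB), the same scale as
#' [expected_dosage()].
#'
#' @param panel A `hap_panel`.
#' @return Integer matrix, markers x individuals.
#' @export
hap_genotypes <- function(panel) {
  stopifnot(inherits(panel, "hap_panel"))
  n <- n_samples(panel)
  if (n == 0) return(matrix(integer(), nrow(panel$markers), 0))
  h1 <- panel$haps[, 2 * seq_len(n) - 1, drop = FALSE]
  h2 <- panel$haps[, 2 * seq_len(n), drop = FALSE]
  g <- 2L - h1 - h2
  colnames(g) <- panel$sample_ids
  g
}

#' Unphased study genotype container
#'
#' Hard-called genotypes for one dataset (site + platform), as read from
#' PLINK text files. Dosages count copies of `allele_a` (2/1/0 = AA/AB/BB,
#' NA = missing).
#'
#' @param markers A marker table.
#' @param geno Integer matrix of allele-A dosages, markers x samples.
#' @param samples Sample roster tibble with `sample_id` (and optionally
#'   `dataset_id`, `call_rate`).
#' @return An object of class `study_data`.
#' @export
study_data <- function(markers, geno, samples) {
  validate_marker_table(markers)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(markers) != nrow(geno)) {
    stop("geno must have one row per marker", call. = FALSE)
  }
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples))
  if (nrow(samples) != ncol(geno)) {
    stop("sample roster length does not match genotype width", call. = FALSE)
  }
  if (length(geno) > 0 && !all(geno %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id must be unique within a dataset", call. = FALSE)
  }
  structure(
    list(markers = tibble::as_tibble(markers), geno = unname(geno),
         samples = tibble::as_tibble(samples)),
    class = "study_data"
  )
}

#' @export
print.study_data <- function(x, ...) {
  cat("<study_data> ", nrow(x$markers), " markers x ", nrow(x$samples),
      " samples\n", sep = "")
  invisible(x)
}

#' Empty info-metric table
#'
#' The 10-column per-marker quality layout written next to imputed GEN
#' files: identifiers, `exp_freq_a1`, `info`, `certainty`, the panel `type`
#' code, and the masked-test metrics `info_type0`, `concord_type0`,
#' `r2_type0`. The value -1 is the only permitted out-of-range sentinel and
#' means "undefined".
#'
#' @return A zero-row tibble with the canonical columns.
#' @export
info_table <- function() {
  tibble::tibble(
    snp_id = character(), rs_id = character(), position = integer(),
    exp_freq_a1 = double(), info = double(), certainty = double(),
    type = integer(), info_type0 = double(), concord_type0 = double(),
    r2_type0 = double()
  )
}

info_metric_cols <- function() {
  c("exp_freq_a1", "info", "certainty", "info_type0", "concord_type0",
    "r2_type0")
}

validate_info_table <- function(info) {
  missing_cols <- setdiff(names(info_table()), names(info))
  if (length(missing_cols) > 0) {
    stop("info table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in info_metric_cols()) {
    v <- info[[col]]
    bad <- !is.na(v) & (v < 0 | v > 1) & v != -1
    if (any(bad)) {
      stop("info column ", col,
           " has values outside [0, 1] that are not the -1 sentinel",
           call. = FALSE)
    }
  }
  invisible(info)
}
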