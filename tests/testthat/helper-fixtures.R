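# Programmatic fixtures shared across test files.

# random marker table on one chromosome, strictly increasing positions
random_markers <- function(n, chrom = "1", seed = NULL, spacing = 1000) {
  build <- function() {
    pos <- cumsum(sample.int(spacing, n, replace = TRUE))
    pairs <- t(vapply(seq_len(n), function(i) sample(c("A", "C", "G", "T"), 2),
                      character(2)))
    marker_table(chrom = chrom, rs_id = paste0("rs", seq_len(n)), pos = pos,
                 allele_a = pairs[, 1], allele_b = pairs[, 2])
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# gen_data with 3-decimal probabilities (representable exactly on re-read)
random_gen <- function(n_markers, n_samples, seed = 1) {
  withr::with_seed(seed, {
    markers <- random_markers(n_markers)
    raw <- matrix(sample(0:1000, n_markers * 3 * n_samples, replace = TRUE),
                  n_markers)
    tot <- raw
    for (s in seq_len(n_samples)) {
      idx <- (3 * s - 2):(3 * s)
      tot[, idx] <- raw[, idx] / pmax(1, rowSums(raw[, idx, drop = FALSE]))
    }
    probs <- round(tot, 3)
    gen_data(markers, probs,
             samples = tibble::tibble(sample_id = sprintf("s%02d",
                                                          seq_len(n_samples))))
  })
}

random_info <- function(markers, seed = 1, sentinel_rate = 0.15) {
  withr::with_seed(seed, {
    n <- nrow(markers)
    rnd <- function() {
      v <- round(stats::runif(n), 3)
      v[stats::runif(n) < sentinel_rate] <- -1
      v
    }
    tibble::tibble(
      snp_id = "---", rs_id = markers$rs_id, position = markers$pos,
      exp_freq_a1 = rnd(), info = rnd(), certainty = rnd(),
      type = sample(0:3, n, replace = TRUE),
      info_type0 = rnd(), concord_type0 = rnd(), r2_type0 = rnd())
  })
}

# small deterministic haplotype panel from an explicit 0/1 matrix
panel_from_matrix <- function(haps, pos = NULL, allele_a = "A",
                              allele_b = "G", chrom = "1") {
  haps <- as.matrix(haps)
  n <- nrow(haps)
  pos <- pos %||% seq_len(n) * 100L
  markers <- marker_table(chrom = chrom, rs_id = paste0("rs", seq_len(n)),
                          pos = pos,
                          allele_a = rep_len(allele_a, n),
                          allele_b = rep_len(allele_b, n))
  hap_panel(markers, haps)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# study_data built from a dosage matrix and a marker table
study_from_geno <- function(markers, geno, dataset_id = "d1") {
  geno <- as.matrix(geno)
  study_data(markers, geno,
             tibble::tibble(sample_id = sprintf("i%02d", seq_len(ncol(geno))),
                            dataset_id = dataset_id,
                            call_rate = colMeans(!is.na(geno))))
}

# wrap an imputation result as a mergeable dataset
as_dataset <- function(id, result, call_rates = NULL, genome_wide = TRUE,
                       masked_concordance = NA_real_) {
  gen <- result$gen
  if (!is.null(call_rates)) {
    gen$samples$call_rate <- unname(call_rates[gen$samples$sample_id])
  }
  info <- result$info[, names(info_table()), drop = FALSE]
  imputed_dataset(id, gen, info, genome_wide = genome_wide,
                  masked_concordance = masked_concordance)
}
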