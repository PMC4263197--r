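#' Deterministic nearest-haplotype imputation of one segment
#'
#' A documented, deterministic stand-in for production HMM imputers, used
#' to exercise the pipeline end-to-end: for each pre-phased study
#' haplotype, the `k` reference haplotypes with the highest agreement
#' (Hamming similarity) over the nearest `flank` genotyped (type-2)
#' markers are selected; at each untyped marker the allele probability is
#' their agreement-weighted vote, and the genotype triplet is the product
#' over the individual's two haplotypes. Genotyped markers keep their
#' observed genotypes as probability-1 triplets. Ties in the neighbor
#' ranking are broken by reference haplotype index, so output is
#' deterministic given inputs.
#'
#' @param study_haps Pre-phased study [hap_panel]; its markers must be a
#'   subset of the reference markers (post-harmonization) and are treated
#'   as the type-2 imputation basis.
#' @param ref_panel Phased reference [hap_panel].
#' @param segment Optional one-row slice of a `segment_plan`; restricts
#'   imputation to markers within `[buffer_lo, buffer_hi]`.
#' @param k Reference haplotypes copied per study haplotype (default 5).
#' @param flank Genotyped markers per similarity window (default 50).
#' @return An `imputation_result`: list with `gen` (a [gen_data] over the
#'   segment's reference markers, marker `type` 2 = genotyped, 0 =
#'   imputed) and `info` (per-marker metric tibble; the masked-test
#'   columns carry the -1 sentinel).
#' @export
impute_segment <- function(study_haps, ref_panel, segment = NULL, k = 5,
                           flank = 50) {
  stopifnot(inherits(study_haps, "hap_panel"), inherits(ref_panel, "hap_panel"))
  rmk <- ref_panel$markers
  rh <- ref_panel$haps
  if (!is.null(segment)) {
    inside <- rmk$pos >= segment$buffer_lo[1] & rmk$pos <= segment$buffer_hi[1]
    rmk <- rmk[inside, , drop = FALSE]
    rh <- rh[inside, , drop = FALSE]
  }
  skey <- paste(study_haps$markers$chrom, study_haps$markers$pos)
  rkey <- paste(rmk$chrom, rmk$pos)
  s_in <- skey %in% rkey
  typed_ref <- match(skey[s_in], rkey)
  if (!is.null(segment)) {
    # study markers outside the segment are simply not used
  } else if (!all(s_in)) {
    stop("study markers must be a subset of the reference panel markers",
         call. = FALSE)
  }
  if (length(typed_ref) == 0) {
    stop("segment contains no genotyped (type-2) markers; refusing to impute",
         call. = FALSE)
  }
  sa <- study_haps$markers$allele_a[s_in]
  if (!all(sa == rmk$allele_a[typed_ref] |
             sa == rmk$allele_b[typed_ref])) {
    stop("study alleles do not match reference alleles; harmonize first",
         call. = FALSE)
  }
  # orient study haplotype coding to the reference allele order
  sh <- study_haps$haps[s_in, , drop = FALSE]
  revd <- study_haps$markers$allele_a[s_in] != rmk$allele_a[typed_ref]
  sh[revd, ] <- 1L - sh[revd, , drop = FALSE]

  n_mark <- nrow(rmk)
  n_sh <- ncol(sh)
  n_ind <- n_sh %/% 2L
  n_typed <- length(typed_ref)
  type <- rep(0L, n_mark)
  type[typed_ref] <- 2L

  # allele-B probability per (marker, study haplotype)
  pB <- matrix(NA_real_, n_mark, n_sh)
  pB[typed_ref, ] <- sh

  untyped <- setdiff(seq_len(n_mark), typed_ref)
  if (length(untyped) > 0) {
    typed_pos <- rmk$pos[typed_ref]
    wsize <- min(flank, n_typed)
    # nearest typed-marker window per untyped marker (ties by index)
    win_of <- function(p) {
      sort(order(abs(typed_pos - p), seq_len(n_typed))[seq_len(wsize)])
    }
    windows <- lapply(rmk$pos[untyped], win_of)
    wkey <- vapply(windows, paste, character(1), collapse = ",")
    for (key in unique(wkey)) {
      grp <- untyped[wkey == key]
      win <- windows[[match(key, wkey)]]
      Rw <- rh[typed_ref[win], , drop = FALSE]       # typed ref rows
      Sw <- sh[win, , drop = FALSE]
      # agreement counts between every ref hap and every study hap
      agree <- crossprod(Rw, Sw) + crossprod(1 - Rw, 1 - Sw)
      W <- matrix(0, nrow(agree), n_sh)
      kk <- min(k, nrow(agree))
      for (s in seq_len(n_sh)) {
        top <- order(-agree[, s], seq_len(nrow(agree)))[seq_len(kk)]
        w <- agree[top, s]
        if (sum(w) == 0) w <- rep(1, kk)
        W[top, s] <- w / sum(w)
      }
      pB[grp, ] <- rh[grp, , drop = FALSE] %*% W
    }
  }

  # genotype triplets from per-haplotype allele probabilities
  q1 <- pB[, 2 * seq_len(n_ind) - 1, drop = FALSE]
  q2 <- pB[, 2 * seq_len(n_ind), drop = FALSE]
  probs <- matrix(0, n_mark, 3 * n_ind)
  probs[, 3 * seq_len(n_ind) - 2] <- (1 - q1) * (1 - q2)   # P(AA)
  probs[, 3 * seq_len(n_ind) - 1] <- q1 * (1 - q2) + (1 - q1) * q2
  probs[, 3 * seq_len(n_ind)] <- q1 * q2                   # P(BB)
  probs <- pmin(pmax(probs, 0), 1)

  out_markers <- rmk
  out_markers$type <- type
  samples <- tibble::tibble(sample_id = study_haps$sample_ids)
  gen <- gen_data(out_markers, probs, samples = samples)

  info <- tibble::tibble(
    snp_id = "---", rs_id = rmk$rs_id, position = rmk$pos,
    exp_freq_a1 = rowMeans(2 * probs[, 3 * seq_len(n_ind) - 2, drop = FALSE] +
                             probs[, 3 * seq_len(n_ind) - 1, drop = FALSE]) / 2,
    info = apply_info_score(probs, n_ind),
    certainty = marker_certainty(probs, n_ind),
    type = type,
    info_type0 = -1, concord_type0 = -1, r2_type0 = -1)
  structure(list(gen = gen, info = info), class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("<imputation_result> ", nrow(x$gen$markers), " markers (",
      sum(x$gen$markers$type == 2L), " genotyped) x ", n_samples(x$gen),
      " samples\n", sep = "")
  invisible(x)
}

# per-marker info score over a gen-layout probability matrix
apply_info_score <- function(probs, n_ind) {
  vapply(seq_len(nrow(probs)), function(i) {
    info_score(matrix(probs[i, ], n_ind, 3, byrow = TRUE))
  }, numeric(1))
}

marker_certainty <- function(probs, n_ind) {
  vapply(seq_len(nrow(probs)), function(i) {
    tr <- matrix(probs[i, ], n_ind, 3, byrow = TRUE)
    keep <- rowSums(tr) > 0
    if (!any(keep)) return(-1)
    mean(apply(tr[keep, , drop = FALSE], 1, max))
  }, numeric(1))
}

#' Imputation certainty ("info") score for one marker
#'
#' Ratio-of-variances measure of imputation certainty: with expected
#' allele-A dosage \eqn{e_i = 2 p_{AA,i} + p_{AB,i}} and frequency
#' \eqn{\theta = \bar e / 2}, the score is
#' \deqn{1 - \frac{\mathrm{mean}_i \mathrm{Var}(d_i)}{2\theta(1-\theta)}}
#' where \eqn{\mathrm{Var}(d_i) = 4 p_{AA,i} + p_{AB,i} - e_i^2}. Certain
#' genotypes give 1; a monomorphic expected frequency
#' (\eqn{\theta \in \{0, 1\}}) or an all-missing marker gives the -1
#' ("undefined") sentinel. All-zero triplets (missing) are excluded.
#'
#' @param triplets Numeric matrix with one row per sample and columns
#'   P(AA), P(AB), P(BB), or a length-3 vector.
#' @return A score in \[0, 1\], or -1 when undefined.
#' @export
info_score <- function(triplets) {
  if (is.null(dim(triplets))) triplets <- matrix(triplets, ncol = 3,
                                                 byrow = TRUE)
  keep <- rowSums(triplets) > 0
  tr <- triplets[keep, , drop = FALSE]
  if (nrow(tr) == 0) return(-1)
  e <- 2 * tr[, 1] + tr[, 2]
  v <- 4 * tr[, 1] + tr[, 2] - e^2
  theta <- mean(e) / 2
  if (theta <= 0 || theta >= 1) return(-1)
  max(0, min(1, 1 - mean(v) / (2 * theta * (1 - theta))))
}

#' Impute a whole chromosome through a segment plan
#'
#' Runs [impute_segment()] on every plan row and stitches the per-segment
#' outputs with [stitch_segments()], removing buffers. Per-marker info
#' metrics are concatenated for core markers only, with a `segment`
#' provenance column.
#'
#' @inheritParams impute_segment
#' @param plan A `segment_plan` covering the reference markers.
#' @return An `imputation_result` over all core markers.
#' @export
impute_chromosome <- function(study_haps, ref_panel, plan, k = 5,
                              flank = 50) {
  stopifnot(inherits(plan, "segment_plan"))
  results <- lapply(seq_len(nrow(plan)), function(i) {
    impute_segment(study_haps, ref_panel, segment = plan[i, , drop = FALSE],
                   k = k, flank = flank)
  })
  gen <- stitch_segments(lapply(results, `[[`, "gen"), plan,
                         targets = ref_panel$markers)
  info <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    inf <- results[[i]]$info
    core <- inf$position >= plan$core_lo[i] & inf$position <= plan$core_hi[i]
    dplyr::mutate(inf[core, , drop = FALSE], segment = plan$segment[i])
  }))
  info <- info[order(info$position), , drop = FALSE]
  structure(list(gen = gen, info = info), class = "imputation_result")
}
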