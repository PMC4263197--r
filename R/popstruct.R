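#' KING-robust pairwise kinship estimates
#'
#' Between-family kinship estimator robust to population stratification:
#' for samples i and j,
#' \deqn{\hat\phi_{ij} = \frac{N^{Aa,Aa}_{ij} - 2 N^{AA,aa}_{ij}}
#'   {N^{Aa}_i + N^{Aa}_j}}
#' with counts taken over markers non-missing in both samples
#' (heterozygous-concordant pairs, opposite-homozygote pairs, and each
#' sample's heterozygote count). Duplicates/MZ twins give about 0.5,
#' parent-offspring about 0.25, unrelated pairs about 0. Invariant to
#' marker order and allele relabeling.
#'
#' @param geno Integer matrix of hard-called allele dosages (0/1/2, NA
#'   missing), markers x samples, with sample ids as column names.
#' @return A tibble with one row per unordered sample pair: `id1`, `id2`,
#'   `phi`, `n_markers` (shared non-missing count). Pairs with no
#'   informative markers are excluded.
#' @export
king_kinship <- function(geno) {
  geno <- as.matrix(geno)
  n <- ncol(geno)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  ids <- colnames(geno) %||% paste0("sample", seq_len(n))
  M <- !is.na(geno)
  H <- (geno == 1L) & M; storage.mode(H) <- "double"; H[is.na(H)] <- 0
  A2 <- (geno == 2L) & M; storage.mode(A2) <- "double"; A2[is.na(A2)] <- 0
  A0 <- (geno == 0L) & M; storage.mode(A0) <- "double"; A0[is.na(A0)] <- 0
  Mm <- matrix(as.double(M), nrow(geno), n)
  n_hh <- crossprod(H)                      # both heterozygous
  n_opp <- crossprod(A2, A0) + crossprod(A0, A2)  # opposite homozygotes
  het_shared <- crossprod(H, Mm)            # i het, j non-missing
  denom <- het_shared + t(het_shared)
  shared <- crossprod(Mm)
  idx <- which(upper.tri(denom), arr.ind = TRUE)
  phi <- (n_hh[idx] - 2 * n_opp[idx]) / denom[idx]
  out <- tibble::tibble(
    id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
    phi = phi, n_markers = as.integer(shared[idx]))
  out[is.finite(out$phi), , drop = FALSE]
}

#' Retain one representative per cluster of close relatives
#'
#' Builds the graph of sample pairs with kinship above `threshold`
#' (0.125 marks second-degree relatives) and keeps exactly one sample
#' per connected component: the one with the highest call rate, ties
#' broken by the lexicographically smallest id.
#'
#' @param kinship Kinship tibble from [king_kinship()].
#' @param sample_ids All sample ids under consideration (samples with no
#'   close relative are retained).
#' @param threshold Kinship cut-off (default 0.125; pairs with
#'   `phi > threshold` are linked).
#' @param call_rates Optional named vector of per-sample call rates used
#'   to pick cluster representatives.
#' @return A tibble with `sample_id`, `component`, `kept`.
#' @export
select_unrelated <- function(kinship, sample_ids, threshold = 0.125,
                             call_rates = NULL) {
  sample_ids <- as.character(sample_ids)
  parent <- seq_along(sample_ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  related <- kinship[!is.na(kinship$phi) & kinship$phi > threshold, ,
                     drop = FALSE]
  i1 <- match(related$id1, sample_ids)
  i2 <- match(related$id2, sample_ids)
  if (anyNA(i1) || anyNA(i2)) {
    stop("kinship pairs refer to samples outside sample_ids", call. = FALSE)
  }
  for (r in seq_len(nrow(related))) {
    a <- find(i1[r]); b <- find(i2[r])
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_along(sample_ids), find, integer(1))
  cr <- if (is.null(call_rates)) stats::setNames(rep(NA_real_,
                                                     length(sample_ids)),
                                                 sample_ids)
        else call_rates[sample_ids]
  tbl <- tibble::tibble(sample_id = sample_ids,
                        component = as.integer(factor(root)),
                        call_rate = unname(cr))
  ranked <- dplyr::mutate(tbl, .cr = dplyr::coalesce(.data$call_rate, -Inf))
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$.cr), .data$sample_id)
  picked <- dplyr::ungroup(dplyr::slice_head(
    dplyr::group_by(ranked, .data$component), n = 1))
  tbl$kept <- tbl$sample_id %in% picked$sample_id
  dplyr::select(tbl, -"call_rate")
}

#' Window-based LD pruning of markers
#'
#' Removes markers below the MAF floor, then repeatedly slides a
#' `window`-marker window (advancing by `step`) and greedily removes one
#' of every marker pair whose squared dosage correlation reaches
#' `r2_threshold` (the lower-MAF marker goes; ties drop the later one),
#' until every within-window pair of surviving markers has
#' r^2 below the threshold.
#'
#' @param geno Dosage matrix (0/1/2, NA missing), markers x samples.
#' @param window Window size in markers (default 100).
#' @param r2_threshold Pairwise r^2 bound (default 0.1).
#' @param maf_floor Minimum MAF; markers at or below it are removed first
#'   (default 0.10, i.e. common markers MAF > 10% are kept).
#' @param step Window step in markers (default 5).
#' @param max_markers Optional cap: thin the surviving set evenly to at
#'   most this many markers.
#' @return Integer vector of retained marker row indices.
#' @export
ld_prune <- function(geno, window = 100, r2_threshold = 0.1,
                     maf_floor = 0.10, step = 5, max_markers = NULL) {
  geno <- as.matrix(geno)
  f <- rowMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  alive <- which(maf > maf_floor)
  repeat {
    removed_any <- FALSE
    starts <- seq(1L, max(1L, length(alive)), by = step)
    for (s in starts) {
      w <- alive[seq(s, min(s + window - 1L, length(alive)))]
      w <- w[!is.na(w)]
      if (length(w) < 2) next
      cc <- suppressWarnings(
        stats::cor(t(geno[w, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      dead <- logical(length(w))
      for (a in seq_len(length(w) - 1)) {
        if (dead[a]) next
        for (b in seq((a + 1), length(w))) {
          if (dead[b]) next
          if (cc[a, b]^2 >= r2_threshold) {
            drop_b <- maf[w[b]] <= maf[w[a]]
            dead[if (drop_b) b else a] <- TRUE
            removed_any <- TRUE
            if (!drop_b) break
          }
        }
      }
      if (any(dead)) alive <- setdiff(alive, w[dead])
    }
    if (!removed_any) break
  }
  if (!is.null(max_markers) && length(alive) > max_markers) {
    alive <- alive[unique(round(seq(1, length(alive),
                                    length.out = max_markers)))]
  }
  alive
}

#' Principal component analysis of a genotype matrix
#'
#' Standardizes each marker by its allele frequency (center by
#' \eqn{2\hat p}, scale by \eqn{\sqrt{2\hat p(1-\hat p)}}), mean-imputes
#' missing cells, and eigendecomposes the sample covariance. Intended for
#' unrelated samples and LD-pruned common markers.
#'
#' @param geno Dosage matrix (0/1/2, NA missing), markers x samples,
#'   sample ids as column names.
#' @param n_components Number of PCs to return (default 32; truncated
#'   with a warning when the sample count is smaller).
#' @return A `genotype_pca` object: `scores` tibble (sample_id, PC1..),
#'   `varexp` (variance-explained fractions, non-increasing, summing to
#'   at most 1), `n_markers`, `n_samples`.
#' @export
pca_genotypes <- function(geno, n_components = 32) {
  geno <- as.matrix(geno)
  ids <- colnames(geno) %||% paste0("sample", seq_len(ncol(geno)))
  n <- ncol(geno)
  p <- rowMeans(geno, na.rm = TRUE) / 2
  use <- !is.na(p) & p > 0 & p < 1
  g <- geno[use, , drop = FALSE]
  p <- p[use]
  for (i in seq_len(nrow(g))) {
    miss <- is.na(g[i, ])
    if (any(miss)) g[i, miss] <- 2 * p[i]
  }
  x <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  if (n_components > n) {
    warning("fewer samples (", n, ") than requested components; truncating",
            call. = FALSE)
    n_components <- n
  }
  cov <- crossprod(x) / max(1, nrow(x))
  eig <- eigen(cov, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  varexp <- if (total > 0) ev / total else rep(0, length(ev))
  k <- n_components
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                   tibble::as_tibble(scores)),
         varexp = varexp[seq_len(k)],
         n_markers = nrow(x), n_samples = n),
    class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("<genotype_pca> ", x$n_samples, " samples, ", x$n_markers,
      " markers, ", length(x$varexp), " components\n",
      "variance explained: ",
      paste(sprintf("%.3f", utils::head(x$varexp, 5)), collapse = " "),
      if (length(x$varexp) > 5) " ..." else "", "\n", sep = "")
  invisible(x)
}
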