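#' Classify strand orientation of study markers against a reference panel
#'
#' Decides, for every study marker matched to the reference panel by
#' (chrom, pos), whether its alleles should be kept, strand-flipped
#' (complemented), or the marker discarded. Three criteria are applied in
#' order:
#'
#' 1. **Observed alleles** — a non-palindromic study allele set equal to
#'    the reference set is kept; equal to the complemented reference set is
#'    flipped; incompatible even after complementing is discarded.
#' 2. **Minor allele frequency** — for palindromic (A/T, C/G) markers with
#'    both study and reference MAF at or below `maf_ambiguity_bound`, the
#'    study minor allele is compared with the reference minor allele: a
#'    match keeps, a match to its complement flips.
#' 3. **LD pattern** — when MAF is uninformative, the signs of pairwise
#'    dosage correlations with up to `window` flanking non-palindromic
#'    markers are compared between study and reference; a majority of
#'    inverted signs flips, a majority of consistent signs keeps. Neighbors
#'    are informative when the reference correlation magnitude is at least
#'    `ld_r_min`; fewer than `min_informative` informative neighbors, or a
#'    tie, discards the marker.
#'
#' Study markers absent from the reference panel are discarded. Decisions
#' are deterministic given fixed inputs.
#'
#' @param study A [study_data] object (post build-conversion).
#' @param ref_panel Reference [hap_panel].
#' @param window Maximum flanking non-palindromic markers consulted for LD
#'   arbitration (default 100).
#' @param maf_ambiguity_bound Palindromic markers with study or reference
#'   MAF above this go to LD arbitration (default 0.4).
#' @param ld_r_min Minimum reference |r| for a neighbor to count as
#'   informative (default 0.2).
#' @param min_informative Minimum informative neighbors for an LD verdict
#'   (default 3).
#' @return A tibble with one decision per study marker: `chrom`, `pos`,
#'   `rs_id`, `action` (keep/flip/discard), `basis`
#'   (allele_match/maf/ld), `detail`.
#' @export
classify_strand <- function(study, ref_panel, window = 100,
                            maf_ambiguity_bound = 0.4, ld_r_min = 0.2,
                            min_informative = 3) {
  stopifnot(inherits(study, "study_data"), inherits(ref_panel, "hap_panel"))
  sm <- study$markers
  rm_ <- ref_panel$markers
  ref_idx <- match(paste(sm$chrom, sm$pos), paste(rm_$chrom, rm_$pos))
  ref_geno <- hap_genotypes(ref_panel)        # allele-A dosage
  study_geno <- study$geno

  n <- nrow(sm)
  action <- basis <- detail <- character(n)

  # study/reference allele frequencies of allele_a
  s_fa <- rowMeans(study_geno, na.rm = TRUE) / 2
  r_fa <- rowMeans(ref_geno) / 2

  # Per-marker alignment bookkeeping against the reference, used both for
  # primary decisions and for orienting LD neighbors.
  pal <- is_palindromic(sm$allele_a, sm$allele_b)
  same_set <- matched_set <- flip_set <- rep(FALSE, n)
  sign_keep <- rep(NA_real_, n)   # +1 study allele_a == ref allele_a, else -1
  mono <- is.na(sm$allele_b)   # only one allele observed in the study
  for (i in seq_len(n)) {
    j <- ref_idx[i]
    if (is.na(j)) next
    if (mono[i]) {
      # a monomorphic study marker offers one allele: orient it by
      # membership in the reference set, unless both readings fit
      a <- sm$allele_a[i]
      if (is.na(a) || !a %in% c("A", "C", "G", "T")) next
      rs <- c(rm_$allele_a[j], rm_$allele_b[j])
      in_fwd <- a %in% rs
      in_rev <- complement_alleles(a) %in% rs
      if (in_fwd && !in_rev) {
        matched_set[i] <- TRUE
        sign_keep[i] <- if (a == rs[1]) 1 else -1
      } else if (in_rev && !in_fwd) {
        flip_set[i] <- TRUE
        sign_keep[i] <- if (complement_alleles(a) == rs[1]) 1 else -1
      }
      next
    }
    ss <- c(sm$allele_a[i], sm$allele_b[i])
    rs <- c(rm_$allele_a[j], rm_$allele_b[j])
    if (setequal(ss, rs)) {
      matched_set[i] <- TRUE
      sign_keep[i] <- if (ss[1] == rs[1]) 1 else -1
    } else if (all(ss %in% c("A", "C", "G", "T")) &&
               setequal(complement_alleles(ss), rs)) {
      flip_set[i] <- TRUE
      cs <- complement_alleles(ss)
      sign_keep[i] <- if (cs[1] == rs[1]) 1 else -1
    }
  }

  # Neighbors usable for LD arbitration: matched, non-palindromic,
  # orientable by allele identity alone.
  neighbor_ok <- !pal & (matched_set | flip_set) & !is.na(ref_idx)

  for (i in seq_len(n)) {
    j <- ref_idx[i]
    if (is.na(j)) {
      action[i] <- "discard"; basis[i] <- "allele_match"
      detail[i] <- "absent from reference panel"
      next
    }
    if (!pal[i]) {
      if (matched_set[i]) {
        action[i] <- "keep"; basis[i] <- "allele_match"
        detail[i] <- "allele sets identical"
      } else if (flip_set[i]) {
        action[i] <- "flip"; basis[i] <- "allele_match"
        detail[i] <- "allele sets identical after complement"
      } else {
        action[i] <- "discard"; basis[i] <- "allele_match"
        detail[i] <- if (mono[i]) {
          "single observed allele cannot be oriented"
        } else {
          "incompatible allele sets"
        }
      }
      next
    }
    # palindromic
    if (!matched_set[i]) {
      action[i] <- "discard"; basis[i] <- "allele_match"
      detail[i] <- "incompatible allele sets"
      next
    }
    s_maf <- min(s_fa[i], 1 - s_fa[i])
    r_maf <- min(r_fa[j], 1 - r_fa[j])
    maf_informative <- is.finite(s_maf) &&
      s_maf <= maf_ambiguity_bound && r_maf <= maf_ambiguity_bound &&
      s_maf < 0.5 && r_maf < 0.5
    if (maf_informative) {
      s_minor <- if (s_fa[i] < 0.5) sm$allele_a[i] else sm$allele_b[i]
      r_minor <- if (r_fa[j] < 0.5) rm_$allele_a[j] else rm_$allele_b[j]
      if (s_minor == r_minor) {
        action[i] <- "keep"; basis[i] <- "maf"
        detail[i] <- sprintf("minor alleles agree (study %.3f, ref %.3f)",
                             s_maf, r_maf)
      } else {
        action[i] <- "flip"; basis[i] <- "maf"
        detail[i] <- sprintf(
          "study minor allele matches reference complement (study %.3f, ref %.3f)",
          s_maf, r_maf)
      }
      next
    }
    # LD arbitration
    cand <- which(neighbor_ok & sm$chrom == sm$chrom[i] &
                    seq_len(n) != i)
    if (length(cand) > window) {
      cand <- cand[order(abs(sm$pos[cand] - sm$pos[i]), cand)][seq_len(window)]
    }
    n_cons <- n_inv <- 0L
    for (m in cand) {
      jm <- ref_idx[m]
      r_ref <- suppressWarnings(stats::cor(ref_geno[j, ], ref_geno[jm, ]))
      if (is.na(r_ref) || abs(r_ref) < ld_r_min) next
      # align neighbor's study dosage to reference allele_a orientation
      d_nb <- study_geno[m, ]
      if (sign_keep[m] < 0) d_nb <- 2 - d_nb
      r_study <- suppressWarnings(stats::cor(study_geno[i, ], d_nb,
                                             use = "pairwise.complete.obs"))
      if (is.na(r_study) || r_study == 0) next
      # sign expected under the "keep" hypothesis for the target
      consistent <- sign(r_study * sign_keep[i]) == sign(r_ref)
      if (consistent) n_cons <- n_cons + 1L else n_inv <- n_inv + 1L
    }
    n_info <- n_cons + n_inv
    if (n_info < min_informative) {
      action[i] <- "discard"; basis[i] <- "ld"
      detail[i] <- if (n_info == 0) "no informative neighbors" else
        sprintf("only %d informative neighbors", n_info)
    } else if (n_cons > n_info / 2) {
      action[i] <- "keep"; basis[i] <- "ld"
      detail[i] <- sprintf("%d/%d neighbors sign-consistent", n_cons, n_info)
    } else if (n_inv > n_info / 2) {
      action[i] <- "flip"; basis[i] <- "ld"
      detail[i] <- sprintf("%d/%d neighbors sign-inverted", n_inv, n_info)
    } else {
      action[i] <- "discard"; basis[i] <- "ld"
      detail[i] <- sprintf("LD signs tied (%d vs %d)", n_cons, n_inv)
    }
  }
  tibble::tibble(chrom = sm$chrom, pos = sm$pos, rs_id = sm$rs_id,
                 action = action, basis = basis, detail = detail)
}

#' Apply strand decisions to a dataset
#'
#' `flip` complements the marker's allele labels (genotype and haplotype
#' encodings are preserved: 0/1 and dosage values keep their meaning under
#' the relabeled alleles); `discard` removes the marker; `keep` leaves it
#' untouched.
#'
#' @param x A [study_data] or [hap_panel] object.
#' @param decisions Decision tibble from [classify_strand()]; must cover
#'   every marker of `x` (matched by chrom and pos).
#' @return An object of the same class as `x`, harmonized.
#' @export
apply_strand_decisions <- function(x, decisions) {
  UseMethod("apply_strand_decisions")
}

strand_match_decisions <- function(markers, decisions) {
  idx <- match(paste(markers$chrom, markers$pos),
               paste(decisions$chrom, decisions$pos))
  if (anyNA(idx)) {
    stop("decisions missing for markers: ",
         paste(utils::head(markers$rs_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  unknown <- !(paste(decisions$chrom, decisions$pos) %in%
                 paste(markers$chrom, markers$pos))
  if (any(unknown)) {
    stop("decisions refer to unknown markers: ",
         paste(utils::head(decisions$rs_id[unknown], 5), collapse = ", "),
         call. = FALSE)
  }
  decisions$action[idx]
}

apply_strand_to_markers <- function(markers, action) {
  flip <- action == "flip"
  markers$allele_a[flip] <- complement_alleles(markers$allele_a[flip])
  markers$allele_b[flip] <- complement_alleles(markers$allele_b[flip])
  markers
}

#' @export
apply_strand_decisions.study_data <- function(x, decisions) {
  action <- strand_match_decisions(x$markers, decisions)
  keep <- action != "discard"
  markers <- apply_strand_to_markers(x$markers, action)[keep, , drop = FALSE]
  study_data(markers, x$geno[keep, , drop = FALSE], x$samples)
}

#' @export
apply_strand_decisions.hap_panel <- function(x, decisions) {
  action <- strand_match_decisions(x$markers, decisions)
  keep <- action != "discard"
  markers <- apply_strand_to_markers(x$markers, action)[keep, , drop = FALSE]
  hap_panel(markers, x$haps[keep, , drop = FALSE], x$sample_ids)
}
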