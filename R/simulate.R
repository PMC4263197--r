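#' Simulation configuration for multi-platform study fixtures
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' desk-scale study: a 5 Mb chromosome with 500 markers, a reference panel
#' of 200 haplotypes carrying block LD from founder-mosaic copying, 100
#' study individuals genotyped on 3 partially overlapping platforms, 2%
#' injected strand flips on non-palindromic markers, a constant stale-build
#' coordinate offset with a matching conversion table, 5 duplicate samples
#' across platforms and 1% missingness.
#'
#' @param n_ref_haplotypes Reference haplotypes (default 200; even).
#' @param n_study_samples Unique study individuals (default 100).
#' @param n_markers Markers on the chromosome (default 500).
#' @param chrom Chromosome label (default "1").
#' @param chrom_length Chromosome length in bp (default 5e6).
#' @param n_founders Founder haplotypes per subpopulation behind the
#'   mosaic (default 8).
#' @param switch_rate Per-marker founder-switch probability; 0 copies one
#'   founder end-to-end (default 0.02).
#' @param mutation_rate Per-site allele flip probability (default 0.002).
#' @param n_platforms Genotyping platforms (default 3).
#' @param platform_fraction Fraction of markers each platform genotypes
#'   (default 0.6).
#' @param platform_overlap Fraction of each platform's markers shared by
#'   all platforms (default 0.6).
#' @param flip_rate Fraction of each platform's non-palindromic markers
#'   receiving an injected complement flip (default 0.02).
#' @param build_offset Stale-build coordinate shift in bp (default 1000).
#' @param unmapped_rate Fraction of markers whose conversion is
#'   indeterminate (default 0.02).
#' @param n_duplicates Samples genotyped on two platforms (default 5).
#' @param missing_rate Per-genotype missingness (default 0.01).
#' @param n_subpops Subpopulations (default 1).
#' @param divergence Balding-Nichols F between subpopulations (default
#'   0.05).
#' @param seed Master seed; the seed fully determines all output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ref_haplotypes = 200, n_study_samples = 100,
                       n_markers = 500, chrom = "1", chrom_length = 5e6,
                       n_founders = 8, switch_rate = 0.02,
                       mutation_rate = 0.002, n_platforms = 3,
                       platform_fraction = 0.6, platform_overlap = 0.6,
                       flip_rate = 0.02, build_offset = 1000,
                       unmapped_rate = 0.02, n_duplicates = 5,
                       missing_rate = 0.01, n_subpops = 1,
                       divergence = 0.05, seed = 1) {
  cfg <- as.list(environment())
  rates <- c("switch_rate", "mutation_rate", "platform_fraction",
             "platform_overlap", "flip_rate", "unmapped_rate",
             "missing_rate", "divergence")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop(r, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (n_ref_haplotypes %% 2 != 0) {
    stop("n_ref_haplotypes must be even", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate a phased reference haplotype panel with block LD
#'
#' Ancestral allele frequencies are drawn uniformly on (0.05, 0.95);
#' subpopulation frequencies follow a Balding-Nichols Beta around the
#' ancestral value with divergence `F`. A small founder pool per
#' subpopulation is drawn from those frequencies, and each output
#' haplotype is a mosaic copy of its subpopulation's founders with the
#' configured per-marker switch rate, which induces block LD that decays
#' with distance. A per-site mutation rate adds noise.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed`.
#' @return A [hap_panel]; individuals carry a `subpop` attribute.
#' @export
simulate_reference <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n_m <- config$n_markers
    pos <- sort(sample.int(config$chrom_length, n_m))
    allele_pairs <- t(vapply(seq_len(n_m), function(i)
      sample(c("A", "C", "G", "T"), 2), character(2)))
    p_anc <- stats::runif(n_m, 0.05, 0.95)
    Fst <- config$divergence
    K <- config$n_subpops
    p_sub <- vapply(seq_len(K), function(k) {
      if (Fst == 0 || K == 1) p_anc else
        stats::rbeta(n_m, p_anc * (1 - Fst) / Fst,
                     (1 - p_anc) * (1 - Fst) / Fst)
    }, numeric(n_m))
    n_h <- config$n_ref_haplotypes
    n_ind <- n_h %/% 2L
    subpop_of_ind <- rep(seq_len(K), length.out = n_ind)
    # one founder pool per subpopulation, shared by all its haplotypes,
    # so that mosaic copying induces allele sharing (LD) across the panel
    founder_pool <- lapply(seq_len(K), function(k) matrix(
      stats::rbinom(n_m * config$n_founders, 1, p_sub[, k]),
      n_m, config$n_founders))
    haps <- matrix(0L, n_m, n_h)
    for (h in seq_len(n_h)) {
      k <- subpop_of_ind[ceiling(h / 2)]
      founders <- founder_pool[[k]]
      # mosaic copy: founder index switches along the chromosome
      f <- sample.int(config$n_founders, 1)
      path <- integer(n_m)
      for (i in seq_len(n_m)) {
        if (i > 1 && stats::runif(1) < config$switch_rate) {
          f <- sample.int(config$n_founders, 1)
        }
        path[i] <- f
      }
      hap <- founders[cbind(seq_len(n_m), path)]
      mut <- stats::runif(n_m) < config$mutation_rate
      hap[mut] <- 1L - hap[mut]
      haps[, h] <- hap
    }
    markers <- tibble::tibble(
      chrom = config$chrom, snp_id = "---",
      rs_id = paste0("rs", seq_len(n_m)), pos = as.integer(pos),
      allele_a = allele_pairs[, 1], allele_b = allele_pairs[, 2],
      type = NA_integer_)
    panel <- hap_panel(markers, haps,
                       sample_ids = paste0("ref", seq_len(n_ind)))
    attr(panel, "subpop") <- subpop_of_ind
    panel
  })
}

#' Simulate multi-platform study datasets with injected artifacts
#'
#' Study individuals are formed by pairing randomly drawn reference
#' haplotypes (subpopulation-matched). Each platform genotypes its own
#' marker subset (a core shared by all platforms plus platform-specific
#' markers), in stale-build coordinates shifted by `build_offset`, with a
#' matching coordinate-conversion table emitted (a fraction of markers is
#' marked unmapped). Complement flips are injected on a recorded subset
#' of each platform's non-palindromic markers; duplicates are copied
#' across platforms with independent missingness. The truth store records
#' every injection so pipeline stages can be verified against it.
#'
#' @param config A [sim_config()].
#' @param panel Reference panel from [simulate_reference()].
#' @param seed Overrides `config$seed + 1`.
#' @return A list with `platforms` (per platform: `study` a [study_data]
#'   in old-build coordinates with flipped alleles, `haps` the pre-phased
#'   truth-phase [hap_panel] in reference coordinates/alleles),
#'   `coordinate_map`, and `truth` (flips, unmapped markers, duplicates,
#'   per-individual subpopulation and the full truth genotype matrix).
#' @export
simulate_study <- function(config, panel, seed = config$seed + 1) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "hap_panel"))
  with_seed(seed, {
    n_m <- nrow(panel$markers)
    n_ind <- config$n_study_samples
    subpop_ref <- attr(panel, "subpop") %||% rep(1L, n_samples(panel))
    subpop_ind <- rep(seq_len(config$n_subpops), length.out = n_ind)
    hap_pool <- split(seq_len(ncol(panel$haps)),
                      rep(subpop_ref, each = 2))
    hap_idx <- t(vapply(subpop_ind, function(k) {
      pool <- hap_pool[[as.character(k)]] %||% seq_len(ncol(panel$haps))
      sample(pool, 2, replace = TRUE)
    }, integer(2)))
    study_haps <- matrix(0L, n_m, 2 * n_ind)
    study_haps[, 2 * seq_len(n_ind) - 1] <- panel$haps[, hap_idx[, 1]]
    study_haps[, 2 * seq_len(n_ind)] <- panel$haps[, hap_idx[, 2]]
    ids <- sprintf("ind%03d", seq_len(n_ind))
    truth_geno <- 2L - study_haps[, 2 * seq_len(n_ind) - 1] -
      study_haps[, 2 * seq_len(n_ind)]
    colnames(truth_geno) <- ids

    # platform marker subsets: shared core + platform-specific remainder
    p_size <- round(config$platform_fraction * n_m)
    core_size <- round(config$platform_overlap * p_size)
    core <- sort(sample.int(n_m, core_size))
    platform_markers <- lapply(seq_len(config$n_platforms), function(p) {
      extra <- sample(setdiff(seq_len(n_m), core), p_size - core_size)
      sort(c(core, extra))
    })

    # coordinate map: every marker, shifted old build -> true build
    unmapped <- sort(sample.int(n_m, round(config$unmapped_rate * n_m)))
    mk <- panel$markers
    coordinate_map <- tibble::tibble(
      old_chrom = mk$chrom, old_pos = mk$pos + config$build_offset,
      old_label = mk$rs_id,
      new_chrom = ifelse(seq_len(n_m) %in% unmapped, NA_character_,
                         mk$chrom),
      new_pos = ifelse(seq_len(n_m) %in% unmapped, NA_integer_, mk$pos),
      new_label = mk$rs_id,
      status = ifelse(seq_len(n_m) %in% unmapped, "unmapped", "mapped"))

    # assign individuals to platforms; add duplicate copies
    platform_of <- rep(seq_len(config$n_platforms), length.out = n_ind)
    dup_ind <- if (config$n_duplicates > 0)
      sort(sample.int(n_ind, config$n_duplicates)) else integer()
    dup_platform <- vapply(dup_ind, function(i) {
      others <- setdiff(seq_len(config$n_platforms), platform_of[i])
      if (length(others) == 0) platform_of[i] else sample(others, 1)
    }, integer(1))

    platforms <- vector("list", config$n_platforms)
    flips <- list()
    for (p in seq_len(config$n_platforms)) {
      pm <- platform_markers[[p]]
      members <- c(which(platform_of == p), dup_ind[dup_platform == p])
      members <- sort(unique(members))
      geno <- truth_geno[pm, members, drop = FALSE]
      miss <- matrix(stats::runif(length(geno)) < config$missing_rate,
                     nrow(geno))
      geno[miss] <- NA_integer_
      mkp <- mk[pm, , drop = FALSE]
      # inject strand flips on non-palindromic platform markers
      nonpal <- which(!is_palindromic(mkp$allele_a, mkp$allele_b))
      n_flip <- round(config$flip_rate * length(nonpal))
      flip_rows <- if (n_flip > 0) sort(sample(nonpal, n_flip)) else integer()
      mkp$allele_a[flip_rows] <- complement_alleles(mkp$allele_a[flip_rows])
      mkp$allele_b[flip_rows] <- complement_alleles(mkp$allele_b[flip_rows])
      flips[[p]] <- tibble::tibble(
        platform = paste0("platform", p),
        chrom = mkp$chrom[flip_rows], pos = mkp$pos[flip_rows],
        rs_id = mkp$rs_id[flip_rows])
      # stale-build coordinates
      mkp_old <- dplyr::mutate(mkp,
                               pos = .data$pos + config$build_offset,
                               type = 2L)
      samples <- tibble::tibble(
        sample_id = ids[members],
        dataset_id = paste0("platform", p),
        call_rate = colMeans(!is.na(geno)))
      hapcols <- as.vector(rbind(2 * members - 1, 2 * members))
      platforms[[p]] <- list(
        id = paste0("platform", p),
        study = study_data(mkp_old, geno, samples),
        haps = hap_panel(dplyr::mutate(mk[pm, , drop = FALSE], type = 2L),
                         study_haps[pm, hapcols, drop = FALSE],
                         sample_ids = ids[members]))
    }
    list(
      platforms = platforms,
      coordinate_map = coordinate_map,
      truth = list(
        flips = dplyr::bind_rows(flips),
        unmapped = mk$rs_id[unmapped],
        duplicates = tibble::tibble(
          sample_id = ids[dup_ind],
          platform_primary = paste0("platform", platform_of[dup_ind]),
          platform_dup = paste0("platform", dup_platform)),
        subpop = stats::setNames(subpop_ind, ids),
        geno = truth_geno,
        study_haps = hap_panel(mk, study_haps, sample_ids = ids)))
  })
}

#' Simulate parent-offspring duos from a reference panel
#'
#' Each duo pairs a parent (two random panel haplotypes) with a child who
#' inherits one of the parent's haplotypes plus one random panel
#' haplotype — giving an expected KING kinship of 0.25.
#'
#' @param panel A [hap_panel].
#' @param n_pairs Number of duos.
#' @param seed RNG seed.
#' @return A dosage matrix (markers x `2 * n_pairs`), columns named
#'   `parentN`/`childN`.
#' @export
simulate_parent_offspring <- function(panel, n_pairs, seed = 1) {
  stopifnot(inherits(panel, "hap_panel"))
  with_seed(seed, {
    n_h <- ncol(panel$haps)
    out <- matrix(0L, nrow(panel$markers), 2 * n_pairs)
    nm <- character(2 * n_pairs)
    for (i in seq_len(n_pairs)) {
      ph <- sample.int(n_h, 2)
      transmitted <- ph[sample.int(2, 1)]
      ch <- c(transmitted, sample.int(n_h, 1))
      out[, 2 * i - 1] <- 2L - panel$haps[, ph[1]] - panel$haps[, ph[2]]
      out[, 2 * i] <- 2L - panel$haps[, ch[1]] - panel$haps[, ch[2]]
      nm[2 * i - 1] <- paste0("parent", i)
      nm[2 * i] <- paste0("child", i)
    }
    colnames(out) <- nm
    out
  })
}
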