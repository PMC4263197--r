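identity_map <- function(markers) {
  tibble::tibble(old_chrom = markers$chrom, old_pos = markers$pos,
                 old_label = markers$rs_id, new_chrom = markers$chrom,
                 new_pos = markers$pos, new_label = markers$rs_id,
                 status = "mapped")
}

test_that("coordinate conversion drops unmapped markers and is an identity on identity maps", {
  markers <- random_markers(20, seed = 21)
  map <- identity_map(markers)
  map$status[3] <- "unmapped"
  map$new_chrom[3] <- NA; map$new_pos[3] <- NA
  res <- apply_coordinate_map(markers, map)
  expect_equal(nrow(res$markers), 19)
  expect_equal(res$dropped$rs_id, markers$rs_id[3])
  expect_false(markers$rs_id[3] %in% res$markers$rs_id)

  res_id <- apply_coordinate_map(markers, identity_map(markers))
  expect_equal(res_id$markers, sort_markers(markers))
  expect_equal(nrow(res_id$dropped), 0)
})

test_that("conversion agrees with a direct table-join oracle on a 100-marker fixture", {
  markers <- random_markers(100, seed = 22)
  map <- identity_map(markers)
  withr::with_seed(23, {
    unmapped <- sample(100, 10)
    renamed <- sample(setdiff(seq_len(100), unmapped), 5)
    shifted <- setdiff(seq_len(100), unmapped)
  })
  map$status[unmapped] <- "unmapped"
  map$new_chrom[unmapped] <- NA; map$new_pos[unmapped] <- NA
  map$new_label[renamed] <- paste0("kgp", seq_along(renamed))
  map$new_pos[shifted] <- map$new_pos[shifted] + 37L

  res <- apply_coordinate_map(markers, map)
  # independent oracle: plain merge in base R
  oracle <- merge(as.data.frame(markers), as.data.frame(map),
                  by.x = c("chrom", "pos", "rs_id"),
                  by.y = c("old_chrom", "old_pos", "old_label"))
  oracle <- oracle[oracle$status == "mapped", ]
  oracle <- oracle[order(oracle$new_pos), ]
  expect_equal(nrow(res$markers), 90)
  expect_equal(nrow(res$dropped), 10)
  expect_equal(res$markers$pos, as.integer(oracle$new_pos))
  expect_equal(res$markers$rs_id, oracle$new_label)
  expect_equal(sum(grepl("^kgp", res$markers$rs_id)), 5)
  # conservation: output + dropped = input
  expect_equal(nrow(res$markers) + nrow(res$dropped), nrow(markers))
})

test_that("conversion collisions are fatal and name both labels", {
  markers <- marker_table(chrom = "1", rs_id = c("rsA", "rsB"),
                          pos = c(100L, 200L), allele_a = c("A", "A"),
                          allele_b = c("G", "G"))
  map <- identity_map(markers)
  map$new_pos <- c(500L, 500L)   # both land on the same spot
  expect_error(apply_coordinate_map(markers, map), "rsA.*rsB")
})

test_that("allele complementation matches a lookup oracle and is an involution", {
  oracle <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(a = bases, b = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]   # all 12 ordered pairs
  for (i in seq_len(nrow(pairs))) {
    expect_identical(complement_alleles(c(pairs$a[i], pairs$b[i])),
                     unname(oracle[c(pairs$a[i], pairs$b[i])]))
  }
  expect_identical(complement_alleles(complement_alleles(bases)), bases)
  expect_error(complement_alleles("I"), "unsupported allele")
  # palindromic pairs keep the same unordered set
  expect_setequal(complement_alleles(c("A", "T")), c("A", "T"))
})

# build a study/reference pair over shared positions with controlled genotypes
strand_fixture <- function(ref_haps, study_geno, study_a, study_b,
                           ref_a = NULL, ref_b = NULL, pos = NULL) {
  n <- nrow(ref_haps)
  pos <- pos %||% seq_len(n) * 1000L
  ref_a <- ref_a %||% rep("A", n)
  ref_b <- ref_b %||% rep("G", n)
  ref <- hap_panel(marker_table(chrom = "1", rs_id = paste0("rs", seq_len(n)),
                                pos = pos, allele_a = ref_a,
                                allele_b = ref_b),
                   ref_haps)
  study <- study_from_geno(
    marker_table(chrom = "1", rs_id = paste0("rs", seq_len(n)), pos = pos,
                 allele_a = study_a, allele_b = study_b),
    study_geno)
  list(study = study, ref = ref)
}

test_that("non-palindromic markers resolve by allele sets alone", {
  haps <- matrix(rbinom(3 * 20, 1, 0.4), 3)
  geno <- matrix(sample(0:2, 3 * 10, replace = TRUE), 3)
  fx <- strand_fixture(haps, geno,
                       study_a = c("A", "T", "A"),
                       study_b = c("G", "C", "C"),
                       ref_a = c("A", "A", "A"),
                       ref_b = c("G", "G", "G"))
  dec <- classify_strand(fx$study, fx$ref)
  expect_equal(dec$action, c("keep", "flip", "discard"))
  expect_equal(dec$basis, rep("allele_match", 3))
})

test_that("palindromic markers follow the MAF decision table", {
  # hand-computed truth table over the four orientations of an A/T SNP:
  # study minor allele vs reference minor allele (ref MAF 0.11 on T)
  n_ref <- 50
  ref_haps_minorB <- matrix(0L, 1, n_ref * 2)
  ref_haps_minorB[1, seq_len(round(0.11 * n_ref * 2))] <- 1L  # allele_b=T minor
  make_geno <- function(minor_dose_on_a) {
    # 10 samples; allele_a dosage; MAF 0.10
    if (minor_dose_on_a) matrix(c(rep(1L, 2), rep(0L, 8)), 1)
    else matrix(c(rep(1L, 2), rep(2L, 8)), 1)
  }
  # study minor = A, ref minor = T  -> flip
  fx <- strand_fixture(ref_haps_minorB, make_geno(TRUE),
                       study_a = "A", study_b = "T",
                       ref_a = "A", ref_b = "T")
  d <- classify_strand(fx$study, fx$ref)
  expect_equal(d$action, "flip"); expect_equal(d$basis, "maf")
  # study minor = T, ref minor = T -> keep
  fx <- strand_fixture(ref_haps_minorB, make_geno(FALSE),
                       study_a = "A", study_b = "T",
                       ref_a = "A", ref_b = "T")
  d <- classify_strand(fx$study, fx$ref)
  expect_equal(d$action, "keep"); expect_equal(d$basis, "maf")
  # same set written in reverse order: study (T, A), minor still on T
  fx <- strand_fixture(ref_haps_minorB, make_geno(TRUE),
                       study_a = "T", study_b = "A",
                       ref_a = "A", ref_b = "T")
  d <- classify_strand(fx$study, fx$ref)
  expect_equal(d$action, "keep"); expect_equal(d$basis, "maf")
  # incompatible set: study C/G vs ref A/T -> discard
  fx <- strand_fixture(ref_haps_minorB, make_geno(TRUE),
                       study_a = "C", study_b = "G",
                       ref_a = "A", ref_b = "T")
  d <- classify_strand(fx$study, fx$ref)
  expect_equal(d$action, "discard")
})

test_that("ambiguous-MAF palindromic markers are arbitrated by LD sign patterns", {
  # target (marker 1) is A/T with MAF ~0.5 in study and reference; four
  # perfectly correlated non-palindromic neighbors carry the LD signal
  n_pairs <- 30
  # allele frequency pinned at exactly 0.5 so MAF is uninformative
  x <- withr::with_seed(77, sample(rep(0:1, n_pairs)))
  ref_haps <- rbind(x, x, x, x, x)   # target + 4 identical neighbors
  ref_geno <- matrix(ref_haps[1, seq(1, 2 * n_pairs, 2)] +
                       ref_haps[1, seq(2, 2 * n_pairs, 2)], 1)[rep(1, 5), ]
  consistent <- 2L - ref_geno        # allele-A dosage, aligned
  inverted <- consistent
  inverted[1, ] <- 2L - inverted[1, ]  # target dosage on the other strand
  mk <- list(study_a = c("A", "A", "A", "A", "A"),
             study_b = c("T", "G", "G", "G", "G"),
             ref_a = c("A", "A", "A", "A", "A"),
             ref_b = c("T", "G", "G", "G", "G"))
  fx <- strand_fixture(ref_haps, consistent, mk$study_a, mk$study_b,
                       mk$ref_a, mk$ref_b)
  d <- classify_strand(fx$study, fx$ref)
  expect_equal(d$action[1], "keep"); expect_equal(d$basis[1], "ld")
  fx <- strand_fixture(ref_haps, inverted, mk$study_a, mk$study_b,
                       mk$ref_a, mk$ref_b)
  d <- classify_strand(fx$study, fx$ref)
  expect_equal(d$action[1], "flip"); expect_equal(d$basis[1], "ld")
  # no informative neighbors -> discard with basis ld
  lone <- strand_fixture(matrix(x, 1), matrix(consistent[1, ], 1),
                         "A", "T", "A", "T")
  d <- classify_strand(lone$study, lone$ref)
  expect_equal(d$action, "discard"); expect_equal(d$basis, "ld")
  expect_match(d$detail, "neighbors")
})

test_that("markers with a single observed allele are oriented by set membership", {
  haps <- matrix(rbinom(3 * 20, 1, 0.4), 3)
  geno <- matrix(0L, 3, 10)    # monomorphic in the study sample
  fx <- strand_fixture(haps, geno,
                       study_a = c("G", "C", "A"),
                       study_b = rep(NA_character_, 3),
                       ref_a = c("A", "A", "A"),
                       ref_b = c("G", "G", "T"))
  dec <- classify_strand(fx$study, fx$ref)
  # G is in the reference set; C only complements into it; A fits an A/T
  # reference both ways and cannot be oriented
  expect_equal(dec$action, c("keep", "flip", "discard"))
  expect_match(dec$detail[3], "single observed allele")
})

test_that("applying decisions flips labels, drops markers and rejects unknowns", {
  markers <- random_markers(10, seed = 31)
  geno <- withr::with_seed(31, matrix(sample(0:2, 50, TRUE), 10))
  study <- study_from_geno(markers, geno)
  dec <- tibble::tibble(chrom = markers$chrom, pos = markers$pos,
                        rs_id = markers$rs_id,
                        action = "keep", basis = "allele_match", detail = "")
  # all-keep is an identity
  expect_equal(apply_strand_decisions(study, dec)$markers, study$markers)
  dec$action[2] <- "flip"; dec$action[5] <- "discard"
  out <- apply_strand_decisions(study, dec)
  expect_equal(nrow(out$markers), 9)
  expect_false(markers$rs_id[5] %in% out$markers$rs_id)
  expect_equal(out$markers$allele_a[out$markers$rs_id == markers$rs_id[2]],
               complement_alleles(markers$allele_a[2]))
  # genotype encodings are preserved under flips
  expect_equal(out$geno[out$markers$rs_id == markers$rs_id[2], ], geno[2, ])
  # decisions for unknown markers are consistency errors
  expect_error(apply_strand_decisions(study, dplyr::mutate(dec, pos = pos + 1)),
               "missing|unknown")
})

test_that("injected complement flips on non-palindromic markers are fully recovered", {
  cfg <- sim_config(n_markers = 300, n_ref_haplotypes = 120,
                    n_study_samples = 60, flip_rate = 0.1, seed = 33)
  panel <- simulate_reference(cfg)
  sim <- simulate_study(cfg, panel)
  for (p in sim$platforms) {
    lifted <- liftover_study(p$study, sim$coordinate_map)
    dec <- classify_strand(lifted$study, panel)
    injected <- sim$truth$flips[sim$truth$flips$platform == p$id, ]
    # flips injected on markers with indeterminate build mappings never
    # reach the strand stage
    injected <- injected[injected$pos %in% dec$pos, ]
    flagged <- dec[dec$action == "flip" & dec$basis == "allele_match", ]
    expect_setequal(flagged$pos, injected$pos)  # exact recovery, no extras
    # applying the decisions restores reference allele sets everywhere
    harm <- apply_strand_decisions(lifted$study, dec)
    ref_idx <- match(paste(harm$markers$chrom, harm$markers$pos),
                     paste(panel$markers$chrom, panel$markers$pos))
    same_set <- mapply(function(a, b, ra, rb) setequal(c(a, b), c(ra, rb)),
                       harm$markers$allele_a, harm$markers$allele_b,
                       panel$markers$allele_a[ref_idx],
                       panel$markers$allele_b[ref_idx])
    expect_true(all(same_set))
    # decisions are deterministic
    expect_identical(dec, classify_strand(lifted$study, panel))
  }
})

test_that("pre-harmonization QC filters remove low call-rate and low-MAF markers", {
  markers <- random_markers(5, seed = 41)
  geno <- rbind(
    rep(1L, 20),                          # MAF 0.5, complete
    c(rep(NA_integer_, 3), rep(1L, 17)),  # call rate 0.85
    rep(0L, 20),                          # monomorphic (MAF 0)
    c(rep(2L, 19), 1L),                   # MAF 0.025
    c(rep(2L, 15), rep(1L, 5)))           # MAF 0.125
  study <- study_from_geno(markers, geno)
  out <- filter_study_qc(study, marker_call_rate = 0.95,
                         sample_call_rate = 0, maf = 0.05)
  expect_equal(out$markers$rs_id, markers$rs_id[c(1, 5)])
  # palindromic pre-filter
  markers2 <- markers
  markers2$allele_a <- c("A", "A", "A", "A", "C")
  markers2$allele_b <- c("T", "G", "G", "G", "G")
  out2 <- filter_study_qc(study_from_geno(markers2, geno),
                          drop_palindromic = TRUE)
  expect_false(any(is_palindromic(out2$markers$allele_a,
                                  out2$markers$allele_b)))
})
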