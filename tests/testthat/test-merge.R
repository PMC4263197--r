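# build a small mergeable dataset from explicit pieces
mk_dataset <- function(id, markers, probs, info_scores, sample_ids,
                       call_rates = NULL, exp_freq = NULL, type = 0L,
                       genome_wide = TRUE, masked_concordance = 0.95) {
  n <- nrow(markers)
  info <- tibble::tibble(
    snp_id = "---", rs_id = markers$rs_id, position = markers$pos,
    exp_freq_a1 = exp_freq %||% rep(0.3, n), info = info_scores,
    certainty = rep(0.98, n), type = rep_len(type, n),
    info_type0 = -1, concord_type0 = -1, r2_type0 = -1)
  samples <- tibble::tibble(sample_id = sample_ids, dataset_id = id,
                            call_rate = call_rates %||%
                              rep(NA_real_, length(sample_ids)))
  imputed_dataset(id, gen_data(markers, probs, samples = samples), info,
                  genome_wide = genome_wide,
                  masked_concordance = masked_concordance)
}

test_that("dataset gates exclude small, sparse or discordant datasets", {
  manifest <- tibble::tibble(
    dataset_id = c("tiny", "sparse", "bad", "ok_boundary", "good"),
    n_samples = c(32L, 500L, 500L, 100L, 1000L),
    genome_wide = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    masked_concordance = c(0.9, 0.9, 0.79, 0.80, 0.99))
  g <- gate_datasets(manifest)
  expect_equal(g$eligible, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_match(g$reason[1], "fewer than 100")
  expect_match(g$reason[2], "genome-wide")
  expect_match(g$reason[3], "concordance")
})

test_that("marker intersection requires info strictly above threshold in all datasets", {
  markers <- random_markers(40, seed = 81)
  probs <- matrix(rep(c(1, 0, 0), 40 * 2), 40, 6, byrow = TRUE)
  ids <- sprintf("s%d", 1:2)
  info_a <- withr::with_seed(82, round(runif(40), 2))
  info_b <- withr::with_seed(83, round(runif(40), 2))
  info_a[5] <- 0.69; info_b[5] <- 0.95      # fails in one dataset only
  info_a[6] <- 0.7                          # boundary: strictly greater
  da <- mk_dataset("a", markers, probs, info_a, ids)
  db <- mk_dataset("b", markers, probs, info_b, paste0(ids, "b"))
  keys <- intersect_markers(list(da, db))
  oracle <- intersect(marker_key(markers)[info_a > 0.7],
                      marker_key(markers)[info_b > 0.7])
  expect_setequal(keys, oracle)
  expect_false(marker_key(markers)[5] %in% keys)
  expect_false(marker_key(markers)[6] %in% keys)
  # single-dataset merge: all of its info > 0.7 markers
  expect_setequal(intersect_markers(list(da)),
                  marker_key(markers)[info_a > 0.7])
})

test_that("label resolution follows plurality, larger-rs ties and drop-both rules", {
  lbl <- function(...) tibble::tibble(key = "1:100:A:G", label = c(...))
  expect_equal(resolve_labels(lbl("rs5", "rs5", "kgp11"))$map$label, "rs5")
  expect_equal(resolve_labels(lbl("rs5", "rs7"))$map$label, "rs7")
  expect_equal(resolve_labels(lbl("rs5", "rs12"))$map$label, "rs12")
  # non rs-style tie: lexicographically larger wins
  expect_equal(resolve_labels(lbl("kgpA", "kgpB"))$map$label, "kgpB")
  # one label at two positions drops both keys
  two_pos <- tibble::tibble(key = c("1:100:A:G", "1:200:C:T"),
                            label = c("rs9", "rs9"))
  res <- resolve_labels(two_pos)
  expect_equal(nrow(res$map), 0)
  expect_setequal(res$dropped$key, two_pos$key)

  # randomized fixtures vs a brute-force oracle
  withr::with_seed(84, {
    keys <- paste0("1:", sample(1000, 30), ":A:G")
    tbl <- tibble::tibble(
      key = rep(keys, each = 3),
      label = paste0("rs", sample(50, 90, replace = TRUE)))
  })
  res <- resolve_labels(tbl)
  for (k in unique(res$map$key)) {
    lbls <- tbl$label[tbl$key == k]
    counts <- table(lbls)
    best <- names(counts)[counts == max(counts)]
    expected <- best[which.max(as.numeric(sub("rs", "", best)))]
    expect_equal(res$map$label[res$map$key == k], expected)
  }
})

test_that("allele alignment swaps P(AA)/P(BB) and is an involution", {
  probs <- c(0.2, 0.3, 0.5, 0.9, 0.1, 0.0)
  r <- align_alleles(probs, "A", "G", "G", "A")
  expect_true(r$reversed)
  expect_equal(r$probs, c(0.5, 0.3, 0.2, 0.0, 0.1, 0.9))
  # identical order: identity
  same <- align_alleles(probs, "A", "G", "A", "G")
  expect_false(same$reversed)
  expect_equal(same$probs, probs)
  # double reversal: identity
  expect_equal(align_alleles(r$probs, "G", "A", "G", "A")$probs, r$probs)
  expect_equal(align_alleles(r$probs, "A", "G", "G", "A")$probs, probs)
  expect_error(align_alleles(probs, "A", "C", "A", "G"), "incompatible")
})

test_that("info-row merging averages with -1 ignored and takes the type minimum", {
  rows <- tibble::tibble(
    snp_id = "---", rs_id = "rs1", position = 100L,
    exp_freq_a1 = c(0.3, 0.35, 0.31), info = c(0.5, -1, 0.3),
    certainty = c(0.9, 0.8, -1), type = c(2L, 0L, 2L),
    info_type0 = c(-1, -1, -1), concord_type0 = c(0.8, 0.9, -1),
    r2_type0 = c(-1, 0.6, -1))
  m <- merge_info_rows(rows)
  expect_equal(m$info, 0.4)              # the worked averaging example
  expect_equal(m$certainty, 0.85)
  expect_equal(m$type, 0L)               # numeric minimum
  expect_equal(m$info_type0, -1)         # all sentinels stay -1
  expect_equal(m$r2_type0, 0.6)
  expect_equal(m$snp_id, "---")

  # single dataset: its own row, snp_id forced to "---"
  one <- merge_info_rows(rows[1, ])
  expect_equal(one$info, rows$info[1])
  expect_equal(one$snp_id, "---")

  # random metric vectors with sentinels vs a filter-then-mean oracle
  withr::with_seed(85, {
    vals <- matrix(round(runif(30), 3), 10, 3)
    vals[sample(30, 8)] <- -1
  })
  rws <- tibble::tibble(
    snp_id = "---", rs_id = "rsX", position = 1L,
    exp_freq_a1 = vals[, 1], info = vals[, 2], certainty = vals[, 3],
    type = 2L, info_type0 = -1, concord_type0 = -1, r2_type0 = -1)
  m2 <- merge_info_rows(rws, minor_allele = FALSE)
  oracle <- function(v) if (all(v == -1)) -1 else mean(v[v != -1])
  expect_equal(m2$exp_freq_a1, oracle(vals[, 1]))
  expect_equal(m2$info, oracle(vals[, 2]))
  expect_equal(m2$certainty, oracle(vals[, 3]))

  # reversed inputs contribute 1 - freq; merged output reports the minor allele
  rev_rows <- rows
  rev_rows$exp_freq_a1 <- c(0.3, 0.72, 0.29)
  m3 <- merge_info_rows(rev_rows, reversed = c(FALSE, TRUE, FALSE))
  expect_equal(m3$exp_freq_a1, mean(c(0.3, 1 - 0.72, 0.29)))
  high <- rows
  high$exp_freq_a1 <- c(0.8, 0.9, 0.85)
  expect_equal(merge_info_rows(high)$exp_freq_a1, 1 - mean(c(0.8, 0.9, 0.85)))
  expect_equal(merge_info_rows(high, minor_allele = FALSE)$exp_freq_a1,
               mean(c(0.8, 0.9, 0.85)))
})

test_that("duplicate samples resolve to the highest call rate with documented ties", {
  rosters <- tibble::tibble(
    sample_id = c("s1", "s2", "s1", "s3"),
    dataset_id = c("a", "a", "b", "b"),
    call_rate = c(0.98, 0.97, 0.99, 0.96))
  w <- resolve_duplicate_samples(rosters)
  expect_equal(nrow(w), 3)
  expect_equal(w$dataset_id[w$sample_id == "s1"], "b")   # 0.99 beats 0.98
  expect_equal(w$n_copies[w$sample_id == "s1"], 2L)
  # no duplicates: identity
  solo <- tibble::tibble(sample_id = c("x", "y"), dataset_id = "a",
                         call_rate = c(0.9, 0.9))
  expect_equal(resolve_duplicate_samples(solo)$sample_id, c("x", "y"))
  # exact tie: first dataset in plan order
  tie <- tibble::tibble(sample_id = c("s", "s"), dataset_id = c("a", "b"),
                        call_rate = c(0.98, 0.98))
  expect_equal(resolve_duplicate_samples(tie)$dataset_id, "a")
  # missing call rates warn and fall back to dataset order
  nocr <- tibble::tibble(sample_id = c("s", "s"), dataset_id = c("a", "b"),
                         call_rate = c(NA, NA))
  expect_warning(res <- resolve_duplicate_samples(nocr), "call rate")
  expect_equal(res$dataset_id, "a")
})

test_that("merging a dataset with itself doubles samples and preserves metrics", {
  markers <- random_markers(30, seed = 86)
  probs <- withr::with_seed(86, {
    raw <- matrix(runif(30 * 9), 30)
    for (s in 1:3) {
      idx <- (3 * s - 2):(3 * s)
      raw[, idx] <- round(raw[, idx] / rowSums(raw[, idx]), 3)
    }
    raw
  })
  info <- withr::with_seed(87, round(runif(30, 0.5, 1), 3))
  da <- mk_dataset("a", markers, probs, info, c("a1", "a2", "a3"),
                   call_rates = c(0.99, 0.98, 0.97),
                   masked_concordance = 0.95)
  db <- mk_dataset("b", markers, probs, info, c("b1", "b2", "b3"),
                   call_rates = c(0.99, 0.98, 0.97),
                   masked_concordance = 0.95)
  # lift both over the gate by faking the sample count check
  merged <- merge_datasets(list(da, db), min_samples = 1)
  expect_equal(nrow(merged$gen$markers), sum(info > 0.7))
  expect_equal(n_samples(merged$gen), 6)
  keep <- info > 0.7
  expect_equal(merged$info$info,
               info[keep][order(markers$pos[keep])])  # mean of identical values
  expect_equal(glance(merged)$n_duplicate_samples, 0)
})

test_that("two platforms with partial overlap merge to the high-quality intersection", {
  cfg <- sim_config(n_markers = 120, n_ref_haplotypes = 60,
                    n_study_samples = 12, n_platforms = 2,
                    n_duplicates = 2, missing_rate = 0, seed = 88)
  panel <- simulate_reference(cfg)
  sim <- simulate_study(cfg, panel)
  datasets <- lapply(sim$platforms, function(p) {
    res <- impute_segment(p$haps, panel, k = 3, flank = 30)
    as_dataset(p$id, res,
               call_rates = setNames(p$study$samples$call_rate,
                                     p$study$samples$sample_id),
               masked_concordance = 0.95)
  })
  merged <- merge_datasets(datasets, min_samples = 1)
  # oracle: brute-force intersection of info>0.7 key sets
  oracle <- Reduce(intersect, lapply(datasets, function(d)
    marker_key(d$gen$markers)[d$info$info > 0.7]))
  expect_setequal(marker_key(merged$gen$markers), oracle)
  expect_true(nrow(merged$gen$markers) <=
                min(vapply(datasets, function(d) sum(d$info$info > 0.7),
                           numeric(1))))
  # duplicates collapse to unique samples
  expect_equal(n_samples(merged$gen), cfg$n_study_samples)
  expect_equal(nrow(merged$duplicates), 2)
  # merged minor-allele frequencies never exceed 0.5
  f <- merged$info$exp_freq_a1
  expect_true(all(f[f != -1] <= 0.5 + 1e-12))
  # all datasets failing the gates refuses the merge
  expect_error(merge_datasets(datasets, min_samples = 1000), "no dataset")
})

test_that("merging is invariant to a dataset's allele order (involution)", {
  markers <- random_markers(20, seed = 89)
  probs <- matrix(round(runif(20 * 6), 3), 20)
  for (s in 1:2) {
    idx <- (3 * s - 2):(3 * s)
    probs[, idx] <- round(probs[, idx] / rowSums(probs[, idx]), 3)
  }
  info <- rep(0.9, 20)
  da <- mk_dataset("a", markers, probs, info, c("a1", "a2"))
  # same data with alleles written in the opposite order
  markers_rev <- markers
  markers_rev$allele_a <- markers$allele_b
  markers_rev$allele_b <- markers$allele_a
  swap <- as.vector(vapply(1:2, function(s) (3 * s):(3 * s - 2),
                           integer(3)))
  db_fwd <- mk_dataset("b", markers, probs, info, c("b1", "b2"))
  db_rev <- mk_dataset("b", markers_rev, probs[, swap, drop = FALSE],
                       info, c("b1", "b2"),
                       exp_freq = 1 - 0.3)
  m_fwd <- merge_datasets(list(da, db_fwd), min_samples = 1)
  m_rev <- merge_datasets(list(da, db_rev), min_samples = 1)
  expect_equal(m_rev$gen$probs, m_fwd$gen$probs)
  expect_equal(m_rev$gen$markers, m_fwd$gen$markers)
  expect_equal(m_rev$info$exp_freq_a1, m_fwd$info$exp_freq_a1)
})
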