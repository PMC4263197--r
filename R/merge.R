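#' Bundle one imputed dataset for merging
#'
#' @param id Dataset identifier (site + platform provenance).
#' @param gen A [gen_data] with a sample roster (`sample_id`, optional
#'   `call_rate`).
#' @param info Companion info-metric tibble aligned row-for-row with
#'   `gen$markers`.
#' @param genome_wide Was the dataset genotyped on a dense genome-wide
#'   platform?
#' @param masked_concordance Mean masked-analysis concordance for the
#'   dataset (NA when not assessed).
#' @return An `imputed_dataset` object.
#' @export
imputed_dataset <- function(id, gen, info, genome_wide = TRUE,
                            masked_concordance = NA_real_) {
  stopifnot(inherits(gen, "gen_data"), is.data.frame(info))
  validate_info_table(info)
  if (nrow(info) != nrow(gen$markers)) {
    stop("info must have one row per marker", call. = FALSE)
  }
  if (is.null(gen$samples)) {
    stop("merging needs a sample roster on each dataset", call. = FALSE)
  }
  structure(list(id = id, gen = gen, info = info,
                 genome_wide = isTRUE(genome_wide),
                 masked_concordance = masked_concordance),
            class = "imputed_dataset")
}

#' Cross-matching key: position plus unordered allele pair
#'
#' Markers are matched across datasets by chromosome, position and the
#' unordered allele pair, never by label (labels are not shared across
#' platforms).
#'
#' @param markers Marker table.
#' @return Character key vector.
#' @export
marker_key <- function(markers) {
  paste(markers$chrom, markers$pos,
        pmin(markers$allele_a, markers$allele_b),
        pmax(markers$allele_a, markers$allele_b), sep = ":")
}

#' Gate datasets for merge eligibility
#'
#' A dataset is excluded when it has fewer than 100 samples, was not
#' genotyped on a dense genome-wide platform, or has a masked-analysis
#' concordance below 0.80 (all boundaries inclusive for the passing
#' side). Datasets without a masked concordance value pass that check.
#'
#' @param manifest Tibble with `dataset_id`, `n_samples`, `genome_wide`,
#'   `masked_concordance`.
#' @param min_samples,min_concordance Gate thresholds (defaults 100, 0.8).
#' @return The manifest with `eligible` and `reason` columns added.
#' @export
gate_datasets <- function(manifest, min_samples = 100,
                          min_concordance = 0.8) {
  stopifnot(all(c("dataset_id", "n_samples", "genome_wide",
                  "masked_concordance") %in% names(manifest)))
  dplyr::mutate(
    tibble::as_tibble(manifest),
    reason = dplyr::case_when(
      n_samples < min_samples ~
        sprintf("fewer than %d samples (n=%d)", min_samples, n_samples),
      !genome_wide ~ "not a dense genome-wide platform",
      !is.na(masked_concordance) & masked_concordance < min_concordance ~
        sprintf("masked concordance %.3f < %.2f", masked_concordance,
                min_concordance),
      TRUE ~ NA_character_),
    eligible = is.na(reason))
}

#' Intersect high-quality markers across datasets
#'
#' Keeps the marker keys present in *all* datasets with an info score
#' strictly above `info_threshold` in each.
#'
#' @param datasets List of `imputed_dataset` objects.
#' @param info_threshold Strict lower bound on the info score (default
#'   0.7).
#' @return Character vector of surviving [marker_key()]s.
#' @export
intersect_markers <- function(datasets, info_threshold = 0.7) {
  key_sets <- lapply(datasets, function(d) {
    marker_key(d$gen$markers)[d$info$info > info_threshold]
  })
  Reduce(intersect, key_sets)
}

rs_number <- function(label) {
  suppressWarnings(as.numeric(sub("^rs([0-9]+)$", "\\1",
                                  ifelse(grepl("^rs[0-9]+$", label), label,
                                         NA_character_))))
}

#' Resolve output marker labels across datasets
#'
#' For each marker key the most common input label wins; plurality ties
#' go to the rs-style label with the larger numeric suffix (or the
#' lexicographically larger label when none is rs-style). Any label
#' attached to more than one distinct position is then considered
#' irreconcilable and every key bearing it is dropped.
#'
#' @param labels Tibble with one row per (dataset, marker) pair: columns
#'   `key` ([marker_key()]) and `label`.
#' @return A list with `map` (tibble `key`, `label`) and `dropped`
#'   (tibble `key`, `label`, `reason`).
#' @export
resolve_labels <- function(labels) {
  stopifnot(all(c("key", "label") %in% names(labels)))
  choose_label <- function(lbl) {
    counts <- sort(table(lbl), decreasing = TRUE)
    tied <- names(counts)[counts == counts[1]]
    if (length(tied) == 1) return(tied)
    nums <- rs_number(tied)
    if (any(!is.na(nums))) {
      tied <- tied[!is.na(nums)]
      return(tied[which.max(nums[!is.na(nums)])])
    }
    max(tied)
  }
  map <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(labels),
                                          .data$key),
                          label = choose_label(.data$label),
                          .groups = "drop")
  # labels attached to >1 distinct position are irreconcilable
  multi <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(labels, .data$key, .data$label),
                    .data$label),
    n_pos = dplyr::n_distinct(.data$key), .groups = "drop")
  bad_labels <- multi$label[multi$n_pos > 1]
  bad_keys <- unique(labels$key[labels$label %in% bad_labels])
  dropped <- dplyr::filter(map, .data$key %in% bad_keys)
  dropped$reason <- "label attached to more than one position"
  map <- dplyr::filter(map, !.data$key %in% bad_keys)
  list(map = map, dropped = dropped)
}

#' Align a probability row to the anchor's allele order
#'
#' When a dataset's ordered alleles are the reverse of the anchor's, the
#' per-sample P(AA) and P(BB) entries are swapped (an involution) and the
#' row is flagged reversed, so that downstream averaging can correct
#' `exp_freq_a1` by `1 - value`.
#'
#' @param probs Numeric probability vector for one marker
#'   (3 per sample).
#' @param allele_a,allele_b The dataset's ordered alleles at the marker.
#' @param anchor_a,anchor_b The anchor dataset's ordered alleles.
#' @return A list with `probs` (aligned) and `reversed` (logical).
#' @export
align_alleles <- function(probs, allele_a, allele_b, anchor_a, anchor_b) {
  if (allele_a == anchor_a && allele_b == anchor_b) {
    return(list(probs = probs, reversed = FALSE))
  }
  if (allele_a == anchor_b && allele_b == anchor_a) {
    n <- length(probs) %/% 3L
    idx <- rep(3 * seq_len(n) - 2, each = 3) + c(2L, 1L, 0L)
    return(list(probs = probs[idx], reversed = TRUE))
  }
  stop("incompatible allele sets: (", allele_a, ",", allele_b,
       ") vs anchor (", anchor_a, ",", anchor_b, ")", call. = FALSE)
}

#' Merge per-dataset info-metric rows for one marker
#'
#' Implements the merged info-file semantics: `snp_id` is always `"---"`;
#' `type` is the numeric minimum of the inputs; every other metric column
#' is the equally weighted average of the inputs with -1 sentinel values
#' ignored (all inputs -1 gives -1). `exp_freq_a1` values from
#' allele-reversed datasets are first replaced by `1 - value`; with
#' `minor_allele = TRUE` (default) the averaged frequency is flipped once
#' more when above 0.5 so the merged file always reports the minor-allele
#' frequency.
#'
#' @param rows Info tibble, one row per dataset, all for one marker key.
#' @param reversed Logical vector flagging datasets whose alleles are
#'   reversed relative to the anchor.
#' @param label,position Output label and position (default: first row's).
#' @param minor_allele Force the merged `exp_freq_a1` to minor-allele
#'   orientation (default `TRUE`); `FALSE` keeps it anchor-relative.
#' @return A one-row info tibble.
#' @export
merge_info_rows <- function(rows, reversed = rep(FALSE, nrow(rows)),
                            label = rows$rs_id[1],
                            position = rows$position[1],
                            minor_allele = TRUE) {
  validate_info_table(rows)
  stopifnot(length(reversed) == nrow(rows))
  avg <- function(v) {
    v <- v[!is.na(v) & v != -1]
    if (length(v) == 0) -1 else mean(v)
  }
  freq <- rows$exp_freq_a1
  flip <- reversed & !is.na(freq) & freq != -1
  freq[flip] <- 1 - freq[flip]
  f <- avg(freq)
  if (minor_allele && f != -1 && f > 0.5) f <- 1 - f
  tibble::tibble(
    snp_id = "---", rs_id = label, position = as.integer(position),
    exp_freq_a1 = f,
    info = avg(rows$info),
    certainty = avg(rows$certainty),
    type = min(rows$type, na.rm = TRUE),
    info_type0 = avg(rows$info_type0),
    concord_type0 = avg(rows$concord_type0),
    r2_type0 = avg(rows$r2_type0))
}

#' Resolve duplicate samples across datasets
#'
#' A sample genotyped on several platforms keeps only the copy from the
#' dataset with the highest call rate; missing call rates (or exact ties)
#' fall back to dataset order, with a warning/message.
#'
#' @param rosters Tibble with `sample_id`, `dataset_id`, `call_rate`, in
#'   dataset order.
#' @return Tibble with one winning row per `sample_id` (`n_copies` counts
#'   the datasets carrying it).
#' @export
resolve_duplicate_samples <- function(rosters) {
  stopifnot(all(c("sample_id", "dataset_id") %in% names(rosters)))
  rosters <- dplyr::mutate(tibble::as_tibble(rosters),
                           .order = dplyr::row_number())
  if (!"call_rate" %in% names(rosters)) rosters$call_rate <- NA_real_
  dup_missing <- dplyr::group_by(rosters, .data$sample_id)
  dup_missing <- dplyr::filter(dup_missing, dplyr::n() > 1 &
                                 any(is.na(.data$call_rate)))
  if (nrow(dup_missing) > 0) {
    warning("duplicate sample(s) with missing call rates; keeping the ",
            "first dataset in plan order: ",
            paste(unique(dup_missing$sample_id), collapse = ", "),
            call. = FALSE)
  }
  ranked <- dplyr::mutate(rosters,
                          .cr = dplyr::coalesce(.data$call_rate, -Inf))
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$.cr), .data$.order)
  winners <- dplyr::ungroup(dplyr::slice_head(
    dplyr::group_by(ranked, .data$sample_id), n = 1))
  counts <- dplyr::count(rosters, .data$sample_id, name = "n_copies")
  out <- dplyr::left_join(winners, counts, by = "sample_id")
  dplyr::select(dplyr::arrange(out, .data$.order), -".order", -".cr")
}

#' Merge imputed datasets into one probabilistic genotype set
#'
#' Applies the full merging protocol: dataset gating (sample size,
#' platform density, masked concordance), marker intersection at a strict
#' info-score threshold, label resolution, allele alignment to the first
#' eligible dataset, info-metric averaging with -1 sentinels ignored, and
#' duplicate-sample resolution by call rate. Output markers are sorted by
#' (chrom, pos); sample columns concatenate the winning samples in
#' dataset order, with provenance on the roster.
#'
#' @param datasets List of `imputed_dataset` objects, in merge order (the
#'   first eligible one anchors allele orientation).
#' @param info_threshold Strict info-score bound for the marker
#'   intersection (default 0.7).
#' @param minor_allele Minor-allele orientation for merged `exp_freq_a1`
#'   (see [merge_info_rows()]).
#' @param min_samples,min_concordance Gate thresholds (see
#'   [gate_datasets()]).
#' @return A `merged_dataset`: list with `gen`, `info`, `gates`,
#'   `dropped_keys`, `duplicates`.
#' @export
merge_datasets <- function(datasets, info_threshold = 0.7,
                           minor_allele = TRUE, min_samples = 100,
                           min_concordance = 0.8) {
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "imputed_dataset")))
  manifest <- purrr::map_dfr(datasets, function(d) tibble::tibble(
    dataset_id = d$id, n_samples = n_samples(d$gen),
    genome_wide = d$genome_wide,
    masked_concordance = d$masked_concordance))
  gates <- gate_datasets(manifest, min_samples = min_samples,
                         min_concordance = min_concordance)
  use <- datasets[gates$eligible]
  if (length(use) == 0) {
    stop("no dataset passes the merge gates: ",
         paste(sprintf("%s (%s)", gates$dataset_id, gates$reason),
               collapse = "; "), call. = FALSE)
  }
  keys <- intersect_markers(use, info_threshold = info_threshold)
  key_idx <- lapply(use, function(d) match(keys, marker_key(d$gen$markers)))
  label_tbl <- purrr::map_dfr(seq_along(use), function(i) tibble::tibble(
    key = keys, label = use[[i]]$gen$markers$rs_id[key_idx[[i]]]))
  lab <- resolve_labels(label_tbl)
  keep <- keys %in% lab$map$key
  keys <- keys[keep]
  key_idx <- lapply(key_idx, `[`, keep)
  label_of <- lab$map$label[match(keys, lab$map$key)]

  anchor <- use[[1]]
  anchor_rows <- key_idx[[1]]
  out_markers <- anchor$gen$markers[anchor_rows, , drop = FALSE]
  out_markers$rs_id <- label_of
  out_markers$snp_id <- "---"

  # duplicate-sample resolution
  roster <- purrr::map_dfr(use, function(d) {
    s <- d$gen$samples
    s$dataset_id <- d$id
    if (!"call_rate" %in% names(s)) s$call_rate <- NA_real_
    s[, c("sample_id", "dataset_id", "call_rate")]
  })
  winners <- resolve_duplicate_samples(roster)
  win_cols <- lapply(use, function(d) {
    which(d$gen$samples$sample_id %in%
            winners$sample_id[winners$dataset_id == d$id])
  })

  n_keys <- length(keys)
  probs_pieces <- vector("list", length(use))
  reversed_mat <- matrix(FALSE, n_keys, length(use))
  for (i in seq_along(use)) {
    d <- use[[i]]
    rows <- key_idx[[i]]
    cols <- win_cols[[i]]
    tri_cols <- as.vector(t(outer(cols, c(-2L, -1L, 0L),
                                  function(c, o) 3L * c + o)))
    p <- d$gen$probs[rows, tri_cols, drop = FALSE]
    rev_i <- d$gen$markers$allele_a[rows] != out_markers$allele_a
    incompat <- rev_i &
      (d$gen$markers$allele_a[rows] != out_markers$allele_b |
         d$gen$markers$allele_b[rows] != out_markers$allele_a)
    if (any(incompat)) {
      stop("incompatible allele sets slipped past key matching", call. = FALSE)
    }
    if (any(rev_i) && length(cols) > 0) {
      n_s <- length(cols)
      swap <- rep(3 * seq_len(n_s) - 2, each = 3) + c(2L, 1L, 0L)
      p[rev_i, ] <- p[rev_i, swap, drop = FALSE]
    }
    reversed_mat[, i] <- rev_i
    probs_pieces[[i]] <- p
  }
  probs <- do.call(cbind, probs_pieces)

  info <- purrr::map_dfr(seq_len(n_keys), function(m) {
    rows <- purrr::map_dfr(seq_along(use), function(i)
      use[[i]]$info[key_idx[[i]][m], , drop = FALSE])
    merge_info_rows(rows, reversed = reversed_mat[m, ],
                    label = label_of[m], position = out_markers$pos[m],
                    minor_allele = minor_allele)
  })

  ord <- order(chrom_rank(out_markers$chrom), out_markers$pos)
  out_samples <- purrr::map_dfr(seq_along(use), function(i) {
    s <- use[[i]]$gen$samples[win_cols[[i]], , drop = FALSE]
    s$dataset_id <- use[[i]]$id
    s
  })
  gen <- gen_data(out_markers[ord, , drop = FALSE],
                  probs[ord, , drop = FALSE], samples = out_samples)
  structure(list(gen = gen, info = info[ord, , drop = FALSE],
                 gates = gates, dropped_keys = lab$dropped,
                 duplicates = winners[winners$n_copies > 1, , drop = FALSE]),
            class = "merged_dataset")
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat("<merged_dataset> ", nrow(x$gen$markers), " markers x ",
      n_samples(x$gen), " samples from ",
      sum(x$gates$eligible), "/", nrow(x$gates), " datasets\n", sep = "")
  invisible(x)
}
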