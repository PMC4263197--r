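#' Plan fixed-size SNP-block segments ("SNPlets") for parallel imputation
#'
#' Divides a sorted, single-chromosome marker list into consecutive blocks
#' of `core_size` markers, each flanked by `buffer_size` extra markers on
#' both sides (truncated at chromosome ends). Every marker belongs to
#' exactly one core; buffer results are discarded at stitching.
#'
#' @param markers Marker table, sorted by position, one chromosome.
#' @param core_size Markers per core block (default 30000).
#' @param buffer_size Flanking markers on each side (default 700).
#' @return A `segment_plan` tibble with marker-index columns
#'   (`core_start`, `core_end`, `buffer_start`, `buffer_end`, inclusive)
#'   and the equivalent base-pair bounds (`core_lo`, `core_hi`,
#'   `buffer_lo`, `buffer_hi`).
#' @export
plan_snplets <- function(markers, core_size = 30000, buffer_size = 700) {
  validate_marker_table(markers)
  if (length(unique(markers$chrom)) > 1) {
    stop("SNPlet planning expects a single chromosome", call. = FALSE)
  }
  if (is.unsorted(markers$pos, strictly = FALSE)) {
    stop("markers must be sorted by position", call. = FALSE)
  }
  n <- nrow(markers)
  if (n == 0) {
    return(new_segment_plan(empty_plan_tbl(index = TRUE), "snplet",
                            unique(markers$chrom) %||% NA_character_))
  }
  starts <- seq(1L, n, by = core_size)
  ends <- pmin(starts + core_size - 1L, n)
  n_seg <- length(starts)
  # base-pair core bounds tile the chromosome so that imputed reference
  # markers falling between two cores' study markers still have exactly
  # one owning segment: internal boundaries sit just before the next
  # core's first study marker, the ends are open
  core_lo <- c(1L, markers$pos[starts[-1]])
  core_hi <- c(markers$pos[starts[-1]] - 1L, .Machine$integer.max)
  buffer_start <- pmax(1L, starts - as.integer(buffer_size))
  buffer_end <- pmin(n, ends + as.integer(buffer_size))
  buffer_lo <- pmin(core_lo, markers$pos[buffer_start])
  buffer_hi <- pmax(core_hi, markers$pos[buffer_end])
  plan <- tibble::tibble(
    segment = seq_len(n_seg),
    core_start = starts, core_end = ends,
    buffer_start = buffer_start, buffer_end = buffer_end,
    core_lo = core_lo, core_hi = core_hi,
    buffer_lo = buffer_lo, buffer_hi = buffer_hi)
  new_segment_plan(plan, "snplet", markers$chrom[1])
}

empty_plan_tbl <- function(index = FALSE) {
  base <- tibble::tibble(segment = integer(), core_lo = integer(),
                         core_hi = integer(), buffer_lo = integer(),
                         buffer_hi = integer())
  if (index) {
    base$core_start <- base$core_end <- integer()
    base$buffer_start <- base$buffer_end <- integer()
  }
  base
}

new_segment_plan <- function(tbl, scheme, chrom) {
  structure(tbl, scheme = scheme, chrom = chrom,
            class = c("segment_plan", class(tbl)))
}

#' @export
print.segment_plan <- function(x, ...) {
  cat("<segment_plan> scheme=", attr(x, "scheme"), ", chrom=",
      attr(x, "chrom"), ", ", nrow(x), " segments\n", sep = "")
  NextMethod()
}

#' Plan genomic-window segments for parallel imputation
#'
#' Divides a chromosome into consecutive base-pair windows of `window`
#' size, beginning at the first imputation target, each flanked by a
#' `buffer` base-pair region (truncated at chromosome ends). Windows that
#' overlap the centromere, terminal remnants shorter than a full window,
#' and windows containing no genotyped (type-2) marker are merged into the
#' segment immediately upstream (or downstream when no upstream segment
#' exists yet).
#'
#' @param markers Marker table, sorted, one chromosome. If a `type` column
#'   is present, type-2 rows are the genotyped backbone; otherwise all
#'   markers count as genotyped.
#' @param chrom_length Chromosome length in bp (defaults to the last marker
#'   position) used to truncate buffers.
#' @param centromere Optional length-2 numeric (start, end) of the
#'   centromere interval in bp.
#' @param window Core window size in bp (default 6e6).
#' @param buffer Flanking buffer in bp on each side (default 250000).
#' @return A `segment_plan` tibble with inclusive base-pair bounds.
#' @export
plan_genomic_windows <- function(markers, chrom_length = NULL,
                                 centromere = NULL, window = 6e6,
                                 buffer = 250000) {
  validate_marker_table(markers)
  if (length(unique(markers$chrom)) > 1) {
    stop("window planning expects a single chromosome", call. = FALSE)
  }
  if (nrow(markers) == 0) {
    return(new_segment_plan(empty_plan_tbl(), "genomic_window",
                            NA_character_))
  }
  if (is.unsorted(markers$pos)) {
    stop("markers must be sorted by position", call. = FALSE)
  }
  typed_pos <- if ("type" %in% names(markers) && any(!is.na(markers$type))) {
    markers$pos[!is.na(markers$type) & markers$type == 2L]
  } else {
    markers$pos
  }
  start0 <- min(markers$pos)
  max_pos <- max(markers$pos)
  chrom_length <- chrom_length %||% max_pos
  n_w <- ceiling((max_pos - start0 + 1) / window)
  lo <- start0 + (seq_len(n_w) - 1) * window
  hi <- lo + window - 1
  partial <- hi[n_w] > max_pos && n_w > 1   # terminal remnant
  overlaps_cen <- function(a, b) {
    !is.null(centromere) && a <= centromere[2] && b >= centromere[1]
  }
  has_typed <- function(a, b) any(typed_pos >= a & typed_pos <= b)
  cores <- list()
  pending_lo <- NA_real_   # offending leading windows awaiting a host
  for (w in seq_len(n_w)) {
    offending <- overlaps_cen(lo[w], hi[w]) ||
      !has_typed(lo[w], hi[w]) || (w == n_w && partial)
    if (offending) {
      if (length(cores) > 0) {
        cores[[length(cores)]][2] <- hi[w]     # merge upstream
      } else if (is.na(pending_lo)) {
        pending_lo <- lo[w]                    # merge downstream later
      }
    } else {
      a <- if (is.na(pending_lo)) lo[w] else pending_lo
      pending_lo <- NA_real_
      cores[[length(cores) + 1]] <- c(a, hi[w])
    }
  }
  if (!is.na(pending_lo)) {
    # every window was offending: single segment spanning the whole range
    cores[[1]] <- c(pending_lo, hi[n_w])
  }
  m <- do.call(rbind, cores)
  plan <- tibble::tibble(
    segment = seq_len(nrow(m)),
    core_lo = m[, 1], core_hi = m[, 2],
    buffer_lo = pmax(1, m[, 1] - buffer),
    buffer_hi = pmin(chrom_length, m[, 2] + buffer))
  new_segment_plan(plan, "genomic_window", markers$chrom[1])
}

#' Stitch per-segment imputation outputs, removing buffers
#'
#' Concatenates per-segment genotype probability outputs, keeping only the
#' rows whose position falls inside the owning segment's core so that each
#' imputed marker has results from exactly one segment. A `segment`
#' provenance column is added to the marker table.
#'
#' @param segment_outputs List of [gen_data] objects, one per plan row, in
#'   plan order, each covering its segment's buffer range.
#' @param plan A `segment_plan`.
#' @param targets Optional marker table of expected output markers; core
#'   markers missing from their segment's output trigger a warning listing
#'   positions.
#' @return A [gen_data] object sorted by position, markers annotated with
#'   their originating segment.
#' @export
stitch_segments <- function(segment_outputs, plan, targets = NULL) {
  stopifnot(inherits(plan, "segment_plan"))
  if (length(segment_outputs) != nrow(plan)) {
    stop("need one segment output per plan row", call. = FALSE)
  }
  pieces <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    g <- segment_outputs[[i]]
    stopifnot(inherits(g, "gen_data"))
    keep <- g$markers$pos >= plan$core_lo[i] & g$markers$pos <= plan$core_hi[i]
    mk <- g$markers[keep, , drop = FALSE]
    mk$segment <- plan$segment[i]
    pieces[[i]] <- list(markers = mk, probs = g$probs[keep, , drop = FALSE])
    if (!is.null(targets)) {
      expected <- targets$pos[targets$pos >= plan$core_lo[i] &
                                targets$pos <= plan$core_hi[i]]
      gap <- setdiff(expected, mk$pos)
      if (length(gap) > 0) {
        warning("segment ", plan$segment[i], " output is missing core ",
                "positions: ", paste(utils::head(gap, 10), collapse = ", "),
                call. = FALSE)
      }
    }
  }
  markers <- dplyr::bind_rows(lapply(pieces, `[[`, "markers"))
  probs <- do.call(rbind, lapply(pieces, `[[`, "probs"))
  key <- paste(markers$chrom, markers$pos,
               pmin(markers$allele_a, markers$allele_b),
               pmax(markers$allele_a, markers$allele_b))
  if (anyDuplicated(key)) {
    dup <- unique(markers$pos[duplicated(key)])
    stop("plan violation: marker(s) present in two cores at position(s) ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  ord <- order(chrom_rank(markers$chrom), markers$pos)
  samples <- segment_outputs[[1]]$samples
  gen_data(markers[ord, , drop = FALSE], probs[ord, , drop = FALSE],
           samples = samples)
}
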