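#' @title Oxford-format and PLINK-text readers and writers
#' @description Whitespace-delimited, unquoted formats: Oxford GEN genotype
#'   probability files, companion sample files (two-line header), SHAPEIT
#'   haps files, IMPUTE2-style 10-column info-metric files, and PLINK text
#'   `.ped`/`.map` pairs. Probability values are preserved to printed
#'   precision and never renormalized on I/O; `read(write(x))` is
#'   field-for-field stable and a second write is bytewise identical to the
#'   first.
#' @name imputeqc-io
NULL

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

# -1 sentinel printed bare; everything else fixed-decimal.
fmt_metric <- function(x, digits = 3) {
  out <- formatC(x, format = "f", digits = digits)
  out[!is.na(x) & x == -1] <- "-1"
  out[is.na(x)] <- "-1"
  out
}

#' Read an Oxford GEN genotype probability file
#'
#' @param path Path to a whitespace-delimited GEN file.
#' @param dialect Meaning of column 1: `"impute2_5col"` (stock IMPUTE2
#'   output: snp_id, rs_id, position, alleleA, alleleB) or `"chrom_first"`
#'   (chromosome, rs_id, position, alleleA, alleleB).
#' @param chrom Chromosome label to attach when the dialect carries none.
#' @param samples Optional sample roster (see [read_sample()]); its length
#'   must match the probability width.
#' @return A [gen_data] object; markers in file order.
#' @export
read_gen <- function(path, dialect = c("impute2_5col", "chrom_first"),
                     chrom = NA_character_, samples = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(gen_data(marker_table(character(), character(), integer(),
                                 character(), character()),
                    matrix(numeric(), 0, 0), samples = samples))
  }
  fields <- split_fields(lines)
  nf <- lengths(fields)
  bad <- which((nf - 5L) %% 3L != 0L | nf < 5L)
  if (length(bad) > 0) {
    stop("malformed GEN row: line ", bad[1], " has ", nf[bad[1]],
         " fields (need 5 + 3 per sample)", call. = FALSE)
  }
  if (length(unique(nf)) > 1) {
    stop("GEN rows disagree on sample count (lines differ in width)",
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  if (dialect == "impute2_5col") {
    markers <- tibble::tibble(
      chrom = as.character(chrom), snp_id = m[, 1], rs_id = m[, 2],
      pos = as.integer(m[, 3]), allele_a = m[, 4], allele_b = m[, 5],
      type = NA_integer_)
  } else {
    markers <- tibble::tibble(
      chrom = m[, 1], snp_id = "---", rs_id = m[, 2],
      pos = as.integer(m[, 3]), allele_a = m[, 4], allele_b = m[, 5],
      type = NA_integer_)
  }
  probs <- matrix(as.numeric(m[, -(1:5), drop = FALSE]), nrow = nrow(m))
  if (length(probs) > 0 && (anyNA(probs) || min(probs) < 0 || max(probs) > 1)) {
    bad_row <- which(apply(is.na(probs) | probs < 0 | probs > 1, 1, any))[1]
    stop("genotype probability outside [0, 1] at line ", bad_row,
         call. = FALSE)
  }
  gen_data(markers, probs, samples = samples)
}

#' Write an Oxford GEN genotype probability file
#'
#' @param gen A [gen_data] object.
#' @param path Output path.
#' @inheritParams read_gen
#' @param digits Decimal places for probabilities (default 3).
#' @return `path`, invisibly.
#' @export
write_gen <- function(gen, path, dialect = c("impute2_5col", "chrom_first"),
                      digits = 3) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(gen, "gen_data"))
  m <- gen$markers
  if (nrow(m) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lead <- if (dialect == "impute2_5col") {
    cbind(ifelse(is.na(m$snp_id), "---", m$snp_id), m$rs_id, m$pos,
          m$allele_a, m$allele_b)
  } else {
    cbind(m$chrom, m$rs_id, m$pos, m$allele_a, m$allele_b)
  }
  pr <- matrix(formatC(gen$probs, format = "f", digits = digits),
               nrow = nrow(gen$probs))
  lines <- apply(cbind(lead, pr), 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Read an IMPUTE2-style info-metric file
#'
#' Ten whitespace-delimited columns with a header line; -1 marks undefined
#' metrics.
#'
#' @param path Path to the info file.
#' @return A tibble with the columns of [info_table()].
#' @export
read_info <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1) return(info_table())
  fields <- split_fields(lines[-1])
  if (any(lengths(fields) != 10)) {
    stop("info rows must have 10 columns", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- tibble::tibble(
    snp_id = m[, 1], rs_id = m[, 2], position = as.integer(m[, 3]),
    exp_freq_a1 = as.numeric(m[, 4]), info = as.numeric(m[, 5]),
    certainty = as.numeric(m[, 6]), type = as.integer(m[, 7]),
    info_type0 = as.numeric(m[, 8]), concord_type0 = as.numeric(m[, 9]),
    r2_type0 = as.numeric(m[, 10]))
  validate_info_table(out)
  out
}

#' Write an IMPUTE2-style info-metric file
#'
#' @param info Info tibble (see [info_table()]).
#' @param path Output path.
#' @param digits Decimal places for metric columns; the -1 sentinel is
#'   always written bare.
#' @return `path`, invisibly.
#' @export
write_info <- function(info, path, digits = 3) {
  validate_info_table(info)
  header <- paste(names(info_table()), collapse = " ")
  if (nrow(info) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  lines <- paste(
    info$snp_id, info$rs_id, info$position,
    fmt_metric(info$exp_freq_a1, digits), fmt_metric(info$info, digits),
    fmt_metric(info$certainty, digits), info$type,
    fmt_metric(info$info_type0, digits),
    fmt_metric(info$concord_type0, digits),
    fmt_metric(info$r2_type0, digits))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a SHAPEIT haps file
#'
#' Columns: chromosome, marker id, position, alleleA, alleleB, then one 0/1
#' column per haplotype (two per individual).
#'
#' @param path Path to the haps file.
#' @param sample_ids Optional roster; defaults to generated ids.
#' @return A [hap_panel].
#' @export
read_haps <- function(path, sample_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(hap_panel(marker_table(character(), character(), integer(),
                                  character(), character()),
                     matrix(integer(), 0, 0), sample_ids = character()))
  }
  fields <- split_fields(lines)
  if (length(unique(lengths(fields))) > 1 || lengths(fields)[1] < 5) {
    stop("haps rows must share one width of 5 + n_haplotypes columns",
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  markers <- tibble::tibble(
    chrom = m[, 1], snp_id = "---", rs_id = m[, 2], pos = as.integer(m[, 3]),
    allele_a = m[, 4], allele_b = m[, 5], type = NA_integer_)
  haps <- matrix(as.integer(m[, -(1:5), drop = FALSE]), nrow = nrow(m))
  hap_panel(markers, haps, sample_ids = sample_ids)
}

#' Write a SHAPEIT haps file
#'
#' @param panel A [hap_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haps <- function(panel, path) {
  stopifnot(inherits(panel, "hap_panel"))
  m <- panel$markers
  if (nrow(m) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- apply(cbind(m$chrom, m$rs_id, m$pos, m$allele_a, m$allele_b,
                       panel$haps), 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Read an Oxford sample file
#'
#' Two header lines (`ID_1 ID_2 missing` / `0 0 0`) followed by one row per
#' sample.
#'
#' @param path Path to the sample file.
#' @return A tibble with `sample_id` (from ID_2), `dataset_id` (from ID_1)
#'   and `missing`.
#' @export
read_sample <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("sample file lacks the two-line Oxford header",
                              call. = FALSE)
  fields <- split_fields(lines[-(1:2)])
  if (length(fields) == 0) {
    return(tibble::tibble(sample_id = character(), dataset_id = character(),
                          missing = double()))
  }
  m <- do.call(rbind, fields)
  tibble::tibble(sample_id = m[, 2], dataset_id = m[, 1],
                 missing = as.numeric(m[, 3]))
}

#' Write an Oxford sample file
#'
#' @param samples Tibble with `sample_id`, optional `dataset_id` and
#'   `missing` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(samples, path) {
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples))
  dataset <- if ("dataset_id" %in% names(samples)) samples$dataset_id
             else samples$sample_id
  missing <- if ("missing" %in% names(samples)) samples$missing
             else rep(0, nrow(samples))
  lines <- c("ID_1 ID_2 missing", "0 0 0",
             paste(dataset, samples$sample_id, missing))
  writeLines(lines, path)
  invisible(path)
}

#' Read PLINK text files (.ped/.map)
#'
#' Hard genotypes are recoded as allele-A dosages with `allele_a` taken as
#' the lexicographically smaller observed allele at each marker (the text
#' format does not record allele roles). Monomorphic markers get
#' `allele_b = NA`.
#'
#' @param prefix Path prefix; `<prefix>.ped` and `<prefix>.map` must exist.
#' @param dataset_id Provenance label stored on the roster.
#' @return A [study_data] object.
#' @export
read_plink_text <- function(prefix, dataset_id = basename(prefix)) {
  map_lines <- readLines(paste0(prefix, ".map"))
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  mm <- do.call(rbind, split_fields(map_lines))
  if (!is.null(mm) && ncol(mm) != 4) {
    stop(".map rows must have 4 columns (chrom, id, cM, pos)", call. = FALSE)
  }
  ped_lines <- readLines(paste0(prefix, ".ped"))
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  pf <- split_fields(ped_lines)
  n_markers <- if (is.null(mm)) 0L else nrow(mm)
  if (any(lengths(pf) != 6L + 2L * n_markers)) {
    stop(".ped rows must have 6 + 2 * n_markers fields", call. = FALSE)
  }
  pm <- if (length(pf) > 0) do.call(rbind, pf) else
    matrix(character(), 0, 6 + 2 * n_markers)
  n_ind <- nrow(pm)
  geno <- matrix(NA_integer_, n_markers, n_ind)
  allele_a <- allele_b <- rep(NA_character_, n_markers)
  for (j in seq_len(n_markers)) {
    a1 <- pm[, 6 + 2 * j - 1]
    a2 <- pm[, 6 + 2 * j]
    obs <- sort(setdiff(unique(c(a1, a2)), "0"))
    if (length(obs) > 2) {
      stop("marker ", mm[j, 2], " has more than two alleles", call. = FALSE)
    }
    if (length(obs) >= 1) allele_a[j] <- obs[1]
    if (length(obs) == 2) allele_b[j] <- obs[2]
    miss <- a1 == "0" | a2 == "0"
    d <- (a1 == allele_a[j]) + (a2 == allele_a[j])
    d[miss] <- NA_integer_
    geno[j, ] <- as.integer(d)
  }
  markers <- tibble::tibble(
    chrom = if (n_markers) mm[, 1] else character(),
    snp_id = "---",
    rs_id = if (n_markers) mm[, 2] else character(),
    pos = if (n_markers) as.integer(mm[, 4]) else integer(),
    allele_a = allele_a, allele_b = allele_b, type = NA_integer_)
  samples <- tibble::tibble(
    sample_id = pm[, 2], dataset_id = dataset_id,
    call_rate = if (n_markers > 0) colMeans(!is.na(geno)) else
      rep(NA_real_, n_ind))
  study_data(markers, geno, samples)
}

#' Write PLINK text files (.ped/.map)
#'
#' @param study A [study_data] object.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(study, prefix) {
  stopifnot(inherits(study, "study_data"))
  m <- study$markers
  writeLines(paste(m$chrom, m$rs_id, 0, m$pos), paste0(prefix, ".map"))
  n_ind <- nrow(study$samples)
  geno_txt <- matrix("0 0", nrow(m), n_ind)
  for (j in seq_len(nrow(m))) {
    a <- m$allele_a[j]
    b <- if (is.na(m$allele_b[j])) a else m$allele_b[j]
    d <- study$geno[j, ]
    geno_txt[j, ] <- dplyr::case_when(
      is.na(d) ~ "0 0",
      d == 2L ~ paste(a, a),
      d == 1L ~ paste(a, b),
      TRUE ~ paste(b, b))
  }
  rows <- vapply(seq_len(n_ind), function(i) {
    paste(c(study$samples$dataset_id[i] %||% study$samples$sample_id[i],
            study$samples$sample_id[i], "0", "0", "0", "-9",
            geno_txt[, i]), collapse = " ")
  }, character(1))
  writeLines(rows, paste0(prefix, ".ped"))
  invisible(prefix)
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x[1])) y else x
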