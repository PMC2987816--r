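#' Read per-sample methylation tracks onto a shared window grid
#'
#' Ingests one 4-column track per sample (`chrom`, `start`, `end`, `score`)
#' and assembles a [meth_matrix()]. Plain TSV tracks are read as 1-based
#' inclusive coordinates; BEDGRAPH tracks (`.bedgraph`/`.bg` extension, or
#' `format = "bedgraph"`) are 0-based half-open and are converted on read.
#' All files must tile the same chromosome with one consistent window size;
#' a `grid` may be supplied to pin the expected geometry (windows absent
#' from a file are `NA`).
#'
#' @param paths Character vector of file paths; names, if set, become
#'   sample ids (otherwise file base names are used).
#' @param grid Optional [meth_grid()] the tracks must align to.
#' @param format `"auto"` (by extension), `"tsv"` or `"bedgraph"`.
#' @return A [meth_matrix()].
#' @export
read_methylation_tracks <- function(paths, grid = NULL,
                                    format = c("auto", "tsv", "bedgraph")) {
  format <- match.arg(format)
  if (length(paths) == 0L) stop("no track files supplied")
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))

  parse_one <- function(path) {
    fmt <- format
    if (fmt == "auto") {
      fmt <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) {
        "bedgraph"
      } else "tsv"
    }
    d <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "start", "end", "score"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
    if (fmt == "bedgraph") {  # 0-based half-open -> 1-based inclusive
      d$start <- d$start + 1
    }
    bad <- which(d$score < 0 | d$score > 1)
    if (length(bad)) {
      stop(sprintf("%s line %d: score %g outside [0, 1]",
                   path, bad[1], d$score[bad[1]]))
    }
    ws <- d$end - d$start + 1
    if (length(unique(ws)) != 1L) {
      stop(sprintf("%s: inconsistent window sizes (%s)", path,
                   paste(utils::head(unique(ws)), collapse = ", ")))
    }
    if (length(unique(d$chrom)) != 1L) {
      stop(sprintf("%s: multiple chromosomes in one track", path))
    }
    d
  }

  tracks <- lapply(paths, parse_one)

  if (is.null(grid)) {
    first <- tracks[[1]]
    ws <- first$end[1] - first$start[1] + 1
    start <- min(vapply(tracks, function(d) min(d$start), 0))
    last <- max(vapply(tracks, function(d) max(d$end), 0))
    grid <- meth_grid(first$chrom[1], start,
                      n_windows = (last - start + 1) / ws,
                      window_size_bp = ws)
  }
  ws <- grid$window_size_bp
  scores <- matrix(NA_real_, nrow = length(tracks), ncol = grid$n_windows)
  for (i in seq_along(tracks)) {
    d <- tracks[[i]]
    if (!identical(d$chrom[1], grid$chrom)) {
      stop(sprintf("%s: chromosome %s does not match grid chromosome %s",
                   paths[i], d$chrom[1], grid$chrom))
    }
    off <- (d$start - grid$start) / ws
    if (any(off != floor(off)) || (d$end[1] - d$start[1] + 1) != ws) {
      stop(sprintf("%s: windows do not align to the grid", paths[i]))
    }
    k <- off + 1
    if (any(k < 1 | k > grid$n_windows)) {
      stop(sprintf("%s: windows fall outside the grid", paths[i]))
    }
    scores[i, k] <- d$score
  }
  meth_matrix(scores, grid, sample_ids = ids)
}

#' Read a genotype table
#'
#' Reads a TSV with a `sample_id` column and one column per SNP. Cells may
#' be allele-dosage codes (0 = common homozygote, 1 = heterozygote, 2 = rare
#' homozygote) or allele pairs such as `"AC"`; pairs are converted to rare
#' allele dosage using the declared common/rare alleles. Dosage orientation
#' is always the rare-allele count; the risk allele need not be the rare
#' one, so allele labels travel with the table.
#'
#' @param path TSV file path.
#' @param alleles Tibble with columns `snp_id`, `common`, `rare` (single
#'   IUPAC bases). Required when any cell holds allele pairs.
#' @return A long tibble: `sample_id`, `snp_id`, `dosage` (0/1/2 or `NA`),
#'   `allele_common`, `allele_rare`.
#' @export
read_genotypes <- function(path, alleles = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(d)) stop("genotype table needs a sample_id column")
  if (anyDuplicated(d$sample_id)) {
    stop(sprintf("duplicate sample_id '%s' in %s",
                 d$sample_id[anyDuplicated(d$sample_id)], path))
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(d), -"sample_id",
                              names_to = "snp_id", values_to = "raw")
  conv <- genotype_dosage(long$raw, long$snp_id, alleles = alleles)
  dplyr::bind_cols(long[, c("sample_id", "snp_id")], conv)
}

# Convert raw genotype cells (dosage codes or allele pairs) to rare-allele
# dosage. Vectorised; snp_id selects the allele declaration per cell.
genotype_dosage <- function(raw, snp_id, alleles = NULL) {
  raw <- toupper(trimws(raw))
  raw[raw %in% c("", "NA", ".", "--", "NN")] <- NA
  out <- rep(NA_real_, length(raw))
  common <- rep(NA_character_, length(raw))
  rare <- rep(NA_character_, length(raw))
  is_code <- !is.na(raw) & raw %in% c("0", "1", "2")
  out[is_code] <- as.numeric(raw[is_code])
  is_pair <- !is.na(raw) & grepl("^[ACGT]{2}$", raw)
  unknown <- !is.na(raw) & !is_code & !is_pair
  if (any(unknown)) {
    stop(sprintf("unknown genotype symbol '%s' (snp %s)",
                 raw[which(unknown)[1]], snp_id[which(unknown)[1]]))
  }
  if (!is.null(alleles)) {
    m <- match(snp_id, alleles$snp_id)
    common <- toupper(alleles$common[m])
    rare <- toupper(alleles$rare[m])
  }
  if (any(is_pair)) {
    if (is.null(alleles)) {
      stop("allele-pair genotypes need an alleles declaration (snp_id, common, rare)")
    }
    if (anyNA(common[is_pair]) || anyNA(rare[is_pair])) {
      stop("allele pairs present for SNPs missing from the alleles declaration")
    }
    a1 <- substr(raw[is_pair], 1, 1)
    a2 <- substr(raw[is_pair], 2, 2)
    ok1 <- a1 == common[is_pair] | a1 == rare[is_pair]
    ok2 <- a2 == common[is_pair] | a2 == rare[is_pair]
    if (any(!ok1 | !ok2)) {
      i <- which(is_pair)[which(!ok1 | !ok2)[1]]
      stop(sprintf("allele pair '%s' does not match declared alleles %s/%s (snp %s)",
                   raw[i], common[i], rare[i], snp_id[i]))
    }
    out[is_pair] <- (a1 == rare[is_pair]) + (a2 == rare[is_pair])
  }
  tibble::tibble(dosage = out, allele_common = common, allele_rare = rare)
}

#' Rare-allele dosage vector for one SNP, aligned to sample order
#'
#' @param genotypes Long genotype tibble as returned by [read_genotypes()]
#'   or [simulate_cohort()].
#' @param snp SNP identifier to extract.
#' @param sample_ids Sample order to align to.
#' @return Numeric vector of dosages (`NA` where missing).
#' @export
dosage_vector <- function(genotypes, snp, sample_ids) {
  g <- genotypes[genotypes$snp_id == snp, ]
  if (nrow(g) == 0L) stop(sprintf("SNP %s not present in genotype table", snp))
  g$dosage[match(sample_ids, g$sample_id)]
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `status` (1 = case,
#'   0 = control), `age` (years), and optionally `sex`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  d <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                           check.names = FALSE))
  if (!all(c("sample_id", "status") %in% names(d))) {
    stop("metadata needs sample_id and status columns")
  }
  if (!all(d$status %in% c(0, 1))) stop("status must be 0 (control) or 1 (case)")
  if ("age" %in% names(d) && any(!is.na(d$age) & d$age <= 0)) {
    stop("age must be positive when present")
  }
  d$sample_id <- as.character(d$sample_id)
  d
}

#' Read region definitions
#'
#' TSV input (`chrom`, `start`, `end`, optional `label`) is 1-based
#' inclusive; files ending in `.bed` are treated as 0-based half-open and
#' converted.
#'
#' @param path File path.
#' @return A region tibble as from [region()].
#' @export
read_regions <- function(path) {
  bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  if (bed) {
    d <- utils::read.table(path, header = FALSE, sep = "\t",
                           check.names = FALSE)
    names(d) <- c("chrom", "start", "end", "label")[seq_len(ncol(d))]
    d$start <- d$start + 1  # 0-based half-open -> 1-based inclusive
  } else {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  }
  region(as.character(d$chrom), d$start, d$end,
         label = if ("label" %in% names(d)) as.character(d$label) else NULL)
}

#' Read SNP context records
#'
#' @param path TSV with columns `snp_id`, `chrom`, `pos`, `left_flank`,
#'   `allele_a`, `allele_b`, `right_flank`, `ancestral` (use `NA` or `.`
#'   when the ancestral base is unknown).
#' @return A tibble of SNP contexts, flanks upper-cased and validated to
#'   contain only `ACGTN`.
#' @export
read_snp_contexts <- function(path) {
  d <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                           colClasses = "character",
                                           check.names = FALSE))
  need <- c("snp_id", "chrom", "pos", "left_flank", "allele_a", "allele_b",
            "right_flank")
  if (!all(need %in% names(d))) {
    stop(sprintf("SNP table needs columns %s", paste(need, collapse = ", ")))
  }
  d$pos <- as.numeric(d$pos)
  for (col in c("left_flank", "right_flank", "allele_a", "allele_b")) {
    d[[col]] <- toupper(d[[col]])
  }
  if (any(!grepl("^[ACGTN]+$", d$left_flank)) ||
      any(!grepl("^[ACGTN]+$", d$right_flank))) {
    stop("flanks may contain only ACGTN")
  }
  if (any(d$allele_a == d$allele_b)) stop("alleles must differ")
  if ("ancestral" %in% names(d)) {
    d$ancestral <- toupper(d$ancestral)
    d$ancestral[d$ancestral %in% c(".", "", "NA", "N")] <- NA
  } else {
    d$ancestral <- NA_character_
  }
  d
}

#' Write a result table
#'
#' Serialises any result tibble to TSV or JSON with deterministic column
#' order (the tibble's own) and full numeric precision, so a write/read
#' round trip is lossless to at least six significant digits.
#'
#' @param x A non-empty data frame of results.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- as.data.frame(x)
  if (nrow(x) == 0L) stop("refusing to write an empty result table")
  if (format == "tsv") {
    readr::write_tsv(x, path)
  } else {
    jsonlite::write_json(x, path, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path File path ending in `.tsv` or `.json`.
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}
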