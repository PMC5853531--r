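#' File formats
#'
#' All on-disk artifacts are plain text. Tabular inputs and outputs are
#' tab-separated with a mandatory header, `"."` for missing values, UTF-8
#' encoding, and optional leading comment lines starting with `#` (written
#' by the command-line interface to record provenance, skipped on read).
#' Internal coordinates are 1-based inclusive, matching pileup/VCF
#' convention; BED output is 0-based half-open.
#'
#' The formats are:
#' \describe{
#'   \item{base counts}{`chrom, pos, ref, count_A, count_C, count_G,
#'     count_T, count_other` — per-site read base counts for one sample.}
#'   \item{bulk counts}{`chrom, pos, wt_allele, mut_allele, wt_count,
#'     mut_count, other_count` — per-SNP parental-allele read counts for a
#'     pooled bulk.}
#'   \item{genome layout}{`chrom, length` — chromosome lengths in bp.}
#'   \item{windows}{`chrom, start, end, n_blocks, avg_neglog10p,
#'     significant` — sliding-window scan scores.}
#'   \item{BED}{`chrom, start, end, name, score` — candidate regions and
#'     origin segments, 0-based half-open.}
#' }
#'
#' @name bsa_formats
NULL

# ---- shared helpers ---------------------------------------------------------

# number of leading comment lines, so validation errors can cite file lines
count_comment_lines <- function(path) {
  lines <- readr::read_lines(path, n_max = 50L)
  n <- 0L
  for (l in lines) {
    if (startsWith(l, "#")) n <- n + 1L else break
  }
  n
}

read_tsv_quiet <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "bsascan_io_error")
  }
  # absent columns are caught by check_columns() with a clearer message,
  # and unparseable fields become NA and fail row validation
  suppressWarnings(
    readr::read_tsv(path, col_types = col_types, comment = "#", na = ".",
                    progress = FALSE))
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("malformed table ", path, ": missing column(s) ",
                 paste(missing, collapse = ", ")),
          class = "bsascan_format_error")
  }
  df[required]
}

# first row (1-based over data rows) violating `bad`; cite the file line
fail_rows <- function(bad, what, path, offset) {
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    i <- which(bad | is.na(bad))[1]
    abort(sprintf("invalid %s in %s at data row %d (file line %d)",
                  what, path, i, i + 1L + offset),
          class = "bsascan_validation_error")
  }
  invisible(NULL)
}

write_tsv_with_header <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0) {
    writeLines(paste0("# ", header_lines), con)
  }
  body <- readr::format_tsv(df, na = ".")
  writeLines(sub("\n$", "", body), con)
  invisible(path)
}

BASES <- c("A", "C", "G", "T")

# ---- base-count table -------------------------------------------------------

#' Read and write per-site base-count tables
#'
#' A base-count table holds, for one sample aligned to a reference, the
#' number of reads supporting each base at each position, plus a column for
#' non-ACGT observations. It is the input to [call_parent_snps()].
#'
#' @param path Path to a tab-separated file with header
#'   `chrom, pos, ref, count_A, count_C, count_G, count_T, count_other`.
#' @return A tibble with those columns, one row per site, in file order.
#'   Malformed rows (negative counts, `pos < 1`, `ref` not one of A/C/G/T)
#'   raise an error citing the offending line.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_base_counts(sim_example_sites(), tf)
#' read_base_counts(tf)
#' @export
read_base_counts <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    ref = readr::col_character(),
    count_A = readr::col_double(), count_C = readr::col_double(),
    count_G = readr::col_double(), count_T = readr::col_double(),
    count_other = readr::col_double()))
  df <- check_columns(df, c("chrom", "pos", "ref", paste0("count_", BASES),
                            "count_other"), path)
  off <- count_comment_lines(path)
  fail_rows(df$pos < 1 | df$pos != floor(df$pos), "pos", path, off)
  fail_rows(!(df$ref %in% BASES), "ref base", path, off)
  for (cc in c(paste0("count_", BASES), "count_other")) {
    fail_rows(df[[cc]] < 0, cc, path, off)
  }
  mutate(df, pos = as.integer(.data$pos))
}

#' @param sites A tibble as returned by [read_base_counts()].
#' @param header_lines Optional character vector written as leading `#`
#'   comment lines (provenance).
#' @rdname read_base_counts
#' @export
write_base_counts <- function(sites, path, header_lines = NULL) {
  sites <- check_columns(sites, c("chrom", "pos", "ref",
                                  paste0("count_", BASES), "count_other"),
                         "write_base_counts() input")
  write_tsv_with_header(sites, path, header_lines)
}

# ---- bulk-count table -------------------------------------------------------

#' Read and write bulk parental-allele count tables
#'
#' A bulk-count table holds, for each parent-vs-reference SNP marker, the
#' number of pooled-bulk reads carrying the wild-type parent's allele and
#' the mutant parent's allele. It is the input to [build_blocks()] and
#' [purity_profile()].
#'
#' @param path Path to a tab-separated file with header
#'   `chrom, pos, wt_allele, mut_allele, wt_count, mut_count, other_count`.
#' @return A tibble with those columns in file order. Rows with
#'   `wt_allele == mut_allele` or negative counts raise an error citing the
#'   offending line.
#' @export
read_bulk_counts <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    wt_allele = readr::col_character(), mut_allele = readr::col_character(),
    wt_count = readr::col_double(), mut_count = readr::col_double(),
    other_count = readr::col_double()))
  df <- check_columns(df, c("chrom", "pos", "wt_allele", "mut_allele",
                            "wt_count", "mut_count", "other_count"), path)
  off <- count_comment_lines(path)
  fail_rows(df$pos < 1 | df$pos != floor(df$pos), "pos", path, off)
  fail_rows(df$wt_allele == df$mut_allele,
            "alleles (wt_allele equals mut_allele)", path, off)
  for (cc in c("wt_count", "mut_count", "other_count")) {
    fail_rows(df[[cc]] < 0, cc, path, off)
  }
  mutate(df, pos = as.integer(.data$pos))
}

#' @param bulk A tibble as returned by [read_bulk_counts()].
#' @inheritParams write_base_counts
#' @rdname read_bulk_counts
#' @export
write_bulk_counts <- function(bulk, path, header_lines = NULL) {
  bulk <- check_columns(bulk, c("chrom", "pos", "wt_allele", "mut_allele",
                                "wt_count", "mut_count", "other_count"),
                        "write_bulk_counts() input")
  write_tsv_with_header(bulk, path, header_lines)
}

# ---- genome layout ----------------------------------------------------------

#' Read and write the chromosome length table
#'
#' @param path Path to a tab-separated file with header `chrom, length`
#'   (lengths in bp).
#' @return A tibble `chrom, length` in file order. Duplicate chromosome
#'   names or non-positive lengths are errors.
#' @export
read_genome_layout <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(chrom = readr::col_character(),
                                         length = readr::col_double()))
  df <- check_columns(df, c("chrom", "length"), path)
  off <- count_comment_lines(path)
  fail_rows(df$length < 1, "chromosome length", path, off)
  if (anyDuplicated(df$chrom)) {
    abort(paste0("duplicate chromosome names in ", path),
          class = "bsascan_validation_error")
  }
  mutate(df, length = as.double(.data$length))
}

#' @param layout A tibble `chrom, length`.
#' @inheritParams write_base_counts
#' @rdname read_genome_layout
#' @export
write_genome_layout <- function(layout, path, header_lines = NULL) {
  layout <- check_columns(layout, c("chrom", "length"),
                          "write_genome_layout() input")
  write_tsv_with_header(layout, path, header_lines)
}

# ---- SNP marker table -------------------------------------------------------

#' Read and write parent SNP marker tables
#'
#' @param path Path to a tab-separated file with header
#'   `chrom, pos, wt_allele, mut_allele, depth, purity`, as produced by
#'   [call_parent_snps()].
#' @return A tibble with those columns.
#' @export
read_parent_snps <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    wt_allele = readr::col_character(), mut_allele = readr::col_character(),
    depth = readr::col_double(), purity = readr::col_double()))
  df <- check_columns(df, c("chrom", "pos", "wt_allele", "mut_allele",
                            "depth", "purity"), path)
  mutate(df, pos = as.integer(.data$pos), depth = as.integer(.data$depth))
}

#' @param snps A tibble as returned by [call_parent_snps()].
#' @inheritParams write_base_counts
#' @rdname read_parent_snps
#' @export
write_parent_snps <- function(snps, path, header_lines = NULL) {
  snps <- check_columns(snps, c("chrom", "pos", "wt_allele", "mut_allele",
                                "depth", "purity"),
                        "write_parent_snps() input")
  write_tsv_with_header(snps, path, header_lines)
}

# ---- window table -----------------------------------------------------------

#' Read and write sliding-window score tables
#'
#' @param windows A tibble as returned by [scan_windows()]; columns
#'   `chrom, start, end, n_blocks, avg_neglog10p, significant` are written
#'   (windows with no blocks carry a missing score, written as `"."`).
#' @param path Output path.
#' @inheritParams write_base_counts
#' @export
write_windows_tsv <- function(windows, path, header_lines = NULL) {
  windows <- check_columns(windows, c("chrom", "start", "end", "n_blocks",
                                      "avg_neglog10p", "significant"),
                           "write_windows_tsv() input")
  write_tsv_with_header(windows, path, header_lines)
}

#' @rdname write_windows_tsv
#' @export
read_windows_tsv <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), n_blocks = readr::col_double(),
    avg_neglog10p = readr::col_double(), significant = readr::col_logical()))
  df <- check_columns(df, c("chrom", "start", "end", "n_blocks",
                            "avg_neglog10p", "significant"), path)
  mutate(df, start = as.integer(.data$start), end = as.integer(.data$end),
         n_blocks = as.integer(.data$n_blocks))
}

# ---- BED conversion ---------------------------------------------------------

#' Convert between 1-based inclusive intervals and BED coordinates
#'
#' Internal coordinates are 1-based inclusive `[start, end]`; BED records
#' are 0-based half-open `[start0, end0)`. The mapping
#' `(start, end) -> (start - 1, end)` is a bijection on valid intervals.
#'
#' @param start,end 1-based inclusive interval bounds (`start <= end`).
#' @param start0,end0 BED bounds (`start0 < end0`).
#' @return A tibble with the converted bounds.
#' @examples
#' to_bed_coords(700000, 3900000)  # the browser-style interval
#' @export
to_bed_coords <- function(start, end) {
  stopifnot(all(start >= 1), all(start <= end))
  tibble(start0 = as.double(start) - 1, end0 = as.double(end))
}

#' @rdname to_bed_coords
#' @export
from_bed_coords <- function(start0, end0) {
  stopifnot(all(start0 >= 0), all(start0 < end0))
  tibble(start = as.double(start0) + 1, end = as.double(end0))
}

write_bed <- function(df, path, name_prefix, score_col, header_lines = NULL) {
  df <- arrange(df, .data$chrom, .data$start, .data$end)
  bed <- tibble(
    chrom = df$chrom,
    start = to_bed_coords(df$start, df$end)$start0,
    end = to_bed_coords(df$start, df$end)$end0,
    name = if (nrow(df) > 0) {
      sprintf("%s_%d", name_prefix, seq_len(nrow(df)))
    } else character(),
    score = df[[score_col]])
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0) writeLines(paste0("# ", header_lines), con)
  if (nrow(bed) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s", bed$chrom, as.integer(bed$start),
                       as.integer(bed$end), bed$name,
                       formatC(bed$score, format = "fg", digits = 6)), con)
  }
  invisible(path)
}

read_bed <- function(path, score_col) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "bsascan_io_error")
  }
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character())
    out[[score_col]] <- double()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  iv <- from_bed_coords(as.double(vapply(parts, `[`, "", 2L)),
                        as.double(vapply(parts, `[`, "", 3L)))
  out <- tibble(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(iv$start), end = as.integer(iv$end),
    name = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, ""))
  out[[score_col]] <- vapply(parts, function(p) {
    if (length(p) >= 5) as.double(p[5]) else NA_real_
  }, 0)
  out
}

#' Write candidate regions or origin segments as BED
#'
#' Regions and segments are stored internally with 1-based inclusive
#' coordinates and written as sorted 0-based half-open BED records with a
#' name (`region_i` / `segment_i`) and a score column (the region peak
#' score, or the segment mean mutant-allele purity).
#'
#' @param regions A tibble as returned by [call_candidate_regions()].
#' @param segments A tibble as returned by [find_origin_runs()].
#' @param path Output path.
#' @inheritParams write_base_counts
#' @export
write_regions_bed <- function(regions, path, header_lines = NULL) {
  regions <- check_columns(regions, c("chrom", "start", "end", "peak_score"),
                           "write_regions_bed() input")
  write_bed(regions, path, "region", "peak_score", header_lines)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  read_bed(path, "peak_score")
}

#' @rdname write_regions_bed
#' @export
write_segments_bed <- function(segments, path, header_lines = NULL) {
  segments <- check_columns(segments, c("chrom", "start", "end",
                                        "mean_purity"),
                            "write_segments_bed() input")
  write_bed(segments, path, "segment", "mean_purity", header_lines)
}

#' @rdname write_regions_bed
#' @export
read_segments_bed <- function(path) {
  read_bed(path, "mean_purity")
}

# ---- VCF entry point --------------------------------------------------------

#' Extract parent SNP markers and bulk counts from a VCF
#'
#' Alternative entry point for users whose variants are already in a VCF
#' with per-sample allele depths (`AD`). Only biallelic SNP records at
#' which the parent sample is homozygous for the alternate allele are
#' retained; the wild-type allele is the REF base and the mutant allele the
#' ALT base. The bulk sample's `AD` field supplies the pooled counts.
#' Multi-allelic records are skipped, never split: the method is defined on
#' two parental alleles.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param parent_sample,bulk_sample Sample names in the VCF.
#' @return A list with elements `snps` (tibble
#'   `chrom, pos, wt_allele, mut_allele, depth, purity`, from the parent's
#'   AD when present), `bulk` (tibble in [read_bulk_counts()] layout) and
#'   `skipped` (tibble `reason, n` summarising discarded records).
#' @export
read_vcf_biallelic_snps <- function(path, parent_sample, bulk_sample) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "bsascan_io_error")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(parent_sample, bulk_sample)) {
    if (!s %in% samples) {
      abort(sprintf("sample '%s' not present in %s (has: %s)", s, path,
                    paste(samples, collapse = ", ")),
            class = "bsascan_validation_error")
    }
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (!any(grepl("(^|:)AD(:|$)", fmt))) {
    abort(paste0("VCF has no AD (allele depth) FORMAT field: ", path),
          class = "bsascan_format_error")
  }
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n <- nrow(fix)
  is_snp <- fix$REF %in% BASES & fix$ALT %in% BASES
  gt <- vcfR::extract.gt(vcf, element = "GT")[, parent_sample]
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  hom_alt <- !is.na(gt_clean) & gt_clean == "1/1"
  ad_bulk <- vcfR::extract.gt(vcf, element = "AD")[, bulk_sample]
  has_ad <- !is.na(ad_bulk) & ad_bulk != "."
  keep <- is_snp & hom_alt & has_ad
  skipped <- tibble(
    reason = c("not_biallelic_snp", "parent_not_hom_alt", "bulk_missing_ad"),
    n = c(sum(!is_snp), sum(is_snp & !hom_alt),
          sum(is_snp & hom_alt & !has_ad)))
  ad_parent <- vcfR::extract.gt(vcf, element = "AD")[, parent_sample]
  parse_ad <- function(x) {
    out <- matrix(NA_real_, nrow = length(x), ncol = 2)
    ok <- !is.na(x) & x != "."
    sp <- strsplit(x[ok], ",", fixed = TRUE)
    out[ok, 1] <- as.double(vapply(sp, `[`, "", 1L))
    out[ok, 2] <- as.double(vapply(sp, function(p) {
      if (length(p) >= 2) p[2] else NA_character_
    }, ""))
    out
  }
  adp <- parse_ad(ad_parent)[keep, , drop = FALSE]
  adb <- parse_ad(ad_bulk)[keep, , drop = FALSE]
  pdepth <- adp[, 1] + adp[, 2]
  snps <- tibble(
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    wt_allele = fix$REF[keep], mut_allele = fix$ALT[keep],
    depth = as.integer(pdepth),
    purity = ifelse(pdepth > 0, adp[, 2] / pdepth, NA_real_))
  bulk <- tibble(
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    wt_allele = fix$REF[keep], mut_allele = fix$ALT[keep],
    wt_count = as.integer(adb[, 1]), mut_count = as.integer(adb[, 2]),
    other_count = 0L)
  list(snps = snps, bulk = bulk, skipped = skipped)
}
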