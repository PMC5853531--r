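test_that("base-count tables parse in file order and validate rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\tcount_A\tcount_C\tcount_G\tcount_T\tcount_other",
               "chr1\t100\tA\t11\t0\t1\t0\t0",
               "chr2\t50\tC\t0\t14\t0\t0\t1",
               "chr1\t200\tG\t0\t0\t9\t0\t0"), tf)
  sites <- read_base_counts(tf)
  expect_equal(nrow(sites), 3)
  expect_equal(sites$pos, c(100L, 50L, 200L))  # file order preserved

  writeLines(c("chrom\tpos\tref\tcount_A\tcount_C\tcount_G\tcount_T\tcount_other",
               "chr1\t100\tA\t-1\t0\t1\t0\t0"), tf)
  expect_error(read_base_counts(tf), "line 2", class = "bsascan_validation_error")

  writeLines("chrom\tpos\tref\tcount_A\tcount_C\tcount_G\tcount_T\tcount_other", tf)
  expect_equal(nrow(read_base_counts(tf)), 0)

  writeLines(c("chrom\tpos\tref\tcount_A"), tf)
  expect_error(read_base_counts(tf), "missing column",
               class = "bsascan_format_error")
})

test_that("bulk-count tables parse, validate alleles and tolerate CRLF", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "chrom\tpos\twt_allele\tmut_allele\twt_count\tmut_count\tother_count"
  writeLines(c(hdr, "chr1\t100\tA\tG\t7\t21\t0"), tf)
  bulk <- read_bulk_counts(tf)
  expect_equal(nrow(bulk), 1)
  expect_equal(bulk$mut_count / (bulk$mut_count + bulk$wt_count), 0.75)

  con <- file(tf, "wb")
  writeLines(c(hdr, "chr1\t100\tA\tG\t7\t21\t0"), con, sep = "\r\n")
  close(con)
  expect_equal(read_bulk_counts(tf), bulk)  # dialect tolerance

  writeLines(c(hdr, "chr1\t100\tA\tA\t7\t21\t0"), tf)
  expect_error(read_bulk_counts(tf), "allele",
               class = "bsascan_validation_error")
})

test_that("every TSV format round-trips exactly", {
  dir <- withr::local_tempdir()
  sites <- make_sites(c("A", "C"), A = c(1, 0), C = c(0, 12), G = c(11, 0))
  bulk <- make_bulk(c(10, 25), mut = c(8, 20))
  layout <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(5e6, 3e6))
  snps <- call_parent_snps(sites)
  windows <- tibble::tibble(chrom = "chr1", start = c(1L, 100001L),
                            end = c(2000000L, 2100000L), n_blocks = c(7L, 0L),
                            avg_neglog10p = c(2.53125, NA),
                            significant = c(TRUE, FALSE))
  f <- function(x) file.path(dir, x)
  write_base_counts(sites, f("s.tsv")); write_bulk_counts(bulk, f("b.tsv"))
  write_genome_layout(layout, f("g.tsv")); write_parent_snps(snps, f("p.tsv"))
  write_windows_tsv(windows, f("w.tsv"))
  expect_equal(read_base_counts(f("s.tsv")), sites)
  expect_equal(read_bulk_counts(f("b.tsv")), bulk)
  expect_equal(read_genome_layout(f("g.tsv")), layout)
  expect_equal(read_parent_snps(f("p.tsv")), snps)
  expect_equal(read_windows_tsv(f("w.tsv")), windows)
})

test_that("comment header lines are written and skipped on read", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  layout <- tibble::tibble(chrom = "chr1", length = 1e6)
  write_genome_layout(layout, tf, header_lines = c("tool 0.1", "params: x=1"))
  expect_true(startsWith(readLines(tf, n = 1), "# "))
  expect_equal(read_genome_layout(tf), layout)
})

test_that("BED output is 0-based half-open, sorted, and handles empty input", {
  tf <- withr::local_tempfile(fileext = ".bed")
  # interval 0.7-3.9 Mb, 1-based inclusive, on chromosome D10
  regions <- tibble::tibble(chrom = "D10", start = 700000L, end = 3900000L,
                            peak_score = 3.2, n_windows = 10L)
  write_regions_bed(regions, tf)
  expect_match(readLines(tf, n = 1), "^D10\t699999\t3900000\t")

  write_regions_bed(regions[0, ], tf)
  expect_equal(length(readLines(tf)), 0)
  expect_equal(nrow(read_regions_bed(tf)), 0)

  shuffled <- tibble::tibble(chrom = c("chr2", "chr1", "chr1"),
                             start = c(100L, 900L, 200L),
                             end = c(200L, 1000L, 300L),
                             peak_score = c(3, 4, 5), n_windows = 1L)
  write_regions_bed(shuffled, tf)
  got <- read_regions_bed(tf)
  expect_equal(got$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(got$start, c(200L, 900L, 100L))
})

test_that("BED coordinate conversion is a bijection on valid intervals", {
  withr::local_seed(42)
  start <- sample.int(1e7, 200)
  end <- start + sample.int(1e6, 200) - 1L
  bed <- to_bed_coords(start, end)
  back <- from_bed_coords(bed$start0, bed$end0)
  expect_equal(back$start, as.double(start))
  expect_equal(back$end, as.double(end))
  expect_true(all(bed$end0 - bed$start0 == end - start + 1))
  expect_error(to_bed_coords(0, 10))
  expect_error(from_bed_coords(5, 5))
})

test_that("segments BED round-trips through write/read", {
  tf <- withr::local_tempfile(fileext = ".bed")
  segs <- tibble::tibble(chrom = "chr3", start = c(2420000L, 2870000L),
                         end = c(2700000L, 3370000L), n_snps = c(12L, 20L),
                         mean_purity = c(1, 0.99))
  write_segments_bed(segs, tf)
  got <- read_segments_bed(tf)
  expect_equal(got$start, segs$start)
  expect_equal(got$end, segs$end)
  expect_equal(got$mean_purity, segs$mean_purity, tolerance = 1e-6)
})

make_test_vcf <- function(path, records) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "##contig=<ID=chr1,length=1000000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "parent", "bulk", sep = "\t"),
    records), path)
}

test_that("VCF entry point retains biallelic hom-alt SNPs and maps AD", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  make_test_vcf(tf, c(
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t1/1:0,30\t0/1:6,18",
    "chr1\t200\t.\tA\tAT\t50\tPASS\t.\tGT:AD\t1/1:0,25\t0/1:5,15",
    "chr1\t300\t.\tC\tT\t50\tPASS\t.\tGT:AD\t0/1:10,12\t0/1:4,16"))
  res <- read_vcf_biallelic_snps(tf, "parent", "bulk")
  expect_equal(nrow(res$snps), 1)
  expect_equal(res$snps$pos, 100L)
  expect_equal(res$snps$wt_allele, "A")
  expect_equal(res$snps$mut_allele, "G")
  expect_equal(res$bulk$wt_count, 6L)
  expect_equal(res$bulk$mut_count, 18L)
  sk <- setNames(res$skipped$n, res$skipped$reason)
  expect_equal(unname(sk["not_biallelic_snp"]), 1L)
  expect_equal(unname(sk["parent_not_hom_alt"]), 1L)

  expect_error(read_vcf_biallelic_snps(tf, "nope", "bulk"), "sample",
               class = "bsascan_validation_error")
})

test_that("VCF without allele depths is rejected", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "parent", "bulk", sep = "\t"),
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t1/1\t0/1"), tf)
  expect_error(read_vcf_biallelic_snps(tf, "parent", "bulk"), "AD",
               class = "bsascan_format_error")
})
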