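blocks_at <- function(mid, p, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start_pos = as.integer(mid),
                 end_pos = as.integer(mid), n_snps = 1L, mut_reads = 20L,
                 wt_reads = 0L, depth = 20L, p_value = p)
}

test_that("window score is the mean -log10(P) and the threshold is strict", {
  layout <- tibble::tibble(chrom = "chr1", length = 2e6)
  blocks <- blocks_at(c(1e5, 2e5, 3e5), c(0.01, 0.001, 0.1))
  w <- scan_windows(blocks, layout, window_size = 2e6, step = 2e6,
                    min_blocks = 3, threshold = 2.0)
  expect_equal(w$n_blocks, 3L)
  expect_equal(w$avg_neglog10p, (2 + 3 + 1) / 3)
  expect_false(w$significant)  # score exactly 2 does not exceed 2
})

test_that("windows with fewer than min_blocks are filtered regardless of score", {
  layout <- tibble::tibble(chrom = "chr1", length = 2e6)
  blocks <- blocks_at(c(1e5, 2e5, 3e5, 4e5), rep(1e-10, 4))
  w <- scan_windows(blocks, layout, window_size = 2e6, step = 2e6,
                    min_blocks = 5, threshold = 2.0)
  expect_true(all(w$filtered))
  expect_false(any(w$significant))
  expect_equal(w$avg_neglog10p[1], 10)
})

test_that("windows tile from position 1 and truncate at the chromosome end", {
  layout <- tibble::tibble(chrom = "chr1", length = 2.5e6)
  w <- scan_windows(blocks_at(1e6, 0.5), layout)
  expect_equal(w$start, seq(1, 2.5e6, by = 1e5))
  expect_equal(w$end[1], 2e6)
  expect_true(all(w$end <= 2.5e6))
  last <- nrow(w)
  expect_equal(w$end[last], 2.5e6)  # truncated
  expect_lt(w$end[last] - w$start[last] + 1, 2e6)
})

test_that("blocks are assigned to windows by midpoint", {
  layout <- tibble::tibble(chrom = "chr1", length = 4e6)
  # block spanning 1.9-2.3 Mb has midpoint 2.1 Mb: it belongs to windows
  # covering 2.1 Mb, not to every window it overlaps
  blocks <- tibble::tibble(chrom = "chr1", start_pos = 1900001L,
                           end_pos = 2300001L, n_snps = 5L, mut_reads = 20L,
                           wt_reads = 0L, depth = 20L, p_value = 0.5)
  w <- scan_windows(blocks, layout, min_blocks = 1)
  mid <- (1900001 + 2300001) %/% 2
  with_block <- w[w$n_blocks > 0, ]
  expect_true(all(with_block$start <= mid & mid <= with_block$end))
  expect_true(all(w$n_blocks[w$start > mid | w$end < mid] == 0))
})

test_that("zero-block windows report a missing score, never zero", {
  layout <- tibble::tibble(chrom = "chr1", length = 5e6)
  w <- scan_windows(blocks_at(1e5, 0.5), layout, min_blocks = 1)
  empty <- w[w$n_blocks == 0, ]
  expect_gt(nrow(empty), 0)
  expect_true(all(is.na(empty$avg_neglog10p)))
  expect_false(any(empty$significant))
})

test_that("a block on a chromosome missing from the layout is an error", {
  layout <- tibble::tibble(chrom = "chr1", length = 2e6)
  expect_error(scan_windows(blocks_at(1e5, 0.5, chrom = "chrX"), layout),
               "chrX", class = "bsascan_validation_error")
})

test_that("window scores equal a brute-force recomputation (random blocks)", {
  withr::local_seed(19)
  layout <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(6e6, 4e6))
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    ch <- sample(layout$chrom, n, replace = TRUE)
    pos <- as.integer(runif(n) * layout$length[match(ch, layout$chrom)] * 0.99 + 1)
    blocks <- tibble::tibble(chrom = ch, start_pos = pos,
                             end_pos = pos + sample.int(5e4, n), n_snps = 2L,
                             mut_reads = 10L, wt_reads = 10L, depth = 20L,
                             p_value = runif(n))
    mb <- sample(1:6, 1)
    w <- scan_windows(blocks, layout, min_blocks = mb, threshold = 2)
    mids <- (blocks$start_pos + blocks$end_pos) %/% 2
    for (i in sample.int(nrow(w), 12)) {
      inwin <- blocks$chrom == w$chrom[i] & mids >= w$start[i] & mids <= w$end[i]
      expect_equal(w$n_blocks[i], sum(inwin))
      if (sum(inwin) > 0) {
        expect_equal(w$avg_neglog10p[i], mean(-log10(blocks$p_value[inwin])))
      } else {
        expect_true(is.na(w$avg_neglog10p[i]))
      }
      expect_equal(w$significant[i],
                   sum(inwin) >= mb && !is.na(w$avg_neglog10p[i]) &&
                     w$avg_neglog10p[i] > 2)
    }
  }
})

test_that("significant windows merge into regions by overlap or abutment", {
  w <- tibble::tibble(
    chrom = "chr1",
    start = c(1L, 100001L), end = c(2000000L, 2100000L),
    n_blocks = 8L, avg_neglog10p = c(2.5, 3.5), filtered = FALSE,
    significant = TRUE)
  r <- call_candidate_regions(w)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 1L)
  expect_equal(r$end, 2100000L)
  expect_equal(r$peak_score, 3.5)
  expect_equal(r$n_windows, 2L)

  # abutting (end + 1 == next start) merges, a 1-bp gap does not
  w2 <- tibble::tibble(chrom = "chr1", start = c(1L, 101L, 203L),
                       end = c(100L, 201L, 300L), n_blocks = 8L,
                       avg_neglog10p = 3, filtered = FALSE, significant = TRUE)
  r2 <- call_candidate_regions(w2)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$end[1], 201L)
})

test_that("region calling is empty-safe, order-independent and idempotent", {
  none <- tibble::tibble(chrom = "chr1", start = 1L, end = 100L,
                         n_blocks = 8L, avg_neglog10p = 1, filtered = FALSE,
                         significant = FALSE)
  expect_message(r0 <- call_candidate_regions(none), "no candidate")
  expect_equal(nrow(r0), 0)

  withr::local_seed(5)
  w <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    start = as.integer(sample.int(100, 30) * 100),
    n_blocks = 8L, avg_neglog10p = runif(30, 2, 4), filtered = FALSE,
    significant = sample(c(TRUE, FALSE), 30, replace = TRUE)) |>
    dplyr::mutate(end = start + 499L)
  r1 <- call_candidate_regions(w)
  r2 <- call_candidate_regions(w[sample.int(30), ])
  expect_equal(r1, r2)
  # windows on different chromosomes never merge
  expect_true(all(table(r1$chrom) >= 1))
})
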