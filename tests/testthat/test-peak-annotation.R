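chrlen <- c(chr1 = 1e6)

test_that("fold enrichment is depth-normalized ratio arithmetic", {
  expect_equal(fold_enrichment(73, 10, 1e6, 1e6, pseudocount = 0), 7.3)
  expect_equal(fold_enrichment(50, 50, 1e6, 1e6, pseudocount = 3), 1)
  # pseudocount keeps a zero control finite: (9+1)/(0+1)
  expect_equal(fold_enrichment(9, 0, 1e6, 1e6, pseudocount = 1), 10)
  expect_equal(fold_enrichment(9, 1, 1e6, 1e6, pseudocount = 1), 5)
  # depth normalization: halving control depth doubles its rate
  expect_equal(fold_enrichment(10, 10, 1e6, 5e5, pseudocount = 0), 0.5)
  expect_error(fold_enrichment(1, 1, 0, 1), "depths")
  expect_error(fold_enrichment(-1, 1, 1, 1), ">= 0")
})

test_that("Up2k boundaries are strand-aware and strictly upstream", {
  g_plus <- make_gene(strand = "+", start = 10000, end = 15000)
  idx <- region_map(g_plus, chrlen)
  cls <- function(idx, pos) {
    classify_positions(idx, tibble::tibble(chrom = "chr1", pos = pos))$region
  }
  expect_equal(cls(idx, 9500), "UP2K")
  expect_equal(cls(idx, 8000), "UP2K")      # tss - 2000, inclusive boundary
  expect_equal(cls(idx, 7999), "INTERGENIC")
  expect_equal(cls(idx, 10000), "EXON")     # tss itself is in the body
  expect_equal(cls(idx, 15500), "DOWN2K")
  expect_equal(cls(idx, 17001), "INTERGENIC")

  # minus-strand gene with body below the TSS: upstream is to the right
  g_minus <- make_gene(strand = "-", start = 5000, end = 10000)
  idx2 <- region_map(g_minus, chrlen)
  expect_equal(cls(idx2, 10500), "UP2K")
  expect_equal(cls(idx2, 12000), "UP2K")
  expect_equal(cls(idx2, 12001), "INTERGENIC")
  expect_equal(cls(idx2, 4500), "DOWN2K")
})

test_that("exon/intron structure is respected inside the gene body", {
  g <- make_gene(strand = "+", start = 10000, end = 16000,
                 exons = tibble::tibble(start = c(10000, 14000),
                                        end = c(11000, 16000)))
  idx <- region_map(g, chrlen)
  got <- classify_positions(
    idx, tibble::tibble(chrom = "chr1", pos = c(10500, 12000, 15000)))
  expect_equal(got$region, c("EXON", "INTRON", "EXON"))
})

test_that("gene outside chromosome bounds is rejected", {
  g <- make_gene(start = 999990, end = 1000100)
  expect_error(region_map(g, chrlen), "bounds")
  expect_error(
    classify_positions(region_map(make_gene(start = 10, end = 5000), chrlen),
                       tibble::tibble(chrom = "chrX", pos = 1)),
    "Unknown chromosome"
  )
})

test_that("classification equals the exhaustive per-position oracle", {
  genes <- sim_gene_models(10, c(chr1 = 3e5), seed = 21)
  idx <- region_map(genes, c(chr1 = 3e5))
  withr::with_seed(22, {
    pos <- sample.int(3e5, 10000, replace = TRUE)
  })
  got <- classify_positions(idx, tibble::tibble(chrom = "chr1", pos = pos))
  want <- vapply(pos, function(p)
    oracle_classify_position(genes, "chr1", p), character(1))
  expect_equal(got$region, want)
})

test_that("strand mirror maps UP2K to the mirrored DOWN2K", {
  center <- 50000
  g <- make_gene(strand = "+", start = 20000, end = 30000)
  g_m <- make_gene(strand = "-", start = 2 * center - 30000,
                   end = 2 * center - 20000)
  idx <- region_map(g, chrlen)
  idx_m <- region_map(g_m, chrlen)
  withr::with_seed(4, pos <- sample(15000:35000, 300))
  a <- classify_positions(idx, tibble::tibble(chrom = "chr1", pos = pos))
  b <- classify_positions(idx_m,
                          tibble::tibble(chrom = "chr1",
                                         pos = 2 * center - pos))
  expect_equal(a$region, b$region)
})

test_that("peaks are classified by their midpoint", {
  g <- make_gene(strand = "+", start = 10000, end = 15000)
  idx <- region_map(g, chrlen)
  pk <- tibble::tibble(peak_id = c("p1", "p2"), chrom = "chr1",
                       start = c(8500, 100000), end = c(9200, 100400))
  got <- classify_peaks(pk, idx)
  expect_equal(got$midpoint[1], 8850)
  expect_equal(got$region, c("UP2K", "INTERGENIC"))
})

test_that("planted peak classes are recovered exactly", {
  genes <- sim_gene_models(60, c(chr1 = 2e6, chr2 = 2e6), seed = 31)
  sim <- sim_peak_experiment(
    genes, c(chr1 = 2e6, chr2 = 2e6),
    counts_per_class = c(UP2K = 12, DOWN2K = 12, EXON = 12, INTRON = 12,
                         INTERGENIC = 12),
    frac_common = 0.5, seed = 32
  )
  truth <- dplyr::filter(sim$truth, signal)
  got <- classify_peaks(
    dplyr::select(truth, peak_id, chrom, start, end), sim$index)
  expect_equal(got$region, truth$class)
})

test_that("filtering and greedy intersection follow the stated rules", {
  m1 <- tibble::tibble(
    peak_id = c("a1", "a2", "a3"), chrom = "chr1",
    start = c(100, 500, 900), end = c(200, 600, 1000),
    fold = c(2.5, 1.8, 4.0)
  )
  m2 <- tibble::tibble(
    peak_id = c("b1", "b3"), chrom = "chr1",
    start = c(150, 950), end = c(250, 1050),
    fold = c(3.0, 2.2)
  )
  cmp <- filter_and_intersect(m1, m2)
  expect_equal(nrow(cmp$m1_pass), 2)
  expect_equal(nrow(cmp$common), 2)
  expect_setequal(cmp$common$m1_id, c("a1", "a3"))

  # identical lists: every passing peak pairs with itself
  cmp2 <- filter_and_intersect(m1, m1)
  expect_equal(nrow(cmp2$common), nrow(cmp2$m1_pass))
  expect_equal(cmp2$common$m1_id, cmp2$common$m2_id)

  # strict cut: fold exactly at the threshold fails unless strict = FALSE
  at <- tibble::tibble(peak_id = "x", chrom = "chr1", start = 1, end = 10,
                       fold = 2)
  expect_equal(nrow(filter_and_intersect(at, at)$m1_pass), 0)
  expect_equal(nrow(filter_and_intersect(at, at, strict = FALSE)$m1_pass), 1)

  # empty inputs give empty outputs, not errors
  empty <- m1[0, ]
  expect_equal(nrow(filter_and_intersect(empty, empty)$common), 0)
})

test_that("each peak joins at most one pair, largest overlap first", {
  m1 <- tibble::tibble(peak_id = c("a1", "a2"), chrom = "chr1",
                       start = c(100, 260), end = c(300, 400),
                       fold = c(3, 3))
  # b1 overlaps both a1 (141 bp) and a2 (41 bp)
  m2 <- tibble::tibble(peak_id = "b1", chrom = "chr1",
                       start = 160, end = 300, fold = 3)
  cmp <- filter_and_intersect(m1, m2)
  expect_equal(nrow(cmp$common), 1)
  expect_equal(cmp$common$m1_id, "a1")
  expect_equal(cmp$common$overlap_bp, 141)
})

test_that("raising the threshold never grows the filtered or common sets", {
  withr::with_seed(17, {
    mk <- function(n) {
      s <- sample.int(1e5, n)
      tibble::tibble(
        peak_id = paste0("p", 1:n),
        chrom = sample(c("chr1", "chr2"), n, TRUE),
        start = s, end = s + sample(50:500, n, TRUE),
        fold = runif(n, 0, 6)
      )
    }
    m1 <- mk(80); m2 <- mk(80)
    prev <- c(Inf, Inf, Inf)
    for (th in c(0.5, 1, 2, 3, 5)) {
      g <- glance(filter_and_intersect(m1, m2, threshold = th))
      now <- c(g$n_m1_pass, g$n_m2_pass, g$n_common)
      expect_true(all(now <= prev))
      prev <- now
    }
  })
})

test_that("per-chromosome counts include zero rows and sum to totals", {
  m1 <- tibble::tibble(
    peak_id = paste0("p", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr5", "chr5"),
    start = seq(100, 4100, by = 1000), end = seq(200, 4200, by = 1000),
    fold = 3
  )
  m2 <- m1[0, ]
  cmp <- filter_and_intersect(m1, m2)
  dist <- chromosome_distribution(cmp, chroms = c("chr1", "chr2", "chr5"))
  expect_equal(dist$m1, c(3L, 0L, 2L))
  expect_equal(dist$m2, c(0L, 0L, 0L))
  expect_equal(sum(dist$m1), nrow(cmp$m1_pass))

  empty <- filter_and_intersect(m1[0, ], m2)
  d0 <- chromosome_distribution(empty, chroms = c("chr1", "chr2"))
  expect_equal(d0$m1 + d0$m2 + d0$common, c(0L, 0L))
})

test_that("planted per-chromosome promoter-peak counts are recovered", {
  sim <- sim_chip_study(n_m1 = 30, n_m2 = 25, n_common = 10, n_noise = 15,
                        seed = 44)
  cmp <- filter_and_intersect(sim$m1, sim$m2)
  truth_m1 <- dplyr::count(
    dplyr::filter(sim$truth, signal, in_m1), chrom, name = "want")
  got <- dplyr::inner_join(cmp$per_chrom, truth_m1, by = "chrom")
  expect_equal(got$m1, got$want)
  expect_equal(glance(cmp)$n_common, 10)
})
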