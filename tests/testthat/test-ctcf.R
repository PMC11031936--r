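mkpeaks <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

test_that("pairwise sharing labels merged events and fixes the percent formula", {
  sh <- classify_sharing(mkpeaks("chr1", 0, 100), mkpeaks("chr1", 50, 150))
  expect_equal(sh$result$n_shared, 1)
  expect_equal(sh$result$union, 1)
  expect_equal(sh$result$percent_shared, 100)

  dis <- classify_sharing(mkpeaks("chr1", 0, 100), mkpeaks("chr1", 500, 600))
  expect_equal(dis$result$n_shared, 0)
  expect_equal(dis$result$union, 2)
  expect_equal(dis$result$percent_shared, 0)

  # abutting peaks do not merge (half-open, >= 1 bp rule)
  ab <- classify_sharing(mkpeaks("chr1", 0, 100), mkpeaks("chr1", 100, 200))
  expect_equal(ab$result$union, 2)
  expect_equal(ab$result$n_shared, 0)

  # symmetry up to swapping the specific counts
  a <- mkpeaks("chr1", c(0, 300, 900), c(100, 400, 950))
  b <- mkpeaks("chr1", c(50, 600), c(120, 700))
  s1 <- classify_sharing(a, b)$result
  s2 <- classify_sharing(b, a)$result
  expect_equal(s1$n_shared, s2$n_shared)
  expect_equal(s1$n_specific1, s2$n_specific2)
  expect_equal(s1$union, s2$union)
  expect_equal(s1$union, s1$n_shared + s1$n_specific1 + s1$n_specific2)
})

test_that("a minimum-overlap threshold demotes marginally covered events", {
  s1 <- mkpeaks("chr1", 0, 3)
  s2 <- mkpeaks("chr1", 1, 200)
  expect_equal(classify_sharing(s1, s2)$result$n_shared, 1)
  strict <- classify_sharing(s1, s2, min_overlap = 5)
  expect_equal(strict$result$n_shared, 0)
  expect_equal(strict$intervals$label, "specific2")
})

test_that("printed-count union arithmetic reproduces the shared percentage", {
  r <- sharing_result(11947, 16424 - 11947, 23859 - 11947)
  expect_equal(r$union, 16424 + 23859 - 11947)
  expect_equal(r$percent_shared, 42.2)
})

test_that("three-way interval sharing matches the per-basepair oracle", {
  one <- mkpeaks("chr1", c(10, 200), c(50, 260))
  same <- three_way_sharing(one, one, one)
  expect_equal(unname(same), c(0, 0, 0, 0, 0, 0, 2))
  dis <- three_way_sharing(mkpeaks("chr1", 0, 10), mkpeaks("chr1", 20, 30),
                           mkpeaks("chr1", 40, 50))
  expect_equal(unname(dis), c(1, 1, 1, 0, 0, 0, 0))
  for (seed in 1:5) {
    set.seed(seed)
    rand <- function() {
      s <- sample.int(1900, 8) - 1
      mkpeaks(sample(c("chr1", "chr2"), 8, TRUE), s, s + sample.int(60, 8))
    }
    a <- rand(); b <- rand(); c <- rand()
    expect_equal(unname(three_way_sharing(a, b, c)),
                 unname(brute_venn_intervals(a, b, c)))
  }
})

test_that("CTCF-bound anchor counts respect half-open overlap and slack", {
  loops <- data.frame(chrom = "chr1", start1 = 1000, end1 = 2000,
                      start2 = 8000, end2 = 9000)
  both <- mkpeaks("chr1", c(1500, 8100), c(1600, 8200))
  expect_equal(classify_loop_ctcf(loops, both), 2L)
  expect_equal(classify_loop_ctcf(loops, both[1, ]), 1L)
  expect_equal(classify_loop_ctcf(loops, mkpeaks("chr2", 1500, 1600)), 0L)
  # peak abutting the anchor end: unbound at slack 0, bound at slack 1
  abut <- mkpeaks("chr1", 2000, 2100)
  expect_equal(classify_loop_ctcf(loops, abut, slack = 0), 0L)
  expect_equal(classify_loop_ctcf(loops, abut, slack = 1), 1L)
  expect_error(classify_loop_ctcf(loops, abut, slack = -1), ">= 0")
  # class proportions sum to one
  s <- ctcf_class_summary(c(0L, 1L, 1L, 2L))
  expect_equal(sum(s$percent), 100)
  expect_equal(sum(s$n), 4)
})

test_that("meta-profile of a constant track is constant in covered bins", {
  peaks <- data.frame(chrom = "chr1", start = c(20000, 50000),
                      end = c(20400, 50400), summit = c(200, 200))
  flat <- data.frame(chrom = "chr1", start = seq(10000, 59950, 50),
                     end = seq(10050, 60000, 50), value = 0.8)
  prof <- metaprofile(peaks, flat, flank = 5000, bin = 100)
  covered <- !is.na(prof$mean_value)
  expect_true(all(abs(prof$mean_value[covered] - 0.8) < 1e-12))
  expect_true(all(prof$n_contributing[covered] == 2))
  expect_error(metaprofile(peaks, flat, flank = 5000, bin = 130),
               "divisible")
})

test_that("meta-profile handles uncovered bins and weights by overlap", {
  peaks <- data.frame(chrom = "chr1", start = 10000, end = 10400,
                      summit = 200)
  # two records of unequal width inside one 100-bp bin: weighted mean
  track <- data.frame(chrom = "chr1", start = c(10200, 10275),
                      end = c(10275, 10300), value = c(1, 5))
  prof <- metaprofile(peaks, track, flank = 5000, bin = 100)
  center <- prof[prof$offset == 0, ]
  expect_equal(center$mean_value, (75 * 1 + 25 * 5) / 100)
  expect_equal(center$n_contributing, 1L)
  far <- prof[prof$offset == -5000, ]
  expect_true(is.na(far$mean_value))
  expect_equal(far$n_contributing, 0L)
})

test_that("cross-analysis ranks, picks longest transcripts and filters coding", {
  genes <- rbind(mkgene("g1", "g1.1", "chr1", "+", 0, 5000),
                 mkgene("g1", "g1.2", "chr1", "+", 0, 8000),
                 mkgene("g2", "g2.1", "chr1", "+", 20000, 30000,
                        coding = FALSE),
                 mkgene("g3", "g3.1", "chr1", "+", 40000, 41000))
  expr <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     fib = c(50, 40, 30, 20), stringsAsFactors = FALSE)
  tr <- data.frame(chrom = "chr1", start = 0, end = 50000, value = 2)
  ca <- cross_analysis(expr, genes, list(sig = tr), "fib", top_n = 3,
                       coding_only = FALSE)
  expect_equal(ca$tx_id[ca$gene_id == "g1"], "g1.2")   # longest isoform
  expect_true(all(ca$mean_sig == 2))                   # constant track
  expect_equal(ca$gene_id, c("g1", "g2", "g3"))
  cod <- cross_analysis(expr, genes, list(sig = tr), "fib", top_n = 3,
                        coding_only = TRUE)
  expect_equal(cod$gene_id, c("g1", "g3"))             # g2 dropped
  expect_warning(
    cross_analysis(expr, genes, list(sig = tr), "fib", top_n = 4),
    "lack a transcript model")
})
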