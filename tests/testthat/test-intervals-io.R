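test_that("loop reader computes sizes, reorders anchors and rejects inter-chromosomal records", {
  f <- tmpfile(c("chr1\t100000\t110000\tchr1\t500000\t510000",
                 "chr1\t500000\t510000\tchr1\t100000\t110000\textra\tcols",
                 "chr1\t0\t10000\tchr2\t0\t10000"))
  expect_warning(loops <- read_loops(f), "inter-chromosomal")
  expect_equal(nrow(loops), 2L)
  expect_equal(attr(loops, "n_skipped"), 1L)
  expect_equal(loops$size, c(400000, 400000))
  # second record was swapped so anchor1 precedes anchor2
  expect_equal(loops$start1[2], 100000)
  expect_equal(loops$extra[2], "extra\tcols")
})

test_that("loop reader skips header lines and errors on malformed coordinates", {
  f <- tmpfile(c("chr1\tx1\tx2\tchr2\ty1\ty2\tobserved",
                 "chr1\t100\t200\tchr1\t900\t1000"))
  loops <- read_loops(f)
  expect_equal(nrow(loops), 1L)
  expect_equal(loops$size, 800)

  bad <- tmpfile(c("chr1\t100\t200\tchr1\t900\t1000",
                   "chr1\t100\toops\tchr1\t900\t1000"))
  expect_error(read_loops(bad), "line 2")
})

test_that("interval readers honour format contracts", {
  bed <- tmpfile("chr1\t0\t100")
  expect_equal(read_intervals(bed, "bed3"),
               data.frame(chrom = "chr1", start = 0, end = 100))

  np <- tmpfile("chr1\t200\t400\tpk1\t500\t.\t8.2\t-1\t-1\t50")
  pk <- read_intervals(np, "narrowPeak")
  expect_equal(pk$start + pk$summit, 250)   # absolute summit
  np2 <- tmpfile("chr1\t200\t400\tpk1\t500\t.\t8.2\t-1\t-1\t-1")
  expect_true(is.na(read_intervals(np2, "narrowPeak")$summit))

  bad <- tmpfile(c("chr1\t0\t10\t0.5", "chr1\t5\t15\t0.6"))
  expect_error(read_intervals(bad, "bedGraph"), "overlap")
  rev <- tmpfile("chr1\t100\t50")
  expect_error(read_intervals(rev, "bed3"), "start >= end")
})

test_that("reading then writing round-trips coordinates bit-exactly", {
  set.seed(42)
  iv <- random_intervals(50, max_pos = 1e7)
  iv <- iv[order(iv$chrom, iv$start), ]
  iv$value <- round(runif(50), 4)
  # drop overlaps so the track is valid
  keep <- c(TRUE, !(iv$chrom[-1] == iv$chrom[-50] & iv$start[-1] < iv$end[-50]))
  track <- iv[keep, ]
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(track, f)
  back <- read_intervals(f, "bedGraph")
  rownames(track) <- NULL
  expect_equal(back, track[, c("chrom", "start", "end", "value")])
  f2 <- tempfile(fileext = ".bedgraph")
  write_bedgraph(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("overlap_length obeys half-open arithmetic and symmetry", {
  a <- genomic_intervals("chr1", 0, 100)
  expect_equal(overlap_length(a, genomic_intervals("chr1", 50, 150)), 50L)
  expect_equal(overlap_length(a, genomic_intervals("chr1", 100, 200)), 0L)
  expect_equal(overlap_length(a, genomic_intervals("chr2", 0, 100)), 0L)
  set.seed(1)
  x <- random_intervals(40); y <- random_intervals(40)
  expect_equal(overlap_length(x, y), overlap_length(y, x))
  expect_true(all(overlap_length(x, y) <=
                  pmin(x$end - x$start, y$end - y$start)))
})

test_that("find_overlaps equals the quadratic brute-force oracle", {
  expect_equal(nrow(find_overlaps(genomic_intervals("chr1", 0, 10),
                                  random_intervals(0))), 0L)
  q <- genomic_intervals("chr1", 0, 10)
  s <- genomic_intervals(c("chr1", "chr1"), c(5, 20), c(8, 30))
  expect_equal(find_overlaps(q, s)$subject, 1L)
  for (seed in 1:5) {
    set.seed(seed)
    q <- random_intervals(200)
    s <- random_intervals(200)
    got <- find_overlaps(q, s)
    ref <- brute_overlaps(q, s)
    expect_equal(got[order(got$query, got$subject), ],
                 ref[order(ref$query, ref$subject), ],
                 ignore_attr = TRUE)
  }
})

test_that("contact statistics aggregate with rounding and guard rails", {
  s <- data.frame(sample = c("es", "epi", "fib"),
                  total_contacts = c(643.2e6, 588.0e6, 699.1e6),
                  inter_chromosomal_fraction = c(0.108, 0.241, 0.322))
  agg <- aggregate_contact_stats(s)
  expect_equal(agg$billions, 1.93)
  one <- aggregate_contact_stats(data.frame(sample = "x", total_contacts = 1e6))
  expect_equal(one$millions, 1)
  expect_equal(one$billions, 0)
  expect_error(aggregate_contact_stats(s[0, ]), "at least one")
  s$total_contacts[1] <- -5
  expect_error(aggregate_contact_stats(s), "negative")
})

test_that("gene models parse from bed12 and refflat with strand-aware TSS", {
  b12 <- tmpfile(paste("chr1", 1000, 9000, "GA.1", 0, "-", 1100, 8900, 0, 2,
                       "2000,3000", "0,5000", sep = "\t"))
  g <- read_genes(b12, "bed12")
  expect_equal(g$gene_id, "GA")
  expect_equal(g$tss, 9000)               # minus strand: TSS at txEnd
  expect_true(g$coding)
  expect_equal(g$exon_start[[1]], c(1000, 6000))
  expect_equal(g$exon_end[[1]], c(3000, 9000))

  rf <- tmpfile(paste("GB", "GB.tx1", "chr2", "+", 500, 4000, 500, 500, 1,
                      "500,", "4000,", sep = "\t"))
  g2 <- read_genes(rf, "refflat")
  expect_equal(g2$tss, 500)
  expect_false(g2$coding)                 # empty CDS -> non-coding
})
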