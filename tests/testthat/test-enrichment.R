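test_that("anchor annotation applies promoter > exon > intron > intergenic", {
  g <- data.frame(gene_id = "G1", tx_id = "G1.1", chrom = "chr1",
                  strand = "+", start = 10000, end = 30000,
                  cds_start = 10000, cds_end = 30000, coding = TRUE,
                  tss = 10000, stringsAsFactors = FALSE)
  g$exon_start <- list(c(10000, 20000))
  g$exon_end <- list(c(12000, 22000))
  ann <- function(s, e) {
    a <- annotate_anchors(data.frame(chrom = "chr1", start = s, end = e), g)
    as.character(a$annotation)
  }
  # over the TSS window: promoter wins even though exon 1 also overlaps
  expect_equal(ann(9000, 10500), "promoter")
  expect_equal(ann(11000, 11500), "exon")
  expect_equal(ann(15000, 16000), "intron")   # inside body, between exons
  expect_equal(ann(50000, 51000), "intergenic")
  a2 <- annotate_anchors(data.frame(chrom = "chr9", start = 0, end = 100), g)
  expect_equal(as.character(a2$annotation), "intergenic")
  expect_true(is.na(a2$gene_id))
})

test_that("promoter-contact genes deduplicate and respect half-open windows", {
  g <- rbind(
    data.frame(gene_id = "X", tx_id = "X.1", chrom = "chr1", strand = "+",
               start = 10000, end = 20000, cds_start = 10000,
               cds_end = 20000, coding = TRUE, tss = 10000),
    data.frame(gene_id = "Y", tx_id = "Y.1", chrom = "chr1", strand = "+",
               start = 50000, end = 60000, cds_start = 50000,
               cds_end = 60000, coding = TRUE, tss = 50000))
  g$exon_start <- list(numeric(0), numeric(0))
  g$exon_end <- list(numeric(0), numeric(0))
  # window for X is [8000, 10100)
  loops <- data.frame(chrom = "chr1", start1 = 9000, end1 = 9500,
                      start2 = 9600, end2 = 9700)
  expect_equal(promoter_contact_genes(loops, g), "X")  # both anchors, once
  outside <- data.frame(chrom = "chr1", start1 = 7000, end1 = 8000,
                        start2 = 100000, end2 = 100100)
  expect_equal(promoter_contact_genes(outside, g), character(0))
})

test_that("three-way gene-set sharing equals per-element brute force", {
  v <- contact_sharing(c("a", "b", "c"), c("b", "c", "d"), "c")
  expect_equal(unname(v), c(1, 1, 0, 1, 0, 0, 1))
  same <- contact_sharing(letters[1:4], letters[1:4], letters[1:4])
  expect_equal(unname(same), c(0, 0, 0, 0, 0, 0, 4))
  dis <- contact_sharing("a", "b", "c")
  expect_equal(unname(dis), c(1, 1, 1, 0, 0, 0, 0))
  for (seed in 1:10) {
    set.seed(seed)
    pool <- sprintf("g%02d", 1:30)
    a <- sample(pool, sample(0:15, 1))
    b <- sample(pool, sample(0:15, 1))
    c <- sample(pool, sample(0:15, 1))
    expect_equal(unname(contact_sharing(a, b, c)),
                 unname(brute_venn_sets(a, b, c)))
    expect_equal(sum(contact_sharing(a, b, c)),
                 length(unique(c(a, b, c))))
  }
})

test_that("hypergeometric ORA matches the exhaustive tail sum to 1e-12", {
  universe <- sprintf("g%02d", 1:20)
  gmt <- list(T1 = universe[1:5])
  query <- universe[c(1, 2, 3, 6, 7)]          # k = 3, K = 5, n = 5, N = 20
  res <- enrich(query, gmt, universe)
  expect_equal(res$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$p, hyper_tail_exhaustive(3, 5, 20, 5), tolerance = 1e-12)

  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(10:30, 1)
    uni <- sprintf("u%02d", 1:N)
    gmt <- lapply(1:4, function(i) sample(uni, sample.int(N, 1)))
    names(gmt) <- paste0("term", 1:4)
    q <- sample(uni, sample.int(N, 1))
    res <- enrich(q, gmt, uni)
    for (i in seq_len(nrow(res)))
      expect_equal(res$p[i],
                   hyper_tail_exhaustive(res$k[i], res$K[i], N, res$n[i]),
                   tolerance = 1e-12)
    # BH never inverts the p ordering
    expect_equal(order(res$q), order(sort(res$p)))
    expect_true(all(res$q >= res$p))
  }
})

test_that("ORA edge contracts: full query, empty overlap, dropped genes", {
  uni <- letters[1:10]
  gmt <- list(T = letters[1:4], empty_after = c("zz1", "zz2"))
  all_q <- enrich(uni, gmt, uni)
  expect_equal(all_q$k, all_q$K)
  expect_equal(all_q$p, 1)
  expect_equal(nrow(all_q), 1L)               # K = 0 term skipped
  none <- enrich(letters[5:10], list(T = letters[1:4]), uni)
  expect_lte(none$k, 0L + none$K)
  zero <- enrich(letters[9:10], list(T = letters[1:4]), uni)
  expect_equal(zero$k, 0L)
  expect_equal(zero$p, 1)
  expect_warning(enrich(c("a", "OUTSIDE"), list(T = letters[1:4]), uni),
                 "outside the universe")
  expect_error(enrich("a", gmt, character(0)), "empty universe")
})

test_that("GMT parsing keeps term -> member structure", {
  f <- tmpfile(c("T1\tdesc\tg1\tg2\tg3", "T2\tdesc\tg2"))
  gmt <- read_gmt(f)
  expect_equal(names(gmt), c("T1", "T2"))
  expect_equal(gmt$T1, c("g1", "g2", "g3"))
  expect_error(read_gmt(tmpfile("T1\tonly")), "fewer than 3")
})
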