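test_that("config validation rejects inconsistent parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(nesting_prob = 1.4), "probabilities")
  expect_error(sim_config(expr_log2_mean_A = 1, expr_log2_mean_B = 2),
               "must exceed")
  expect_error(sim_config(meth_dip_depth = 0.9, meth_baseline = 0.5),
               "cannot exceed")
  expect_error(sim_config(n_loops = c(intra = 5)), "n_loops")
  expect_error(sim_config(chrom_sizes = c(1e6, 2e6)), "named")
})

test_that("unsatisfiable category counts fail loudly", {
  # a genome far too small to host TADs means intra loops cannot be placed
  tiny <- sim_config(chrom_sizes = c(chrZ = 2e5), n_genes = 2,
                     n_loops = c(intra = 3, inter = 1, one_anchor = 1,
                                 not_in_tad = 1),
                     peak_sharing = c(epi_only = 1, fib_only = 1, shared = 1),
                     n_crystallin = 1, seed = 2)
  expect_error(generate_universe(tiny, file.path(tempdir(), "tiny_uni")),
               "unsatisfiable|too large|cannot place")
})

test_that("planted features are internally consistent with their labels", {
  uni <- shared_universe()
  truth <- uni$truth
  # per-category loop definitions hold on the truth ledger itself
  for (cell in c("epi", "fib")) {
    lt <- truth$loops[truth$loops$cell == cell, ]
    tads <- read_intervals(file.path(uni$dir,
                                     sprintf("tads_%s.bed", cell)), "bed3")
    contain <- function(m, ch) {
      which(tads$chrom == ch & tads$start <= m & m < tads$end)
    }
    for (i in seq_len(nrow(lt))) {
      t1 <- contain(lt$m1[i], lt$chrom[i])
      t2 <- contain(lt$m2[i], lt$chrom[i])
      both <- intersect(t1, t2)
      ok <- switch(lt$category[i],
        INTRA = length(both) >= 1,
        INTER = length(both) == 0 && length(t1) >= 1 && length(t2) >= 1,
        ONE_ANCHOR = xor(length(t1) >= 1, length(t2) >= 1),
        NOT_IN_TAD = length(t1) == 0 && length(t2) == 0)
      expect_true(ok, info = sprintf("%s loop %d", lt$category[i], i))
    }
  }
  # planted shared peaks appear in both emitted files, specific ones in one
  epi <- read_intervals(file.path(uni$dir, "ctcf_epi.narrowPeak"),
                        "narrowPeak")
  fib <- read_intervals(file.path(uni$dir, "ctcf_fib.narrowPeak"),
                        "narrowPeak")
  shared_ids <- truth$peaks$peak_id[truth$peaks$membership == "shared"]
  expect_true(all(shared_ids %in% epi$name) && all(shared_ids %in% fib$name))
  epi_only <- truth$peaks$peak_id[truth$peaks$membership == "epi_only"]
  expect_true(all(epi_only %in% epi$name) && !any(epi_only %in% fib$name))
  # every emitted peak maps back to exactly one truth entry
  expect_true(all(sort(unique(c(epi$name, fib$name))) ==
                  sort(truth$peaks$peak_id)))
})

test_that("emitted tracks respect their declared ranges and structure", {
  uni <- shared_universe()
  meth <- read_intervals(file.path(uni$dir, "meth_epi.bedgraph"), "bedGraph")
  expect_true(all(meth$value >= 0 & meth$value <= 1))
  expect_true(all(meth$start %% 50 == 0))          # CpG grid
  pc1 <- read_intervals(file.path(uni$dir, "pc1_epi.bedgraph"), "bedGraph")
  expect_true(all(pc1$end - pc1$start == 10000))   # 10-kb eigenvector bins
  expect_true(all(pc1$value != 0))
  pol <- read_intervals(file.path(uni$dir, "polII.bedgraph"), "bedGraph")
  expect_true(all(pol$value >= 0))
  # gene-body coverage is proportional to fiber expression
  expr <- read_expression(file.path(uni$dir, "expression.tsv"))
  genes <- read_genes(file.path(uni$dir, "genes.bed12"))
  merged <- merge(
    data.frame(chrom = pol$chrom, start = pol$start, value = pol$value),
    data.frame(chrom = genes$chrom, start = genes$start,
               gene_id = genes$gene_id),
    by = c("chrom", "start"))
  fpkm <- setNames(expr$fib, expr$gene_id)
  expect_equal(cor(merged$value, fpkm[merged$gene_id]), 1,
               tolerance = 1e-6)
})

test_that("same seed reproduces files byte-identically, new seed perturbs them", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  d3 <- file.path(tempdir(), "det3")
  small <- function(seed) sim_config(
    chrom_sizes = c(chr1 = 2e7), n_genes = 60,
    n_loops = c(intra = 8, inter = 4, one_anchor = 2, not_in_tad = 2),
    peak_sharing = c(epi_only = 5, fib_only = 5, shared = 5),
    n_crystallin = 3, seed = seed)
  generate_universe(small(5), d1)
  generate_universe(small(5), d2)
  generate_universe(small(6), d3)
  files <- setdiff(list.files(d1), "pipeline_config.yaml")  # embeds outdir
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  expect_true(any(vapply(files, function(f)
    !identical(readLines(file.path(d1, f)), readLines(file.path(d3, f))),
    logical(1))))
})

test_that("boundary genes are the only compartment mislabels", {
  db <- file.path(tempdir(), "bnd_uni")
  cfgb <- sim_config(chrom_sizes = c(chr1 = 3e7), n_genes = 80,
                     boundary_genes = 8,
                     n_loops = c(intra = 5, inter = 2, one_anchor = 1,
                                 not_in_tad = 1),
                     peak_sharing = c(epi_only = 3, fib_only = 3, shared = 3),
                     n_crystallin = 3, seed = 9)
  truth <- generate_universe(cfgb, db)
  genes <- read_genes(file.path(db, "genes.bed12"))
  bins <- compartment_bins(read_intervals(file.path(db, "pc1_epi.bedgraph"),
                                          "bedGraph"))
  calls <- assign_gene_compartment(genes, bins)
  m <- merge(calls$genes, truth$genes, by = "gene_id")
  mismatch <- m$gene_id[m$label.x != m$label.y]
  expect_true(all(mismatch %in% truth$genes$gene_id[truth$genes$boundary]))
  non_boundary <- m[!m$boundary, ]
  expect_equal(mean(non_boundary$label.x == non_boundary$label.y), 1)
  # boundary promoters really straddle: all planted mislabels are boundary
  expect_equal(sort(mismatch),
               sort(truth$genes$gene_id[truth$genes$boundary]))
})
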