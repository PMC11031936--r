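# Seeded generator of a coherent toy feature universe: a small genome
# tiled with (optionally nested) TADs, chromatin loops planted to satisfy
# each loop-TAD arrangement category by construction, CTCF peaks at loop
# anchors and in the background with controlled sharing between two cell
# types, blocky +/- eigenvector compartments, genes whose promoters sit
# wholly inside compartment blocks, expression elevated in compartment A,
# methylation dips at CTCF peak centers, and gene-body coverage tracks
# proportional to expression.  Everything planted is recorded in a
# ground-truth ledger so downstream classifiers can be validated exactly.
#
# All planted peak centers and anchor midpoints live on a 50-bp grid
# (the CpG grid of the methylation track), peak centers are >= 1 kb
# apart, and anchor midpoints >= 12 kb apart across cell types, so
# merged-interval peak sharing and per-anchor CTCF classification recover
# the planted labels exactly.

#' Build a generator configuration
#'
#' Defaults describe a two-chromosome 80-Mb toy genome; see the package
#' vignette for the rationale behind each value.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param tad_size_log_mean,tad_size_log_sd Log-normal TAD size
#'   parameters (log-bp); default median 300 kb.
#' @param nesting_prob Probability a top-level TAD receives one strictly
#'   nested child (nesting depth <= 2).
#' @param gap_prob,gap_min,gap_max Inter-TAD gap model: with probability
#'   `gap_prob` a gap of Uniform(`gap_min`, `gap_max`) bp follows a TAD.
#' @param n_loops Named counts per category:
#'   `intra`, `inter`, `one_anchor`, `not_in_tad` (per cell type).
#' @param anchor_width Loop-anchor bin width (bp, default 10 kb).
#' @param ctcf_at_anchor_prob Probability each loop anchor receives a
#'   CTCF peak (planted as shared between the cell types).
#' @param peak_sharing Named counts of background peaks per membership:
#'   `epi_only`, `fib_only`, `shared`.
#' @param peak_width CTCF peak width (bp).
#' @param compartment_block_size Width of alternating A/B blocks (bp).
#' @param pc_magnitude Eigenvector magnitude (sign alternates per block).
#' @param n_genes Number of genes (split evenly between A and B blocks).
#' @param boundary_genes Number of extra genes whose promoter straddles a
#'   compartment block edge (default 0).
#' @param noncoding_frac Fraction of genes flagged non-coding.
#' @param n_crystallin Number of "crystallin-like" genes: coding,
#'   compartment A, planted at the very top of the fiber expression
#'   ranking (and hence of the gene-body Pol II / CTCF coverage).
#' @param expr_log2_mean_A,expr_log2_mean_B,expr_log2_sd Per-compartment
#'   log2-expression model; A must exceed B.
#' @param meth_baseline,meth_dip_depth,meth_dip_halfwidth Methylation
#'   model: baseline fraction with linear dips to
#'   `baseline - dip_depth` within `+/- dip_halfwidth` of peak centers.
#' @param meth_window Half-width (bp) of the CpG-covered window emitted
#'   around each peak center (50-bp grid).
#' @param cells Names of the two cell types.
#' @param seed Integer seed governing all randomness.
#' @return Validated config list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 50e6, chr2 = 30e6),
                       tad_size_log_mean = log(3e5),
                       tad_size_log_sd = 0.4,
                       nesting_prob = 0.3,
                       gap_prob = 0.6, gap_min = 5e4, gap_max = 2e5,
                       n_loops = c(intra = 60, inter = 25,
                                   one_anchor = 10, not_in_tad = 5),
                       anchor_width = 1e4,
                       ctcf_at_anchor_prob = 0.7,
                       peak_sharing = c(epi_only = 30, fib_only = 50,
                                        shared = 20),
                       peak_width = 400,
                       compartment_block_size = 2e6,
                       pc_magnitude = 1.5,
                       n_genes = 400,
                       boundary_genes = 0,
                       noncoding_frac = 0.2,
                       n_crystallin = 10,
                       expr_log2_mean_A = 5, expr_log2_mean_B = 3,
                       expr_log2_sd = 1,
                       meth_baseline = 0.8, meth_dip_depth = 0.7,
                       meth_dip_halfwidth = 250,
                       meth_window = 6000,
                       cells = c("epi", "fib"),
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$nesting_prob, cfg$gap_prob, cfg$ctcf_at_anchor_prob,
             cfg$noncoding_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (is.null(names(cfg$chrom_sizes)) || any(cfg$chrom_sizes <= 0))
    stop("chrom_sizes must be a named vector of positive lengths")
  need <- c("intra", "inter", "one_anchor", "not_in_tad")
  if (!all(need %in% names(cfg$n_loops)))
    stop("n_loops needs counts for: ", paste(need, collapse = ", "))
  if (!all(c("epi_only", "fib_only", "shared") %in% names(cfg$peak_sharing)))
    stop("peak_sharing needs epi_only, fib_only, shared counts")
  if (any(cfg$n_loops < 0) || any(cfg$peak_sharing < 0))
    stop("counts must be non-negative")
  if (cfg$expr_log2_mean_A <= cfg$expr_log2_mean_B)
    stop("expr_log2_mean_A must exceed expr_log2_mean_B")
  sizes <- c(cfg$anchor_width, cfg$peak_width, cfg$compartment_block_size,
             cfg$meth_dip_halfwidth, cfg$meth_window)
  if (any(sizes <= 0)) stop("sizes must be positive")
  if (cfg$meth_dip_depth > cfg$meth_baseline)
    stop("meth_dip_depth cannot exceed meth_baseline")
  if (length(cfg$cells) != 2L) stop("exactly two cell types are modelled")
  if (!.is_count(cfg$seed)) stop("seed must be a non-negative integer")
  class(cfg) <- "sim_config"
  cfg
}

.grid50 <- function(x) round(x / 50) * 50

# ---- TAD layout -----------------------------------------------------------

.sim_tads_chrom <- function(L, cfg) {
  top <- list(); child <- list()
  pos <- 0
  repeat {
    size <- .grid50(min(max(stats::rlnorm(1, cfg$tad_size_log_mean,
                                          cfg$tad_size_log_sd), 5e4), 2e6))
    if (pos + size > L - 1e5) break
    top[[length(top) + 1L]] <- c(pos, pos + size)
    if (stats::runif(1) < cfg$nesting_prob && size >= 1.5e5) {
      csize <- .grid50(size * stats::runif(1, 0.25, 0.45))
      cstart <- .grid50(pos + stats::runif(1, 0.1, 0.5) * (size - csize))
      if (cstart > pos && cstart + csize < pos + size)
        child[[length(child) + 1L]] <- c(cstart, cstart + csize)
    }
    pos <- pos + size
    if (stats::runif(1) < cfg$gap_prob)
      pos <- pos + .grid50(stats::runif(1, cfg$gap_min, cfg$gap_max))
  }
  mk <- function(lst) if (length(lst))
    data.frame(start = vapply(lst, `[`, 0, 1), end = vapply(lst, `[`, 0, 2))
  else data.frame(start = numeric(), end = numeric())
  list(top = mk(top), child = mk(child))
}

.gaps_of <- function(top, L) {
  if (nrow(top) == 0L) return(data.frame(start = 0, end = L))
  top <- top[order(top$start), ]
  start <- c(0, top$end)
  end <- c(top$start, L)
  g <- data.frame(start = start, end = end)
  g[g$end - g$start >= 4e4, , drop = FALSE]
}

# ---- placement helpers ----------------------------------------------------

.sample_in <- function(lo, hi) {
  if (hi <= lo) return(NULL)
  .grid50(stats::runif(1, lo, hi))
}

# anchor midpoints must stay >= 12 kb apart across all loops and cells so
# that a peak planted at one anchor can never overlap another loop's anchor
.new_registry <- function() new.env(parent = emptyenv())
.reg_ok <- function(reg, key, pos, min_sep) {
  v <- reg[[key]]
  is.null(v) || all(abs(v - pos) >= min_sep)
}
.reg_add <- function(reg, key, pos) reg[[key]] <- c(reg[[key]], pos)

.place_midpoint <- function(reg, chrom, lo, hi, min_sep = 12e3, tries = 80) {
  for (i in seq_len(tries)) {
    m <- .sample_in(lo, hi)
    if (!is.null(m) && .reg_ok(reg, paste0("a_", chrom), m, min_sep)) {
      .reg_add(reg, paste0("a_", chrom), m)
      return(m)
    }
  }
  NULL
}

.place_peak_center <- function(reg, chrom, pos, min_sep = 1e3) {
  if (.reg_ok(reg, paste0("p_", chrom), pos, min_sep)) {
    .reg_add(reg, paste0("p_", chrom), pos)
    TRUE
  } else FALSE
}

# ---- loop planting --------------------------------------------------------

.plant_loops_cell <- function(tads_by_chrom, cfg, reg) {
  chroms <- names(cfg$chrom_sizes)
  rows <- list()
  plant <- function(category, n) {
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        ch <- sample(chroms, 1, prob = cfg$chrom_sizes)
        td <- tads_by_chrom[[ch]]
        gaps <- td$gaps
        m <- switch(category,
          intra = {
            ok <- td$top[td$top$end - td$top$start >= 6e4, , drop = FALSE]
            if (nrow(ok) == 0L) NULL else {
              t <- ok[sample.int(nrow(ok), 1), ]
              m1 <- .place_midpoint(reg, ch, t$start + 1e3, t$end - 22e3)
              m2 <- if (is.null(m1)) NULL else
                .place_midpoint(reg, ch, m1 + 2e4, t$end - 1e3)
              if (is.null(m1) || is.null(m2)) NULL else c(m1, m2)
            }
          },
          inter = {
            if (nrow(td$top) < 2L) NULL else {
              pick <- sort(sample.int(nrow(td$top), 2))
              t1 <- td$top[pick[1], ]; t2 <- td$top[pick[2], ]
              m1 <- .place_midpoint(reg, ch, t1$start + 1e3, t1$end - 1e3)
              m2 <- if (is.null(m1)) NULL else
                .place_midpoint(reg, ch, t2$start + 1e3, t2$end - 1e3)
              if (is.null(m1) || is.null(m2)) NULL else c(m1, m2)
            }
          },
          one_anchor = {
            if (nrow(td$top) == 0L || nrow(gaps) == 0L) NULL else {
              t <- td$top[sample.int(nrow(td$top), 1), ]
              g <- gaps[sample.int(nrow(gaps), 1), ]
              mt <- .place_midpoint(reg, ch, t$start + 1e3, t$end - 1e3)
              mg <- if (is.null(mt)) NULL else
                .place_midpoint(reg, ch, g$start + 1e3, g$end - 1e3)
              if (is.null(mt) || is.null(mg)) NULL else sort(c(mt, mg))
            }
          },
          not_in_tad = {
            if (nrow(gaps) == 0L) NULL else {
              g1 <- gaps[sample.int(nrow(gaps), 1), ]
              g2 <- gaps[sample.int(nrow(gaps), 1), ]
              m1 <- .place_midpoint(reg, ch, g1$start + 1e3, g1$end - 1e3)
              m2 <- if (is.null(m1)) NULL else
                .place_midpoint(reg, ch, g2$start + 1e3, g2$end - 1e3)
              if (is.null(m1) || is.null(m2) || m1 == m2) NULL else sort(c(m1, m2))
            }
          })
        if (!is.null(m) && m[1] != m[2]) {
          rows[[length(rows) + 1L]] <<- data.frame(
            chrom = ch, m1 = min(m), m2 = max(m), category = toupper(category),
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("cannot place a '%s' loop on this genome: %s", category,
                     "category counts unsatisfiable with the given TAD layout"))
    }
  }
  plant("intra", cfg$n_loops[["intra"]])
  plant("inter", cfg$n_loops[["inter"]])
  plant("one_anchor", cfg$n_loops[["one_anchor"]])
  plant("not_in_tad", cfg$n_loops[["not_in_tad"]])
  df <- data.table::rbindlist(rows)
  as.data.frame(df)
}

# ---- main entry -----------------------------------------------------------

#' Generate the synthetic feature universe
#'
#' Writes every standard-format file the pipeline consumes into `outdir`
#' and returns (and writes, as `truth.json`) the ground-truth ledger.
#' With a fixed seed the run is byte-identical.
#'
#' Emitted files: `tads_<cell>.bed`, `loops_<cell>.bedpe`,
#' `ctcf_<cell>.narrowPeak`, `pc1_<cell>.bedgraph`, `meth_<cell>.bedgraph`,
#' `polII.bedgraph`, `ctcf_cov_<cell>.bedgraph`, `genes.bed12`,
#' `expression.tsv`, `chrom_sizes.tsv`, `truth.json`, `config.yaml` and a
#' ready-to-run pipeline config `pipeline_config.yaml`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the truth ledger: a list with data.frames `loops`
#'   (per-cell planted categories and CTCF anchor classes), `peaks`
#'   (origin and cell-type membership), `genes` (compartment label,
#'   coding/boundary/crystallin flags, planted log2 expression) plus
#'   `chrom_sizes` and the file manifest.
#' @export
generate_universe <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  cells <- cfg$cells
  chroms <- names(cfg$chrom_sizes)
  reg <- .new_registry()

  # -- TADs per cell --
  tads_by_cell <- lapply(cells, function(cell) {
    by_chrom <- lapply(chroms, function(ch) {
      td <- .sim_tads_chrom(cfg$chrom_sizes[[ch]], cfg)
      td$gaps <- .gaps_of(td$top, cfg$chrom_sizes[[ch]])
      td
    })
    names(by_chrom) <- chroms
    by_chrom
  })
  names(tads_by_cell) <- cells

  # -- loops per cell (placed against that cell's TADs) --
  loops_truth <- list()
  for (cell in cells) {
    lp <- .plant_loops_cell(tads_by_cell[[cell]], cfg, reg)
    lp$cell <- cell
    loops_truth[[cell]] <- lp
  }

  # -- CTCF peaks: anchor peaks (shared) + background with planted sharing --
  peak_rows <- list()
  add_peak <- function(chrom, center, origin, membership) {
    peak_rows[[length(peak_rows) + 1L]] <<- data.frame(
      chrom = chrom, center = center, origin = origin,
      membership = membership, stringsAsFactors = FALSE)
  }
  for (cell in cells) {
    lp <- loops_truth[[cell]]
    ctcf_class <- integer(nrow(lp))
    for (i in seq_len(nrow(lp))) {
      for (m in c(lp$m1[i], lp$m2[i])) {
        if (stats::runif(1) < cfg$ctcf_at_anchor_prob &&
            .place_peak_center(reg, lp$chrom[i], m)) {
          add_peak(lp$chrom[i], m, "anchor", "shared")
          ctcf_class[i] <- ctcf_class[i] + 1L
        }
      }
    }
    loops_truth[[cell]]$ctcf_class <- ctcf_class
  }
  for (membership in c("epi_only", "fib_only", "shared")) {
    n <- cfg$peak_sharing[[membership]]
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(400)) {
        ch <- sample(chroms, 1, prob = cfg$chrom_sizes)
        pos <- .sample_in(1e4, cfg$chrom_sizes[[ch]] - 1e4)
        # keep background peaks clear of every planted anchor bin
        if (!is.null(pos) &&
            .reg_ok(reg, paste0("a_", ch), pos, cfg$anchor_width / 2 + 2e3) &&
            .place_peak_center(reg, ch, pos)) {
          add_peak(ch, pos, "background", membership)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("cannot place background peak: genome too crowded")
    }
  }
  peaks <- as.data.frame(data.table::rbindlist(peak_rows))
  peaks$peak_id <- sprintf("P%05d", seq_len(nrow(peaks)))

  # -- compartments: alternating-sign blocks, 10-kb eigenvector bins --
  bs <- cfg$compartment_block_size
  comp_bins <- lapply(cells, function(cell) {
    dt <- data.table::rbindlist(lapply(chroms, function(ch) {
      L <- cfg$chrom_sizes[[ch]]
      start <- seq(0, L - 1e4, by = 1e4)
      block <- floor(start / bs)
      sign <- ifelse(block %% 2 == 0, 1, -1)
      data.table::data.table(
        chrom = ch, start = start, end = start + 1e4,
        value = sign * cfg$pc_magnitude * stats::runif(length(start), 0.7, 1.3))
    }))
    as.data.frame(dt)
  })
  names(comp_bins) <- cells
  block_sign <- function(chrom, pos) ifelse(floor(pos / bs) %% 2 == 0, "A", "B")

  # -- genes in 80-kb slots wholly inside compartment blocks --
  slot_pitch <- 8e4
  slots <- data.table::rbindlist(lapply(chroms, function(ch) {
    L <- cfg$chrom_sizes[[ch]]
    nblock <- floor(L / bs)
    data.table::rbindlist(lapply(seq_len(nblock) - 1, function(b) {
      k <- seq_len(floor(bs / slot_pitch)) - 1
      st <- b * bs + k * slot_pitch
      data.table::data.table(chrom = ch, slot_start = st,
                             label = if (b %% 2 == 0) "A" else "B",
                             first_in_block = k == 0)
    }))
  }))
  if (cfg$boundary_genes > 0) slots <- slots[!(first_in_block)]
  nA <- ceiling(cfg$n_genes / 2); nB <- cfg$n_genes - nA
  sA <- slots[label == "A"]; sB <- slots[label == "B"]
  if (nrow(sA) < nA || nrow(sB) < nB)
    stop("n_genes too large for the genome's compartment blocks")
  picked <- rbind(sA[sample.int(nrow(sA), nA)], sB[sample.int(nrow(sB), nB)])
  picked <- picked[sample.int(nrow(picked))]           # shuffle order

  gene_rows <- list(); tx_rows <- list()
  mk_tx <- function(gene_id, iso, chrom, strand, g0, len, coding) {
    e1 <- c(0, round(0.4 * len), round(0.8 * len))
    e2 <- c(round(0.2 * len), round(0.6 * len), len)
    tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = g0, end = g0 + len,
      name = sprintf("%s.%d", gene_id, iso), score = 0, strand = strand,
      thick_start = if (coding) g0 + round(0.1 * len) else g0,
      thick_end = if (coding) g0 + round(0.9 * len) else g0,
      rgb = 0, block_count = 3,
      block_sizes = paste(e2 - e1, collapse = ","),
      block_starts = paste(e1, collapse = ","), stringsAsFactors = FALSE)
  }
  n_total <- nrow(picked)
  coding <- stats::runif(n_total) >= cfg$noncoding_frac
  crystallin <- rep(FALSE, n_total)
  cand <- which(coding & picked$label == "A")
  if (length(cand) < cfg$n_crystallin)
    stop("not enough coding compartment-A genes for n_crystallin")
  crystallin[sample(cand, cfg$n_crystallin)] <- TRUE
  for (i in seq_len(n_total)) {
    gid <- sprintf("G%04d", i)
    ch <- picked$chrom[i]
    strand <- sample(c("+", "-"), 1)
    len <- round(stats::runif(1, 5e3, 6e4))
    g0 <- picked$slot_start[i] + 3e3
    mk_tx(gid, 1, ch, strand, g0, len, coding[i])
    n_iso <- 1L
    if (stats::runif(1) < 0.3) {
      mk_tx(gid, 2, ch, strand, g0, round(len * 0.6), coding[i])
      n_iso <- 2L
    }
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = gid, chrom = ch, start = g0, end = g0 + len, strand = strand,
      label = picked$label[i], boundary = FALSE, coding = coding[i],
      crystallin = crystallin[i], n_isoforms = n_iso, stringsAsFactors = FALSE)
  }
  # optional boundary-straddling genes: promoter crosses a block edge
  if (cfg$boundary_genes > 0) {
    nblock1 <- floor(cfg$chrom_sizes[[1]] / bs)
    if (cfg$boundary_genes > nblock1 - 1)
      stop("boundary_genes exceeds the number of block boundaries on ",
           chroms[1])
    bpos <- sample(seq_len(nblock1 - 1), cfg$boundary_genes) * bs
    for (j in seq_len(cfg$boundary_genes)) {
      gid <- sprintf("G%04d", n_total + j)
      ch <- chroms[1]
      tss <- bpos[j] + 500                 # promoter [tss-2000, tss+500)
      len <- round(stats::runif(1, 5e3, 3e4))
      mk_tx(gid, 1, ch, "+", tss, len, TRUE)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gid, chrom = ch, start = tss, end = tss + len, strand = "+",
        label = block_sign(ch, tss), boundary = TRUE, coding = TRUE,
        crystallin = FALSE, n_isoforms = 1L, stringsAsFactors = FALSE)
    }
  }
  genes_truth <- as.data.frame(data.table::rbindlist(gene_rows))
  tx <- as.data.frame(data.table::rbindlist(tx_rows))

  # -- expression: log-normal per compartment, crystallins on top --
  mu <- ifelse(genes_truth$label == "A", cfg$expr_log2_mean_A,
               cfg$expr_log2_mean_B)
  x_epi <- stats::rnorm(nrow(genes_truth), mu, cfg$expr_log2_sd)
  x_fib <- stats::rnorm(nrow(genes_truth), mu, cfg$expr_log2_sd)
  x_fib[genes_truth$crystallin] <-
    cfg$expr_log2_mean_A + 4 + stats::runif(sum(genes_truth$crystallin), 0, 1)
  genes_truth$expr_log2_epi <- x_epi
  genes_truth$expr_log2_fib <- x_fib
  expr <- data.frame(gene_id = genes_truth$gene_id,
                     epi = round(2^x_epi, 4), fib = round(2^x_fib, 4),
                     stringsAsFactors = FALSE)

  # -- methylation: linear dips at each cell's peak centers, 50-bp CpGs --
  meth_track <- function(cell_peaks) {
    dt <- data.table::rbindlist(lapply(seq_len(nrow(cell_peaks)), function(i) {
      pos <- seq(cell_peaks$center[i] - cfg$meth_window,
                 cell_peaks$center[i] + cfg$meth_window, by = 50)
      pos <- pos[pos >= 0]
      d <- abs(pos - cell_peaks$center[i])
      data.table::data.table(
        chrom = cell_peaks$chrom[i], start = pos,
        value = cfg$meth_baseline -
          cfg$meth_dip_depth * pmax(0, 1 - d / cfg$meth_dip_halfwidth))
    }))
    dt <- dt[, .(value = min(value)), by = .(chrom, start)]
    data.table::setorder(dt, chrom, start)
    df <- as.data.frame(dt)
    df$end <- df$start + 1
    df$value <- round(pmin(pmax(df$value, 0), 1), 4)
    df[, c("chrom", "start", "end", "value")]
  }

  # -- gene-body coverage proportional to fiber expression --
  cov_track <- function(scale) {
    df <- data.frame(chrom = genes_truth$chrom, start = genes_truth$start,
                     end = genes_truth$end,
                     value = round(scale * 2^genes_truth$expr_log2_fib, 4),
                     stringsAsFactors = FALSE)
    df[order(df$chrom, df$start, method = "radix"), ]
  }

  # ---- emit files ----
  fp <- function(...) file.path(outdir, sprintf(...))
  files <- list()
  for (cell in cells) {
    td <- tads_by_cell[[cell]]
    tad_df <- data.table::rbindlist(lapply(chroms, function(ch) {
      b <- rbind(td[[ch]]$top, td[[ch]]$child)
      if (nrow(b) == 0L) return(NULL)
      data.table::data.table(chrom = ch, start = b$start, end = b$end)
    }))
    tad_df <- as.data.frame(tad_df)[order(tad_df$chrom, tad_df$start), ]
    tad_df$name <- sprintf("TAD_%s_%04d", cell, seq_len(nrow(tad_df)))
    files[[paste0("tads_", cell)]] <- fp("tads_%s.bed", cell)
    write_bed(tad_df, files[[paste0("tads_", cell)]])

    lp <- loops_truth[[cell]]
    w <- cfg$anchor_width / 2
    loop_df <- data.frame(chrom = lp$chrom,
                          start1 = lp$m1 - w, end1 = lp$m1 + w,
                          start2 = lp$m2 - w, end2 = lp$m2 + w,
                          loop_id = sprintf("L%05d", seq_len(nrow(lp))))
    loops_truth[[cell]]$loop_id <- loop_df$loop_id
    files[[paste0("loops_", cell)]] <- fp("loops_%s.bedpe", cell)
    write_bedpe(loop_df, files[[paste0("loops_", cell)]])

    memb_keep <- c("shared", paste0(cell, "_only"))
    cp <- peaks[peaks$membership %in% memb_keep, , drop = FALSE]
    cp <- cp[order(cp$chrom, cp$center), ]
    pk <- data.frame(chrom = cp$chrom, start = cp$center - cfg$peak_width / 2,
                     end = cp$center + cfg$peak_width / 2, name = cp$peak_id,
                     score = 500, strand = ".",
                     signal = round(stats::runif(nrow(cp), 5, 15), 2),
                     pvalue = -1, qvalue = -1, summit = cfg$peak_width / 2)
    files[[paste0("ctcf_", cell)]] <- fp("ctcf_%s.narrowPeak", cell)
    write_narrowpeak(pk, files[[paste0("ctcf_", cell)]])

    files[[paste0("pc1_", cell)]] <- fp("pc1_%s.bedgraph", cell)
    cb <- comp_bins[[cell]]
    cb$value <- round(cb$value, 4)
    write_bedgraph(cb, files[[paste0("pc1_", cell)]])

    files[[paste0("meth_", cell)]] <- fp("meth_%s.bedgraph", cell)
    write_bedgraph(meth_track(cp), files[[paste0("meth_", cell)]])

    files[[paste0("ctcf_cov_", cell)]] <- fp("ctcf_cov_%s.bedgraph", cell)
    write_bedgraph(cov_track(if (cell == cells[1]) 0.045 else 0.05),
                   files[[paste0("ctcf_cov_", cell)]])
  }
  files$polII <- fp("polII.bedgraph")
  write_bedgraph(cov_track(0.1), files$polII)

  tx <- tx[order(tx$chrom, tx$start, tx$name), ]
  files$genes <- fp("genes.bed12")
  .fwrite_plain(data.table::as.data.table(tx), files$genes)

  files$expression <- fp("expression.tsv")
  data.table::fwrite(expr, files$expression, sep = "\t", scipen = 50)

  files$chrom_sizes <- fp("chrom_sizes.tsv")
  data.table::fwrite(data.frame(chrom = chroms,
                                size = unname(cfg$chrom_sizes)),
                     files$chrom_sizes, sep = "\t", col.names = FALSE,
                     scipen = 50)

  truth <- list(
    chrom_sizes = as.list(cfg$chrom_sizes),
    loops = as.data.frame(data.table::rbindlist(loops_truth)),
    peaks = peaks,
    genes = genes_truth,
    loop_category_counts = lapply(loops_truth, function(lp)
      as.list(table(factor(lp$category, levels = LOOP_TAD_LEVELS)))),
    peak_sharing_counts = as.list(table(peaks$membership)),
    files = files)
  jsonlite::write_json(truth[setdiff(names(truth), "files")],
                       fp("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  cfg_plain <- unclass(cfg)
  cfg_plain$chrom_sizes <- as.list(cfg$chrom_sizes)
  cfg_plain$n_loops <- as.list(cfg$n_loops)
  cfg_plain$peak_sharing <- as.list(cfg$peak_sharing)
  yaml::write_yaml(cfg_plain, fp("config.yaml"))
  .write_pipeline_config(cfg, files, outdir)
  invisible(truth)
}

# a ready-to-run pipeline configuration pointing at the emitted files
.write_pipeline_config <- function(cfg, files, outdir) {
  pc <- list(
    outdir = file.path(outdir, "results"),
    seed = cfg$seed,
    genes = files$genes,
    gene_format = "bed12",
    expression = files$expression,
    cells = stats::setNames(lapply(cfg$cells, function(cell) list(
      loops = files[[paste0("loops_", cell)]],
      tads = files[[paste0("tads_", cell)]],
      ctcf = files[[paste0("ctcf_", cell)]],
      pc1 = files[[paste0("pc1_", cell)]],
      meth = files[[paste0("meth_", cell)]])), cfg$cells),
    tracks = c(list(polII = files$polII),
               stats::setNames(
                 lapply(cfg$cells, function(cell)
                   files[[paste0("ctcf_cov_", cell)]]),
                 paste0("ctcf_cov_", cfg$cells))))
  yaml::write_yaml(pc, file.path(outdir, "pipeline_config.yaml"))
  invisible(pc)
}
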