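# Small programmatic fixtures and independent oracles shared across tests.

tmpfile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# brute-force quadratic overlap oracle (the reference for find_overlaps)
brute_overlaps <- function(query, subject) {
  rows <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] != subject$chrom[j]) next
    ov <- min(query$end[i], subject$end[j]) - max(query$start[i], subject$start[j])
    if (ov > 0) rows[[length(rows) + 1L]] <- c(i, j, ov)
  }
  if (!length(rows))
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  m <- do.call(rbind, rows)
  data.frame(query = m[, 1], subject = m[, 2], overlap_bp = m[, 3])
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(200, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# exhaustive hypergeometric upper-tail oracle via binomial coefficients
hyper_tail_exhaustive <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# per-element brute-force Venn classifier for three gene sets
brute_venn_sets <- function(a, b, c) {
  u <- unique(c(a, b, c))
  key <- paste0(as.integer(u %in% a), as.integer(u %in% b),
                as.integer(u %in% c))
  vapply(c("100", "010", "001", "110", "101", "011", "111"),
         function(r) sum(key == r), integer(1))
}

# per-basepair brute force for three-way interval sharing: enumerates the
# merged union and labels every event by covering sets, base by base
brute_venn_intervals <- function(setA, setB, setC, max_pos = 2000) {
  covered <- function(s, pos) {
    any(s$start <= pos & pos < s$end)
  }
  sets <- list(setA, setB, setC)
  counts <- setNames(integer(7),
                     c("100", "010", "001", "110", "101", "011", "111"))
  for (ch in unique(c(setA$chrom, setB$chrom, setC$chrom))) {
    sub <- lapply(sets, function(s) s[s$chrom == ch, , drop = FALSE])
    anycov <- rep(FALSE, max_pos)
    for (s in sub) for (i in seq_len(nrow(s)))
      anycov[(s$start[i] + 1):s$end[i]] <- TRUE
    # walk merged events left to right
    pos <- 1
    while (pos <= max_pos) {
      if (!anycov[pos]) { pos <- pos + 1; next }
      ev_end <- pos
      while (ev_end < max_pos && anycov[ev_end + 1]) ev_end <- ev_end + 1
      inset <- vapply(sub, function(s)
        any(s$end > pos - 1 & s$start < ev_end), logical(1))
      key <- paste0(as.integer(inset), collapse = "")
      counts[key] <- counts[key] + 1L
      pos <- ev_end + 1
    }
  }
  counts
}

# minimal single-transcript gene-model row
mkgene <- function(gene_id, tx_id, chrom, strand, start, end,
                   coding = TRUE) {
  g <- data.frame(gene_id = gene_id, tx_id = tx_id, chrom = chrom,
                  strand = strand, start = start, end = end,
                  cds_start = start, cds_end = if (coding) end else start,
                  coding = coding, stringsAsFactors = FALSE)
  g$exon_start <- list(start)
  g$exon_end <- list(end)
  g$tss <- ifelse(strand == "-", end, start)
  g
}

# one generated universe shared by the recovery tests (built once per run)
shared_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "loopscape_uni")
      cache <<- list(truth = generate_universe(sim_config(seed = 11), dir),
                     dir = dir)
    }
    cache
  }
})
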