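# Four-way loop-TAD arrangement classification and size statistics.
#
# Containment is decided by the anchor MIDPOINT: an anchor sits in a TAD
# iff its midpoint falls in [tad.start, tad.end).  Anchors are fixed-width
# bins that can straddle TAD boundaries; the midpoint rule yields an
# unambiguous partition.  With nested TADs an existence quantifier is
# used: a loop lying inside both a child TAD and its parent is INTRA.

LOOP_TAD_LEVELS <- c("INTRA", "INTER", "ONE_ANCHOR", "NOT_IN_TAD")

#' Classify loops by their arrangement relative to TADs
#'
#' Each loop receives exactly one of four labels, so the labels partition
#' any loop set:
#' * `INTRA` — some single TAD contains both anchor midpoints;
#' * `INTER` — each midpoint is inside at least one TAD but no TAD
#'   contains both (the loop connects two separate TADs);
#' * `ONE_ANCHOR` — exactly one midpoint is inside a TAD;
#' * `NOT_IN_TAD` — neither midpoint is inside any TAD.
#'
#' @param loops Loop table ([read_loops()]).
#' @param tads Interval data.frame of TAD calls; may be nested or
#'   overlapping, duplicates are harmless.
#' @param containment `"midpoint"` (default): an anchor is in a TAD iff
#'   its midpoint falls in `[tad.start, tad.end)`; `"overlap"`: iff the
#'   anchor interval overlaps the TAD by >= 1 bp.  The midpoint rule keeps
#'   boundary-straddling anchors unambiguous.
#' @return Factor of length `nrow(loops)` with levels
#'   `INTRA, INTER, ONE_ANCHOR, NOT_IN_TAD`.
#' @export
classify_loops <- function(loops, tads,
                           containment = c("midpoint", "overlap")) {
  containment <- match.arg(containment)
  n <- nrow(loops)
  out <- factor(rep("NOT_IN_TAD", n), levels = LOOP_TAD_LEVELS)
  if (n == 0L) return(out)
  if (containment == "midpoint") {
    s1 <- floor(interval_midpoint(loops$start1, loops$end1))
    e1 <- s1 + 1
    s2 <- floor(interval_midpoint(loops$start2, loops$end2))
    e2 <- s2 + 1
  } else {
    s1 <- loops$start1; e1 <- loops$end1
    s2 <- loops$start2; e2 <- loops$end2
  }
  if (nrow(tads) == 0L) return(out)
  h1 <- .fo(loops$chrom, s1, e1, tads$chrom, tads$start, tads$end)
  h2 <- .fo(loops$chrom, s2, e2, tads$chrom, tads$start, tads$end)
  in1 <- seq_len(n) %in% S4Vectors::queryHits(h1)
  in2 <- seq_len(n) %in% S4Vectors::queryHits(h2)
  key1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
  key2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
  common <- unique(S4Vectors::queryHits(h1)[key1 %in% key2])
  intra <- logical(n); intra[common] <- TRUE
  out[intra] <- "INTRA"
  out[!intra & in1 & in2] <- "INTER"
  out[xor(in1, in2)] <- "ONE_ANCHOR"
  out
}

#' Classify a single loop
#'
#' @param loop One-row loop table.
#' @param tads TAD interval table.
#' @inheritParams classify_loops
#' @return A single character label.
#' @export
classify_loop <- function(loop, tads, containment = "midpoint") {
  as.character(classify_loops(loop[1, , drop = FALSE], tads, containment))
}

#' Count loops per loop-TAD category
#'
#' @inheritParams classify_loops
#' @return Named integer vector over the four categories; sums to
#'   `nrow(loops)`.
#' @export
classify_all <- function(loops, tads) {
  table(classify_loops(loops, tads))
}

#' Architecture summary statistics
#'
#' Loop and TAD counts, mean/median loop size, median TAD size, census of
#' long-range loops (size strictly greater than `long_threshold`), and a
#' per-chromosome breakdown.
#'
#' @inheritParams classify_loops
#' @param long_threshold Long-loop size cutoff in bp (default 3 Mb);
#'   counting is strict (`size > long_threshold`).
#' @return List with scalar fields `n_loops`, `n_tads`, `mean_loop_size`,
#'   `median_loop_size`, `median_tad_size`, `n_long_loops`,
#'   `long_threshold` and a `per_chromosome` data.frame.
#' @export
summarize_architecture <- function(loops, tads, long_threshold = 3e6) {
  tad_size <- tads$end - tads$start
  chroms <- sort(unique(c(loops$chrom, tads$chrom)))
  per <- do.call(rbind, lapply(chroms, function(ch) {
    ls <- loops$size[loops$chrom == ch]
    ts <- tad_size[tads$chrom == ch]
    data.frame(chrom = ch, n_loops = length(ls), n_tads = length(ts),
               mean_loop_size = if (length(ls)) mean(ls) else NA_real_,
               median_loop_size = if (length(ls)) stats::median(ls) else NA_real_,
               median_tad_size = if (length(ts)) stats::median(ts) else NA_real_,
               n_long_loops = sum(ls > long_threshold),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    per <- data.frame(chrom = character(), n_loops = integer(),
                      n_tads = integer(), mean_loop_size = numeric(),
                      median_loop_size = numeric(), median_tad_size = numeric(),
                      n_long_loops = integer())
  list(n_loops = nrow(loops), n_tads = nrow(tads),
       mean_loop_size = if (nrow(loops)) mean(loops$size) else NA_real_,
       median_loop_size = if (nrow(loops)) stats::median(loops$size) else NA_real_,
       median_tad_size = if (nrow(tads)) stats::median(tad_size) else NA_real_,
       n_long_loops = sum(loops$size > long_threshold),
       long_threshold = long_threshold,
       per_chromosome = per)
}

#' Compare two size distributions
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) with normal approximation
#' and tie correction — the conventional test for loop/TAD size
#' distributions, which are heavy-tailed.
#'
#' @param a,b Numeric size vectors (bp), both non-empty.
#' @return List with `statistic` (U), `p_value`, `n_a`, `n_b`.
#' @export
compare_sizes <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both size samples must be non-empty")
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Per-chromosome size comparison with BH correction
#'
#' Runs [compare_sizes()] on every chromosome present in both tables and
#' adjusts the p-value family by Benjamini-Hochberg.
#'
#' @param a,b data.frames with columns `chrom` and `size`.
#' @return data.frame `chrom, n_a, n_b, statistic, p_value, padj`.
#' @export
compare_sizes_per_chrom <- function(a, b) {
  chroms <- sort(intersect(unique(a$chrom), unique(b$chrom)))
  rows <- lapply(chroms, function(ch) {
    r <- compare_sizes(a$size[a$chrom == ch], b$size[b$chrom == ch])
    data.frame(chrom = ch, n_a = r$n_a, n_b = r$n_b,
               statistic = r$statistic, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), n_a = integer(), n_b = integer(),
                      statistic = numeric(), p_value = numeric(),
                      padj = numeric()))
  out$padj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
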