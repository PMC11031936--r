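# CTCF peak sharing, CTCF-bound loop anchors, methylation meta-profiles
# around peak centers, and the expression x Pol II x CTCF gene-body
# cross-analysis.
#
# Sharing uses merged-interval event semantics: peaks of both sets are
# merged wherever they overlap by >= 1 bp (abutting peaks are NOT merged)
# and each merged interval counts once, labelled shared when covered by at
# least one peak from each set.  This is order-independent and well
# defined for many-to-many overlaps; when the two peak sets match
# one-to-one it reduces to the familiar union arithmetic
# shared / (n1 + n2 - shared).

.reduce_set <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(.gr(df$chrom, df$start, df$end),
                              min.gapwidth = 0L)
  grd <- as.data.frame(gr)
  data.frame(chrom = as.character(grd$seqnames),
             start = grd$start - 1,
             end = as.numeric(grd$end),
             stringsAsFactors = FALSE)
}

#' Build a sharing summary from event counts
#'
#' @param n_shared,n_specific1,n_specific2 Event counts.
#' @return List with the counts, `union` and `percent_shared`
#'   (`100 * shared / union`, rounded to 1 decimal).
#' @examples
#' # printed-count arithmetic: 16,424 and 23,859 peaks, 11,947 shared
#' sharing_result(11947, 16424 - 11947, 23859 - 11947)$percent_shared  # 42.2
#' @export
sharing_result <- function(n_shared, n_specific1, n_specific2) {
  union <- n_shared + n_specific1 + n_specific2
  list(n_shared = n_shared, n_specific1 = n_specific1,
       n_specific2 = n_specific2, union = union,
       percent_shared = if (union > 0) round(100 * n_shared / union, 1) else NA_real_)
}

#' Classify peak sharing between two cell types
#'
#' Peaks within each set are merged first (sets are expected
#' non-overlapping within themselves); the union of both sets is then
#' merged into events and each event labelled `shared`, `specific1` or
#' `specific2` by which sets cover it.
#'
#' @param set1,set2 Peak/interval data.frames.
#' @param min_overlap Minimum covered bp for a set to count as present in
#'   a merged event (default 1, i.e. any overlap).
#' @return List: `result` (a [sharing_result()]), `intervals` (merged
#'   events with a `label` column), `n_set1`, `n_set2` (input peak counts
#'   after within-set merging).
#' @export
classify_sharing <- function(set1, set2, min_overlap = 1) {
  stopifnot(min_overlap >= 1)
  s1 <- .reduce_set(set1)
  s2 <- .reduce_set(set2)
  events <- .reduce_set(rbind(s1, s2))
  if (nrow(events)) {
    covered_bp <- function(s) {
      hits <- find_overlaps(events, s)
      bp <- numeric(nrow(events))
      if (nrow(hits)) {
        agg <- tapply(hits$overlap_bp, hits$query, sum)
        bp[as.integer(names(agg))] <- agg
      }
      bp
    }
    c1 <- covered_bp(s1) >= min_overlap
    c2 <- covered_bp(s2) >= min_overlap
    events$label <- ifelse(c1 & c2, "shared",
                           ifelse(c1, "specific1",
                                  ifelse(c2, "specific2", "uncovered")))
  } else events$label <- character(0)
  res <- sharing_result(sum(events$label == "shared"),
                        sum(events$label == "specific1"),
                        sum(events$label == "specific2"))
  list(result = res, intervals = events,
       n_set1 = nrow(s1), n_set2 = nrow(s2))
}

#' Three-way peak sharing (Venn regions)
#'
#' Merged tri-set union events labelled by the combination of covering
#' sets; the seven region counts sum to the union event count.
#'
#' @param setA,setB,setC Peak/interval data.frames.
#' @param names Labels for the three sets.
#' @return Named integer vector with elements `A_only`, `B_only`,
#'   `C_only`, `AB`, `AC`, `BC`, `ABC` (names substituted from `names`).
#' @export
three_way_sharing <- function(setA, setB, setC, names = c("A", "B", "C")) {
  sets <- lapply(list(setA, setB, setC), .reduce_set)
  events <- .reduce_set(do.call(rbind, sets))
  cover <- if (nrow(events)) {
    vapply(sets, function(s)
      .oa(events$chrom, events$start, events$end,
          s$chrom, s$start, s$end), logical(nrow(events)))
  } else matrix(logical(0), 0, 3)
  cover <- matrix(cover, ncol = 3)
  .venn_counts(cover, names)
}

.venn_counts <- function(cover, names) {
  key <- paste0(cover[, 1] + 0, cover[, 2] + 0, cover[, 3] + 0)
  regions <- c("100", "010", "001", "110", "101", "011", "111")
  counts <- vapply(regions, function(r) sum(key == r), integer(1))
  names(counts) <- c(paste0(names[1], "_only"), paste0(names[2], "_only"),
                     paste0(names[3], "_only"),
                     paste(names[1], names[2], sep = "_"),
                     paste(names[1], names[3], sep = "_"),
                     paste(names[2], names[3], sep = "_"),
                     paste(names, collapse = "_"))
  counts
}

#' Count CTCF-bound anchors per loop
#'
#' An anchor is bound iff at least one peak overlaps the anchor interval
#' extended by `slack` bp on each side (half-open semantics: a peak
#' abutting the anchor end is unbound at `slack = 0`).
#'
#' @param loops Loop table.
#' @param peaks Peak/interval data.frame.
#' @param slack Non-negative extension in bp (default 0).
#' @return Integer vector in `{0, 1, 2}`, one value per loop.
#' @export
classify_loop_ctcf <- function(loops, peaks, slack = 0) {
  if (slack < 0) stop("slack must be >= 0")
  n <- nrow(loops)
  if (n == 0L) return(integer(0))
  if (nrow(peaks) == 0L) return(rep(0L, n))
  bound <- function(s, e) {
    .oa(loops$chrom, pmax(s - slack, 0), e + slack,
        peaks$chrom, peaks$start, peaks$end)
  }
  as.integer(bound(loops$start1, loops$end1)) +
    as.integer(bound(loops$start2, loops$end2))
}

#' Summarise CTCF-anchor classes over a loop set
#'
#' @param classes Integer vector from [classify_loop_ctcf()].
#' @return data.frame `class` (0/1/2), `n`, `percent` (1 dp; sums to 100).
#' @export
ctcf_class_summary <- function(classes) {
  n <- vapply(0:2, function(k) sum(classes == k), integer(1))
  data.frame(class = 0:2, n = n,
             percent = if (length(classes)) round(100 * n / length(classes), 1) else NA_real_)
}

#' Peak centers (summit if present, else midpoint)
#' @param peaks Peak table.
#' @return Numeric vector of absolute center positions.
#' @keywords internal
peak_centers <- function(peaks) {
  mid <- floor(interval_midpoint(peaks$start, peaks$end))
  if ("summit" %in% names(peaks))
    mid <- ifelse(is.na(peaks$summit), mid, peaks$start + peaks$summit)
  mid
}

#' Meta-profile of a signal track around peak centers
#'
#' Offset bins of width `bin` tile `[-flank, +flank)` relative to each
#' peak center (summit when available).  Within each peak x bin window the
#' track records overlapping the window are averaged weighted by overlap
#' length; the profile value of a bin is the unweighted mean of those
#' per-peak means across the peaks that have at least one covered record
#' there.  Bases with no record contribute nothing (they are not zeros).
#'
#' @param peaks Peak table.
#' @param track Signal track (validated bedGraph).
#' @param flank Half-window in bp (default 5000); must be divisible by
#'   `bin`.
#' @param bin Bin width in bp (default 100).
#' @return data.frame `offset` (bin start relative to center),
#'   `offset_mid`, `mean_value` (`NA` where nothing is covered),
#'   `n_contributing`.
#' @export
metaprofile <- function(peaks, track, flank = 5000, bin = 100) {
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  track <- validate_signal_track(track)
  centers <- peak_centers(peaks)
  offsets <- seq(-flank, flank - bin, by = bin)
  nb <- length(offsets)
  np <- nrow(peaks)
  win <- data.table::data.table(
    chrom = rep(peaks$chrom, each = nb),
    start = rep(centers, each = nb) + rep(offsets, np),
    peak = rep(seq_len(np), each = nb),
    off = rep(offsets, np))
  win[, end := start + bin]
  win <- win[start >= 0]
  prof <- data.frame(offset = offsets, offset_mid = offsets + bin / 2,
                     mean_value = NA_real_, n_contributing = 0L)
  if (nrow(win) == 0L || nrow(track) == 0L || np == 0L) return(prof)
  hits <- .fo(win$chrom, win$start, win$end,
              track$chrom, track$start, track$end)
  if (length(hits) == 0L) return(prof)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  dt <- data.table::data.table(
    off = win$off[qi], peak = win$peak[qi],
    w = pmin(win$end[qi], track$end[si]) - pmax(win$start[qi], track$start[si]),
    v = track$value[si])
  per_peak <- dt[, .(m = sum(w * v) / sum(w)), by = .(off, peak)]
  per_bin <- per_peak[, .(mean_value = mean(m), n_contributing = .N), by = off]
  idx <- match(per_bin$off, prof$offset)
  prof$mean_value[idx] <- per_bin$mean_value
  prof$n_contributing[idx] <- per_bin$n_contributing
  prof
}

#' Length-weighted mean track signal over intervals
#'
#' @param intervals Interval data.frame.
#' @param track Signal track.
#' @return Numeric vector, one weighted mean per interval (`NA` when no
#'   record overlaps; uncovered bases contribute nothing).
#' @export
mean_signal <- function(intervals, track) {
  out <- rep(NA_real_, nrow(intervals))
  if (nrow(intervals) == 0L || nrow(track) == 0L) return(out)
  hits <- .fo(intervals$chrom, intervals$start, intervals$end,
              track$chrom, track$start, track$end)
  if (length(hits) == 0L) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  dt <- data.table::data.table(
    q = qi,
    w = pmin(intervals$end[qi], track$end[si]) -
        pmax(intervals$start[qi], track$start[si]),
    v = track$value[si])
  agg <- dt[, .(m = sum(w * v) / sum(w)), by = q]
  out[agg$q] <- agg$m
  out
}

#' Expression x Pol II x CTCF gene-body cross-analysis
#'
#' Genes are ranked by expression (descending FPKM in `rank_column`, ties
#' by `gene_id`); the `top_n` are kept; for each the longest transcript is
#' chosen (`end - start`; ties by lexicographically smallest `tx_id`);
#' each supplied track is averaged over the transcript interval with
#' length weighting; non-coding genes are dropped when `coding_only`.
#'
#' @param expression Expression table ([read_expression()]).
#' @param genes Gene-model table.
#' @param tracks Named list of signal tracks; one `mean_<name>` output
#'   column per track.
#' @param rank_column Expression column used for ranking.
#' @param top_n Number of top-expressed genes to keep (default 100).
#' @param coding_only Drop non-coding genes after selection (default TRUE).
#' @return data.frame sorted by rank: `rank`, `gene_id`, `expression`,
#'   `tx_id`, `chrom`, `start`, `end`, `coding`, `mean_<track>` columns.
#'   Attribute `n_missing_model` counts top genes without a gene model.
#' @export
cross_analysis <- function(expression, genes, tracks, rank_column,
                           top_n = 100, coding_only = TRUE) {
  if (!rank_column %in% names(expression))
    stop("expression table has no column '", rank_column, "'")
  ord <- order(-expression[[rank_column]], expression$gene_id)
  top <- expression[ord, , drop = FALSE][seq_len(min(top_n, nrow(expression))), ]
  # longest transcript per gene (tie -> smallest tx_id)
  g <- genes[order(genes$gene_id, -(genes$end - genes$start), genes$tx_id), ]
  g <- g[!duplicated(g$gene_id), , drop = FALSE]
  hit <- match(top$gene_id, g$gene_id)
  n_missing <- sum(is.na(hit))
  if (n_missing > 0)
    warning(sprintf("%d top-ranked gene(s) lack a transcript model and were excluded",
                    n_missing))
  keep <- !is.na(hit)
  top <- top[keep, , drop = FALSE]; hit <- hit[keep]
  out <- data.frame(rank = which(keep), gene_id = top$gene_id,
                    expression = top[[rank_column]],
                    tx_id = g$tx_id[hit], chrom = g$chrom[hit],
                    start = g$start[hit], end = g$end[hit],
                    coding = g$coding[hit], stringsAsFactors = FALSE)
  for (nm in names(tracks))
    out[[paste0("mean_", nm)]] <- mean_signal(out, tracks[[nm]])
  if (coding_only) out <- out[out$coding, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_missing_model = n_missing)
}
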