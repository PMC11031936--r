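#' Construct a table of genomic intervals
#'
#' Intervals are the universal currency of the package: plain data.frames
#' with BED-style coordinates (0-based start, half-open `[start, end)`).
#' All readers and analysis functions produce and consume this layout.
#'
#' @param chrom Chromosome names (character, non-empty).
#' @param start 0-based inclusive start positions (bp).
#' @param end Exclusive end positions (bp); must satisfy `start < end`.
#' @param name Optional labels.
#' @param score Optional numeric scores.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (unstranded).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = as.character(name),
                   score = as.numeric(score),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate interval invariants
#'
#' Checks `start >= 0`, `start < end`, non-empty `chrom` and (if present)
#' a legal `strand` column.  Called by every reader; exported so user-built
#' tables can be checked too.
#'
#' @param df A data.frame with at least `chrom`, `start`, `end` columns.
#' @return `df`, invisibly.
#' @export
validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop("interval with empty chromosome name")
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval with missing coordinate")
  if (any(df$start < 0))
    stop("interval with negative start")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("interval with start >= end (first at row %d: [%s, %s))",
                 bad[1], format(df$start[bad[1]], scientific = FALSE),
                 format(df$end[bad[1]], scientific = FALSE)))
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Overlap length between intervals
#'
#' Vectorised over rows of `a` and `b` (recycled if one has a single row).
#' Half-open semantics: abutting intervals (`a$end == b$start`) overlap by
#' 0 bp.  Intervals on different chromosomes never overlap.
#'
#' @param a,b Interval data.frames (see [genomic_intervals()]).
#' @return Integer vector of overlap lengths in bp (>= 0).
#' @examples
#' overlap_length(genomic_intervals("chr1", 0, 100),
#'                genomic_intervals("chr1", 50, 150))  # 50
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  same <- a$chrom[idx_a] == b$chrom[idx_b]
  ov <- pmax(0, pmin(a$end[idx_a], b$end[idx_b]) -
                pmax(a$start[idx_a], b$start[idx_b]))
  as.integer(ov * same)
}

#' Find all overlapping query/subject interval pairs
#'
#' Returns exactly the pairs with `overlap_length > 0` that a brute-force
#' all-against-all scan would return, in deterministic order: query row
#' order first, then subject coordinate `(chrom, start, end, name)`.
#'
#' @param query,subject Interval data.frames.
#' @return data.frame with columns `query`, `subject` (row indices) and
#'   `overlap_bp`.
#' @export
find_overlaps <- function(query, subject) {
  empty <- data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer())
  if (nrow(query) == 0L || nrow(subject) == 0L) return(empty)
  hits <- .fo(query$chrom, query$start, query$end,
              subject$chrom, subject$start, subject$end)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0L) return(empty)
  nm <- if ("name" %in% names(subject)) as.character(subject$name[si])
        else character(length(si))
  ord <- order(qi, subject$chrom[si], subject$start[si], subject$end[si],
               nm, method = "radix")
  qi <- qi[ord]; si <- si[ord]
  data.frame(query = qi, subject = si,
             overlap_bp = as.integer(pmin(query$end[qi], subject$end[si]) -
                                     pmax(query$start[qi], subject$start[si])))
}

#' Midpoints of loop anchors
#'
#' The midpoint of the half-open interval `[start, end)` is
#' `(start + end) / 2`; loop size is the distance between the two anchor
#' midpoints.
#'
#' @param start,end Coordinate vectors.
#' @return Numeric midpoints.
#' @keywords internal
interval_midpoint <- function(start, end) (start + end) / 2

#' Aggregate per-sample Hi-C contact statistics
#'
#' Sums total contact counts across samples and reports the total in
#' millions and in billions (rounded to 2 decimals), mirroring how
#' sequencing-depth statistics are quoted.
#'
#' @param stats data.frame with columns `sample`, `total_contacts` and
#'   optionally `inter_chromosomal_fraction`.
#' @return List with `total`, `millions`, `billions` (2 dp) and
#'   `n_samples`.
#' @examples
#' s <- data.frame(sample = c("a", "b", "c"),
#'                 total_contacts = c(643.2e6, 588.0e6, 699.1e6))
#' aggregate_contact_stats(s)$billions  # 1.93
#' @export
aggregate_contact_stats <- function(stats) {
  if (!is.data.frame(stats) || nrow(stats) < 1L)
    stop("need at least one contact-statistics record")
  if (!all(c("sample", "total_contacts") %in% names(stats)))
    stop("stats must have columns 'sample' and 'total_contacts'")
  if (any(is.na(stats$total_contacts)) || any(stats$total_contacts < 0))
    stop("negative or missing contact count")
  total <- sum(stats$total_contacts)
  list(total = total,
       millions = round(total / 1e6, 1),
       billions = round(total / 1e9, 2),
       n_samples = nrow(stats))
}
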