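# Readers and writers for every plain-text format the pipeline touches.
# All coordinates leave the readers 0-based half-open; refFlat-style tables
# (already 0-based in UCSC dumps) and BED dialects therefore pass through
# unchanged.  Malformed coordinates are fatal with a line number; the one
# tolerated irregularity is an inter-chromosomal BEDPE record, which is
# skipped and counted (loop analyses are intra-chromosomal).

.numeric_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a chromatin-loop list (BEDPE dialect)
#'
#' Parses HiCCUPS-style loop lists: whitespace-delimited
#' `chr1 x1 x2 chr2 y1 y2 [extra columns...]`.  A header line (one whose
#' coordinate fields do not parse as numbers) is skipped silently, as are
#' `#` comment lines.  Anchors are reordered so that anchor 1 has the
#' smaller midpoint; inter-chromosomal records are skipped with a warning
#' and counted in the `n_skipped` attribute.
#'
#' @param path Path to the loop list.
#' @param dialect `"hiccups_bedpe"` or `"plain_bedpe"` (parsed identically;
#'   the dialect records provenance of extra columns).
#' @return data.frame with columns `chrom`, `start1`, `end1`, `start2`,
#'   `end2`, `loop_id`, `size` (midpoint distance, bp) and `extra`
#'   (tab-joined surplus columns, `NA` if none).  Attribute `n_skipped`
#'   counts rejected inter-chromosomal records.
#' @export
read_loops <- function(path, dialect = c("hiccups_bedpe", "plain_bedpe")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(structure(.empty_loops(), n_skipped = 0L))
  toks <- strsplit(trimws(lines), "[ \t]+")
  # header: first retained line whose coordinate fields are non-numeric
  first <- toks[[1]]
  if (length(first) >= 6 &&
      anyNA(.numeric_or_na(first[c(2, 3, 5, 6)]))) {
    toks <- toks[-1]; lineno <- lineno[-1]
  }
  if (length(toks) == 0L)
    return(structure(.empty_loops(), n_skipped = 0L))
  nfield <- lengths(toks)
  if (any(nfield < 6))
    stop(sprintf("malformed loop record at line %d: fewer than 6 fields",
                 lineno[which(nfield < 6)[1]]))
  m <- t(vapply(toks, function(t) t[1:6], character(6)))
  coords <- matrix(.numeric_or_na(m[, c(2, 3, 5, 6)]), ncol = 4)
  if (anyNA(coords))
    stop(sprintf("malformed coordinate at line %d",
                 lineno[which(rowSums(is.na(coords)) > 0)[1]]))
  extra <- vapply(toks, function(t)
    if (length(t) > 6) paste(t[-(1:6)], collapse = "\t") else NA_character_,
    character(1))
  inter <- m[, 1] != m[, 4]
  n_skipped <- sum(inter)
  if (n_skipped > 0)
    warning(sprintf("skipped %d inter-chromosomal loop record(s)", n_skipped))
  m <- m[!inter, , drop = FALSE]
  coords <- coords[!inter, , drop = FALSE]
  extra <- extra[!inter]
  if (nrow(m) == 0L)
    return(structure(.empty_loops(), n_skipped = n_skipped))
  df <- data.frame(chrom = m[, 1],
                   start1 = coords[, 1], end1 = coords[, 2],
                   start2 = coords[, 3], end2 = coords[, 4],
                   stringsAsFactors = FALSE)
  if (any(df$start1 >= df$end1) || any(df$start2 >= df$end2))
    stop("loop anchor with start >= end")
  mid1 <- interval_midpoint(df$start1, df$end1)
  mid2 <- interval_midpoint(df$start2, df$end2)
  swap <- mid1 > mid2
  if (any(swap)) {
    tmp <- df[swap, c("start1", "end1")]
    df[swap, c("start1", "end1")] <- df[swap, c("start2", "end2")]
    df[swap, c("start2", "end2")] <- tmp
    t2 <- mid1[swap]; mid1[swap] <- mid2[swap]; mid2[swap] <- t2
  }
  if (any(mid1 == mid2))
    stop("degenerate loop with identical anchor midpoints")
  df$loop_id <- sprintf("L%05d", seq_len(nrow(df)))
  df$size <- mid2 - mid1
  df$extra <- extra
  structure(df, n_skipped = n_skipped)
}

.empty_loops <- function() {
  data.frame(chrom = character(), start1 = numeric(), end1 = numeric(),
             start2 = numeric(), end2 = numeric(), loop_id = character(),
             size = numeric(), extra = character(), stringsAsFactors = FALSE)
}

#' Split a loop table into its anchor intervals
#'
#' @param loops Loop table from [read_loops()].
#' @return Interval data.frame with `2 * nrow(loops)` rows; column `loop`
#'   gives the source row, `anchor` is 1 or 2.
#' @export
loop_anchors <- function(loops) {
  data.frame(chrom = rep(loops$chrom, 2),
             start = c(loops$start1, loops$start2),
             end = c(loops$end1, loops$end2),
             loop = rep(seq_len(nrow(loops)), 2),
             anchor = rep(1:2, each = nrow(loops)),
             stringsAsFactors = FALSE)
}

#' Read genomic intervals, peaks or signal tracks
#'
#' One reader for the BED family.  `bed3`/`bed6`/`bed12` return interval
#' tables, `narrowPeak` returns a peak table with a `summit` column
#' (absolute-offset from `start`; ENCODE's `-1` sentinel becomes `NA`),
#' `bedGraph` returns a signal track sorted by `(chrom, start)` and
#' validated to be non-overlapping within each chromosome.
#'
#' @param path File path.
#' @param format One of `"bed3"`, `"bed6"`, `"bed12"`, `"narrowPeak"`,
#'   `"bedGraph"`.
#' @return data.frame; layout depends on `format` (see Details).
#' @export
read_intervals <- function(path, format = c("bed3", "bed6", "bed12",
                                            "narrowPeak", "bedGraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", dec = ".",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(switch(format,
      bedGraph = data.frame(chrom = character(), start = numeric(),
                            end = numeric(), value = numeric()),
      data.frame(chrom = character(), start = numeric(), end = numeric())))
  }
  need <- c(bed3 = 3L, bed6 = 6L, bed12 = 12L, narrowPeak = 10L, bedGraph = 4L)[format]
  if (ncol(dt) < need)
    stop(sprintf("%s requires %d columns, found %d", format, need, ncol(dt)))
  df <- data.frame(chrom = as.character(dt[[1]]),
                   start = as.numeric(dt[[2]]),
                   end = as.numeric(dt[[3]]),
                   stringsAsFactors = FALSE)
  if (format == "bedGraph") {
    df$value <- as.numeric(dt[[4]])
    validate_intervals(df)
    return(validate_signal_track(df[order(df$chrom, df$start, method = "radix"), ,
                                    drop = FALSE]))
  }
  if (format %in% c("bed6", "bed12", "narrowPeak")) {
    df$name <- as.character(dt[[4]])
    df$score <- as.numeric(dt[[5]])
    df$strand <- as.character(dt[[6]])
    df$strand[!df$strand %in% c("+", "-")] <- "."
  }
  if (format == "narrowPeak") {
    df$signal <- as.numeric(dt[[7]])
    df$pvalue <- as.numeric(dt[[8]])
    df$qvalue <- as.numeric(dt[[9]])
    summit <- as.numeric(dt[[10]])
    summit[summit < 0] <- NA_real_
    df$summit <- summit
    bad <- which(!is.na(df$summit) & df$summit >= (df$end - df$start))
    if (length(bad))
      stop(sprintf("narrowPeak summit offset outside peak at row %d", bad[1]))
  }
  if (format == "bed12") {
    df$thick_start <- as.numeric(dt[[7]])
    df$thick_end <- as.numeric(dt[[8]])
    df$block_count <- as.integer(dt[[10]])
    df$block_sizes <- as.character(dt[[11]])
    df$block_starts <- as.character(dt[[12]])
  }
  validate_intervals(df)
  rownames(df) <- NULL
  df
}

#' Validate a signal track
#'
#' A signal track is an interval table with a `value` column, sorted by
#' `(chrom, start)` with no overlapping records within a chromosome
#' (bedGraph contract).  Overlap is an error, not a warning: downstream
#' weighted means assume each base is covered at most once.
#'
#' @param track Signal-track data.frame.
#' @return `track` (sorted), invisibly usable.
#' @export
validate_signal_track <- function(track) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (nrow(track) < 2L) return(track)
  ord <- order(track$chrom, track$start, method = "radix")
  track <- track[ord, , drop = FALSE]
  same <- track$chrom[-1] == track$chrom[-nrow(track)]
  clash <- same & (track$start[-1] < track$end[-nrow(track)])
  if (any(clash))
    stop(sprintf("overlapping bedGraph records on %s near position %s",
                 track$chrom[which(clash)[1] + 1],
                 format(track$start[which(clash)[1] + 1], scientific = FALSE)))
  rownames(track) <- NULL
  track
}

#' Read gene models
#'
#' Two dialects: BED12 (one transcript per line; `gene_id` is derived by
#' stripping a trailing `.&lt;n&gt;` isoform suffix from the name field) and
#' refFlat (`geneName name chrom strand txStart txEnd cdsStart cdsEnd
#' exonCount exonStarts exonEnds`, UCSC 0-based half-open).  Coding status
#' is a non-empty CDS (`thickStart < thickEnd` / `cdsStart < cdsEnd`).
#'
#' @param path File path.
#' @param format `"bed12"` or `"refflat"`.
#' @return data.frame, one row per transcript: `gene_id`, `tx_id`, `chrom`,
#'   `strand`, `start`, `end`, `cds_start`, `cds_end`, `coding`, `tss`
#'   (strand-aware), and list-columns `exon_start`, `exon_end`.
#' @export
read_genes <- function(path, format = c("bed12", "refflat")) {
  format <- match.arg(format)
  if (format == "bed12") {
    df <- read_intervals(path, "bed12")
    sizes <- lapply(strsplit(df$block_sizes, ","), as.numeric)
    offs <- lapply(strsplit(df$block_starts, ","), as.numeric)
    genes <- data.frame(gene_id = sub("\\.[0-9]+$", "", df$name),
                        tx_id = df$name, chrom = df$chrom,
                        strand = df$strand, start = df$start, end = df$end,
                        cds_start = df$thick_start, cds_end = df$thick_end,
                        stringsAsFactors = FALSE)
    genes$exon_start <- Map(function(s, o) s + o, df$start, offs)
    genes$exon_end <- Map(`+`, genes$exon_start, sizes)
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", dec = ".",
                            colClasses = list(character = c(1, 2, 3, 4)))
    if (ncol(dt) < 11) stop("refflat requires 11 columns")
    genes <- data.frame(gene_id = as.character(dt[[1]]),
                        tx_id = as.character(dt[[2]]),
                        chrom = as.character(dt[[3]]),
                        strand = as.character(dt[[4]]),
                        start = as.numeric(dt[[5]]), end = as.numeric(dt[[6]]),
                        cds_start = as.numeric(dt[[7]]),
                        cds_end = as.numeric(dt[[8]]),
                        stringsAsFactors = FALSE)
    genes$exon_start <- lapply(strsplit(as.character(dt[[10]]), ","), as.numeric)
    genes$exon_end <- lapply(strsplit(as.character(dt[[11]]), ","), as.numeric)
  }
  validate_intervals(genes)
  genes$coding <- genes$cds_start < genes$cds_end
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes$tss[genes$strand == "."] <- NA_real_
  genes
}

#' Read an expression table
#'
#' Tab-separated with a header: `gene_id` then one FPKM column per cell
#' type.
#'
#' @param path File path.
#' @return data.frame keyed by `gene_id`.
#' @export
read_expression <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  if (!"gene_id" %in% names(df)) stop("expression table needs a gene_id column")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table")
  df
}

#' Read a per-sample contact-statistics table
#'
#' Tab-separated with header `sample  total_contacts
#' inter_chromosomal_fraction`.
#'
#' @param path File path.
#' @return data.frame ready for [aggregate_contact_stats()].
#' @export
read_contact_stats <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("sample", "total_contacts", "inter_chromosomal_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("contact-stats table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$inter_chromosomal_fraction < 0 | df$inter_chromosomal_fraction > 1,
          na.rm = TRUE))
    stop("inter_chromosomal_fraction outside [0, 1]")
  df
}

#' Read a GMT gene-set file
#'
#' One term per line: `term_id <TAB> description <TAB> gene1 <TAB> gene2...`.
#'
#' @param path File path.
#' @return Named list of character vectors (term -> member genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(toks) < 3)) stop("GMT line with fewer than 3 fields")
  stats::setNames(lapply(toks, function(t) unique(t[-(1:2)])),
                  vapply(toks, `[`, character(1), 1))
}

#' Read a differential-compartment table
#'
#' Consumes (does not recompute) a dcHiC-style differential table: TSV with
#' header containing at least `chrom`, `start`, `end`, `padj` plus any
#' per-cell-type eigenvector columns, which are passed through.
#'
#' @param path File path.
#' @return data.frame with the required columns validated.
#' @export
read_differential_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  miss <- setdiff(c("chrom", "start", "end", "padj"), names(df))
  if (length(miss)) stop("differential table missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_intervals(df)
  df
}

#' Keep significant differential bins
#'
#' @param bins Table from [read_differential_table()].
#' @param alpha Adjusted-significance cutoff; bins with `padj < alpha` are
#'   retained.
#' @return The retained subset with attribute `n_significant`.
#' @export
filter_significant <- function(bins, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  keep <- bins[!is.na(bins$padj) & bins$padj < alpha, , drop = FALSE]
  rownames(keep) <- NULL
  structure(keep, n_significant = nrow(keep))
}

# ---- writers (round-trip bit-exact on coordinates) ----

.fwrite_plain <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     scipen = 50, quote = FALSE, na = ".")
}

#' Write intervals as BED
#'
#' Emits BED3 or BED6 depending on which columns are present.
#'
#' @param df Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  if (!all(c("chrom", "start", "end") %in% cols)) stop("not an interval table")
  .fwrite_plain(data.table::as.data.table(df[, cols, drop = FALSE]), path)
  invisible(path)
}

#' Write a loop table as BEDPE
#' @param loops Loop table from [read_loops()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  dt <- data.table::data.table(loops$chrom, loops$start1, loops$end1,
                               loops$chrom, loops$start2, loops$end2)
  if ("loop_id" %in% names(loops)) dt[, V7 := loops$loop_id]
  .fwrite_plain(dt, path)
  invisible(path)
}

#' Write a peak table as ENCODE narrowPeak
#' @param peaks Peak table (as from `read_intervals(format = "narrowPeak")`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  summit <- if ("summit" %in% names(peaks)) peaks$summit else NA_real_
  summit <- ifelse(is.na(summit), -1, summit)
  dt <- data.table::data.table(
    peaks$chrom, peaks$start, peaks$end,
    if ("name" %in% names(peaks)) peaks$name else ".",
    if ("score" %in% names(peaks)) peaks$score else 0,
    if ("strand" %in% names(peaks)) peaks$strand else ".",
    if ("signal" %in% names(peaks)) peaks$signal else 0,
    if ("pvalue" %in% names(peaks)) peaks$pvalue else -1,
    if ("qvalue" %in% names(peaks)) peaks$qvalue else -1,
    summit)
  .fwrite_plain(dt, path)
  invisible(path)
}

#' Write a signal track as bedGraph
#' @param track Signal-track data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  .fwrite_plain(data.table::as.data.table(
    track[, c("chrom", "start", "end", "value")]), path)
  invisible(path)
}
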