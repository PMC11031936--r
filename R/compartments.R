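# A/B compartment labelling and gene assignment.
#
# The compartment label is the SIGN of the eigenvector value, exactly:
# positive -> A (active), negative -> B (inactive), zero -> unassigned
# (the sign rule is undefined at 0 and such bins are excluded from
# medians).  Genes are tied to compartments through their promoter:
# the promoter window is intersected with the eigenvector bins and the
# bin with the largest overlap supplies the label.

#' Label eigenvector bins as compartment A or B
#'
#' @param track Signal track of eigenvector (PC) values per bin, as read
#'   by `read_intervals(format = "bedGraph")`.
#' @return The track with `pc_value` and `label` columns
#'   (`A` / `B` / `unassigned`).
#' @export
compartment_bins <- function(track) {
  track <- validate_signal_track(track)
  track$pc_value <- track$value
  track$label <- ifelse(track$pc_value > 0, "A",
                        ifelse(track$pc_value < 0, "B", "unassigned"))
  track
}

#' Strand-aware promoter windows
#'
#' For a + strand transcript the promoter is
#' `[TSS - upstream, TSS + downstream)`; for a - strand transcript
#' `[TSS - downstream, TSS + upstream)`.  Windows are clipped at 0 and,
#' when `chrom_sizes` is supplied, at the chromosome end.
#'
#' @param genes Gene-model table ([read_genes()]).
#' @param upstream,downstream Window extents in bp (defaults 2000/500).
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   right-clipping.
#' @return Interval data.frame with `gene_id`, `tx_id` carried through.
#' @export
promoter_regions <- function(genes, upstream = 2000, downstream = 500,
                             chrom_sizes = NULL) {
  if (any(genes$strand == "."))
    stop("unstranded gene model: TSS undefined, cannot build promoter")
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$tss - downstream, genes$tss - upstream)
  end <- ifelse(minus, genes$tss + upstream, genes$tss + downstream)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[genes$chrom]
    if (anyNA(lim)) stop("chromosome missing from chrom_sizes")
    end <- pmin(end, unname(lim))
  }
  data.frame(chrom = genes$chrom, start = start, end = end,
             gene_id = genes$gene_id, tx_id = genes$tx_id,
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Assign genes to compartments by the promoter largest-overlap rule
#'
#' Every transcript isoform is assigned separately: its promoter window is
#' intersected with the compartment bins and the maximal-overlap bin kept
#' (ties broken by lower bin start).  A per-gene consensus is then taken:
#' majority label across isoforms; on a tie, the label of the isoform with
#' the longest transcript (further ties by transcript id).
#'
#' @param genes Gene-model table.
#' @param bins Labelled bins from [compartment_bins()] (sorted,
#'   non-overlapping; overlap is an error).
#' @param upstream,downstream Promoter window (defaults 2000/500 bp).
#' @param chrom_sizes Optional chromosome lengths for clipping.
#' @return List with `isoforms` (per-transcript calls: `gene_id`, `tx_id`,
#'   `bin_start`, `bin_end`, `pc_value`, `label`, `overlap_bp`), `genes`
#'   (per-gene consensus: `gene_id`, `label`, `n_isoforms`) and
#'   `n_unassigned` (transcripts whose promoter touched no bin).
#' @export
assign_gene_compartment <- function(genes, bins, upstream = 2000,
                                    downstream = 500, chrom_sizes = NULL) {
  bins <- validate_signal_track(bins)          # errors on overlap
  if (!"label" %in% names(bins)) bins <- compartment_bins(bins)
  prom <- promoter_regions(genes, upstream, downstream, chrom_sizes)
  hits <- find_overlaps(prom, bins)
  iso <- data.frame(gene_id = character(), tx_id = character(),
                    bin_start = numeric(), bin_end = numeric(),
                    pc_value = numeric(), label = character(),
                    overlap_bp = integer(), stringsAsFactors = FALSE)
  n_unassigned <- nrow(prom)
  if (nrow(hits)) {
    dt <- data.table::data.table(q = hits$query, s = hits$subject,
                                 ov = hits$overlap_bp,
                                 bs = bins$start[hits$subject])
    # largest overlap; tie -> lower bin start (find_overlaps emits subject
    # hits in coordinate order so the first maximal hit is the winner)
    best <- dt[order(q, -ov, bs), .SD[1], by = q]
    iso <- data.frame(gene_id = prom$gene_id[best$q],
                      tx_id = prom$tx_id[best$q],
                      bin_start = bins$start[best$s],
                      bin_end = bins$end[best$s],
                      pc_value = bins$pc_value[best$s],
                      label = bins$label[best$s],
                      overlap_bp = best$ov, stringsAsFactors = FALSE)
    n_unassigned <- nrow(prom) - nrow(iso)
  }
  gene_calls <- .consensus_gene_label(iso, genes)
  list(isoforms = iso, genes = gene_calls, n_unassigned = n_unassigned)
}

# majority vote across isoform labels; ties -> label of the longest
# transcript, then lexicographically smallest tx_id
.consensus_gene_label <- function(iso, genes) {
  if (nrow(iso) == 0L)
    return(data.frame(gene_id = character(), label = character(),
                      n_isoforms = integer(), stringsAsFactors = FALSE))
  len <- stats::setNames(genes$end - genes$start, genes$tx_id)
  dt <- data.table::as.data.table(iso)
  dt[, tx_len := unname(len[tx_id])]
  out <- dt[, {
    tab <- sort(table(label), decreasing = TRUE)
    winners <- names(tab)[tab == tab[1]]
    lab <- if (length(winners) == 1L) winners[1] else {
      sub <- .SD[label %in% winners][order(-tx_len, tx_id)]
      sub$label[1]
    }
    list(label = lab, n_isoforms = .N)
  }, by = gene_id]
  as.data.frame(out[order(gene_id)])
}

#' Expression by compartment label
#'
#' FPKM values are transformed as `log2(FPKM + 1)` (the pseudocount keeps
#' unexpressed genes finite) and summarised per compartment label.  Genes
#' without an expression value are excluded and counted.
#'
#' @param gene_calls Per-gene consensus table from
#'   [assign_gene_compartment()]`$genes`.
#' @param expression Expression table ([read_expression()]).
#' @param column Name of the FPKM column to use.
#' @return List with `medians` (named vector over labels, `NA` for an empty
#'   class), `n` per label, `values` (data.frame `gene_id`, `label`,
#'   `log2_expr`) and `n_missing_expression`.
#' @export
expression_by_compartment <- function(gene_calls, expression, column) {
  if (!column %in% names(expression))
    stop("expression table has no column '", column, "'")
  fpkm <- stats::setNames(expression[[column]], expression$gene_id)
  matched <- gene_calls$gene_id %in% names(fpkm)
  vals <- data.frame(gene_id = gene_calls$gene_id[matched],
                     label = gene_calls$label[matched],
                     log2_expr = log2(fpkm[gene_calls$gene_id[matched]] + 1),
                     stringsAsFactors = FALSE, row.names = NULL)
  vals <- vals[vals$label %in% c("A", "B"), , drop = FALSE]
  labs <- c("A", "B")
  med <- vapply(labs, function(l) {
    v <- vals$log2_expr[vals$label == l]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
  n <- vapply(labs, function(l) sum(vals$label == l), integer(1))
  list(medians = med, n = n, values = vals,
       n_missing_expression = sum(!matched))
}
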