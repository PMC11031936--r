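# Loop-anchor genomic annotation, promoter-contact gene sets, three-way
# contact sharing, and hypergeometric over-representation analysis (ORA).

ANNOTATION_LEVELS <- c("promoter", "exon", "intron", "intergenic")

#' Annotate anchors as promoter / exon / intron / intergenic
#'
#' Fixed precedence promoter > exon > intron > intergenic (an anchor over
#' a TSS window is a promoter even when it also overlaps exon 1).  The
#' promoter window here defaults to 2 kb upstream / 100 bp downstream of
#' the TSS — the convention for contact annotation, narrower downstream
#' than the compartment-assignment window.  `gene_id` reports the first
#' matching gene in `(chrom, start)` order.
#'
#' @param anchors Interval data.frame.
#' @param genes Gene-model table with exon structure.
#' @param upstream,downstream Promoter window (defaults 2000/100 bp).
#' @return data.frame `annotation` (factor) and `gene_id` (`NA` for
#'   intergenic), one row per anchor.
#' @export
annotate_anchors <- function(anchors, genes, upstream = 2000, downstream = 100) {
  n <- nrow(anchors)
  out <- data.frame(annotation = factor(rep("intergenic", n),
                                        levels = ANNOTATION_LEVELS),
                    gene_id = rep(NA_character_, n), stringsAsFactors = FALSE)
  if (n == 0L || nrow(genes) == 0L) return(out)
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  rank_of <- integer(nrow(genes)); rank_of[ord] <- seq_len(nrow(genes))

  prom <- promoter_regions(genes, upstream, downstream)
  exons <- data.frame(chrom = rep(genes$chrom, lengths(genes$exon_start)),
                      start = unlist(genes$exon_start),
                      end = unlist(genes$exon_end),
                      gene = rep(seq_len(nrow(genes)), lengths(genes$exon_start)),
                      stringsAsFactors = FALSE)
  bodies <- data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, gene = seq_len(nrow(genes)),
                       stringsAsFactors = FALSE)
  assign_level <- function(feat, gene_idx, level) {
    hits <- find_overlaps(anchors, feat)
    if (nrow(hits) == 0L) return()
    dt <- data.table::data.table(a = hits$query, g = gene_idx[hits$subject])
    dt[, r := rank_of[g]]
    best <- dt[order(a, r), .SD[1], by = a]
    todo <- best$a[out$annotation[best$a] == "intergenic"]
    sel <- best[a %in% todo]
    out$annotation[sel$a] <<- level
    out$gene_id[sel$a] <<- genes$gene_id[sel$g]
  }
  # precedence enforced by assigning most-specific first and never
  # overwriting an already-labelled anchor
  assign_level(prom, seq_len(nrow(genes)), "promoter")
  assign_level(exons, exons$gene, "exon")
  assign_level(bodies, bodies$gene, "intron")
  out
}

#' Genes whose promoter is contacted by a loop anchor
#'
#' A gene is included iff any anchor of any loop overlaps its strand-aware
#' promoter window (half-open: an anchor ending exactly at the window
#' start is excluded).  Genes are deduplicated across loops, anchors and
#' isoforms.
#'
#' @param loops Loop table.
#' @param genes Gene-model table.
#' @param upstream,downstream Promoter window (defaults 2000/100 bp).
#' @return Sorted character vector of gene ids.
#' @export
promoter_contact_genes <- function(loops, genes, upstream = 2000,
                                   downstream = 100) {
  if (nrow(loops) == 0L || nrow(genes) == 0L) return(character(0))
  anchors <- loop_anchors(loops)
  prom <- promoter_regions(genes, upstream, downstream)
  hits <- find_overlaps(anchors, prom)
  sort(unique(prom$gene_id[hits$subject]))
}

#' Three-way sharing of gene sets (Venn regions)
#'
#' Exact set algebra on membership; region counts sum to the size of the
#' union.
#'
#' @param setA,setB,setC Character vectors (e.g. promoter-contact gene
#'   sets per cell type).
#' @param names Labels for the three sets.
#' @return Named integer vector, as [three_way_sharing()].
#' @export
contact_sharing <- function(setA, setB, setC, names = c("A", "B", "C")) {
  setA <- unique(setA); setB <- unique(setB); setC <- unique(setC)
  u <- unique(c(setA, setB, setC))
  cover <- cbind(u %in% setA, u %in% setB, u %in% setC)
  .venn_counts(matrix(cover, ncol = 3), names)
}

#' Hypergeometric over-representation analysis
#'
#' For each term with members `K` in a universe of size `N`, and a query
#' of size `n` overlapping the term in `k` genes, the upper-tail
#' probability `P(X >= k)` of the hypergeometric distribution is computed
#' and BH-adjusted across the tested terms.  Query genes outside the
#' universe are dropped with a warning; terms are intersected with the
#' universe, and terms empty after intersection are skipped.
#'
#' @param query Character vector of gene ids.
#' @param gmt Named list of term -> member genes ([read_gmt()]).
#' @param universe Background gene set (e.g. all genes in the gene-model
#'   file).
#' @return data.frame sorted by p ascending: `term_id`, `k`, `K`, `n`,
#'   `N`, `p`, `q`.
#' @export
enrich <- function(query, gmt, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gmt), function(term) {
    members <- intersect(unique(gmt[[term]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
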