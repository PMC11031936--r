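# Configuration-driven orchestration: validate a YAML config, run every
# stage whose inputs are present, write one TSV per stage output (each
# with a provenance comment line), and return a consolidated report.
# Stages themselves are deterministic; the single config seed governs the
# only stochastic component (the synthetic generator, when used upstream).

.known_top_keys <- c("outdir", "seed", "cells", "tracks", "genes",
                     "gene_format", "expression", "gmt", "differential",
                     "contact_stats", "params", "stages")
.known_params <- c("long_threshold", "promoter_upstream", "promoter_downstream",
                   "contact_upstream", "contact_downstream", "flank", "bin",
                   "top_n", "coding_only", "alpha", "slack", "rank_column")
.default_params <- list(long_threshold = 3e6, promoter_upstream = 2000,
                        promoter_downstream = 500, contact_upstream = 2000,
                        contact_downstream = 100, flank = 5000, bin = 100,
                        top_n = 100, coding_only = TRUE, alpha = 0.05,
                        slack = 0, rank_column = NULL)
.all_stages <- c("architecture", "compartments", "ctcf_sharing",
                 "ctcf_anchors", "metaprofile", "annotation", "contacts",
                 "enrichment", "cross_analysis", "contact_stats")

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML config, rejects unknown keys, checks that every referenced
#' file exists, fills parameter defaults and decides which stages can run
#' from the inputs present (an explicit `stages` list restricts further).
#'
#' @param path Path to a YAML configuration file.
#' @return A resolved config list of class `loopscape_config` with
#'   elements `cells`, `tracks`, `params`, `stages`, `outdir`, `seed`, ...
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .known_top_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  unknown_p <- setdiff(names(cfg$params), .known_params)
  if (length(unknown_p))
    stop("unknown params key(s): ", paste(unknown_p, collapse = ", "))
  params <- utils::modifyList(.default_params,
                              if (is.null(cfg$params)) list() else cfg$params)
  cfg$params <- params
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outdir)) cfg$outdir <- "loopscape_out"
  if (is.null(cfg$gene_format)) cfg$gene_format <- "bed12"

  paths <- c(unlist(cfg$cells), unlist(cfg$tracks), cfg$genes,
             cfg$expression, cfg$gmt, cfg$differential, cfg$contact_stats)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "))

  has <- function(field) {
    !is.null(cfg$cells) &&
      all(vapply(cfg$cells, function(c) !is.null(c[[field]]), logical(1)))
  }
  possible <- c(
    architecture = has("loops") && has("tads"),
    compartments = has("pc1") && !is.null(cfg$genes) && !is.null(cfg$expression),
    ctcf_sharing = has("ctcf") && length(cfg$cells) >= 2,
    ctcf_anchors = has("loops") && has("ctcf"),
    metaprofile = has("ctcf") && has("meth"),
    annotation = has("loops") && !is.null(cfg$genes),
    contacts = has("loops") && !is.null(cfg$genes),
    enrichment = has("loops") && !is.null(cfg$genes) && !is.null(cfg$gmt),
    cross_analysis = !is.null(cfg$tracks) && !is.null(cfg$genes) &&
      !is.null(cfg$expression),
    contact_stats = !is.null(cfg$contact_stats))
  enabled <- names(possible)[possible]
  if (!is.null(cfg$stages)) {
    bad <- setdiff(cfg$stages, .all_stages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    enabled <- intersect(cfg$stages, enabled)
  }
  cfg$stages <- enabled
  class(cfg) <- "loopscape_config"
  cfg
}

.provenance <- function(stage) {
  sprintf("# loopscape %s | stage=%s",
          as.character(utils::packageVersion("loopscape")), stage)
}

.write_stage_table <- function(df, path, stage) {
  con <- file(path, "w")
  writeLines(.provenance(stage), con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE,
                     scipen = 50)
  path
}

#' Run the pipeline
#'
#' Executes every enabled stage on the configured inputs, writes one TSV
#' per stage output into `outdir` (header plus a provenance comment line)
#' and returns a report.  A stage failure is caught: partial outputs are
#' retained and the report marks the stage failed; the function then
#' raises an error at the end so batch callers exit non-zero.
#'
#' @param config A `loopscape_config` from [validate_config()], or a path
#'   to a YAML config.
#' @return Invisibly, the report: per-stage summaries, warning census and
#'   run metadata.  Regenerating with identical config and inputs yields
#'   byte-identical tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "loopscape_config"))
  p <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), warnings = character(0),
                 meta = list(version = as.character(utils::packageVersion("loopscape")),
                             seed = config$seed, stages = config$stages))
  wcount <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  failed <- character(0)
  run_stage <- function(name, fn) {
    res <- tryCatch(withCallingHandlers(fn(), warning = wcount),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- c(failed, name)
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res)
    }
  }
  out <- function(...) file.path(config$outdir, sprintf(...))
  cells <- names(config$cells)

  loops <- lapply(config$cells, function(cc)
    if (!is.null(cc$loops)) read_loops(cc$loops) else NULL)
  tads <- lapply(config$cells, function(cc)
    if (!is.null(cc$tads)) read_intervals(cc$tads, "bed3") else NULL)
  peaks <- lapply(config$cells, function(cc)
    if (!is.null(cc$ctcf)) read_intervals(cc$ctcf, "narrowPeak") else NULL)
  genes <- if (!is.null(config$genes))
    read_genes(config$genes, config$gene_format) else NULL
  expr <- if (!is.null(config$expression))
    read_expression(config$expression) else NULL

  if ("architecture" %in% config$stages) run_stage("architecture", function() {
    rows <- list()
    for (cell in cells) {
      s <- summarize_architecture(loops[[cell]], tads[[cell]],
                                  p$long_threshold)
      cats <- classify_loops(loops[[cell]], tads[[cell]])
      .write_stage_table(
        data.frame(loop_id = loops[[cell]]$loop_id, category = cats),
        out("loop_categories_%s.tsv", cell), "architecture")
      .write_stage_table(s$per_chromosome,
                         out("architecture_per_chrom_%s.tsv", cell),
                         "architecture")
      cnt <- table(cats)
      rows[[cell]] <- data.frame(
        cell = cell, n_loops = s$n_loops, n_tads = s$n_tads,
        mean_loop_size = s$mean_loop_size,
        median_loop_size = s$median_loop_size,
        median_tad_size = s$median_tad_size, n_long_loops = s$n_long_loops,
        n_intra = cnt[["INTRA"]], n_inter = cnt[["INTER"]],
        n_one_anchor = cnt[["ONE_ANCHOR"]],
        n_not_in_tad = cnt[["NOT_IN_TAD"]])
    }
    summary <- do.call(rbind, rows)
    .write_stage_table(summary, out("architecture_summary.tsv"),
                       "architecture")
    if (length(cells) >= 2) {
      cmp <- compare_sizes(loops[[cells[1]]]$size, loops[[cells[2]]]$size)
      .write_stage_table(
        data.frame(comparison = paste(cells[1], "vs", cells[2]),
                   statistic = cmp$statistic, p_value = cmp$p_value),
        out("loop_size_comparison.tsv"), "architecture")
    }
    list(summary = summary)
  })

  if ("compartments" %in% config$stages) run_stage("compartments", function() {
    rows <- list()
    for (cell in cells) {
      bins <- compartment_bins(read_intervals(config$cells[[cell]]$pc1,
                                              "bedGraph"))
      calls <- assign_gene_compartment(genes, bins, p$promoter_upstream,
                                       p$promoter_downstream)
      .write_stage_table(calls$genes, out("compartment_genes_%s.tsv", cell),
                         "compartments")
      eb <- expression_by_compartment(calls$genes, expr,
                                      if (is.null(p$rank_column)) cell
                                      else p$rank_column)
      rows[[cell]] <- data.frame(cell = cell,
                                 median_A = eb$medians[["A"]],
                                 median_B = eb$medians[["B"]],
                                 n_A = eb$n[["A"]], n_B = eb$n[["B"]],
                                 n_missing_expression = eb$n_missing_expression)
    }
    summary <- do.call(rbind, rows)
    .write_stage_table(summary, out("compartment_summary.tsv"),
                       "compartments")
    list(summary = summary)
  })

  if ("ctcf_sharing" %in% config$stages) run_stage("ctcf_sharing", function() {
    sh <- classify_sharing(peaks[[cells[1]]], peaks[[cells[2]]])
    .write_stage_table(sh$intervals, out("ctcf_sharing_intervals.tsv"),
                       "ctcf_sharing")
    summary <- data.frame(set1 = cells[1], set2 = cells[2],
                          n_set1 = sh$n_set1, n_set2 = sh$n_set2,
                          n_shared = sh$result$n_shared,
                          n_specific1 = sh$result$n_specific1,
                          n_specific2 = sh$result$n_specific2,
                          union = sh$result$union,
                          percent_shared = sh$result$percent_shared)
    .write_stage_table(summary, out("ctcf_sharing.tsv"), "ctcf_sharing")
    list(summary = summary)
  })

  if ("ctcf_anchors" %in% config$stages) run_stage("ctcf_anchors", function() {
    rows <- list()
    for (cell in cells) {
      cls <- classify_loop_ctcf(loops[[cell]], peaks[[cell]], p$slack)
      .write_stage_table(
        data.frame(loop_id = loops[[cell]]$loop_id, ctcf_class = cls),
        out("ctcf_anchor_classes_%s.tsv", cell), "ctcf_anchors")
      s <- ctcf_class_summary(cls)
      s$cell <- cell
      rows[[cell]] <- s
    }
    summary <- do.call(rbind, rows)
    .write_stage_table(summary, out("ctcf_anchor_summary.tsv"),
                       "ctcf_anchors")
    list(summary = summary)
  })

  if ("metaprofile" %in% config$stages) run_stage("metaprofile", function() {
    ns <- integer(0)
    for (cell in cells) {
      meth <- read_intervals(config$cells[[cell]]$meth, "bedGraph")
      prof <- metaprofile(peaks[[cell]], meth, p$flank, p$bin)
      .write_stage_table(prof, out("metaprofile_%s.tsv", cell),
                         "metaprofile")
      ns[cell] <- sum(prof$n_contributing > 0)
    }
    list(summary = data.frame(cell = cells, covered_bins = unname(ns)))
  })

  if ("annotation" %in% config$stages) run_stage("annotation", function() {
    rows <- list()
    for (cell in cells) {
      anch <- loop_anchors(loops[[cell]])
      ann <- annotate_anchors(anch, genes, p$contact_upstream,
                              p$contact_downstream)
      ann$loop_id <- loops[[cell]]$loop_id[anch$loop]
      ann$anchor <- anch$anchor
      .write_stage_table(ann[, c("loop_id", "anchor", "annotation", "gene_id")],
                         out("anchor_annotation_%s.tsv", cell), "annotation")
      tab <- table(ann$annotation)
      rows[[cell]] <- data.frame(cell = cell, annotation = names(tab),
                                 n = as.integer(tab),
                                 proportion = as.integer(tab) / sum(tab))
    }
    summary <- do.call(rbind, rows)
    .write_stage_table(summary, out("anchor_annotation_summary.tsv"),
                       "annotation")
    list(summary = summary)
  })

  contact_sets <- NULL
  if ("contacts" %in% config$stages) run_stage("contacts", function() {
    sets <- lapply(cells, function(cell)
      promoter_contact_genes(loops[[cell]], genes, p$contact_upstream,
                             p$contact_downstream))
    names(sets) <- cells
    contact_sets <<- sets
    for (cell in cells)
      .write_stage_table(data.frame(gene_id = sets[[cell]]),
                         out("promoter_contacts_%s.tsv", cell), "contacts")
    summary <- data.frame(cell = cells,
                          n_contact_genes = vapply(sets, length, 0L))
    if (length(cells) >= 3) {
      venn <- contact_sharing(sets[[1]], sets[[2]], sets[[3]], names = cells)
      .write_stage_table(data.frame(region = names(venn),
                                    n = as.integer(venn)),
                         out("contact_sharing.tsv"), "contacts")
    }
    .write_stage_table(summary, out("promoter_contact_summary.tsv"),
                       "contacts")
    list(summary = summary)
  })

  if ("enrichment" %in% config$stages) run_stage("enrichment", function() {
    gmt <- read_gmt(config$gmt)
    universe <- unique(genes$gene_id)
    ns <- integer(0)
    for (cell in cells) {
      query <- if (!is.null(contact_sets)) contact_sets[[cell]] else
        promoter_contact_genes(loops[[cell]], genes, p$contact_upstream,
                               p$contact_downstream)
      res <- enrich(query, gmt, universe)
      .write_stage_table(res, out("enrichment_%s.tsv", cell), "enrichment")
      ns[cell] <- sum(res$q < p$alpha)
    }
    list(summary = data.frame(cell = cells, n_significant = unname(ns)))
  })

  if ("cross_analysis" %in% config$stages) run_stage("cross_analysis", function() {
    tracks <- lapply(config$tracks, function(f) read_intervals(f, "bedGraph"))
    rank_col <- if (is.null(p$rank_column)) cells[length(cells)] else
      p$rank_column
    ca <- cross_analysis(expr, genes, tracks, rank_col, p$top_n,
                         p$coding_only)
    .write_stage_table(ca, out("cross_analysis.tsv"), "cross_analysis")
    list(summary = data.frame(rank_column = rank_col, n_rows = nrow(ca),
                              n_missing_model = attr(ca, "n_missing_model")))
  })

  if ("contact_stats" %in% config$stages) run_stage("contact_stats", function() {
    st <- read_contact_stats(config$contact_stats)
    agg <- aggregate_contact_stats(st)
    summary <- data.frame(n_samples = agg$n_samples, total = agg$total,
                          millions = agg$millions, billions = agg$billions)
    .write_stage_table(summary, out("contact_stats.tsv"), "contact_stats")
    list(summary = summary)
  })

  report$n_warnings <- length(report$warnings)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (length(failed))
    stop("stage(s) failed: ", paste(failed, collapse = ", "),
         " (partial outputs retained in ", config$outdir, ")")
  invisible(report)
}
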