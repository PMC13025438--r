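#' Pipeline configuration
#'
#' Collects the tunable parameters of the screening funnel with their
#' defaults: DEG thresholds (Q <= 0.05, |log2FC| >= 1), enrichment
#' significance (Q <= 0.05), top-5 term comparison, top-25% core pool,
#' top-8 centrality lists, and MCODE parameters. `apoptosis_patterns` is the
#' configurable allowlist of pathway-name patterns realizing the "apoptosis
#' and tumour-suppressive pathways" selection (matched case-insensitively
#' against enriched pathway names).
#'
#' @param deg_q_max,deg_lfc_min DEG classification thresholds.
#' @param enrich_q_max enrichment significance threshold (default 0.05).
#' @param top_terms_k terms compared across species (default 5).
#' @param core_fraction fraction of the conserved ranking kept as the core
#'   gene pool (default 0.25, ceiling rule).
#' @param hub_top_k list size of each centrality screen (default 8).
#' @param mcode_vwp,mcode_haircut MCODE parameters.
#' @param mcode_full_module MCODE contributes its top complex's full
#'   membership (default TRUE) rather than a top-k weight cut.
#' @param apoptosis_patterns character vector of regular expressions
#'   selecting apoptosis / tumour-suppressive pathway names.
#' @param seed integer seed recorded in the report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(deg_q_max = 0.05, deg_lfc_min = 1,
                            enrich_q_max = 0.05, top_terms_k = 5,
                            core_fraction = 0.25, hub_top_k = 8,
                            mcode_vwp = 0.2, mcode_haircut = TRUE,
                            mcode_full_module = TRUE,
                            apoptosis_patterns = c("apoptosis", "NF-kappa B",
                                                   "TNF", "Jak-STAT"),
                            seed = 1) {
  stopifnot(deg_q_max > 0, deg_q_max <= 1, deg_lfc_min >= 0,
            enrich_q_max > 0, enrich_q_max <= 1,
            core_fraction > 0, core_fraction <= 1,
            top_terms_k >= 1, hub_top_k >= 1)
  structure(list(deg_q_max = deg_q_max, deg_lfc_min = deg_lfc_min,
                 enrich_q_max = enrich_q_max, top_terms_k = top_terms_k,
                 core_fraction = core_fraction, hub_top_k = hub_top_k,
                 mcode_vwp = mcode_vwp, mcode_haircut = mcode_haircut,
                 mcode_full_module = mcode_full_module,
                 apoptosis_patterns = apoptosis_patterns, seed = seed),
            class = "pipeline_config")
}

stage_check <- function(ok, stage, what) {
  if (!ok) stop(sprintf("stage '%s': %s", stage, what), call. = FALSE)
}

#' Run the cross-species hub-screening funnel
#'
#' Executes the full analysis on in-memory inputs: differential expression
#' -> down-regulated genes -> apoptosis/tumour-suppressive pathway filter ->
#' species-presence filter against the human PPI network -> GO-BP
#' over-representation in both species -> top-term comparison and
#' shared-term gene intersection -> conserved set -> ascending-Q ranking ->
#' top-fraction core pool -> confidence-filtered induced subnetwork (dynamic
#' threshold on the core-pool size) -> five topological screens -> consensus.
#' Every stage failing to produce a non-empty required set raises a
#' stage-named error. The run is fully deterministic.
#'
#' @param x a `synthetic_study` from [generate_study()], or a named list with
#'   elements `counts` (matrix), `group`, `go_human`, `go_mouse`, `pathways`
#'   ([gene_set_collection()]s; pathways in counts casing), and `network`
#'   ([ppi_network()]); a precomputed DEG table may be supplied as `deg`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, every stage artifact
#'   plus `report.json` is written there.
#' @return A `pipeline_report`: a list of stage tallies, per-stage gene and
#'   term lists, the per-method hub lists, the consensus, and a config echo.
#' @export
run_pipeline <- function(x, config = pipeline_config(), out_dir = NULL) {
  if (inherits(x, "synthetic_study")) {
    x <- list(counts = x$counts, group = x$group, go_human = x$go_human,
              go_mouse = x$go_mouse, pathways = x$pathways_mouse,
              network = x$network)
  }
  need <- c("counts", "group", "go_human", "go_mouse", "pathways", "network")
  stopifnot(all(need %in% names(x)))
  counts <- x$counts
  group <- x$group

  # --- differential expression ------------------------------------------
  deg <- if (!is.null(x$deg)) x$deg else {
    deg_table(counts, group, q_max = config$deg_q_max,
              lfc_min = config$deg_lfc_min)
  }
  if (is.null(deg$direction)) {
    deg <- classify_degs(deg, q_max = config$deg_q_max,
                         lfc_min = config$deg_lfc_min)
  }
  down <- deg$gene[deg$direction == "down"]
  up <- deg$gene[deg$direction == "up"]
  stage_check(length(down) > 0, "deg_down", "no genes called down")

  # --- pathway enrichment and apoptosis filter --------------------------
  pw_universe <- intersect(rownames(counts), collection_genes(x$pathways))
  stage_check(length(pw_universe) > 0, "pathway_enrichment",
              "empty pathway universe")
  pw <- enrich(intersect(down, pw_universe), x$pathways, pw_universe)
  pat <- paste(config$apoptosis_patterns, collapse = "|")
  pw_sel <- pw[pw$q <= config$enrich_q_max &
                 grepl(pat, pw$term_name, ignore.case = TRUE), , drop = FALSE]
  stage_check(nrow(pw_sel) > 0, "apoptosis_filter",
              "no significant apoptosis/tumour-suppressive pathway")
  sel_genes <- unique(unlist(x$pathways$genes[pw_sel$term_id]))
  apoptosis_down <- sort(intersect(down, sel_genes))
  stage_check(length(apoptosis_down) > 0, "apoptosis_filter",
              "no down-regulated gene on the selected pathways")

  # --- species-presence filter against the human PPI network ------------
  present <- toupper(apoptosis_down) %in% x$network$nodes
  ppi_present <- apoptosis_down[present]
  species_specific <- sort(apoptosis_down[!present])
  stage_check(length(ppi_present) > 0, "ppi_presence",
              "no gene present in the PPI network")

  # --- GO-BP enrichment in both species ---------------------------------
  uni_h <- intersect(toupper(rownames(counts)), collection_genes(x$go_human))
  uni_m <- intersect(rownames(counts), collection_genes(x$go_mouse))
  stage_check(length(uni_h) > 0 && length(uni_m) > 0, "go_enrichment",
              "empty GO universe")
  query_h <- intersect(toupper(ppi_present), uni_h)
  query_m <- intersect(ppi_present, uni_m)
  stage_check(length(query_h) > 0 && length(query_m) > 0, "go_enrichment",
              "empty GO query")
  go_h <- enrich(query_h, x$go_human, uni_h)
  go_m <- enrich(query_m, x$go_mouse, uni_m)
  top_h <- top_terms(go_h, config$top_terms_k)
  top_m <- top_terms(go_m, config$top_terms_k)
  shared <- match_shared_terms(top_h$term_name, top_m$term_name)
  stage_check(length(shared) > 0, "shared_terms",
              "no shared term among the top terms of both species")

  # --- shared-term gene intersection (conserved set) --------------------
  term_genes_for <- function(collection, top, query) {
    sel <- top$term_id[normalize_term_name(top$term_name) %in% shared]
    sort(intersect(unique(unlist(collection$genes[sel])), query))
  }
  genes_h <- term_genes_for(x$go_human, top_h, query_h)
  genes_m <- term_genes_for(x$go_mouse, top_m, query_m)
  conserved <- intersect_orthologs(genes_m, genes_h)
  stage_check(length(conserved) > 0, "conserved_set",
              "ortholog intersection is empty")

  # --- Q ranking and core pool ------------------------------------------
  idx <- match(conserved, toupper(deg$gene))
  ranked <- rank_degs(data.frame(gene = conserved, q = deg$q[idx],
                                 log2fc = deg$log2fc[idx],
                                 stringsAsFactors = FALSE))
  core <- select_top_fraction(ranked$gene, config$core_fraction)
  stage_check(length(core) > 0, "core_pool", "core pool is empty")

  # --- induced subnetwork and topological screens -----------------------
  threshold <- dynamic_threshold(length(core))
  sub <- induced_subnetwork(filter_by_confidence(x$network, threshold), core)
  stage_check(n_edges(sub$network) > 0, "subnetwork",
              "core-pool subnetwork has no edges")
  screens <- screen_hubs(sub$network, top_k = config$hub_top_k,
                         mcode_full_module = config$mcode_full_module,
                         vwp = config$mcode_vwp,
                         haircut = config$mcode_haircut)
  stage_check(length(screens$consensus) > 0, "consensus",
              "the five screening lists have an empty intersection")

  report <- structure(list(
    n_genes = nrow(counts), n_samples = ncol(counts),
    n_up = length(up), n_down = length(down),
    pathways_selected = pw_sel$term_name,
    n_apoptosis_down = length(apoptosis_down),
    n_ppi_present = length(ppi_present),
    species_specific_dropped = species_specific,
    go_top_human = top_h$term_name, go_top_mouse = top_m$term_name,
    shared_terms = shared,
    n_shared_term_genes_human = length(genes_h),
    n_shared_term_genes_mouse = length(genes_m),
    n_conserved = length(conserved), conserved = ranked$gene,
    n_core = length(core), core_pool = core,
    ppi_threshold = threshold,
    n_subnetwork_edges = n_edges(sub$network),
    per_method = screens$per_method,
    consensus = screens$consensus,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("hubfunnel"))),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    write_report_artifacts(report, out_dir, deg = deg, pathway_enrichment = pw,
                           go_human = go_h, go_mouse = go_m,
                           subnetwork = sub$network)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  DEGs: %d up, %d down (of %d genes)\n",
              x$n_up, x$n_down, x$n_genes))
  cat(sprintf("  apoptosis-linked down genes: %d (PPI-present: %d, species-specific dropped: %d)\n",
              x$n_apoptosis_down, x$n_ppi_present,
              length(x$species_specific_dropped)))
  cat(sprintf("  shared GO terms: %s\n", paste(x$shared_terms, collapse = "; ")))
  cat(sprintf("  conserved genes: %d -> core pool: %d (PPI threshold %.1f)\n",
              x$n_conserved, x$n_core, x$ppi_threshold))
  cat(sprintf("  consensus hub(s): %s\n", paste(x$consensus, collapse = ", ")))
  invisible(x)
}

# persist every stage artifact plus the machine-readable report
write_report_artifacts <- function(report, out_dir, deg, pathway_enrichment,
                                   go_human, go_mouse, subnetwork) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(deg, "deg.tsv")
  wt(pathway_enrichment, "pathway_enrichment.tsv")
  wt(go_human, "go_enrichment_human.tsv")
  wt(go_mouse, "go_enrichment_mouse.tsv")
  wt(data.frame(gene = report$conserved), "conserved_genes.tsv")
  wt(data.frame(gene = report$core_pool, rank = seq_along(report$core_pool)),
     "core_pool.tsv")
  write_edge_list(subnetwork, file.path(out_dir, "subnetwork_edges.tsv"))
  scores <- do.call(rbind, lapply(names(report$per_method), function(m) {
    genes <- report$per_method[[m]]
    if (length(genes) == 0) return(NULL)
    data.frame(gene = genes, method = m, rank = seq_along(genes),
               stringsAsFactors = FALSE)
  }))
  wt(scores, "screen_lists.tsv")
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read pipeline inputs from files
#'
#' Loads the on-disk representation of a study (as written by
#' [write_study()] or assembled by hand) into the in-memory input list
#' accepted by [run_pipeline()].
#'
#' @param counts path to a counts TSV (first column `gene`, then one column
#'   per sample).
#' @param samples path to a two-column TSV `sample`, `group`.
#' @param go_human,go_mouse,pathways paths to GMT files.
#' @param ppi path to a STRING-style edge list TSV.
#' @param deg optional path to a precomputed DEG table TSV (alternative entry
#'   point bypassing the internal test).
#' @return A named list suitable for [run_pipeline()].
#' @export
read_pipeline_inputs <- function(counts, samples, go_human, go_mouse,
                                 pathways, ppi, deg = NULL) {
  for (p in c(counts, samples, go_human, go_mouse, pathways, ppi, deg)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  ctab <- utils::read.delim(counts, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (names(ctab)[1] != "gene") stop("counts file must start with a 'gene' column")
  mat <- as.matrix(ctab[, -1, drop = FALSE])
  rownames(mat) <- ctab$gene
  storage.mode(mat) <- "integer"
  stab <- utils::read.delim(samples, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(stab))) {
    stop("samples file must have columns 'sample' and 'group'")
  }
  grp <- stats::setNames(stab$group, stab$sample)
  if (!all(colnames(mat) %in% names(grp))) {
    stop("every counts column needs a group label")
  }
  out <- list(counts = mat, group = grp[colnames(mat)],
              go_human = read_gmt(go_human, species = "human"),
              go_mouse = read_gmt(go_mouse, species = "mouse"),
              pathways = read_gmt(pathways, species = "mouse"),
              network = read_edge_list(ppi))
  if (!is.null(deg)) out$deg <- read_deg_table(deg)
  out
}
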