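# Integration: intersect predicted miRNA targets with literature-derived
# disease genes, annotate the overlap with enriched pathways, and run the
# full pipeline end-to-end.

#' Overlap predicted targets with disease genes
#'
#' Case-normalised, whitespace-stripped intersection of the two gene lists,
#' optionally routed through an alias table first (gene symbols in the wild
#' mix styles, e.g. `Bcl-2` vs `BCL2`). Commutative; every overlap gene
#' carries both provenance flags.
#'
#' @param targets Predicted target symbols (non-empty).
#' @param disease_genes Literature-derived disease gene symbols (non-empty).
#' @param aliases Optional named character vector mapping alias -> canonical
#'   symbol (applied to both lists after upper-casing).
#' @return Object of class `overlap_report`: list with `overlap_genes`
#'   (sorted), `provenance` (data frame `gene`, `in_targets`,
#'   `in_disease`), and `counts` (`targets`, `disease_genes`, `overlap`).
#' @export
gene_overlap <- function(targets, disease_genes, aliases = NULL) {
  if (length(targets) == 0L) stopf("target gene set must be non-empty")
  if (length(disease_genes) == 0L) stopf("disease gene set must be non-empty")
  t_norm <- unique(normalize_symbols(targets, aliases))
  d_norm <- unique(normalize_symbols(disease_genes, aliases))
  ov <- sort(intersect(t_norm, d_norm))
  structure(list(
    overlap_genes = ov,
    provenance = data.frame(gene = ov,
                            in_targets = rep(TRUE, length(ov)),
                            in_disease = rep(TRUE, length(ov)),
                            stringsAsFactors = FALSE),
    counts = list(targets = length(t_norm), disease_genes = length(d_norm),
                  overlap = length(ov))
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap report: %d targets x %d disease genes -> %d shared\n",
              x$counts$targets, x$counts$disease_genes, x$counts$overlap))
  if (length(x$overlap_genes))
    cat(" ", paste(utils::head(x$overlap_genes, 12), collapse = ", "),
        if (length(x$overlap_genes) > 12) "..." else "", "\n")
  invisible(x)
}

#' Annotate an overlap report with enriched pathways
#'
#' Keeps the enrichment results passing `alpha` (with at least one overlap
#' gene) and maps each overlap gene to the significant sets containing it,
#' with membership taken from the collection.
#'
#' @param report An `overlap_report` from [gene_overlap()].
#' @param enrichment Enrichment table from [enrich()] (computed on the
#'   overlap or target set).
#' @param collection The `gene_set_collection` the enrichment used.
#' @param alpha Significance level (`p <= alpha`).
#' @return The report with `significant_pathways` (filtered enrichment
#'   rows) and `per_gene_pathways` (named list gene -> pathway names,
#'   empty for genes in no significant set) added.
#' @export
annotate_overlap <- function(report, enrichment, collection, alpha = 0.05) {
  if (!inherits(report, "overlap_report")) stopf("report must be an overlap_report")
  sig <- enrichment[enrichment$p <= alpha & enrichment$overlap_count > 0, , drop = FALSE]
  per_gene <- lapply(report$overlap_genes, function(g) {
    hit <- vapply(sig$set_name, function(nm) g %in% collection$sets[[nm]], logical(1))
    unname(sig$set_name[hit])
  })
  names(per_gene) <- report$overlap_genes
  report$significant_pathways <- sig
  report$per_gene_pathways <- per_gene
  report
}

#' Default pipeline configuration
#'
#' A fully synthetic configuration with planted ground truth: 150 genes, of
#' which 40 are true miRNA targets and 30 are disease-associated, with an
#' overlap of 20 planted disease-targets. Corpus, predictor, gene-set and
#' network simulators all derive their seeds from the single `seed`.
#'
#' @param seed Integer master seed.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  genes <- sprintf("G%03d", 1:150)
  true_targets <- genes[21:60]    # 40 genes
  disease_genes <- genes[41:70]   # 30 genes; 20 overlap the targets
  seeds <- derive_seeds(seed, 4L)
  list(
    seed = as.integer(seed),
    genes = genes,
    planted_targets = true_targets,
    planted_disease = disease_genes,
    meta = list(n_studies = 11L, delta = 0.63, tau = 0.23, seed = seeds[1]),
    corpus = list(n_docs = 2000L, disease_doc_rate = 0.3, gene_doc_rate = 0.05,
                  multiplier = 20, alpha = 0.01, seed = seeds[2]),
    predictions = list(n_tools = 11L, hit_rate_true = 0.8, hit_rate_false = 0.1,
                       threshold = 4L, seed = seeds[3]),
    sets_edges = list(n_sets = 10L, set_size_range = c(5L, 20L), n_edges = 120L,
                      enrichment_alpha = 0.05, seed = seeds[4])
  )
}

#' Run the integrative pipeline end-to-end
#'
#' Orchestrates all stages on synthetic inputs generated from the
#' configuration: expression meta-analysis, literature co-citation mining,
#' consensus target calling, target-disease overlap, pathway enrichment of
#' the overlap, and interaction-network hub analysis. Writes one JSON
#' report bundle plus per-stage TSVs; stage timings and record counts are
#' logged to the console (`message()`), never into the bundle, so reruns
#' under the same seed are byte-identical.
#'
#' @param config Configuration list from [default_pipeline_config()], or a
#'   path to a YAML/JSON file with the same structure.
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param quiet Suppress stage logging.
#' @return The report bundle (list), invisibly when files are written.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  log_stage <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    log_stage("stage %-12s done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }
  genes <- config$genes

  studies <- run_stage("simulate", {
    simulate_meta_studies(meta_sim_config(
      n_studies = config$meta$n_studies, delta = config$meta$delta,
      tau = config$meta$tau, seed = config$meta$seed))
  })

  meta <- run_stage("meta", {
    eff <- study_effects(studies)
    list(effects = eff, pooled = pool_random_effects(eff))
  })

  cocite <- run_stage("cocite", {
    corpus <- simulate_corpus(corpus_sim_config(
      n_docs = config$corpus$n_docs, genes = genes,
      disease_doc_rate = config$corpus$disease_doc_rate,
      gene_doc_rate = config$corpus$gene_doc_rate,
      enriched_genes = config$planted_disease,
      multiplier = config$corpus$multiplier, seed = config$corpus$seed))
    ranked <- rank_genes(corpus$mentions, genes = genes, n_docs = corpus$n_docs)
    list(mentions = corpus$mentions, ranked = ranked,
         disease_genes = filter_significant(ranked, config$corpus$alpha))
  })

  consensus <- run_stage("consensus", {
    pm <- simulate_predictions(predictor_sim_config(
      genes = genes, n_tools = config$predictions$n_tools,
      true_targets = config$planted_targets,
      hit_rate_true = config$predictions$hit_rate_true,
      hit_rate_false = config$predictions$hit_rate_false,
      seed = config$predictions$seed))
    list(matrix = pm,
         called = consensus_targets(pm, config$predictions$threshold))
  })

  overlap <- run_stage("overlap",
    gene_overlap(consensus$called$gene, cocite$disease_genes))

  se <- run_stage("enrich", {
    sim <- simulate_genesets_and_edges(
      genes, n_sets = config$sets_edges$n_sets,
      set_size_range = config$sets_edges$set_size_range,
      n_edges = config$sets_edges$n_edges, seed = config$sets_edges$seed)
    enr <- if (length(intersect(overlap$overlap_genes, sim$collection$universe)))
      enrich(overlap$overlap_genes, sim$collection,
             alpha = config$sets_edges$enrichment_alpha) else NULL
    list(sim = sim, enrichment = enr)
  })
  if (!is.null(se$enrichment))
    overlap <- annotate_overlap(overlap, se$enrichment, se$sim$collection,
                                alpha = config$sets_edges$enrichment_alpha)

  network <- run_stage("network", {
    g <- build_network(se$sim$edges)
    deg <- connectivity(g)
    hubs <- if (length(deg) >= 2L) hub_test(deg) else NULL
    list(graph = g, degrees = deg, hubs = hubs)
  })

  planted_overlap <- intersect(toupper(config$planted_targets),
                               toupper(config$planted_disease))
  recall <- if (length(planted_overlap))
    length(intersect(overlap$overlap_genes, planted_overlap)) / length(planted_overlap)
  else NA_real_

  bundle <- list(
    schema = "mirhcc_report/1",
    config = config[c("seed", "meta", "corpus", "predictions", "sets_edges")],
    meta = c(as.list(as.data.frame(meta$pooled)),
             list(n_studies = nrow(studies))),
    cocite = list(n_docs = config$corpus$n_docs,
                  n_disease_docs = sum(cocite$mentions$disease_flag),
                  n_disease_genes = length(cocite$disease_genes),
                  disease_genes = cocite$disease_genes),
    consensus = list(threshold = attr(consensus$called, "threshold"),
                     n_called = nrow(consensus$called),
                     called = consensus$called$gene),
    overlap = list(counts = overlap$counts, genes = overlap$overlap_genes,
                   planted_recall = recall,
                   significant_pathways =
                     if (!is.null(overlap$significant_pathways))
                       overlap$significant_pathways$set_name else character(0),
                   per_gene_pathways = overlap$per_gene_pathways),
    network = list(n_nodes = length(network$degrees),
                   n_edges = igraph::ecount(network$graph),
                   degenerate = if (!is.null(network$hubs))
                     isTRUE(attr(network$hubs, "degenerate")) else NA,
                   top_hubs = if (!is.null(network$hubs))
                     utils::head(network$hubs, 5) else NULL)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_studies_tsv(studies, file.path(out_dir, "studies.tsv"))
    write_tsv_file(forest_table(meta$effects, meta$pooled),
                   file.path(out_dir, "forest.tsv"))
    write_mentions_tsv(cocite$mentions, file.path(out_dir, "mentions.tsv"))
    write_tsv_file(cocite$ranked, file.path(out_dir, "cocitation.tsv"))
    write_prediction_tsv(consensus$matrix, file.path(out_dir, "predictions.tsv"))
    write_tsv_file(consensus$called, file.path(out_dir, "consensus.tsv"))
    if (!is.null(se$enrichment))
      write_tsv_file(se$enrichment, file.path(out_dir, "enrichment.tsv"))
    write_gmt(se$sim$collection, file.path(out_dir, "genesets.gmt"))
    write_edges_tsv(se$sim$edges, file.path(out_dir, "edges.tsv"))
    if (!is.null(network$hubs))
      write_tsv_file(network$hubs, file.path(out_dir, "hubs.tsv"))
    export_graph(network$graph, file.path(out_dir, "network.graphml"))
    jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    return(invisible(bundle))
  }
  bundle
}

#' Validate a report bundle against the expected schema
#'
#' @param bundle Report list from [run_pipeline()] (or parsed from its
#'   JSON).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_bundle <- function(bundle) {
  need <- c("schema", "config", "meta", "cocite", "consensus", "overlap", "network")
  miss <- setdiff(need, names(bundle))
  if (length(miss)) stopf("bundle is missing sections: %s", paste(miss, collapse = ", "))
  if (!identical(as.character(bundle$schema), "mirhcc_report/1"))
    stopf("unknown bundle schema '%s'", bundle$schema)
  for (f in c("smd", "ci_low", "ci_high", "i2", "tau2"))
    if (!is.numeric(bundle$meta[[f]])) stopf("bundle meta section lacks numeric '%s'", f)
  if (!is.numeric(bundle$overlap$counts$overlap)) stopf("bundle lacks overlap count")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stopf("config file must be .yaml/.yml or .json")
}
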