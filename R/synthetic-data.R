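# Synthetic generators for every pipeline input, with known ground truth.
#
# Each generator takes one integer seed; per-record randomness runs on
# sub-stream seeds derived deterministically from it, so output is
# reproducible without any seed bookkeeping by the caller, and the
# caller's RNG state is left untouched.

#' Configuration for simulated two-group expression studies
#'
#' Defaults describe an eleven-study tissue comparison with a true pooled
#' SMD of 0.63 and moderate between-study heterogeneity (tau = 0.23 gives a
#' mean I-squared near 40% under this sample-size roster), with per-arm
#' sizes spanning the 4-96 range typical of public HCC expression series.
#'
#' @param n_studies Number of studies.
#' @param delta True standardized mean difference (control minus case;
#'   positive = lower in cases).
#' @param tau Between-study SD of the true study effects (>= 0).
#' @param n_case_range,n_control_range Inclusive integer ranges for per-arm
#'   sample sizes; lower bound >= 2 (an SD needs two observations).
#' @param within_sd Within-group SD on the expression scale (> 0).
#' @param stratum Stratum label stamped on every study.
#' @param seed Integer master seed.
#' @return Object of class `meta_sim_config`.
#' @export
meta_sim_config <- function(n_studies = 11L, delta = 0.63, tau = 0.23,
                            n_case_range = c(4L, 96L),
                            n_control_range = c(4L, 96L),
                            within_sd = 1, stratum = "tissue", seed = 1L) {
  if (!is_count(n_studies) || n_studies < 1) stopf("n_studies must be a positive integer")
  if (!is.numeric(tau) || tau < 0) stopf("tau must be >= 0")
  if (!is.numeric(within_sd) || within_sd <= 0) stopf("within_sd must be > 0")
  for (r in list(n_case_range, n_control_range)) {
    if (length(r) != 2L || any(r != trunc(r)) || r[1] > r[2] || r[1] < 2)
      stopf("sample-size ranges must be non-empty integer ranges with lower bound >= 2")
  }
  if (!stratum %in% KNOWN_STRATA) stopf("unknown stratum '%s'", stratum)
  structure(list(n_studies = as.integer(n_studies), delta = delta, tau = tau,
                 n_case_range = as.integer(n_case_range),
                 n_control_range = as.integer(n_control_range),
                 within_sd = within_sd, stratum = stratum,
                 seed = as.integer(seed)),
            class = "meta_sim_config")
}

#' Simulate two-group expression studies
#'
#' Study i draws a true effect `delta_i ~ Normal(delta, tau^2)`, then
#' observation-level expression values: cases `Normal(0, within_sd^2)` and
#' controls `Normal(delta_i * within_sd, within_sd^2)` (controls shifted
#' upward, so a positive delta models a transcript downregulated in cases).
#' Group means and SDs are computed from the simulated observations, so SD
#' sampling noise — and hence the small-sample bias that the Hedges
#' correction addresses — is realistic rather than assumed away.
#'
#' @param config A [meta_sim_config()].
#' @return Wide study table: `study_id`, `stratum`, `n_case`, `mean_case`,
#'   `sd_case`, `n_control`, `mean_control`, `sd_control`, with the
#'   per-study true effects attached as attribute `"true_effects"`.
#' @export
simulate_meta_studies <- function(config) {
  if (!inherits(config, "meta_sim_config")) stopf("config must be a meta_sim_config")
  seeds <- derive_seeds(config$seed, config$n_studies)
  rows <- lapply(seq_len(config$n_studies), function(i) {
    with_seed(seeds[i], {
      d_i <- stats::rnorm(1, config$delta, config$tau)
      n1 <- sample(config$n_case_range[1]:config$n_case_range[2], 1)
      n2 <- sample(config$n_control_range[1]:config$n_control_range[2], 1)
      case_obs <- stats::rnorm(n1, 0, config$within_sd)
      ctrl_obs <- stats::rnorm(n2, d_i * config$within_sd, config$within_sd)
      data.frame(study_id = sprintf("SIM%03d", i), stratum = config$stratum,
                 n_case = n1, mean_case = mean(case_obs), sd_case = stats::sd(case_obs),
                 n_control = n2, mean_control = mean(ctrl_obs),
                 sd_control = stats::sd(ctrl_obs),
                 true_effect = d_i, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  true_eff <- out$true_effect
  out$true_effect <- NULL
  attr(out, "true_effects") <- true_eff
  out
}

#' Configuration for a simulated literature corpus
#'
#' Emulates a PubMed-scale mention table: each document is independently
#' disease-relevant with `disease_doc_rate`, and mentions each gene with
#' `gene_doc_rate`; for enriched genes the odds of mention are multiplied
#' by `multiplier` inside disease documents, planting a true gene-disease
#' co-citation signal.
#'
#' @param n_docs Corpus size N.
#' @param genes Gene symbol list.
#' @param disease_doc_rate,gene_doc_rate Probabilities in `[0, 1]`.
#' @param enriched_genes Subset of `genes` carrying the planted signal.
#' @param multiplier Co-mention odds multiplier (> 1) for enriched genes in
#'   disease documents.
#' @param seed Integer master seed.
#' @return Object of class `corpus_sim_config`.
#' @export
corpus_sim_config <- function(n_docs = 2000L, genes, disease_doc_rate = 0.3,
                              gene_doc_rate = 0.05, enriched_genes = character(0),
                              multiplier = 20, seed = 1L) {
  if (length(genes) == 0L) stopf("gene list must be non-empty")
  genes <- unique(toupper(trimws(genes)))
  enriched_genes <- unique(toupper(trimws(enriched_genes)))
  if (!is_count(n_docs) || n_docs < 1) stopf("n_docs must be a positive integer")
  for (r in c(disease_doc_rate, gene_doc_rate))
    if (!is.numeric(r) || r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  if (!all(enriched_genes %in% genes)) stopf("enriched_genes must be a subset of genes")
  if (!is.numeric(multiplier) || multiplier <= 0) stopf("multiplier must be > 0")
  structure(list(n_docs = as.integer(n_docs), genes = genes,
                 disease_doc_rate = disease_doc_rate, gene_doc_rate = gene_doc_rate,
                 enriched_genes = enriched_genes, multiplier = multiplier,
                 seed = as.integer(seed)),
            class = "corpus_sim_config")
}

#' Simulate a document-gene mention table
#'
#' @param config A [corpus_sim_config()].
#' @return List with `mentions` (data frame `doc_id`, `disease_flag`,
#'   `genes` semicolon-joined) and `n_docs`.
#' @export
simulate_corpus <- function(config) {
  if (!inherits(config, "corpus_sim_config")) stopf("config must be a corpus_sim_config")
  G <- length(config$genes)
  seeds <- derive_seeds(config$seed, 2L)
  disease <- with_seed(seeds[1],
    stats::runif(config$n_docs) < config$disease_doc_rate)
  base_p <- config$gene_doc_rate
  # odds-multiplier model: p' = M*odds / (1 + M*odds)
  enr_p <- if (base_p >= 1) 1 else {
    o <- config$multiplier * base_p / (1 - base_p)
    o / (1 + o)
  }
  pm <- matrix(base_p, nrow = config$n_docs, ncol = G)
  colnames(pm) <- config$genes
  if (length(config$enriched_genes) && any(disease))
    pm[disease, config$enriched_genes] <- enr_p
  hits <- with_seed(seeds[2],
    matrix(stats::runif(config$n_docs * G), config$n_docs, G) < pm)
  gene_strings <- apply(hits, 1, function(h) paste(config$genes[h], collapse = ";"))
  list(mentions = data.frame(doc_id = sprintf("DOC%05d", seq_len(config$n_docs)),
                             disease_flag = disease,
                             genes = gene_strings, stringsAsFactors = FALSE),
       n_docs = config$n_docs)
}

#' Configuration for simulated target predictions
#'
#' Per-cell Bernoulli support: tools call a true target with
#' `hit_rate_true` and any other gene with `hit_rate_false`.
#'
#' @param genes Gene symbol list.
#' @param n_tools Number of prediction tools (default 11; when 11, the
#'   canonical tool names in [MIRNA_PREDICTION_TOOLS] label the columns).
#' @param true_targets Subset of `genes` that are genuine targets.
#' @param hit_rate_true,hit_rate_false Per-tool hit probabilities;
#'   `hit_rate_true > hit_rate_false`.
#' @param seed Integer master seed.
#' @return Object of class `predictor_sim_config`.
#' @export
predictor_sim_config <- function(genes, n_tools = 11L, true_targets = character(0),
                                 hit_rate_true = 0.8, hit_rate_false = 0.1,
                                 seed = 1L) {
  if (length(genes) == 0L) stopf("gene list must be non-empty")
  genes <- unique(toupper(trimws(genes)))
  true_targets <- unique(toupper(trimws(true_targets)))
  if (!is_count(n_tools) || n_tools < 1) stopf("n_tools must be a positive integer")
  if (!all(true_targets %in% genes)) stopf("true_targets must be a subset of genes")
  if (!(hit_rate_true > hit_rate_false)) stopf("hit_rate_true must exceed hit_rate_false")
  for (r in c(hit_rate_true, hit_rate_false))
    if (!is.numeric(r) || r < 0 || r > 1) stopf("hit rates must lie in [0, 1]")
  structure(list(genes = genes, n_tools = as.integer(n_tools),
                 true_targets = true_targets, hit_rate_true = hit_rate_true,
                 hit_rate_false = hit_rate_false, seed = as.integer(seed)),
            class = "predictor_sim_config")
}

#' Simulate a genes-by-tools prediction matrix
#'
#' @param config A [predictor_sim_config()].
#' @return Prediction matrix (see [prediction_matrix()]) with the true
#'   target set attached as attribute `"true_targets"`.
#' @export
simulate_predictions <- function(config) {
  if (!inherits(config, "predictor_sim_config")) stopf("config must be a predictor_sim_config")
  G <- length(config$genes)
  p <- ifelse(config$genes %in% config$true_targets,
              config$hit_rate_true, config$hit_rate_false)
  hits <- with_seed(config$seed,
    matrix(stats::runif(G * config$n_tools), G, config$n_tools) < p)
  tools <- if (config$n_tools == length(MIRNA_PREDICTION_TOOLS))
    MIRNA_PREDICTION_TOOLS else sprintf("tool%02d", seq_len(config$n_tools))
  out <- prediction_matrix(hits, genes = config$genes, tools = tools)
  attr(out, "true_targets") <- config$true_targets
  out
}

#' Simulate a gene-set collection and a typed edge list
#'
#' Gene sets draw members without replacement (no duplicates within a
#' set); edges draw distinct endpoint pairs with interaction types and
#' polarity labels (association / inhibition / activation) sampled
#' uniformly.
#'
#' @param genes Gene symbol list.
#' @param n_sets Number of gene sets.
#' @param set_size_range Inclusive range of set sizes (upper bound must not
#'   exceed the number of genes).
#' @param n_edges Number of edges (0 allowed).
#' @param seed Integer master seed.
#' @return List with `collection` (a [gene_set_collection()]) and `edges`
#'   (a validated edge data frame, possibly empty).
#' @export
simulate_genesets_and_edges <- function(genes, n_sets = 10L,
                                        set_size_range = c(5L, 20L),
                                        n_edges = 50L, seed = 1L) {
  if (length(genes) == 0L) stopf("gene list must be non-empty")
  genes <- unique(toupper(trimws(genes)))
  if (length(set_size_range) != 2L || set_size_range[1] > set_size_range[2] ||
      set_size_range[1] < 1)
    stopf("set_size_range must be a non-empty positive integer range")
  if (set_size_range[2] > length(genes))
    stopf("set size %d exceeds the number of genes (%d)",
          set_size_range[2], length(genes))
  if (!is_count(n_sets) || n_sets < 1) stopf("n_sets must be a positive integer")
  if (!is_count(n_edges)) stopf("n_edges must be a non-negative integer")
  seeds <- derive_seeds(seed, 2L)
  sets <- with_seed(seeds[1], {
    sizes <- sample(set_size_range[1]:set_size_range[2], n_sets, replace = TRUE)
    stats::setNames(lapply(sizes, function(sz) sort(sample(genes, sz))),
                    sprintf("set%03d", seq_len(n_sets)))
  })
  edges <- if (n_edges == 0L) {
    data.frame(source = character(0), target = character(0),
               type = character(0), polarity = character(0),
               stringsAsFactors = FALSE)
  } else {
    with_seed(seeds[2], {
      src <- sample(genes, n_edges, replace = TRUE)
      tgt <- vapply(src, function(s) sample(setdiff(genes, s), 1), character(1))
      data.frame(source = src, target = tgt,
                 type = sample(EDGE_TYPES, n_edges, replace = TRUE),
                 polarity = sample(EDGE_POLARITIES, n_edges, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
  }
  rownames(edges) <- NULL
  list(collection = gene_set_collection(sets, universe = genes),
       edges = edges)
}

#' Read / write study tables as long TSV
#'
#' Long format, two rows per study: `study_id`, `group` (`case` /
#' `control`), `n`, `mean`, `sd`, `stratum`.
#'
#' @param studies Wide study table (see [simulate_meta_studies()]).
#' @param path File path.
#' @return `write_studies_tsv()` returns the path invisibly;
#'   `read_studies_tsv()` returns the wide study table.
#' @export
write_studies_tsv <- function(studies, path) {
  long <- rbind(
    data.frame(study_id = studies$study_id, group = "case",
               n = studies$n_case, mean = studies$mean_case, sd = studies$sd_case,
               stratum = studies$stratum, stringsAsFactors = FALSE),
    data.frame(study_id = studies$study_id, group = "control",
               n = studies$n_control, mean = studies$mean_control,
               sd = studies$sd_control, stratum = studies$stratum,
               stringsAsFactors = FALSE))
  long <- long[order(long$study_id, long$group), ]
  write_tsv_file(long, path)
}

#' @rdname write_studies_tsv
#' @export
read_studies_tsv <- function(path) {
  long <- read_tsv_file(path)
  need <- c("study_id", "group", "n", "mean", "sd", "stratum")
  miss <- setdiff(need, names(long))
  if (length(miss)) stopf("study TSV is missing columns: %s", paste(miss, collapse = ", "))
  case <- long[long$group == "case", ]
  ctrl <- long[long$group == "control", ]
  if (!setequal(case$study_id, ctrl$study_id))
    stopf("every study needs both a case and a control row")
  i <- match(case$study_id, ctrl$study_id)
  data.frame(study_id = case$study_id, stratum = case$stratum,
             n_case = case$n, mean_case = case$mean, sd_case = case$sd,
             n_control = ctrl$n[i], mean_control = ctrl$mean[i],
             sd_control = ctrl$sd[i], stringsAsFactors = FALSE)
}

#' Write a mention table as TSV
#'
#' Columns: `doc_id`, `disease_flag` (0/1), `genes` (semicolon-joined).
#'
#' @param mentions Mention data frame (see [simulate_corpus()]).
#' @param path File path.
#' @return The path, invisibly; `read_mentions_tsv()` returns the table.
#' @export
write_mentions_tsv <- function(mentions, path) {
  out <- mentions
  out$disease_flag <- as.integer(as.logical(out$disease_flag))
  write_tsv_file(out, path)
}

#' @rdname write_mentions_tsv
#' @export
read_mentions_tsv <- function(path) {
  df <- read_tsv_file(path)
  if (!"genes" %in% names(df)) stopf("mention TSV needs a 'genes' column")
  df$disease_flag <- as.logical(as.integer(df$disease_flag))
  df$genes <- as.character(df$genes)
  df$genes[is.na(df$genes)] <- ""
  df
}
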