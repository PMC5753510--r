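# Independent oracles and fixture builders used across the suite.

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n)
# disease-document subsets (feasible for small N only). Fully independent
# of the package's log-gamma evaluation path.
enum_hyper_tail <- function(k, n, m, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  gene_docs <- seq_len(m)  # which documents mention the gene is arbitrary
  hits <- apply(subsets, 2, function(s) sum(s %in% gene_docs))
  mean(hits >= k)
}

# Hypergeometric upper tail by direct pmf summation with plain binomial
# coefficients (exact in double precision for N <= 40). Returns the whole
# tail vector for k = 0..min(m, n).
choose_tail <- function(m, n, N) {
  hi <- min(m, n)
  pmf <- choose(m, 0:hi) * choose(N - m, n - (0:hi)) / choose(N, n)
  pmin(1, rev(cumsum(rev(pmf))))
}

# Random effect-size fixture on the meta-analysis scale.
random_effects <- function(k, seed) {
  set.seed(seed)
  g <- rnorm(k, 0.5, 0.4)
  v <- runif(k, 0.02, 0.3)
  out <- data.frame(study_id = paste0("S", seq_len(k)), g = g, variance = v,
                    stringsAsFactors = FALSE)
  out$ci_low <- g - qnorm(0.975) * sqrt(v)
  out$ci_high <- g + qnorm(0.975) * sqrt(v)
  out
}

# Random boolean prediction matrix.
random_prediction_matrix <- function(n_genes, n_tools, seed, p = 0.4) {
  set.seed(seed)
  prediction_matrix(matrix(runif(n_genes * n_tools) < p, n_genes, n_tools),
                    genes = sprintf("g%03d", seq_len(n_genes)),
                    tools = sprintf("t%02d", seq_len(n_tools)))
}

# Brute-force node degree: count edge-list incidences after dropping
# self-loops and collapsing duplicate unordered pairs.
brute_force_degrees <- function(edges) {
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  pairs <- unique(paste(a, b, sep = "|"))
  ends <- unlist(strsplit(pairs, "|", fixed = TRUE))
  tab <- table(ends)
  setNames(as.integer(tab), names(tab))
}

# Random typed edge list over a small node pool (duplicates allowed).
random_edge_list <- function(n_edges, n_nodes, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  data.frame(source = sample(nodes, n_edges, replace = TRUE),
             target = sample(nodes, n_edges, replace = TRUE),
             type = sample(c("enzyme_enzyme", "protein_protein",
                             "gene_expression", "cocitation"),
                           n_edges, replace = TRUE),
             polarity = sample(c("association", "inhibition", "activation"),
                               n_edges, replace = TRUE),
             stringsAsFactors = FALSE)
}
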