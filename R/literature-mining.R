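# Gene-disease co-citation scoring from document mention tables.
#
# Counts are document-level: a gene counts once per document regardless of
# how many times it is mentioned. With N eligible documents, n of them
# disease-relevant, m mentioning the gene and k doing both, the association
# score is the hypergeometric upper tail P[X >= k] — the probability of at
# least k co-citations under random assortment of the two document sets.

#' Tag gene mentions in raw documents with a dictionary matcher
#'
#' Case-insensitive whole-word matching of lexicon symbols against document
#' text. This is plumbing so that raw-text fixtures can feed
#' [rank_genes()]; it does no entity recognition beyond word boundaries.
#'
#' @param documents Character vector of document texts; names (if any) are
#'   used as document ids.
#' @param lexicon Character vector of gene symbols to match.
#' @return Named list, one character vector of matched (upper-cased)
#'   symbols per document.
#' @examples
#' tag_mentions(c(d1 = "BCL2 and CCND1 interact"), c("BCL2", "CCND1", "MET"))
#' @export
tag_mentions <- function(documents, lexicon) {
  if (length(lexicon) == 0L) stopf("lexicon must be non-empty")
  lexicon <- unique(toupper(trimws(lexicon)))
  # \b fails around non-word symbol characters (e.g. a trailing '-');
  # lookarounds on word characters behave consistently there.
  pats <- paste0("(?<![[:alnum:]_])", vapply(lexicon, function(s)
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s), character(1)),
    "(?![[:alnum:]_])")
  ids <- if (!is.null(names(documents))) names(documents)
         else paste0("doc_", seq_along(documents))
  out <- lapply(documents, function(txt) {
    hit <- vapply(pats, function(p)
      grepl(p, txt, ignore.case = TRUE, perl = TRUE), logical(1))
    lexicon[hit]
  })
  names(out) <- ids
  out
}

#' Co-citation p-value (hypergeometric upper tail)
#'
#' `p = 1 - sum_{i=0}^{k-1} C(m,i) C(N-m, n-i) / C(N,n)`, i.e.
#' `P[X >= k]` for X hypergeometric with population N, m gene documents and
#' n disease documents. Evaluated with log-gamma binomial coefficients and
#' log-sum-exp accumulation so realistic corpus sizes do not overflow;
#' `k = 0` returns exactly 1 (empty sum).
#'
#' @param k Co-mention document count (vectorised).
#' @param n Disease document count.
#' @param m Gene document count.
#' @param N Total eligible documents.
#' @return Numeric vector of upper-tail probabilities in `[0, 1]`.
#' @examples
#' cocitation_pvalue(k = 3, n = 5, m = 4, N = 10)
#' cocitation_pvalue(k = 0, n = 5, m = 4, N = 10)  # exactly 1
#' @export
cocitation_pvalue <- function(k, n, m, N) {
  if (!is_count(n) || !is_count(m) || !is_count(N))
    stopf("n, m, N must be single non-negative integers")
  if (m > N || n > N) stopf("m and n must not exceed N")
  if (any(k < 0) || any(k != trunc(k))) stopf("k must be non-negative integers")
  if (any(k > min(m, n))) stopf("k must not exceed min(m, n)")
  hyper_upper_tail(k, m = m, n = n, N = N)
}

# one mention per document: duplicates within a document collapse
split_genes <- function(x) {
  if (is.list(x)) return(lapply(x, function(g) unique(toupper(trimws(as.character(g))))))
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(g) unique(toupper(trimws(g[nzchar(trimws(g))]))))
}

#' Score and rank genes by disease co-citation
#'
#' Tabulates, for each gene, the documents mentioning it (m), the disease
#' documents (n), their co-mentions (k) and the corpus size (N), and scores
#' each gene with [cocitation_pvalue()]. Results are sorted by ascending p,
#' ties broken by descending k then alphabetically.
#'
#' @param mentions Mention table: data frame with columns `doc_id`,
#'   `disease_flag` (logical or 0/1) and `genes` (semicolon-joined symbols,
#'   or a list column of symbol vectors).
#' @param genes Optional gene universe; defaults to all mentioned symbols.
#'   Genes never mentioned get `m = k = 0` and `p = 1`.
#' @param n_docs Corpus size N; defaults to `nrow(mentions)`.
#' @return Data frame with columns `gene`, `k`, `m`, `n`, `N`, `p`.
#' @export
rank_genes <- function(mentions, genes = NULL, n_docs = NULL) {
  if (is.null(mentions) || nrow(mentions) == 0L) stopf("mention table must be non-empty")
  if (!all(c("disease_flag", "genes") %in% names(mentions)))
    stopf("mention table needs 'disease_flag' and 'genes' columns")
  N <- if (is.null(n_docs)) nrow(mentions) else n_docs
  if (!is_count(N) || N < nrow(mentions))
    stopf("n_docs must be an integer >= the number of rows")
  doc_genes <- split_genes(mentions$genes)
  disease <- as.logical(mentions$disease_flag)
  n <- sum(disease)
  if (is.null(genes)) genes <- sort(unique(unlist(doc_genes)))
  genes <- unique(toupper(trimws(genes)))
  m <- k <- integer(length(genes))
  if (length(doc_genes)) {
    all_tab <- table(factor(unlist(doc_genes), levels = genes))
    dis_tab <- table(factor(unlist(doc_genes[disease]), levels = genes))
    m <- as.integer(all_tab)
    k <- as.integer(dis_tab)
  }
  p <- vapply(seq_along(genes), function(i)
    cocitation_pvalue(k[i], n = n, m = m[i], N = N), numeric(1))
  out <- data.frame(gene = genes, k = k, m = m, n = n, N = N, p = p,
                    stringsAsFactors = FALSE)
  out[order(out$p, -out$k, out$gene), , drop = FALSE]
}

#' Filter co-citation results at a significance level
#'
#' @param results Output of [rank_genes()].
#' @param alpha Significance level in (0, 1]; genes with `p < alpha` are
#'   kept (order preserved).
#' @param adjust `"none"` (default; raw p-values) or `"BH"` for
#'   Benjamini-Hochberg adjustment before thresholding.
#' @return Character vector of gene symbols.
#' @export
filter_significant <- function(results, alpha, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stopf("alpha must be a single value in (0, 1]")
  p <- results$p
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  results$gene[p < alpha]
}
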