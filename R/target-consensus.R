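# Consensus miRNA-target calling by support voting across predictors.

#' Canonical miRNA target-prediction tool names
#'
#' The eleven independent prediction algorithms whose boolean outputs the
#' consensus step consumes. Used as default column labels for simulated
#' prediction matrices of matching width.
#' @export
MIRNA_PREDICTION_TOOLS <- c(
  "DIANA-microT", "MicroInspector", "miRanda", "MirTarget2", "miTarget",
  "NBmiRTar", "PicTar", "PITA", "RNA22", "RNAhybrid", "TargetScan")

#' Construct / validate a prediction matrix
#'
#' A genes-by-tools boolean support grid: cell `[g, t]` is `TRUE` when tool
#' `t` predicts gene `g` as a target of the miRNA.
#'
#' @param support Logical (or 0/1) matrix.
#' @param genes,tools Row and column labels; default to the dimnames of
#'   `support`.
#' @return Logical matrix with gene rownames and tool colnames.
#' @export
prediction_matrix <- function(support, genes = rownames(support), tools = colnames(support)) {
  if (is.null(genes) || is.null(tools)) stopf("genes and tools labels are required")
  if (anyDuplicated(genes)) stopf("duplicate gene symbols in prediction matrix")
  if (anyDuplicated(tools)) stopf("duplicate tool names in prediction matrix")
  support <- as.matrix(support)
  if (nrow(support) != length(genes) || ncol(support) != length(tools))
    stopf("support grid dimensions (%d x %d) do not match labels (%d genes, %d tools)",
          nrow(support), ncol(support), length(genes), length(tools))
  mode(support) <- "logical"
  if (anyNA(support)) stopf("support grid must be boolean with no missing values")
  dimnames(support) <- list(genes, tools)
  support
}

#' Consensus targets at a support threshold
#'
#' A gene is called a consensus target when at least `threshold` tools
#' predict it (default 4 of 11, the conventional reliability cut for
#' combining independent target predictors).
#'
#' @param matrix Prediction matrix (see [prediction_matrix()]).
#' @param threshold Minimum number of supporting tools, between 1 and the
#'   number of tools.
#' @return Data frame `gene`, `support` (tool count) for the called genes,
#'   sorted by descending support then symbol; the threshold is attached as
#'   attribute `"threshold"`.
#' @examples
#' m <- prediction_matrix(matrix(c(1, 1, 0, 1, 1, 0), 2, 3),
#'                        genes = c("A", "B"), tools = c("t1", "t2", "t3"))
#' consensus_targets(m, threshold = 2)
#' @export
consensus_targets <- function(matrix, threshold = 4L) {
  matrix <- prediction_matrix(matrix)
  if (!is_count(threshold) || threshold < 1 || threshold > ncol(matrix))
    stopf("threshold must be an integer in [1, %d]", ncol(matrix))
  supp <- rowSums(matrix)
  keep <- supp >= threshold
  out <- data.frame(gene = rownames(matrix)[keep],
                    support = as.integer(supp[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- as.integer(threshold)
  out
}

#' Support-level histogram
#'
#' Diagnostic count of genes at each support level 0..T (T = tool count);
#' the histogram always sums to the number of genes.
#'
#' @inheritParams consensus_targets
#' @return Named integer vector over levels `0:ncol(matrix)`.
#' @export
support_histogram <- function(matrix) {
  matrix <- prediction_matrix(matrix)
  tab <- table(factor(rowSums(matrix), levels = 0:ncol(matrix)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read / write prediction matrices as TSV
#'
#' Format: a `gene` column followed by one 0/1 column per tool (header =
#' tool names).
#'
#' @param path File path.
#' @param matrix Prediction matrix to write.
#' @return `read_prediction_tsv()` returns a prediction matrix;
#'   `write_prediction_tsv()` returns the path invisibly.
#' @export
read_prediction_tsv <- function(path) {
  df <- read_tsv_file(path)
  if (names(df)[1] != "gene") stopf("first column of a prediction TSV must be 'gene'")
  prediction_matrix(as.matrix(df[, -1, drop = FALSE]) == 1,
                    genes = df$gene, tools = names(df)[-1])
}

#' @rdname read_prediction_tsv
#' @export
write_prediction_tsv <- function(matrix, path) {
  matrix <- prediction_matrix(matrix)
  df <- data.frame(gene = rownames(matrix),
                   matrix * 1L, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}
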