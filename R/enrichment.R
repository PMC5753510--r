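# Hypergeometric gene-set / pathway enrichment and GO-namespace grouping.

GO_NAMESPACES <- c("GO_biological_process", "GO_cellular_component",
                   "GO_molecular_function")
SET_CATEGORIES <- c("pathway", GO_NAMESPACES)

#' Construct a gene-set collection
#'
#' @param sets Named list of member symbol vectors (names = set names).
#' @param categories Optional character vector (recycled or per-set) from
#'   `pathway`, `GO_biological_process`, `GO_cellular_component`,
#'   `GO_molecular_function`; defaults to `pathway`.
#' @param universe Background gene population; defaults to the union of all
#'   members. Members must lie inside the universe.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, categories = NULL, universe = NULL) {
  if (length(sets) == 0L || is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("sets must be a non-empty named list")
  if (anyDuplicated(names(sets))) stopf("duplicate set names")
  sets <- lapply(sets, function(g) unique(toupper(trimws(g))))
  if (any(lengths(sets) == 0L)) stopf("every gene set must be non-empty")
  if (is.null(categories)) categories <- rep("pathway", length(sets))
  if (length(categories) == 1L) categories <- rep(categories, length(sets))
  if (!all(categories %in% SET_CATEGORIES))
    stopf("unknown set category; expected one of: %s", paste(SET_CATEGORIES, collapse = ", "))
  members <- sort(unique(unlist(sets)))
  if (is.null(universe)) universe <- members
  universe <- unique(toupper(trimws(universe)))
  if (!all(members %in% universe)) stopf("set members must be contained in the universe")
  structure(list(sets = sets, categories = stats::setNames(categories, names(sets)),
                 universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric gene-set enrichment
#'
#' For a query of n genes (after restriction to the universe of size N) and
#' each set of size K, the overlap k is scored with the upper-tail
#' hypergeometric probability `P[X >= k]` — identical to a one-sided Fisher
#' exact test on the 2x2 membership table. Query genes outside the universe
#' are dropped with a warning rather than inflating significance; duplicate
#' query entries are ignored.
#'
#' @param query Character vector of gene symbols.
#' @param collection A `gene_set_collection`.
#' @param alpha Significance level for the `significant` flag
#'   (`p <= alpha`, matching the inclusive threshold conventional in
#'   pathway tables).
#' @param universe Optional override of the collection's background.
#' @return Data frame sorted by ascending p: `set_name`, `category`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`, `p`,
#'   `significant`, `overlap_genes` (semicolon-joined).
#' @examples
#' coll <- gene_set_collection(list(s1 = LETTERS[1:5]), universe = LETTERS)
#' enrich("A", coll)  # single-draw tail: p = 5/26
#' @export
enrich <- function(query, collection, alpha = 0.05, universe = NULL) {
  if (!inherits(collection, "gene_set_collection"))
    stopf("collection must be a gene_set_collection")
  uni <- if (is.null(universe)) collection$universe
         else unique(toupper(trimws(universe)))
  query <- unique(toupper(trimws(query)))
  dropped <- setdiff(query, uni)
  if (length(dropped))
    warning(sprintf("%d query gene(s) outside the universe dropped: %s",
                    length(dropped), paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  query <- intersect(query, uni)
  if (length(query) == 0L) stopf("no query genes inside the universe")
  N <- length(uni); n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], uni)
    K <- length(members)
    ov <- intersect(query, members)
    k <- length(ov)
    p <- if (K == 0L) 1 else hyper_upper_tail(k, m = K, n = n, N = N)
    data.frame(set_name = nm, category = unname(collection$categories[nm]),
               overlap_count = k, set_size = K, query_size = n,
               universe_size = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p <= alpha
  out <- out[order(out$p, -out$overlap_count, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group genes by GO namespace
#'
#' Splits an annotation table into per-namespace gene groupings
#' (biological process, cellular component, molecular function); a gene
#' annotated in several namespaces appears in each, and genes with no
#' annotation are reported separately.
#'
#' @param genes Character vector of gene symbols.
#' @param annotation Data frame with columns `gene` and `annotation`
#'   (`namespace:term`, e.g. `"GO_biological_process:cell cycle"`), as read
#'   from a two-column TSV.
#' @return List with one element per namespace — a named list mapping gene
#'   to its terms — plus `unannotated`, the genes with no annotation.
#' @export
categorize_go <- function(genes, annotation) {
  genes <- unique(toupper(trimws(genes)))
  out <- stats::setNames(vector("list", length(GO_NAMESPACES)), GO_NAMESPACES)
  for (ns in GO_NAMESPACES) out[[ns]] <- list()
  annotated <- character(0)
  if (!is.null(annotation) && nrow(annotation)) {
    if (!all(c("gene", "annotation") %in% names(annotation)))
      stopf("annotation table needs 'gene' and 'annotation' columns")
    ann_gene <- toupper(trimws(annotation$gene))
    parts <- regmatches(annotation$annotation,
                        regexpr(":", annotation$annotation), invert = TRUE)
    ns <- vapply(parts, `[`, character(1), 1)
    term <- vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_, character(1))
    ok <- ann_gene %in% genes & ns %in% GO_NAMESPACES & !is.na(term)
    for (i in which(ok))
      out[[ns[i]]][[ann_gene[i]]] <- c(out[[ns[i]]][[ann_gene[i]]], term[i])
    annotated <- unique(ann_gene[ok])
  }
  out$unannotated <- setdiff(genes, annotated)
  out
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line — name, description, then tab-separated member
#' symbols.
#'
#' @param path File path.
#' @param categories,universe Passed to [gene_set_collection()] when
#'   reading.
#' @return `read_gmt()` returns a `gene_set_collection` (descriptions kept
#'   as attribute `"descriptions"`); `write_gmt()` returns the path
#'   invisibly.
#' @export
read_gmt <- function(path, categories = NULL, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stopf("GMT line %d has fewer than 3 fields", bad[1])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  coll <- gene_set_collection(sets, categories = categories, universe = universe)
  attr(coll, "descriptions") <- stats::setNames(
    vapply(fields, `[`, character(1), 2), names(sets))
  coll
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection` (or plain named list of sets).
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets else collection
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
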