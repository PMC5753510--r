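# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == trunc(x)
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators never disturb the
#' caller's random-number stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive n independent sub-stream seeds from one master seed
#'
#' Callers hand the package a single integer seed; per-study / per-document
#' randomness uses seeds drawn deterministically from it, so records are
#' reproducible without seed bookkeeping by the caller.
#' @noRd
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

#' Hypergeometric upper tail P[X >= k] in log-gamma space
#'
#' X counts successes in n draws without replacement from a population of
#' size N containing m successes. Terms are accumulated with log-sum-exp so
#' the computation survives corpus sizes where factorials overflow.
#' Vectorised over k.
#' @noRd
hyper_upper_tail <- function(k, m, n, N) {
  hi <- min(m, n)
  lo <- max(0, n + m - N)
  vapply(k, function(kk) {
    if (kk <= lo) return(1)
    if (kk > hi) return(0)
    i <- kk:hi
    lp <- lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)
    lp <- lp[is.finite(lp)]
    if (!length(lp)) return(0)
    mx <- max(lp)
    min(1, exp(mx + log(sum(exp(lp - mx)))))
  }, numeric(1))
}

#' Normalise gene symbols: upper-case, strip whitespace, optional aliases
#' @noRd
normalize_symbols <- function(x, aliases = NULL) {
  x <- toupper(trimws(as.character(x)))
  if (!is.null(aliases)) {
    if (is.null(names(aliases))) stopf("aliases must be a named character vector (alias -> canonical)")
    map <- toupper(trimws(unname(aliases)))
    names(map) <- toupper(trimws(names(aliases)))
    hit <- x %in% names(map)
    x[hit] <- map[x[hit]]
  }
  x
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
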