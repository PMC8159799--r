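#' Fold enrichment of one gene set within another
#'
#' The ratio of the observed joint frequency to the product of the marginal
#' frequencies, `prob(GPCR & Disorder) / [prob(GPCR) * prob(Disorder)]`,
#' which reduces to `k * N / (m * n)` for an overlap of `k` genes between a
#' GPCR set of size `m` and a disorder set of size `n` in a genome of `N`
#' genes.
#'
#' @param k Observed overlap count.
#' @param n Disorder set size.
#' @param m GPCR set size.
#' @param N Genome (universe) size.
#' @return Fold enrichment at full precision (reporting conventionally
#'   rounds to one decimal).
#' @export
fold_enrichment <- function(k, n, m, N) {
  if (N <= 0) stop("universe size must be positive")
  if (m <= 0 || n <= 0) stop("set sizes must be positive")
  if (k < 0 || k > min(m, n)) stop("overlap k must satisfy 0 <= k <= min(m, n)")
  k * N / (m * n)
}

#' Exact one-sided binomial tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, computed by direct summation of
#' the tail terms in log space (log-sum-exp), so that p-values on the order
#' of 1e-6 and far below are exact to working precision.
#'
#' @param k Observed count (0..n).
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return The upper-tail probability in `[0, 1]`.
#' @export
binomial_tail_p <- function(k, n, p0) {
  stopifnot(p0 >= 0, p0 <= 1, k >= 0, k <= n, n >= 0)
  if (k <= 0) return(1)
  if (p0 == 0) return(0)
  if (p0 == 1) return(1)
  i <- k:n
  lt <- lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' Construct a gene-set universe for enrichment analysis
#'
#' @param N Total number of genes in the genome.
#' @param gpcr Character vector of (6TM-)GPCR gene symbols.
#' @param disorder_sets Named list of character vectors (disorder gene
#'   lists). Duplicate symbols within any set are an error: sets must be
#'   sets.
#' @param universe Optional explicit universe of symbols; when given, all
#'   sets must be subsets of it.
#' @return Object of class `gene_set_universe`.
#' @export
gene_set_universe <- function(N, gpcr, disorder_sets, universe = NULL) {
  stopifnot(N >= 1, is.list(disorder_sets), length(disorder_sets) > 0,
            !is.null(names(disorder_sets)), all(nzchar(names(disorder_sets))))
  norm <- function(x) toupper(as.character(x))
  gpcr <- norm(gpcr)
  disorder_sets <- lapply(disorder_sets, norm)
  for (nm in names(disorder_sets))
    if (anyDuplicated(disorder_sets[[nm]]))
      stop("duplicate symbols in disorder set '", nm, "': sets must be sets")
  if (anyDuplicated(gpcr)) stop("duplicate symbols in GPCR set: sets must be sets")
  if (!is.null(universe)) {
    universe <- norm(universe)
    for (nm in names(disorder_sets))
      if (!all(disorder_sets[[nm]] %in% universe))
        stop("disorder set '", nm, "' is not a subset of the universe")
    if (!all(gpcr %in% universe)) stop("GPCR set is not a subset of the universe")
    if (length(universe) > N) stop("explicit universe larger than N")
  }
  if (N < max(length(gpcr), vapply(disorder_sets, length, 0L)))
    stop("N smaller than a member set")
  structure(list(N = as.integer(N), gpcr = gpcr,
                 disorder_sets = disorder_sets, universe = universe),
            class = "gene_set_universe")
}

#' @export
print.gene_set_universe <- function(x, ...) {
  cat("gene_set_universe: N =", x$N, ", |GPCR| =", length(x$gpcr),
      ", disorder sets:",
      paste(sprintf("%s (%d)", names(x$disorder_sets),
                    lengths(x$disorder_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Run the gene-set enrichment analysis
#'
#' For each disorder set: the overlap with the GPCR set (case-normalised
#' symbol match), the fold enrichment, and the exact one-sided binomial
#' p-value comparing the expected genome frequency of GPCR genes (`m / N`)
#' with their observed frequency among the `n` disorder genes. No
#' multiple-testing correction is applied (raw binomial p-values are
#' reported).
#'
#' @param universe A [gene_set_universe()].
#' @return `data.frame` with one row per disorder set: `disorder`, `k`,
#'   `n`, `m`, `N`, `fold`, `fold_rounded` (one decimal), `p`.
#' @export
run_enrichment <- function(universe) {
  stopifnot(inherits(universe, "gene_set_universe"))
  m <- length(universe$gpcr)
  rows <- lapply(names(universe$disorder_sets), function(nm) {
    set <- universe$disorder_sets[[nm]]
    k <- length(intersect(universe$gpcr, set))
    n <- length(set)
    fold <- fold_enrichment(k, n, m, universe$N)
    data.frame(disorder = nm, k = k, n = n, m = m, N = universe$N,
               fold = fold, fold_rounded = round(fold, 1),
               p = binomial_tail_p(k, n, m / universe$N),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
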