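#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector of per-residue hydropathy indices for the 20 standard
#' amino acids (positive = hydrophobic).
#'
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Predict transmembrane helices by sliding-window hydropathy
#'
#' Deterministic stand-in for server-based transmembrane (TM) topology
#' predictors: the mean Kyte-Doolittle hydropathy is computed in a window of
#' odd length `window` centred at every admissible residue; maximal runs of
#' centres with mean `>= threshold` become helix calls. A run that abuts the
#' first (last) admissible centre is extended to the window edge, i.e. to the
#' protein terminus, so that terminal helices are not clipped by the window
#' half-width; interior helix boundaries are the centre run itself. Calls
#' shorter than `min_len` residues are dropped; overlapping calls are merged.
#'
#' @param protein Amino-acid sequence (character). `X` is scored 0; other
#'   non-standard letters are an error.
#' @param window Sliding window length in residues (odd; default 19).
#' @param threshold Mean-hydropathy cutoff for a helix centre (default 1.6).
#' @param min_len Minimum reported helix length in residues (default 15).
#' @return `data.frame` with columns `start_res`, `end_res`,
#'   `peak_hydropathy` (max window mean within the run); zero rows if the
#'   protein is shorter than `window` or no run qualifies.
#' @export
predict_tm_helices <- function(protein, window = 19L, threshold = 1.6,
                               min_len = 15L) {
  stopifnot(window %% 2L == 1L, window >= 3L, min_len >= 1L)
  aa <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  empty <- data.frame(start_res = integer(), end_res = integer(),
                      peak_hydropathy = numeric())
  n <- length(aa)
  if (n < window) return(empty)
  h <- unname(KYTE_DOOLITTLE[aa])
  h[aa == "X"] <- 0
  if (anyNA(h)) stop("non-amino-acid character in protein sequence")
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(h))
  centers <- (half + 1L):(n - half)
  means <- (cs[centers + half + 1L] - cs[centers - half]) / window
  above <- means >= threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- which(r$values)
  calls <- lapply(keep, function(k) {
    i1 <- starts_i[k]; i2 <- ends_i[k]
    s <- centers[i1]; e <- centers[i2]
    if (i1 == 1L) s <- 1L            # run reaches first admissible centre
    if (i2 == length(centers)) e <- n # run reaches last admissible centre
    c(s, e, max(means[i1:i2]))
  })
  m <- do.call(rbind, calls)
  # merge overlapping calls (possible only via terminal extension)
  ord <- order(m[, 1L])
  m <- m[ord, , drop = FALSE]
  merged <- list(m[1L, ])
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    last <- merged[[length(merged)]]
    if (m[i, 1L] <= last[2L]) {
      last[2L] <- max(last[2L], m[i, 2L])
      last[3L] <- max(last[3L], m[i, 3L])
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- m[i, ]
  }
  m <- do.call(rbind, merged)
  m <- m[m[, 2L] - m[, 1L] + 1 >= min_len, , drop = FALSE]
  data.frame(start_res = as.integer(m[, 1L]), end_res = as.integer(m[, 2L]),
             peak_hydropathy = m[, 3L])
}
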