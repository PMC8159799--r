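# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles recompute quantities by direct per-element loops, never by
# calling the implementation's internals.

# direct O(n*w) sliding-window helix recomputation
oracle_tm_helices <- function(protein, window = 19L, threshold = 1.6,
                              min_len = 15L) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  n <- length(aa)
  empty <- data.frame(start_res = integer(), end_res = integer(),
                      peak_hydropathy = numeric())
  if (n < window) return(empty)
  h <- unname(sixtm::KYTE_DOOLITTLE[aa])
  h[aa == "X"] <- 0
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  means <- vapply(centers, function(c) mean(h[(c - half):(c + half)]),
                  numeric(1L))
  above <- means >= threshold
  calls <- list()
  i <- 1L
  while (i <= length(centers)) {
    if (above[i]) {
      j <- i
      while (j < length(centers) && above[j + 1L]) j <- j + 1L
      s <- centers[i]; e <- centers[j]
      if (i == 1L) s <- 1L
      if (j == length(centers)) e <- n
      calls[[length(calls) + 1L]] <- c(s, e, max(means[i:j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(calls)) return(empty)
  m <- do.call(rbind, calls)
  merged <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (r in 2:nrow(m)) {
    last <- nrow(merged)
    if (m[r, 1L] <= merged[last, 2L]) {
      merged[last, 2L] <- max(merged[last, 2L], m[r, 2L])
      merged[last, 3L] <- max(merged[last, 3L], m[r, 3L])
    } else merged <- rbind(merged, m[r, , drop = FALSE])
  }
  merged <- merged[merged[, 2L] - merged[, 1L] + 1 >= min_len, , drop = FALSE]
  data.frame(start_res = as.integer(merged[, 1L]),
             end_res = as.integer(merged[, 2L]),
             peak_hydropathy = merged[, 3L])
}

# per-column substitution recount
oracle_substitution_counts <- function(q, s) {
  qc <- strsplit(toupper(q), "")[[1L]]
  sc <- strsplit(toupper(s), "")[[1L]]
  lenQ <- 0L; lenS <- 0L; lenA <- 0L; TT <- 0L; TV <- 0L
  pur <- c("A", "G")
  for (i in seq_along(qc)) {
    if (qc[i] != "-") lenQ <- lenQ + 1L
    if (sc[i] != "-") lenS <- lenS + 1L
    if (qc[i] %in% c("A", "C", "G", "T") && sc[i] %in% c("A", "C", "G", "T")) {
      lenA <- lenA + 1L
      if (qc[i] != sc[i]) {
        if ((qc[i] %in% pur) == (sc[i] %in% pur)) TT <- TT + 1L
        else TV <- TV + 1L
      }
    }
  }
  list(lenQ = lenQ, lenS = lenS, lenA = lenA, TT = TT, TV = TV)
}

# exact Binomial(n, p0) upper tail by iterative convolution of Bernoulli
# distributions (no choose(), no dbinom)
oracle_binomial_tail <- function(k, n, p0) {
  dist <- 1
  for (i in seq_len(n)) {
    dist <- c(dist * (1 - p0), 0) + c(0, dist * p0)
  }
  if (k <= 0) 1 else sum(dist[(k + 1L):(n + 1L)])
}

random_protein <- function(len) {
  paste(sample(names(sixtm::KYTE_DOOLITTLE), len, replace = TRUE),
        collapse = "")
}

random_gapped_pair <- function(len, gap_p = 0.1, n_p = 0.05) {
  draw <- function() {
    x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    x[runif(len) < n_p] <- "N"
    x[runif(len) < gap_p] <- "-"
    x
  }
  list(q = paste(draw(), collapse = ""), s = paste(draw(), collapse = ""))
}

# write a tiny genome FASTA + return its path
write_tmp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

write_tmp_lines <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
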