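# hydrophobic (TM) and hydrophilic (loop/tail) residue pools with sampling
# weights; chosen so that a 21-residue TM run is unambiguous under the
# default helix predictor while loops stay below threshold
TM_RESIDUES <- c(L = 0.40, I = 0.25, V = 0.25, F = 0.10)
LOOP_RESIDUES <- c(S = 0.30, T = 0.25, G = 0.20, N = 0.15, P = 0.10)

sample_residues <- function(n, pool) {
  paste(sample(names(pool), n, replace = TRUE, prob = pool), collapse = "")
}

# evaluate code with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a synthetic 7TM receptor protein
#'
#' Constructs a canonical GPCR-like protein: a hydrophilic N-terminal tail,
#' seven hydrophobic (L/I/V/F-rich) transmembrane stretches separated by
#' hydrophilic (S/T/N/G-rich) loops, and a C-terminal tail. Loops are
#' redrawn (up to `max_redraws`) until [predict_tm_helices()] with default
#' parameters reports exactly seven helices, so the construction truth and
#' the predictor agree by design. Call within [with_seed()] or after
#' `set.seed()` for determinism.
#'
#' @param tm_len Residues per transmembrane helix (default 21).
#' @param loop_len Residues per connecting loop (default 15).
#' @param ntail_len,ctail_len Tail lengths (default 20).
#' @param max_redraws Redraw budget before erroring (default 100).
#' @return List with `sequence` and `tm` (`data.frame` of TM1..TM7 residue
#'   ranges).
#' @export
build_receptor_protein <- function(tm_len = 21L, loop_len = 15L,
                                   ntail_len = 20L, ctail_len = 20L,
                                   max_redraws = 100L) {
  stopifnot(tm_len >= 19L, loop_len >= 10L, ntail_len >= 10L)
  tm_starts <- ntail_len + (0:6) * (tm_len + loop_len) + 1L
  tm_ends <- tm_starts + tm_len - 1L
  tms <- replicate(7L, sample_residues(tm_len, TM_RESIDUES))
  for (i in seq_len(max_redraws)) {
    ntail <- sample_residues(ntail_len, LOOP_RESIDUES)
    loops <- replicate(6L, sample_residues(loop_len, LOOP_RESIDUES))
    ctail <- sample_residues(ctail_len, LOOP_RESIDUES)
    seq <- paste0(ntail, paste0(tms, c(loops, ""), collapse = ""), ctail)
    hel <- predict_tm_helices(seq)
    if (nrow(hel) == 7L) {
      return(list(sequence = seq,
                  tm = data.frame(tm = paste0("TM", 1:7),
                                  start = tm_starts, end = tm_ends)))
    }
  }
  stop("failed to construct a 7-helix protein in ", max_redraws, " redraws")
}

# reverse-translate a protein into codons, sampling synonymous codons
CODON_TABLE <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)

reverse_translate <- function(protein, fixed_codons = NULL) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- vapply(aa, function(a) {
    opts <- CODON_TABLE[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1L), USE.NAMES = FALSE)
  if (!is.null(fixed_codons))
    codons[as.integer(names(fixed_codons))] <- unname(fixed_codons)
  codons
}

# AUG/CUG/GUG-free filler (no G at all), for UTRs, introns and pads
neutral_filler <- function(n) {
  paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
}
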