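START_CODONS <- list(aug_only = "ATG", aug_gug_cug = c("ATG", "CTG", "GTG"))

# display name of a DNA start codon ("ATG" -> "AUG")
rna_codon <- function(codon) chartr("T", "U", codon)

#' Scan an mRNA for open reading frames
#'
#' Reports one open reading frame (ORF) per qualifying start codon,
#' translated with the standard genetic code. Under the `aug_gug_cug` policy
#' the near-cognate starts CUG and GUG also qualify; the initiator residue is
#' always reported as methionine, as near-cognate initiators are decoded as
#' Met by the initiator tRNA. A codon containing `N` is untranslatable and
#' terminates the scan of that ORF at that point (no stop recorded). ORFs are
#' ordered by start position.
#'
#' @param mrna mRNA sequence (character; `U` is accepted and read as `T`).
#' @param start_policy `"aug_only"` (default) or `"aug_gug_cug"`.
#' @return `data.frame` with columns `start_pos`, `stop_pos` (last base of
#'   the stop codon, or the transcript end when no stop is reached),
#'   `has_stop`, `start_codon` (RNA spelling), `peptide`. Zero rows when no
#'   qualifying start exists.
#' @export
scan_orfs <- function(mrna, start_policy = c("aug_only", "aug_gug_cug")) {
  start_policy <- match.arg(start_policy)
  seq <- chartr("Uu", "Tt", toupper(mrna))
  n <- nchar(seq)
  if (n < 3L) stop("mRNA shorter than one codon")
  starts <- START_CODONS[[start_policy]]

  empty <- data.frame(start_pos = integer(), stop_pos = integer(),
                      has_stop = logical(), start_codon = character(),
                      peptide = character(), stringsAsFactors = FALSE)

  # per-frame codon translation, computed once
  frame_info <- lapply(1:3, function(f) {
    ncod <- (n - f + 1L) %/% 3L
    if (ncod == 0L) return(NULL)
    at <- seq.int(f, by = 3L, length.out = ncod)
    codons <- substring(seq, at, at + 2L)
    aa <- Biostrings::GENETIC_CODE[codons]   # NA for codons containing N
    list(at = at, aa = aa, ncod = ncod)
  })

  hits <- lapply(starts, function(cod) {
    m <- gregexpr(cod, seq, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer() else as.integer(m)
  })
  pos <- sort(unique(unlist(hits)))
  pos <- pos[pos + 2L <= n]
  if (!length(pos)) return(empty)

  rows <- lapply(pos, function(p) {
    fr <- ((p - 1L) %% 3L) + 1L
    fi <- frame_info[[fr]]
    i0 <- (p - fr) %/% 3L + 1L
    aa <- fi$aa[i0:fi$ncod]
    stop_i <- which(aa == "*")[1L]
    bad_i <- which(is.na(aa))[1L]
    if (!is.na(bad_i) && (is.na(stop_i) || bad_i < stop_i)) {
      # N codon encountered first: ORF ends there, no stop
      pep <- aa[seq_len(bad_i - 1L)]
      has_stop <- FALSE
      stop_pos <- n
    } else if (!is.na(stop_i)) {
      pep <- aa[seq_len(stop_i - 1L)]
      has_stop <- TRUE
      stop_pos <- fi$at[i0 + stop_i - 1L] + 2L
    } else {
      pep <- aa
      has_stop <- FALSE
      stop_pos <- n
    }
    if (!length(pep)) pep <- "M"   # start codon itself encodes the initiator
    pep[1L] <- "M"                  # initiator decoded as Met
    data.frame(start_pos = p, stop_pos = stop_pos, has_stop = has_stop,
               start_codon = rna_codon(substr(seq, p, p + 2L)),
               peptide = paste(pep, collapse = ""), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$start_pos), , drop = FALSE]
}

# the single ORF starting at a given transcript position (reinitiation scan)
orf_at <- function(mrna, pos, start_policy = "aug_gug_cug") {
  orfs <- scan_orfs(mrna, start_policy)
  orfs[orfs$start_pos == pos, , drop = FALSE]
}

#' Positions of exon-exon junctions in transcript coordinates
#'
#' A junction is addressed by the transcript coordinate of the last base of
#' the upstream exon.
#'
#' @param tx A [transcript_model()].
#' @return Integer vector (length `n_exons - 1`).
#' @export
exon_junctions <- function(tx) {
  cl <- cumsum(exon_lengths(tx))
  cl[-length(cl)]
}

#' Flag a transcript/ORF pair as a nonsense-mediated decay candidate
#'
#' Applies the classical junction rule: an ORF is an NMD candidate when its
#' stop codon lies at least `junction_rule_nt` nucleotides upstream of the
#' final exon-exon junction (a premature termination codon, PTC). Single-exon
#' transcripts are never NMD candidates.
#'
#' @param tx The [transcript_model()] the ORF lives on.
#' @param orf One row of [scan_orfs()] output (must terminate at a stop).
#' @param junction_rule_nt Distance threshold in nucleotides (default 50).
#' @return Logical scalar.
#' @export
flag_nmd <- function(tx, orf, junction_rule_nt = 50L) {
  if (!isTRUE(orf$has_stop[1L]))
    stop("ORF has no stop codon; PTC status cannot be assessed")
  j <- exon_junctions(tx)
  if (!length(j)) return(FALSE)
  (j[length(j)] - orf$stop_pos[1L]) >= junction_rule_nt
}
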