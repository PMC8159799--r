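#' Construct a pairwise nucleotide alignment
#'
#' Gapped query (human role) and subject (macaque role) strings of equal
#' length over `{A,C,G,T,N,-}`.
#'
#' @param query,subject Gapped nucleotide strings.
#' @return Object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(query, subject) {
  query <- toupper(query); subject <- toupper(subject)
  if (nchar(query) != nchar(subject))
    stop("query and subject gapped lengths differ")
  if (grepl("[^ACGTN-]", query) || grepl("[^ACGTN-]", subject))
    stop("alignment contains characters outside {A,C,G,T,N,-}")
  structure(list(query = query, subject = subject),
            class = "pairwise_alignment")
}

#' Read a pairwise alignment from aligned FASTA
#'
#' @param path Aligned FASTA with exactly two records (query first).
#' @return A [pairwise_alignment()].
#' @export
read_pairwise_alignment <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L)
    stop("aligned FASTA must contain exactly 2 records, found ", length(recs))
  pairwise_alignment(as.character(recs[[1L]]), as.character(recs[[2L]]))
}

PURINES <- c("A", "G")

#' Count substitutions in a pairwise alignment
#'
#' Transitions are purine-purine or pyrimidine-pyrimidine mismatches
#' (A<->G, C<->T); every other mismatch is a transversion. Columns
#' containing a gap or `N` are excluded from the aligned length `lenA` and
#' from the counts; the ungapped lengths `lenQ`/`lenS` count all non-gap
#' residues including `N`.
#'
#' @param aln A [pairwise_alignment()].
#' @return Named list `lenQ`, `lenS`, `lenA`, `TT` (transitions), `TV`
#'   (transversions).
#' @export
substitution_counts <- function(aln) {
  q <- strsplit(aln$query, "", fixed = TRUE)[[1L]]
  s <- strsplit(aln$subject, "", fixed = TRUE)[[1L]]
  lenQ <- sum(q != "-")
  lenS <- sum(s != "-")
  ok <- q %in% c("A", "C", "G", "T") & s %in% c("A", "C", "G", "T")
  q <- q[ok]; s <- s[ok]
  mism <- q != s
  ts <- mism & ((q %in% PURINES) == (s %in% PURINES))
  list(lenQ = lenQ, lenS = lenS, lenA = sum(ok),
       TT = sum(ts), TV = sum(mism & !ts))
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]`, the substitutions-per-site
#' estimate correcting separately for the observed transition proportion `P`
#' and transversion proportion `Q`.
#'
#' @param P Observed transition fraction (transitions / aligned sites).
#' @param Q_frac Observed transversion fraction.
#' @return The distance `K` (>= 0; 0 iff `P = Q_frac = 0`).
#' @export
k2p_distance <- function(P, Q_frac) {
  if (P < 0 || Q_frac < 0 || P + Q_frac > 1)
    stop("P and Q must be non-negative fractions with P + Q <= 1")
  a <- 1 - 2 * P - Q_frac
  b <- 1 - 2 * Q_frac
  if (a <= 0 || b <= 0)
    stop("divergence saturated: Kimura two-parameter distance undefined ",
         "(1 - 2P - Q = ", signif(a, 4), ", 1 - 2Q = ", signif(b, 4), ")")
  -0.5 * log(a * sqrt(b))
}

#' Per-exon divergence statistics from a pairwise alignment
#'
#' Composes [substitution_counts()] and [k2p_distance()] into the full
#' divergence row for an exon: alignment lengths, transition/transversion
#' counts and proportions, and the K2P evolutionary rate. The same
#' computation serves untranslated (`K_u`) and coding (`K_e`) regions; the
#' `region` label is carried through unchanged.
#'
#' @param aln A [pairwise_alignment()].
#' @param exon_label Optional exon name.
#' @param region Optional region label (e.g. `"UTR"`, `"CDS"`).
#' @return `data.frame` (one row) with `exon_label`, `region`, `lenQ`,
#'   `lenS`, `lenA`, `TT`, `TV`, `P`, `Q_frac`, `K`.
#' @export
exon_divergence <- function(aln, exon_label = NA_character_,
                            region = NA_character_) {
  sc <- substitution_counts(aln)
  if (sc$lenA == 0L) stop("no aligned (gap- and N-free) columns")
  P <- sc$TT / sc$lenA
  Q <- sc$TV / sc$lenA
  data.frame(exon_label = exon_label, region = region,
             lenQ = sc$lenQ, lenS = sc$lenS, lenA = sc$lenA,
             TT = sc$TT, TV = sc$TV, P = P, Q_frac = Q,
             K = k2p_distance(P, Q), stringsAsFactors = FALSE)
}

#' Conservation summary of an exon from a score track
#'
#' Mean and standard error of the per-base conservation scores over the
#' exon's own positions. `flank_nt` names the retrieval context used when
#' conservation tracks are fetched around an exon (100 nt on both ends by
#' convention); flanking positions never enter the mean. Positions absent
#' from the track are skipped and not counted.
#'
#' @param track A [score_track()].
#' @param exon One-row `data.frame` (or list) with `chrom`, `start`, `end`
#'   and optionally `label`.
#' @param flank_nt Retrieval flank in nt (default 100; excluded from the
#'   summary).
#' @return `data.frame` with `exon_label`, `n_positions`, `mean_score`,
#'   `sem`, `sd`.
#' @export
conservation_summary <- function(track, exon, flank_nt = 100L) {
  lab <- if (!is.null(exon$label)) exon$label else NA_character_
  sc <- track_scores(track, exon$chrom, seq.int(exon$start, exon$end))
  sc <- sc[!is.na(sc)]
  n <- length(sc)
  if (n == 0L)
    stop("no scored positions in exon ", lab, " (", exon$chrom, ":",
         exon$start, "-", exon$end, ")")
  sdv <- if (n > 1L) stats::sd(sc) else 0
  data.frame(exon_label = lab, n_positions = n, mean_score = mean(sc),
             sem = sdv / sqrt(n), sd = sdv, stringsAsFactors = FALSE)
}
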