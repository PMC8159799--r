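#' Classify the receptor products a transcript can encode
#'
#' Decides which receptor products -- full-length 7TM, N-terminally
#' truncated 6TM, and/or a 1TM fragment -- a spliced transcript holds the
#' potential to code for, mirroring how experimentally observed opioid
#' receptor transcripts map to receptor types:
#'
#' * The ORF from the 5'-most qualifying start codon is translated and its
#'   helices predicted. Seven helices give a 7TM product; six helices whose
#'   alignment to the canonical receptor shows TM1 absent and TM2..TM7
#'   present give a 6TM product.
#' * If that primary ORF terminates at a premature termination codon (PTC;
#'   a stop upstream of the final exon-exon junction) with exactly one
#'   helix, a 1TM fragment is recorded and reinitiation is considered: the
#'   first AUG downstream of the PTC (which, in the opioid receptor gene
#'   architecture, is the restart methionine at the start of exon 2) is
#'   translated and accepted as a 6TM product when it yields six helices
#'   aligning to canonical TM2..TM7.
#' * The NMD candidacy of the transcript is judged on the primary ORF by
#'   [flag_nmd()].
#'
#' @param tx A [transcript_model()].
#' @param genome Sequence store covering the transcript's chromosome.
#' @param canonical_ref [isoform_record_set()] carrying the canonical
#'   receptor protein and its TM1..TM7 annotation for this gene.
#' @param start_policy Start-codon policy of [scan_orfs()]; the default
#'   `aug_only` restricts to AUG, `aug_gug_cug` admits near-cognate starts.
#' @param junction_rule_nt NMD junction rule threshold (nt, default 50).
#' @param coverage_min TM-presence threshold for the canonical alignment.
#' @param helix_args Arguments passed to [predict_tm_helices()].
#' @return List of class `topology_call`: `transcript_id`, `products`
#'   (character subset of `"7TM"`, `"6TM"`, `"1TM"`; empty when no ORF
#'   qualifies), `nmd_candidate`, `orfs` (supporting ORF rows), and
#'   `helix_counts` (named per product).
#' @export
classify_products <- function(tx, genome, canonical_ref,
                              start_policy = c("aug_only", "aug_gug_cug"),
                              junction_rule_nt = 50L, coverage_min = 0.5,
                              helix_args = list()) {
  start_policy <- match.arg(start_policy)
  if (!is.na(tx$gene) && !is.na(canonical_ref$gene) &&
      tx$gene != canonical_ref$gene)
    stop("transcript ", tx$id, " does not map to gene ", canonical_ref$gene)
  mrna <- spliced_sequence(tx, genome)
  orfs <- scan_orfs(mrna, start_policy)
  empty_call <- structure(
    list(transcript_id = tx$id, products = character(0),
         nmd_candidate = FALSE, orfs = orfs[0, ], helix_counts = integer(0)),
    class = "topology_call")
  if (nrow(orfs) == 0L) return(empty_call)

  canon <- canonical_ref$canonical
  pattern_6tm <- function(pep) {
    p <- tm_presence(align_isoform(canon$sequence, pep), canon$tm, coverage_min)
    !p[1L] && all(p[2:7])
  }

  primary <- orfs[1L, , drop = FALSE]   # 5'-most qualifying start
  hel <- do.call(predict_tm_helices, c(list(primary$peptide), helix_args))
  k <- nrow(hel)
  j <- exon_junctions(tx)
  is_ptc <- isTRUE(primary$has_stop) && length(j) > 0L &&
    primary$stop_pos <= j[length(j)]

  products <- character(0)
  helix_counts <- integer(0)
  support <- primary
  if (k == 7L) {
    products <- "7TM"; helix_counts <- c("7TM" = 7L)
  } else if (k == 6L && nchar(primary$peptide) >= 19L &&
             pattern_6tm(primary$peptide)) {
    products <- "6TM"; helix_counts <- c("6TM" = 6L)
  } else if (k == 1L && is_ptc) {
    products <- "1TM"; helix_counts <- c("1TM" = 1L)
    # reinitiation: first AUG downstream of the PTC
    atg <- gregexpr("ATG", chartr("U", "T", toupper(mrna)), fixed = TRUE)[[1L]]
    atg <- atg[atg > primary$stop_pos]
    if (length(atg)) {
      re_orf <- orf_at(mrna, atg[1L],
                       if (start_policy == "aug_only") "aug_only" else "aug_gug_cug")
      if (nrow(re_orf)) {
        hel2 <- do.call(predict_tm_helices, c(list(re_orf$peptide), helix_args))
        if (nrow(hel2) == 6L && pattern_6tm(re_orf$peptide)) {
          products <- c(products, "6TM")
          helix_counts <- c(helix_counts, "6TM" = 6L)
          support <- rbind(primary, re_orf)
        }
      }
    }
  }
  nmd <- if (isTRUE(primary$has_stop))
    flag_nmd(tx, primary, junction_rule_nt) else FALSE
  structure(list(transcript_id = tx$id, products = products,
                 nmd_candidate = nmd, orfs = support,
                 helix_counts = helix_counts),
            class = "topology_call")
}

#' @export
print.topology_call <- function(x, ...) {
  cat("topology_call", x$transcript_id, ": products {",
      paste(x$products, collapse = ", "), "}",
      if (x$nmd_candidate) "[NMD candidate]" else "", "\n")
  invisible(x)
}
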