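#' The published N-terminally truncated 6TM GPCR gene list
#'
#' The twelve human genes with annotated transcripts coding for
#' N-terminally truncated 6TM receptor variants, four of which are opioid
#' receptors (OPRD1, OPRK1, OPRL1, OPRM1).
#'
#' @return Character vector of 12 gene symbols.
#' @export
sixtm_truncated_genes <- function() {
  c("CCKAR", "CCKBR", "GLP2R", "OPRD1", "OPRK1", "OPRL1", "OPRM1",
    "OR2AJ1", "OR56A5", "OR9Q2", "QRFPR", "TACR2")
}

#' Synthetic stand-in for the disorder and GPCR gene lists
#'
#' The full pain / psychiatric-disorder / addiction gene lists and the
#' 824-gene GPCR list are supplementary data that are not part of this
#' package; this function reconstructs a synthetic universe that reproduces
#' every published marginal of those lists exactly: set sizes 800 (pain),
#' 1383 (psychiatric), 383 (addiction) and 824 (GPCR) in a genome of 19,020
#' genes; overlaps of the 12-gene 6TM list with the disorder sets of 7, 4
#' and 3; and all-GPCR overlaps of 118 (pain) and 96 (psychiatric) -- the
#' integer counts implied by the published ~3.4-fold and ~1.6-fold
#' enrichments -- with a chance-level 17 for addiction (not enriched). The
#' 12 6TM symbols are the real published ones; every filler symbol is
#' synthetic (`GPCRS*`, `PAINS*`, `PSYCS*`, `ADDIS*`). Which individual 6TM
#' genes fall in which disorder list is not published; opioid receptors are
#' assigned first, which has no effect on any computed statistic.
#'
#' @return List with `sixtm` and `gpcr`, both [gene_set_universe()] objects
#'   sharing the same disorder sets (GPCR set = 12-gene 6TM list and
#'   824-gene GPCR list, respectively), plus the component gene lists.
#' @export
synthetic_supplementary_gene_sets <- function() {
  sixtm <- sixtm_truncated_genes()
  oprs <- c("OPRM1", "OPRD1", "OPRK1", "OPRL1")
  gpcr_fill <- sprintf("GPCRS%03d", 1:812)
  gpcr <- c(sixtm, gpcr_fill)
  pain <- c(c(oprs, "CCKBR", "TACR2", "QRFPR"),          # 7 of the 12
            gpcr_fill[1:111],                            # 118 GPCRs in total
            sprintf("PAINS%03d", 1:682))                 # n = 800
  psych <- c(oprs,                                       # 4 of the 12
             gpcr_fill[1:92],                            # 96 GPCRs in total
             sprintf("PSYCS%04d", 1:1287))               # n = 1383
  addiction <- c(oprs[1:3],                              # 3 of the 12
                 gpcr_fill[1:14],                        # 17 GPCRs: chance level
                 sprintf("ADDIS%03d", 1:366))            # n = 383
  N <- 19020L
  sets <- list(pain = pain, psychiatric = psych, addiction = addiction)
  list(sixtm = gene_set_universe(N, sixtm, sets),
       gpcr = gene_set_universe(N, gpcr, sets),
       sixtm_genes = sixtm, gpcr_genes = gpcr,
       disorder_sets = sets)
}
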