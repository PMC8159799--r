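#' Generate a splice-isoform benchmark with planted truncation truth
#'
#' One synthetic receptor gene per requested isoform, each gene carrying a
#' fresh canonical 7TM protein and one isoform of the planted category.
#' Truncations are whole-TM deletions with a 5-residue margin into the
#' neighbouring loop, so alignment-based TM-presence calls are unambiguous:
#'
#' * `full`: isoform identical to the canonical (truth `full_7TM`).
#' * `N_trunc_6TM` / `N_trunc_5TM`: N-terminus through TM1 (TM1-TM2)
#'   deleted plus margin.
#' * `C_trunc_6TM` / `C_trunc_5TM`: TM7 (TM6-TM7) through C-terminus
#'   deleted plus margin.
#' * `rescue`: TM1 and margin deleted but replaced by a fresh hydrophobic
#'   run -- the isoform still folds seven helices (truth `full_7TM`).
#' * `fragment`: a fragment-flagged record (truth `excluded_fragment`,
#'   excluded before analysis).
#'
#' @param seed Integer seed.
#' @param category_mix Named integer vector over the categories above
#'   (default: 3 `N_trunc_6TM`, 2 `C_trunc_6TM`, 5 `full`).
#' @return List with `records` (list of [isoform_record_set()]) and `truth`
#'   (`data.frame` of `gene`, `isoform_id`, `category`).
#' @export
gen_isoform_benchmark <- function(seed,
                                  category_mix = c(N_trunc_6TM = 3L,
                                                   C_trunc_6TM = 2L,
                                                   full = 5L)) {
  known <- c("full", "N_trunc_6TM", "C_trunc_6TM", "N_trunc_5TM",
             "C_trunc_5TM", "rescue", "fragment")
  bad <- setdiff(names(category_mix), known)
  if (length(bad)) stop("unknown isoform category: ", bad[1L])
  cats <- rep(names(category_mix), category_mix)
  with_seed(seed, {
    cats <- sample(cats)   # shuffle category-to-gene assignment
    margin <- 5L
    records <- list()
    truth <- list()
    for (i in seq_along(cats)) {
      gene <- sprintf("SIMG%03d", i)
      prot <- build_receptor_protein()
      seq <- prot$sequence
      tm <- prot$tm
      n <- nchar(seq)
      cat_i <- cats[i]
      iso_seq <- switch(cat_i,
        full = seq,
        N_trunc_6TM = substr(seq, tm$end[1L] + margin + 1L, n),
        N_trunc_5TM = substr(seq, tm$end[2L] + margin + 1L, n),
        C_trunc_6TM = substr(seq, 1L, tm$start[7L] - margin - 1L),
        C_trunc_5TM = substr(seq, 1L, tm$start[6L] - margin - 1L),
        rescue = paste0(sample_residues(21L, TM_RESIDUES),
                        substr(seq, tm$end[1L] + margin + 1L, n)),
        fragment = substr(seq, 1L, tm$end[3L]))
      truth_cat <- switch(cat_i,
        full = "full_7TM", rescue = "full_7TM",
        fragment = "excluded_fragment", cat_i)
      iso_id <- paste0(gene, "_iso1")
      records[[gene]] <- isoform_record_set(
        gene, seq, tm$start, tm$end,
        data.frame(id = iso_id, sequence = iso_seq,
                   fragment = (cat_i == "fragment")))
      truth[[gene]] <- data.frame(gene = gene, isoform_id = iso_id,
                                  planted = cat_i, category = truth_cat,
                                  stringsAsFactors = FALSE)
    }
    list(records = records, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}

#' Generate an evolved alignment pair under the two-parameter model
#'
#' Each site independently carries a transition with probability `P_target`,
#' a transversion with probability `Q_target` (both transversion partners
#' equiprobable), and is otherwise identical, so the planted proportions are
#' realised-proportion targets and the closed-form
#' [k2p_distance()]`(P_target, Q_target)` is the exact oracle for the
#' estimator. No indels are introduced.
#'
#' @param seed Integer seed.
#' @param length Alignment length in nt (>= 100).
#' @param P_target Per-site transition probability.
#' @param Q_target Per-site transversion probability
#'   (`P_target + Q_target < 0.5`).
#' @return List with `aln` (a [pairwise_alignment()]), `P_target`,
#'   `Q_target`, `K_expected`.
#' @export
gen_k2p_pair <- function(seed, length = 10000L, P_target = 0.05,
                         Q_target = 0.02) {
  stopifnot(length >= 100L, P_target >= 0, Q_target >= 0)
  if (P_target + Q_target >= 0.5)
    stop("P_target + Q_target must be < 0.5 (clear of saturation)")
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  with_seed(seed, {
    anc <- sample(bases, length, replace = TRUE)
    u <- stats::runif(length)
    der <- anc
    is_ts <- u < P_target
    is_tv <- !is_ts & u < P_target + Q_target
    der[is_ts] <- transition[anc[is_ts]]
    pick <- stats::runif(sum(is_tv)) < 0.5
    der[is_tv] <- mapply(function(b, first) transversions[[b]][if (first) 1L else 2L],
                         anc[is_tv], pick)
    list(aln = pairwise_alignment(paste(anc, collapse = ""),
                                  paste(der, collapse = "")),
         P_target = P_target, Q_target = Q_target,
         K_expected = if (P_target + Q_target > 0)
           k2p_distance(P_target, Q_target) else 0)
  })
}

#' Generate a synthetic conservation score track
#'
#' Beta-distributed per-base scores with optional highly conserved regions,
#' emulating the bimodal look of PhastCons tracks (background near 0,
#' conserved elements near 1).
#'
#' @param seed Integer seed.
#' @param chrom Chromosome id.
#' @param length Track length (positions `1..length`).
#' @param conserved `data.frame` with `start`, `end` rows to score from the
#'   high component, or `NULL`.
#' @return A [score_track()].
#' @export
gen_score_track <- function(seed, chrom = "chrSim", length = 1000L,
                            conserved = NULL) {
  with_seed(seed, {
    sc <- stats::rbeta(length, 0.5, 8)
    if (!is.null(conserved)) {
      for (i in seq_len(nrow(conserved))) {
        idx <- conserved$start[i]:conserved$end[i]
        sc[idx] <- stats::rbeta(length(idx), 8, 0.5)
      }
    }
    score_track(chrom, seq_len(length), sc)
  })
}

#' Generate a gene universe with planted (or null) overlap
#'
#' Synthetic gene symbols with a GPCR set of size `m` and one disorder set
#' of size `n` overlapping in exactly `k_planted` genes; when `k_planted` is
#' `NULL` the overlap is drawn from the null hypergeometric distribution
#' `Hyper(N, m, n)` (chance co-membership).
#'
#' @param seed Integer seed.
#' @param N Universe size.
#' @param m GPCR set size.
#' @param n Disorder set size.
#' @param k_planted Planted overlap (`<= min(m, n)`), or `NULL` for a null
#'   draw.
#' @param disorder_name Name of the disorder set.
#' @return List with `universe` (a [gene_set_universe()]) and `k_planted`
#'   (the realised overlap).
#' @export
gen_enrichment_universe <- function(seed, N, m, n, k_planted = NULL,
                                    disorder_name = "disorder") {
  stopifnot(N >= 2, m >= 1, n >= 1, m + n - min(m, n) <= N)
  with_seed(seed, {
    k <- if (is.null(k_planted)) stats::rhyper(1L, m, N - m, n)
    else as.integer(k_planted)
    if (k > min(m, n) || n - k > N - m)
      stop("infeasible planted overlap k = ", k)
    symbols <- sprintf("SYNG%05d", seq_len(N))
    gpcr <- sample(symbols, m)
    others <- setdiff(symbols, gpcr)
    disorder <- c(sample(gpcr, k), sample(others, n - k))
    universe <- gene_set_universe(N, gpcr,
                                  stats::setNames(list(disorder), disorder_name),
                                  universe = symbols)
    list(universe = universe, k_planted = k)
  })
}
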