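#' Which canonical TM domains survive in an aligned isoform?
#'
#' TMk is called present when at least `coverage_min` of its canonical
#' residues align to non-gap isoform residues (mismatches count as aligned).
#' The fractional criterion tolerates splice-boundary shifts inside helices
#' while rejecting whole-helix deletions.
#'
#' @param aln An [align_isoform()] result.
#' @param tm_domains `data.frame` with columns `start`, `end`: the 7
#'   canonical TM residue ranges (1-based inclusive).
#' @param coverage_min Minimum aligned fraction (default 0.5).
#' @return Logical vector of length 7 named TM1..TM7.
#' @export
tm_presence <- function(aln, tm_domains, coverage_min = 0.5) {
  stopifnot(nrow(tm_domains) == 7L)
  cc <- strsplit(aln$aligned_canonical, "", fixed = TRUE)[[1L]]
  ci <- strsplit(aln$aligned_isoform, "", fixed = TRUE)[[1L]]
  res_col <- which(cc != "-")           # column of each canonical residue
  if (max(tm_domains$end) > length(res_col))
    stop("TM domain outside the canonical sequence")
  out <- vapply(seq_len(7L), function(k) {
    cols <- res_col[tm_domains$start[k]:tm_domains$end[k]]
    mean(ci[cols] != "-") >= coverage_min
  }, logical(1L))
  stats::setNames(out, paste0("TM", 1:7))
}

#' Extract candidate replacement segments for absent TM domains
#'
#' For each absent TM, returns the maximal isoform-only run (isoform residue
#' opposite canonical gap) adjacent to that TM's alignment columns -- the
#' alternative sequence that replaced the helix, to be tested for de novo
#' helix-forming potential. Empty string when no adjacent insertion exists.
#'
#' @param aln An [align_isoform()] result.
#' @param tm_domains Canonical TM ranges as in [tm_presence()].
#' @param presence Logical 7-vector from [tm_presence()].
#' @return Character vector of length 7 (empty strings for present TMs).
#' @export
replaced_segments <- function(aln, tm_domains, presence) {
  cc <- strsplit(aln$aligned_canonical, "", fixed = TRUE)[[1L]]
  ci <- strsplit(aln$aligned_isoform, "", fixed = TRUE)[[1L]]
  res_col <- which(cc != "-")
  ins <- cc == "-" & ci != "-"
  r <- rle(ins)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  ins_runs <- cbind(run_start, run_end)[r$values, , drop = FALSE]
  out <- rep("", 7L)
  for (k in which(!presence)) {
    span <- res_col[tm_domains$start[k]:tm_domains$end[k]]
    # an insertion run is adjacent when it abuts or overlaps the TM's columns
    adj <- ins_runs[ins_runs[, 2L] >= min(span) - 1L &
                    ins_runs[, 1L] <= max(span) + 1L, , drop = FALSE]
    if (nrow(adj)) {
      best <- adj[which.max(adj[, 2L] - adj[, 1L]), ]
      out[k] <- paste(ci[best[1L]:best[2L]], collapse = "")
    }
  }
  stats::setNames(out, paste0("TM", 1:7))
}

#' Classify a splice isoform's truncation pattern
#'
#' An absent TM whose replacement segment itself forms a predicted helix
#' (see [predict_tm_helices()]) is counted as rescued: the isoform is not
#' truncated at that position. The category is assigned from the effective
#' TM count after rescue: missing TM1 gives the N-terminal series, missing
#' TM7 (with TM1 intact) the C-terminal series.
#'
#' @param presence Logical 7-vector from [tm_presence()].
#' @param replaced Character 7-vector from [replaced_segments()] (or `NULL`
#'   to skip the rescue check).
#' @param isoform_id Identifier carried into the result.
#' @param helix_args List of arguments passed to [predict_tm_helices()] for
#'   the rescue check.
#' @return List of class `truncation_call` with fields `isoform_id`,
#'   `tm_present` (after rescue), `n_tm`, `category` (one of `full_7TM`,
#'   `N_trunc_6TM`, `C_trunc_6TM`, `N_trunc_5TM`, `C_trunc_5TM`, `other`),
#'   `de_novo_helix_rescue`.
#' @export
classify_truncation <- function(presence, replaced = NULL,
                                isoform_id = NA_character_,
                                helix_args = list()) {
  stopifnot(length(presence) == 7L)
  rescued <- rep(FALSE, 7L)
  if (!is.null(replaced)) {
    for (k in which(!presence & nzchar(replaced))) {
      hel <- do.call(predict_tm_helices, c(list(replaced[[k]]), helix_args))
      if (nrow(hel) > 0L) rescued[k] <- TRUE
    }
  }
  eff <- presence | rescued
  n_tm <- sum(eff)
  category <-
    if (all(eff)) "full_7TM"
    else if (!eff[1L] && n_tm == 6L) "N_trunc_6TM"
    else if (!eff[7L] && n_tm == 6L) "C_trunc_6TM"
    else if (!eff[1L] && n_tm == 5L) "N_trunc_5TM"
    else if (!eff[7L] && n_tm == 5L) "C_trunc_5TM"
    else "other"
  structure(list(isoform_id = isoform_id,
                 tm_present = stats::setNames(eff, paste0("TM", 1:7)),
                 n_tm = n_tm, category = category,
                 de_novo_helix_rescue = any(rescued)),
            class = "truncation_call")
}

#' @export
print.truncation_call <- function(x, ...) {
  cat("truncation_call", x$isoform_id, ":", x$category, "(", x$n_tm, "TM",
      if (x$de_novo_helix_rescue) ", de novo rescue" else "", ")\n")
  invisible(x)
}

#' Run the splice-isoform truncation screen
#'
#' For every non-fragment isoform of every gene: align to the canonical
#' receptor, map the seven TM domains across the alignment, test replacement
#' segments of absent TMs for de novo helix potential, and classify. The
#' selection mirrors the screen's rule: isoforms with at least 4 TM helices
#' that miss the first or the seventh helix. Isoforms flagged as fragments
#' are excluded before analysis (category `excluded_fragment`, never
#' selected).
#'
#' @param records List of [isoform_record_set()] objects.
#' @param coverage_min Aligned-fraction threshold for TM presence.
#' @param helix_args Arguments for the rescue helix prediction.
#' @return List with `calls` (data.frame over all isoforms: `gene`,
#'   `isoform_id`, `category`, `n_tm`, TM1..TM7 presence, `rescue`,
#'   `selected`), `selected` (the selected subset), and `summary`
#'   (category counts).
#' @export
run_screen <- function(records, coverage_min = 0.5, helix_args = list()) {
  rows <- list()
  for (rec in records) {
    tm <- rec$canonical$tm
    for (i in seq_len(nrow(rec$isoforms))) {
      iso <- rec$isoforms[i, ]
      if (iso$fragment) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = rec$gene, isoform_id = iso$id, category = "excluded_fragment",
          n_tm = NA_integer_, t(stats::setNames(rep(NA, 7L), paste0("TM", 1:7))),
          rescue = NA, selected = FALSE)
        next
      }
      aln <- align_isoform(rec$canonical$sequence, iso$sequence)
      pres <- tm_presence(aln, tm, coverage_min)
      repl <- replaced_segments(aln, tm, pres)
      call <- classify_truncation(pres, repl, iso$id, helix_args)
      sel <- call$n_tm >= 4L && (!call$tm_present[1L] || !call$tm_present[7L])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = rec$gene, isoform_id = iso$id, category = call$category,
        n_tm = call$n_tm, t(call$tm_present), rescue = call$de_novo_helix_rescue,
        selected = sel)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene = character(), isoform_id = character(),
                  category = character(), n_tm = integer(), rescue = logical(),
                  selected = logical())
  rownames(calls) <- NULL
  list(calls = calls,
       selected = calls[which(calls$selected), , drop = FALSE],
       summary = as.data.frame(table(category = calls$category),
                               responseName = "n"))
}
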