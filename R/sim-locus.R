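#' Generate a planted 7TM receptor locus with its transcript variants
#'
#' Emulates the architecture shared by the opioid receptor genes: exon 1
#' carries the canonical start codon, the N-terminal tail and the first
#' transmembrane domain(s); exons 2-3 carry TM2..TM7; a cassette exon
#' between exons 1 and 2 introduces a premature termination codon (PTC).
#' Three transcripts are produced with construction truth labels:
#'
#' * `canonical_7TM` (exons 1-2-3): full-length receptor, `{7TM}`.
#' * `exon1_skipped_6TM` (exons 2-3): starts at the in-frame AUG planted as
#'   the first codon of exon 2, `{6TM}`.
#' * `cassette_PTC_1TM6TM` (exons 1-cassette-2-3, when `cassette_ptc`):
#'   the exon-1 ORF runs into a PTC inside the cassette after TM1, giving a
#'   1TM fragment, an NMD-candidate flag, and a reinitiated 6TM from exon 2:
#'   `{1TM, 6TM}`.
#'
#' Untranslated regions, introns and pads are built without any `G`, so no
#' incidental AUG/CUG/GUG start can precede the planted ones. The generator
#' verifies its own truth (7 helices on the canonical protein, exactly one
#' on the 1TM fragment peptide) and redraws hydrophilic segments on
#' violation; it is fully deterministic in `seed`.
#'
#' @param seed Integer seed.
#' @param n_tm_exon1 Number of TM domains encoded by exon 1 (default 1).
#' @param tm_len,loop_len Protein geometry passed to
#'   [build_receptor_protein()].
#' @param cassette_ptc Include the PTC cassette exon and its transcript
#'   (default `TRUE`).
#' @param utr_len Length of the 5' and 3' UTRs in nt (default 60).
#' @param strand Strand to place the locus on (default `"+"`).
#' @param out_dir If non-`NULL`, write `genome.fa`, `transcripts.gtf`,
#'   `canonical_records.tsv` and `truth.json` there.
#' @return List of class `receptor_locus`: `genome` (`DNAStringSet`),
#'   `models` (named list of [transcript_model()]), `canonical_record`
#'   ([isoform_record_set()]), `protein`, `truth` (per-transcript expected
#'   products and NMD flag, schema-versioned), `seed`.
#' @export
gen_receptor_locus <- function(seed, n_tm_exon1 = 1L, tm_len = 21L,
                               loop_len = 15L, cassette_ptc = TRUE,
                               utr_len = 60L, strand = "+", out_dir = NULL) {
  stopifnot(n_tm_exon1 >= 1L, n_tm_exon1 <= 6L, utr_len >= 10L,
            strand %in% c("+", "-"))
  with_seed(seed, {
    ntail_len <- 20L
    # exon 1 ends a few residues into the loop after the last exon-1 TM;
    # exon 2 begins with a planted in-frame methionine (restart codon)
    split1 <- ntail_len + n_tm_exon1 * tm_len + (n_tm_exon1 - 1L) * loop_len + 4L
    restart <- split1 + 1L
    protein <- NULL
    for (redraw in 1:100) {
      prot <- build_receptor_protein(tm_len, loop_len, ntail_len = ntail_len)
      aa <- strsplit(prot$sequence, "", fixed = TRUE)[[1L]]
      aa[restart] <- "M"
      cand <- paste(aa, collapse = "")
      if (nrow(predict_tm_helices(cand)) == 7L) { protein <- cand; break }
    }
    if (is.null(protein)) stop("locus verification failed after 100 redraws")
    n_res <- nchar(protein)
    # exon 2/3 boundary: mid-way through the remaining residues
    split2 <- restart + ((n_res - restart) %/% 2L)

    # 1TM fragment peptide of the cassette transcript: exon-1 residues plus
    # the cassette-encoded hydrophilic stretch before its PTC
    cass_res_n <- 8L
    for (redraw in 1:100) {
      cass_res <- sample_residues(cass_res_n, LOOP_RESIDUES)
      frag_pep <- paste0(substr(protein, 1L, split1), cass_res)
      if (nrow(predict_tm_helices(frag_pep)) == n_tm_exon1) break
      if (redraw == 100) stop("locus verification failed after 100 redraws")
    }

    codons <- reverse_translate(protein,
                                fixed_codons = stats::setNames("ATG", restart))
    codons[1L] <- "ATG"   # canonical initiator
    exon1_cds <- paste(codons[1:split1], collapse = "")
    exon2_cds <- paste(codons[restart:split2], collapse = "")
    exon3_cds <- paste(codons[(split2 + 1L):n_res], collapse = "")
    cassette_seq <- paste0(paste(reverse_translate(cass_res), collapse = ""),
                           "TAA", neutral_filler(30L))

    utr5 <- neutral_filler(utr_len)
    utr3 <- neutral_filler(utr_len)
    exon1_seq <- paste0(utr5, exon1_cds)
    exon3_seq <- paste0(exon3_cds, "TAA", utr3)
    pad <- 50L; intron <- 80L
    parts <- c(neutral_filler(pad), exon1_seq, neutral_filler(intron),
               cassette_seq, neutral_filler(intron), exon2_cds,
               neutral_filler(intron), exon3_seq, neutral_filler(pad))
    chrom_seq <- paste(parts, collapse = "")
    starts <- cumsum(c(1L, nchar(parts)))[seq_along(parts)]
    iv <- function(i) c(starts[i], starts[i] + nchar(parts[i]) - 1L)
    ex1 <- iv(2L); cas <- iv(4L); ex2 <- iv(6L); ex3 <- iv(8L)

    L <- nchar(chrom_seq)
    if (strand == "-") {
      chrom_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(chrom_seq)))
      flip <- function(x) c(L - x[2L] + 1L, L - x[1L] + 1L)
      ex1 <- flip(ex1); cas <- flip(cas); ex2 <- flip(ex2); ex3 <- flip(ex3)
    }
    chrom <- "chrSim"
    genome <- Biostrings::DNAStringSet(stats::setNames(chrom_seq, chrom))
    gene <- "SIMOPR"
    exon_df <- function(ivs, labels)
      data.frame(chrom = chrom, start = vapply(ivs, `[`, 0L, 1L),
                 end = vapply(ivs, `[`, 0L, 2L), label = labels)
    models <- list(
      canonical_7TM = transcript_model(
        "canonical_7TM", exon_df(list(ex1, ex2, ex3),
                                 c("exon1", "exon2", "exon3")),
        strand, gene),
      exon1_skipped_6TM = transcript_model(
        "exon1_skipped_6TM", exon_df(list(ex2, ex3), c("exon2", "exon3")),
        strand, gene))
    truth <- list(
      canonical_7TM = list(products = "7TM", nmd_candidate = FALSE),
      exon1_skipped_6TM = list(products = "6TM", nmd_candidate = FALSE))
    if (cassette_ptc) {
      models$cassette_PTC_1TM6TM <- transcript_model(
        "cassette_PTC_1TM6TM",
        exon_df(list(ex1, cas, ex2, ex3),
                c("exon1", "cassette", "exon2", "exon3")),
        strand, gene)
      truth$cassette_PTC_1TM6TM <- list(products = c("1TM", "6TM"),
                                        nmd_candidate = TRUE)
    }
    rec <- isoform_record_set(gene, protein, prot$tm$start, prot$tm$end)
    locus <- structure(
      list(genome = genome, models = models, canonical_record = rec,
           protein = protein, seed = seed,
           truth = list(schema_version = "1.0", seed = seed,
                        transcripts = truth)),
      class = "receptor_locus")
    if (!is.null(out_dir)) write_locus(locus, out_dir)
    locus
  })
}

#' @export
print.receptor_locus <- function(x, ...) {
  cat("receptor_locus (seed", x$seed, "):",
      BiocGenerics::width(x$genome)[1L], "nt genome,",
      length(x$models), "transcript(s)\n")
  invisible(x)
}

#' Write a generated locus to standard formats
#'
#' Emits `genome.fa` (FASTA), `transcripts.gtf` (GTF),
#' `canonical_records.tsv` (isoform record schema) and `truth.json`
#' (versioned truth labels) into `dir`.
#'
#' @param locus A [gen_receptor_locus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(locus$genome, file.path(dir, "genome.fa"))
  write_gtf(locus$models, file.path(dir, "transcripts.gtf"))
  write_isoform_records(list(locus$canonical_record),
                        file.path(dir, "canonical_records.tsv"))
  jsonlite::write_json(locus$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
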