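#' Read a genome (or transcript) FASTA into a validated sequence store
#'
#' Sequences are uppercased and restricted to the alphabet `A,C,G,T,N`.
#' `N` bases are allowed and propagate into spliced transcripts, where any
#' codon containing `N` is untranslatable.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no sequences: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  validate_genome(seqs)
}

#' @keywords internal
validate_genome <- function(seqs) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("genome sequences must be named by chromosome id")
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  freq <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(bad > 0L))
    stop("sequence ", names(seqs)[which(bad > 0L)[1L]],
         " contains characters outside {A,C,G,T,N}")
  if (any(BiocGenerics::width(seqs) == 0L)) stop("empty sequence in genome")
  seqs
}

#' Construct a transcript model
#'
#' A transcript model is an ordered set of exon intervals (1-based, closed,
#' GTF convention) on one strand of one chromosome. Exons are stored in
#' transcription order, i.e. 5' to 3' in the orientation of the transcript:
#' ascending genomic start on `+`, descending on `-`.
#'
#' @param id Transcript identifier.
#' @param exons `data.frame` with columns `chrom`, `start`, `end` and
#'   optionally `label` (exon names such as `"exon 13b"`).
#' @param strand `"+"` or `"-"`.
#' @param gene Gene symbol.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, exons, strand, gene = NA_character_) {
  stopifnot(is.data.frame(exons), all(c("chrom", "start", "end") %in% names(exons)))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (nrow(exons) == 0L) stop("transcript ", id, " has no exons")
  if (length(unique(exons$chrom)) != 1L)
    stop("transcript ", id, ": exons span multiple chromosomes")
  if (any(exons$start > exons$end) || any(exons$start < 1L))
    stop("transcript ", id, ": invalid exon interval")
  if (is.null(exons$label)) exons$label <- paste0("exon", seq_len(nrow(exons)))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  # transcription order: 5'->3' in transcript orientation
  ord <- order(exons$start, decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  genomic <- exons[order(exons$start), , drop = FALSE]
  if (nrow(genomic) > 1L &&
      any(genomic$start[-1L] <= genomic$end[-nrow(genomic)]))
    stop("transcript ", id, ": overlapping exons")
  structure(list(id = id, gene = gene, strand = strand, exons = exons),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$id, "(", x$gene, ")", x$strand, "strand,",
      nrow(x$exons), "exon(s),", sum(exon_lengths(x)), "nt\n")
  invisible(x)
}

#' @keywords internal
exon_lengths <- function(tx) tx$exons$end - tx$exons$start + 1L

# fail early on tab-count errors so the user gets a line number; the heavy
# parsing is then delegated to rtracklayer
precheck_columns <- function(path, n_required, comment_prefixes = c("#", "track", "browser")) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl(paste0("^(", paste(comment_prefixes, collapse = "|"), ")"), lines) &
    nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  bad <- which(keep)[!(nf %in% n_required)]
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path, ": expected ",
         paste(n_required, collapse = " or "), " tab-separated fields")
  invisible(TRUE)
}

#' Load transcript models and their genome
#'
#' Reads exon structures from GTF/GFF3 (1-based closed coordinates, kept
#' as-is) or BED (0-based half-open, converted to 1-based closed at this
#' boundary) together with the genome FASTA they refer to. In GTF/GFF input,
#' exons are grouped into transcripts by the `transcript_id` attribute; in
#' 6-column BED, lines sharing a name form one transcript (each line one
#' exon); 3-column BED yields one single-exon transcript per line.
#'
#' @param annotation_file Path to a GTF/GFF3 (`.gtf`, `.gff`, `.gff3`) or BED
#'   (`.bed`) file.
#' @param genome Path to the matching FASTA file, or an already loaded
#'   sequence store.
#' @return A list with elements `models` (list of [transcript_model()]) and
#'   `genome` (a `DNAStringSet`).
#' @export
load_gene_models <- function(annotation_file, genome) {
  gen <- if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    read_genome_fasta(genome) else validate_genome(genome)
  ext <- tolower(tools::file_ext(annotation_file))
  if (ext %in% c("gtf", "gff", "gff3")) {
    precheck_columns(annotation_file, 9L)
    gr <- rtracklayer::import(annotation_file,
                              format = if (ext == "gtf") "gtf" else "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) == "exon"]
    if (length(gr) == 0L) stop("no exon records in ", annotation_file)
    txid <- as.character(gr$transcript_id)
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      gene = if (!is.null(gr$gene_id)) as.character(gr$gene_id) else NA_character_,
      label = if (!is.null(gr$exon_id)) as.character(gr$exon_id) else NA_character_,
      tx = txid, stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    precheck_columns(annotation_file, c(3L, 6L))
    gr <- rtracklayer::import(annotation_file, format = "bed")
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr),   # rtracklayer converts to 1-based closed
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      gene = NA_character_, label = NA_character_,
      tx = if (!is.null(gr$name)) as.character(gr$name)
           else paste0("interval_", seq_along(gr)),
      stringsAsFactors = FALSE)
  } else stop("unsupported annotation format: .", ext)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  unknown <- setdiff(unique(df$chrom), names(gen))
  if (length(unknown))
    stop("annotation refers to unknown chromosome id: ", unknown[1L])
  models <- lapply(split(df, df$tx), function(d) {
    ex <- data.frame(chrom = d$chrom, start = d$start, end = d$end)
    if (!anyNA(d$label)) ex$label <- d$label
    transcript_model(d$tx[1L], ex, strand = d$strand[1L], gene = d$gene[1L])
  })
  models <- models[unique(df$tx)]
  chrom_len <- stats::setNames(BiocGenerics::width(gen), names(gen))
  for (m in models) {
    if (any(m$exons$end > chrom_len[[m$exons$chrom[1L]]]))
      stop("transcript ", m$id, ": exon beyond end of ", m$exons$chrom[1L])
  }
  list(models = models, genome = gen)
}

#' Write transcript models to GTF
#'
#' Emits one `exon` feature per exon with `gene_id`, `transcript_id` and
#' `exon_id` attributes, in 1-based closed coordinates. Round-trips exactly
#' through [load_gene_models()].
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(m) {
    g <- if (is.na(m$gene)) m$id else m$gene
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    sprintf('%s\tsixtm\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_id "%s";',
            ex$chrom, ex$start, ex$end, m$strand, g, m$id, ex$label)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Assemble the spliced mRNA sequence of a transcript
#'
#' Exon substrings are concatenated in genomic order; for minus-strand
#' transcripts the concatenation is reverse complemented, so the returned
#' string always reads 5' to 3' in mRNA orientation. Length equals the sum of
#' exon lengths.
#'
#' @param tx A [transcript_model()].
#' @param genome A sequence store (named `DNAStringSet` or named character
#'   vector).
#' @return The mRNA as an uppercase character string over `{A,C,G,T,N}`.
#' @export
spliced_sequence <- function(tx, genome) {
  gen <- validate_genome(genome)
  chrom <- tx$exons$chrom[1L]
  if (!chrom %in% names(gen)) stop("unknown chromosome id: ", chrom)
  chrseq <- gen[[chrom]]
  if (any(tx$exons$end > length(chrseq)))
    stop("transcript ", tx$id, ": exon beyond end of ", chrom)
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  parts <- Biostrings::DNAStringSet(chrseq,
                                    start = ex$start, end = ex$end)
  joined <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (tx$strand == "-") joined <- Biostrings::reverseComplement(joined)
  as.character(joined)
}

#' Construct a per-base conservation score track
#'
#' A sparse container of scores in `[0, 1]` addressed by 1-based position;
#' positions absent from the track are treated as missing (not zero), the
#' convention of PhastCons-style conservation tracks.
#'
#' @param chrom Chromosome id (scalar, or vector parallel to `pos`).
#' @param pos Integer vector of 1-based positions.
#' @param score Numeric scores in `[0, 1]`.
#' @return An object of class `score_track`.
#' @export
score_track <- function(chrom, pos, score) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos), length(pos) == length(score))
  if (any(score < 0 | score > 1))
    stop("invalid conservation score: values range from 0 to 1")
  if (any(pos < 1L)) stop("positions must be >= 1")
  df <- data.frame(pos = as.integer(pos), score = as.numeric(score))
  by_chrom <- lapply(split(df, chrom), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (anyDuplicated(d$pos)) stop("duplicate position in score track")
    rownames(d) <- NULL
    d
  })
  structure(list(by_chrom = by_chrom), class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat("score_track:", length(x$by_chrom), "chromosome(s),",
      sum(vapply(x$by_chrom, nrow, 0L)), "scored position(s)\n")
  invisible(x)
}

#' Look up track scores at given positions
#'
#' @param track A [score_track()].
#' @param chrom Chromosome id.
#' @param positions Integer positions (1-based).
#' @return Numeric vector, `NA` where the track has no score.
#' @export
track_scores <- function(track, chrom, positions) {
  d <- track$by_chrom[[chrom]]
  if (is.null(d)) return(rep(NA_real_, length(positions)))
  d$score[match(positions, d$pos)]
}

#' Load a conservation score track from bedGraph or wiggle
#'
#' Interval rows are expanded to per-base scores (bedGraph's 0-based
#' half-open intervals become 1-based positions). Scores outside `[0, 1]`
#' are rejected.
#'
#' @param path Path to a `.bedgraph`/`.bg` or `.wig` file.
#' @return A [score_track()].
#' @export
load_score_track <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext, bedgraph = , bg = "bedGraph", wig = "wig",
                stop("unsupported score track format: .", ext))
  gr <- rtracklayer::import(path, format = fmt)
  if (length(gr) == 0L) stop("empty score track: ", path)
  n <- BiocGenerics::width(gr)
  pos <- unlist(lapply(seq_along(gr), function(i)
    seq.int(BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i])))
  score_track(rep(as.character(GenomicRanges::seqnames(gr)), n),
              pos, rep(gr$score, n))
}

#' Construct an isoform record set for one GPCR gene
#'
#' Mirrors the information used in a UniProt-style screen: the canonical
#' receptor protein with its seven annotated transmembrane (TM) domains,
#' plus splice isoforms, each carrying a fragment flag (fragment-flagged
#' records are excluded from downstream analysis).
#'
#' @param gene Gene symbol.
#' @param canonical_seq Canonical protein sequence (one-letter amino acids).
#' @param tm_starts,tm_ends Integer vectors of length 7: 1-based inclusive
#'   residue ranges of TM1..TM7, ascending and non-overlapping.
#' @param isoforms `data.frame` with columns `id`, `sequence`, `fragment`.
#' @return An object of class `isoform_record_set`.
#' @export
isoform_record_set <- function(gene, canonical_seq, tm_starts, tm_ends,
                               isoforms = data.frame(id = character(),
                                                     sequence = character(),
                                                     fragment = logical())) {
  if (length(tm_starts) != 7L || length(tm_ends) != 7L)
    stop("gene ", gene, ": canonical GPCR record must annotate exactly 7 TM domains")
  if (any(tm_starts > tm_ends) || any(tm_starts < 1L) ||
      any(tm_ends > nchar(canonical_seq)))
    stop("gene ", gene, ": TM domain outside canonical sequence")
  if (any(diff(tm_starts) <= 0) || any(tm_starts[-1L] <= tm_ends[-7L]))
    stop("gene ", gene, ": TM domains must be ascending and non-overlapping")
  stopifnot(all(c("id", "sequence", "fragment") %in% names(isoforms)))
  validate_protein(canonical_seq)
  for (s in isoforms$sequence) validate_protein(s)
  structure(list(
    gene = gene,
    canonical = list(sequence = toupper(canonical_seq),
                     tm = data.frame(tm = paste0("TM", 1:7),
                                     start = as.integer(tm_starts),
                                     end = as.integer(tm_ends))),
    isoforms = data.frame(id = as.character(isoforms$id),
                          sequence = toupper(isoforms$sequence),
                          fragment = as.logical(isoforms$fragment),
                          stringsAsFactors = FALSE)),
    class = "isoform_record_set")
}

#' @export
print.isoform_record_set <- function(x, ...) {
  cat("isoform_record_set", x$gene, ":", nchar(x$canonical$sequence),
      "aa canonical, 7 TM domains,", nrow(x$isoforms), "isoform(s)\n")
  invisible(x)
}

#' @keywords internal
validate_protein <- function(seq) {
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYacdefghiklmnpqrstvwy]", seq))
    stop("non-amino-acid character in protein sequence")
  invisible(seq)
}

#' Read isoform records from TSV or JSON
#'
#' The TSV schema has one row per protein with columns `gene`, `isoform_id`,
#' `sequence`, `is_canonical`, `fragment`, `tm_starts`, `tm_ends`; the TM
#' columns are comma-separated 1-based residue ranges, filled on the
#' canonical row only. The JSON schema is a list of objects with fields
#' `gene`, `canonical` (`sequence`, `tm_starts`, `tm_ends`) and `isoforms`.
#' A canonical record with other than 7 TM annotations is rejected (GPCR
#' contract).
#'
#' @param path Path to a `.tsv` or `.json` file.
#' @return A list of [isoform_record_set()] objects, named by gene.
#' @export
load_isoform_records <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    out <- lapply(recs, function(r) {
      iso <- if (length(r$isoforms)) do.call(rbind, lapply(r$isoforms, function(i)
        data.frame(id = i$id, sequence = i$sequence, fragment = isTRUE(i$fragment))))
      else data.frame(id = character(), sequence = character(), fragment = logical())
      isoform_record_set(r$gene, r$canonical$sequence,
                         unlist(r$canonical$tm_starts), unlist(r$canonical$tm_ends),
                         iso)
    })
  } else if (ext == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "isoform_id", "sequence", "is_canonical", "fragment",
              "tm_starts", "tm_ends")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols))
      stop("isoform TSV missing column(s): ", paste(missing_cols, collapse = ", "))
    out <- lapply(split(df, df$gene), function(d) {
      can <- d[as.logical(d$is_canonical), , drop = FALSE]
      if (nrow(can) != 1L)
        stop("gene ", d$gene[1L], ": expected exactly one canonical row")
      iso <- d[!as.logical(d$is_canonical), , drop = FALSE]
      isoform_record_set(
        d$gene[1L], can$sequence,
        as.integer(strsplit(can$tm_starts, ",")[[1L]]),
        as.integer(strsplit(can$tm_ends, ",")[[1L]]),
        data.frame(id = iso$isoform_id, sequence = iso$sequence,
                   fragment = as.logical(iso$fragment)))
    })
  } else stop("unsupported isoform record format: .", ext)
  stats::setNames(out, vapply(out, `[[`, "", "gene"))
}

#' Write isoform records to the documented TSV schema
#'
#' @param records List of [isoform_record_set()] objects.
#' @param path Output path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_isoform_records <- function(records, path) {
  rows <- lapply(records, function(r) {
    rbind(
      data.frame(gene = r$gene, isoform_id = paste0(r$gene, "_canonical"),
                 sequence = r$canonical$sequence, is_canonical = TRUE,
                 fragment = FALSE,
                 tm_starts = paste(r$canonical$tm$start, collapse = ","),
                 tm_ends = paste(r$canonical$tm$end, collapse = ",")),
      if (nrow(r$isoforms))
        data.frame(gene = r$gene, isoform_id = r$isoforms$id,
                   sequence = r$isoforms$sequence, is_canonical = FALSE,
                   fragment = r$isoforms$fragment, tm_starts = "", tm_ends = ""))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
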