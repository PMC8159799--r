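test_that("BED half-open and GTF closed coordinates both map to 1-based closed exons", {
  fa <- write_tmp_fasta(list(chr1 = "AAGGTTCC"))
  bed <- write_tmp_lines("chr1\t2\t5", ".bed")
  mod <- load_gene_models(bed, fa)$models[[1L]]
  expect_equal(mod$exons$start, 3L)
  expect_equal(mod$exons$end, 5L)

  gtf <- write_tmp_lines(
    'chr1\tsrc\texon\t3\t5\t.\t+\t.\tgene_id "g"; transcript_id "t";', ".gtf")
  mod2 <- load_gene_models(gtf, fa)$models[[1L]]
  expect_equal(mod2$exons$start, 3L)
  expect_equal(mod2$exons$end, 5L)
})

test_that("minus-strand transcripts order exons 5' to 3'", {
  fa <- write_tmp_fasta(list(chr1 = "AAGGTTCC"))
  gtf <- write_tmp_lines(c(
    'chr1\tsrc\texon\t1\t3\t.\t-\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tsrc\texon\t6\t8\t.\t-\t.\tgene_id "g"; transcript_id "t";'), ".gtf")
  mod <- load_gene_models(gtf, fa)$models[[1L]]
  expect_equal(mod$exons$start, c(6L, 1L))
  expect_equal(mod$exons$end, c(8L, 3L))
})

test_that("annotation errors are specific: unknown chromosome, malformed line", {
  fa <- write_tmp_fasta(list(chr1 = "AAGGTTCC"))
  gtf <- write_tmp_lines(
    'chrX\tsrc\texon\t1\t3\t.\t+\t.\tgene_id "g"; transcript_id "t";', ".gtf")
  expect_error(load_gene_models(gtf, fa), "chrX")
  bad <- write_tmp_lines(c(
    'chr1\tsrc\texon\t1\t3\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    "chr1\tonly\tthree"), ".gtf")
  expect_error(load_gene_models(bad, fa), "line 2")
})

test_that("spliced sequences follow exon structure and strand", {
  genome <- c(chr1 = "AAGGTTCC")
  one <- transcript_model("t1", data.frame(chrom = "chr1", start = 1, end = 3), "+")
  expect_equal(spliced_sequence(one, genome), "AAG")
  full <- transcript_model("t2", data.frame(chrom = "chr1", start = 1, end = 8), "+")
  expect_equal(spliced_sequence(full, genome), "AAGGTTCC")
  minus <- transcript_model("t3", data.frame(chrom = "chr1",
                                             start = c(1, 6), end = c(3, 8)), "-")
  expect_equal(spliced_sequence(minus, genome), "GGACTT")
  oob <- transcript_model("t4", data.frame(chrom = "chr1", start = 5, end = 12), "+")
  expect_error(spliced_sequence(oob, genome), "beyond")
})

test_that("spliced length and strand symmetry hold for random exon sets", {
  set.seed(42)
  chrom_seq <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                            prob = c(.24, .24, .24, .24, .04)), collapse = "")
  genome <- c(chrZ = chrom_seq)
  for (i in 1:25) {
    n_ex <- sample(1:5, 1)
    bounds <- sort(sample(500, 2 * n_ex))
    exons <- data.frame(chrom = "chrZ",
                        start = bounds[seq(1, by = 2, length.out = n_ex)],
                        end = bounds[seq(2, by = 2, length.out = n_ex)])
    plus <- transcript_model(paste0("p", i), exons, "+")
    minus <- transcript_model(paste0("m", i), exons, "-")
    sp <- spliced_sequence(plus, genome)
    sm <- spliced_sequence(minus, genome)
    expect_equal(nchar(sp), sum(exons$end - exons$start + 1))
    expect_equal(sm, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sp))))
  }
})

test_that("transcript models round-trip through GTF exactly", {
  set.seed(7)
  genome <- c(chrR = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                           collapse = ""))
  models <- lapply(1:5, function(i) {
    n_ex <- sample(1:4, 1)
    bounds <- sort(sample(300, 2 * n_ex))
    transcript_model(
      paste0("tx", i),
      data.frame(chrom = "chrR",
                 start = bounds[seq(1, by = 2, length.out = n_ex)],
                 end = bounds[seq(2, by = 2, length.out = n_ex)],
                 label = paste0("e", seq_len(n_ex))),
      sample(c("+", "-"), 1), gene = "G1")
  })
  names(models) <- vapply(models, `[[`, "", "id")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(models, gtf)
  fa <- write_tmp_fasta(list(chrR = genome[["chrR"]]))
  back <- load_gene_models(gtf, fa)$models
  for (id in names(models)) {
    expect_equal(back[[id]]$exons[c("chrom", "start", "end", "label")],
                 models[[id]]$exons[c("chrom", "start", "end", "label")])
    expect_equal(back[[id]]$strand, models[[id]]$strand)
  }
})

test_that("score tracks expand interval rows per base and reject out-of-range scores", {
  bg <- write_tmp_lines("chr1\t0\t4\t0.5", ".bedgraph")
  tr <- load_score_track(bg)
  expect_equal(track_scores(tr, "chr1", 1:4), rep(0.5, 4))
  expect_true(is.na(track_scores(tr, "chr1", 5)))

  bg2 <- write_tmp_lines(c("chr1\t0\t2\t0.0", "chr1\t2\t4\t1.0"), ".bedgraph")
  tr2 <- load_score_track(bg2)
  expect_equal(track_scores(tr2, "chr1", 1:4), c(0, 0, 1, 1))

  bad <- write_tmp_lines("chr1\t0\t4\t1.2", ".bedgraph")
  expect_error(load_score_track(bad), "0 to 1")

  wig <- write_tmp_lines(c("fixedStep chrom=chr2 start=10 step=1",
                           "0.1", "0.2", "0.3"), ".wig")
  tw <- load_score_track(wig)
  expect_equal(track_scores(tw, "chr2", 10:12), c(0.1, 0.2, 0.3))
})

test_that("isoform records enforce the 7-TM canonical contract and keep fragment flags", {
  seq <- strrep("A", 300)
  starts <- seq(10, by = 40, length.out = 7)
  rec <- isoform_record_set("G1", seq, starts, starts + 20,
                            data.frame(id = "i1", sequence = "MKT",
                                       fragment = TRUE))
  expect_true(rec$isoforms$fragment[1L])
  expect_error(isoform_record_set("G2", seq, starts[1:6], starts[1:6] + 20),
               "exactly 7")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_isoform_records(list(rec), tsv)
  back <- load_isoform_records(tsv)[["G1"]]
  expect_equal(back$canonical$tm, rec$canonical$tm)
  expect_equal(back$isoforms$fragment, TRUE)
  expect_equal(back$isoforms$sequence, "MKT")
})
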