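test_that("generators are seed-deterministic, down to written bytes", {
  a <- gen_receptor_locus(12)
  b <- gen_receptor_locus(12)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$models, b$models)
  expect_identical(a$truth, b$truth)
  c <- gen_receptor_locus(13)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_locus(a, d1); write_locus(b, d2)
  for (f in c("genome.fa", "transcripts.gtf", "canonical_records.tsv",
              "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }

  expect_identical(gen_isoform_benchmark(3)$truth, gen_isoform_benchmark(3)$truth)
  expect_identical(gen_k2p_pair(3, 500)$aln, gen_k2p_pair(3, 500)$aln)

  # generators restore the caller's RNG state
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(gen_receptor_locus(4)); after <- runif(1)
  expect_identical(before, after)
})

test_that("written locus artifacts pass the package's own loaders", {
  loc <- gen_receptor_locus(6)
  dir <- withr::local_tempdir()
  write_locus(loc, dir)
  loaded <- load_gene_models(file.path(dir, "transcripts.gtf"),
                             file.path(dir, "genome.fa"))
  expect_setequal(names(loaded$models), names(loc$models))
  for (id in names(loc$models)) {
    expect_equal(spliced_sequence(loaded$models[[id]], loaded$genome),
                 spliced_sequence(loc$models[[id]], loc$genome))
  }
  recs <- load_isoform_records(file.path(dir, "canonical_records.tsv"))
  expect_equal(recs[[1L]]$canonical$sequence, loc$canonical_record$canonical$sequence)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$schema_version, "1.0")
  expect_equal(truth$transcripts$canonical_7TM$products, "7TM")
})

test_that("locus geometry options are honoured", {
  loc2 <- gen_receptor_locus(8, n_tm_exon1 = 2)
  call <- classify_products(loc2$models$cassette_PTC_1TM6TM, loc2$genome,
                            loc2$canonical_record)
  # with two TMs on exon 1 the PTC fragment is no longer a 1TM product
  expect_false("1TM" %in% call$products)
  no_cass <- gen_receptor_locus(8, cassette_ptc = FALSE)
  expect_named(no_cass$models, c("canonical_7TM", "exon1_skipped_6TM"))
})

test_that("evolved pairs carry their planted divergence truth", {
  zero <- gen_k2p_pair(1, length = 500, P_target = 0, Q_target = 0)
  expect_identical(zero$aln$query, zero$aln$subject)
  expect_equal(exon_divergence(zero$aln)$K, 0)
  expect_equal(zero$K_expected, 0)

  expect_error(gen_k2p_pair(1, length = 500, P_target = 0.3, Q_target = 0.25),
               "saturation")
  expect_error(gen_k2p_pair(1, length = 50), "length")

  big <- gen_k2p_pair(2, length = 100000, P_target = 0.2, Q_target = 0.1)
  expect_lt(abs(big$K_expected - 0.402360), 1e-6)
  expect_lt(abs(exon_divergence(big$aln)$K - 0.402360), 0.01)
})

test_that("synthetic score tracks validate and respect conserved regions", {
  tr <- gen_score_track(5, length = 400,
                        conserved = data.frame(start = 101, end = 200))
  expect_identical(tr, gen_score_track(5, length = 400,
                                       conserved = data.frame(start = 101, end = 200)))
  cons <- conservation_summary(tr, list(chrom = "chrSim", start = 101, end = 200))
  back <- conservation_summary(tr, list(chrom = "chrSim", start = 201, end = 300))
  expect_gt(cons$mean_score, back$mean_score)
  expect_true(cons$mean_score <= 1 && back$mean_score >= 0)
})

test_that("enrichment universes plant exact or null overlaps", {
  sim <- gen_enrichment_universe(1, N = 19020, m = 12, n = 800, k_planted = 7)
  res <- run_enrichment(sim$universe)
  expect_equal(res$k, 7L)
  expect_equal(res$fold_rounded, 13.9)

  zero <- gen_enrichment_universe(1, N = 1000, m = 10, n = 20, k_planted = 0)
  r0 <- run_enrichment(zero$universe)
  expect_equal(r0$fold, 0)
  expect_equal(r0$p, 1)

  expect_error(gen_enrichment_universe(1, N = 100, m = 5, n = 10, k_planted = 6),
               "infeasible")
})
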