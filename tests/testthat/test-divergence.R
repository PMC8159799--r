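test_that("substitution counting follows the transition/transversion definitions", {
  ident <- pairwise_alignment("ACGTACGTAC", "ACGTACGTAC")
  sc <- substitution_counts(ident)
  expect_equal(sc[c("TT", "TV", "lenA")], list(TT = 0L, TV = 0L, lenA = 10L))

  expect_equal(substitution_counts(pairwise_alignment("AG", "GG"))$TT, 1L)
  expect_equal(substitution_counts(pairwise_alignment("AG", "GG"))$TV, 0L)

  # 10 columns with mismatches A/G (ts), C/T (ts), A/C (tv)
  aln <- pairwise_alignment("AAACCCAGCA", "GAATCCCGCA")
  sc <- substitution_counts(aln)
  expect_equal(sc$TT, 2L)
  expect_equal(sc$TV, 1L)
  div <- exon_divergence(aln)
  expect_equal(div$P, 0.2)
  expect_equal(div$Q_frac, 0.1)

  # gap and N columns leave lenA but not lenQ/lenS
  g <- substitution_counts(pairwise_alignment("A-GNT", "AC-GT"))
  expect_equal(g$lenQ, 4L)
  expect_equal(g$lenS, 4L)
  expect_equal(g$lenA, 2L)

  expect_error(pairwise_alignment("ACGT", "ACG"), "lengths differ")
  expect_error(pairwise_alignment("ACGU", "ACGT"), "outside")
})

test_that("substitution counts equal a per-column brute-force recount", {
  set.seed(13)
  for (i in 1:1000) {
    pair <- random_gapped_pair(sample(20:80, 1))
    expect_equal(substitution_counts(pairwise_alignment(pair$q, pair$s)),
                 oracle_substitution_counts(pair$q, pair$s))
  }
})

test_that("the Kimura two-parameter closed form and its domain are exact", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_lt(abs(k2p_distance(0.2, 0.1) - 0.402360), 1e-6)
  expect_equal(k2p_distance(0.2, 0.1),
               -0.5 * log((1 - 0.4 - 0.1) * sqrt(1 - 0.2)))
  expect_error(k2p_distance(0.45, 0.15), "saturated")
  expect_error(k2p_distance(-0.1, 0), "non-negative")
  expect_error(k2p_distance(0.6, 0.5), "P \\+ Q")
})

test_that("the K2P correction always inflates the raw divergence", {
  set.seed(19)
  for (i in 1:200) {
    P <- runif(1, 0, 0.3); Q <- runif(1, 0, 0.2)
    expect_gte(k2p_distance(P, Q), P + Q)
  }
  expect_equal(k2p_distance(0, 0), 0)
})

test_that("divergence of an evolved pair recovers the planted distance", {
  pair <- gen_k2p_pair(101, length = 10000, P_target = 0.05, Q_target = 0.02)
  div <- exon_divergence(pair$aln, "planted")
  expect_equal(div$lenA, 10000L)
  # binomial sampling error on P and Q at n = 10,000 keeps K within ~3 SE
  expect_lt(abs(div$K - pair$K_expected), 0.01)

  same <- exon_divergence(pairwise_alignment("ACGTACGT", "ACGTACGT"))
  expect_equal(same$K, 0)
  expect_equal(same$lenQ, same$lenA)
})

test_that("K2P agrees with an independent phylogenetics implementation", {
  skip_if_not_installed("ape")
  pair <- gen_k2p_pair(55, length = 2000, P_target = 0.08, Q_target = 0.03)
  bin <- ape::as.DNAbin(rbind(
    q = strsplit(tolower(pair$aln$query), "")[[1L]],
    s = strsplit(tolower(pair$aln$subject), "")[[1L]]))
  ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
  expect_equal(exon_divergence(pair$aln)$K, ref, tolerance = 1e-10)
})

test_that("conservation summaries average the exon's scored positions only", {
  const <- score_track("chr1", 1:200, rep(0.5, 200))
  s <- conservation_summary(const, list(chrom = "chr1", start = 50, end = 99,
                                        label = "e1"))
  expect_equal(s$mean_score, 0.5)
  expect_equal(s$sem, 0)
  expect_equal(s$n_positions, 50L)

  two <- score_track("chr1", 1:2, c(0, 1))
  s2 <- conservation_summary(two, list(chrom = "chr1", start = 1, end = 2))
  expect_equal(s2$mean_score, 0.5)
  expect_equal(s2$sem, 0.5)

  sparse <- score_track("chr1", 1:10, seq(0, 0.9, by = 0.1))
  s3 <- conservation_summary(sparse, list(chrom = "chr1", start = 1, end = 15))
  expect_equal(s3$n_positions, 10L)

  expect_error(conservation_summary(sparse, list(chrom = "chr1", start = 100,
                                                 end = 120)), "no scored")

  # exact mean for a constant track, any exon
  set.seed(23)
  for (c0 in c(0.1, 0.73, 1)) {
    tr <- score_track("chrC", 1:500, rep(c0, 500))
    a <- sort(sample(500, 2))
    expect_equal(conservation_summary(tr, list(chrom = "chrC", start = a[1],
                                               end = a[2]))$mean_score, c0)
  }
})
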