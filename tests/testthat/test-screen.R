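test_that("global protein alignment behaves as specified on controlled cases", {
  id <- align_isoform("MKTWL", "MKTWL")
  expect_equal(id$aligned_canonical, "MKTWL")
  expect_equal(id$aligned_isoform, "MKTWL")

  # unit match/mismatch +1/-1, linear gap -2: best score for MKT vs MT is 0,
  # with K opposite a gap (verified by enumerating all 3 alignments of
  # length 3: gap at M gives -1-2+1 = -2, at K gives 1-2+1 = 0, at T gives
  # 1-2-1 = -2)
  aa <- Biostrings::AA_ALPHABET[1:20]
  unit <- matrix(-1, 20, 20, dimnames = list(aa, aa)); diag(unit) <- 1
  small <- align_isoform("MKT", "MT", substitution_matrix = unit,
                         gap_open = 0, gap_extend = 2)
  expect_equal(small$score, 0)
  expect_equal(small$aligned_canonical, "MKT")
  expect_equal(small$aligned_isoform, "M-T")

  expect_error(align_isoform("MKT", "M1T"), "amino")
  expect_error(align_isoform("", "MKT"), "non-empty")

  # N-terminal deletion opens a canonical-only gap block covering TM1
  set.seed(3)
  prot <- build_receptor_protein()
  iso <- substr(prot$sequence, 51, nchar(prot$sequence))
  aln <- align_isoform(prot$sequence, iso)
  gap_cols <- sum(strsplit(aln$aligned_isoform, "")[[1L]] == "-")
  expect_equal(gap_cols, 50L)
  expect_equal(gsub("-", "", aln$aligned_canonical), prot$sequence)
  expect_equal(gsub("-", "", aln$aligned_isoform), iso)
})

test_that("TM presence is the aligned-coverage criterion", {
  tm1 <- data.frame(start = c(2, 30, 40, 50, 60, 70, 80),
                    end = c(24, 35, 45, 55, 65, 75, 85))
  canon <- strrep("A", 90)
  # identity alignment: everything present
  ident <- structure(list(aligned_canonical = canon, aligned_isoform = canon,
                          score = 0), class = "alignment_result")
  expect_true(all(tm_presence(ident, tm1)))

  # TM1's 23 residues entirely opposite gaps
  iso_gapped <- paste0("A", strrep("-", 23), strrep("A", 66))
  gapped <- structure(list(aligned_canonical = canon,
                           aligned_isoform = iso_gapped, score = 0),
                      class = "alignment_result")
  pres <- tm_presence(gapped, tm1)
  expect_false(pres[["TM1"]])
  expect_true(all(pres[2:7]))

  # 12 of 23 aligned (52%) clears the 0.5 threshold, 11 (48%) does not
  iso12 <- paste0("A", strrep("A", 12), strrep("-", 11), strrep("A", 66))
  expect_true(tm_presence(structure(list(aligned_canonical = canon,
                                         aligned_isoform = iso12, score = 0),
                                    class = "alignment_result"), tm1)[["TM1"]])
  iso11 <- paste0("A", strrep("A", 11), strrep("-", 12), strrep("A", 66))
  expect_false(tm_presence(structure(list(aligned_canonical = canon,
                                          aligned_isoform = iso11, score = 0),
                                     class = "alignment_result"), tm1)[["TM1"]])
})

test_that("truncation categories follow effective TM counts, with de novo rescue", {
  all7 <- rep(TRUE, 7)
  expect_equal(classify_truncation(all7)$category, "full_7TM")

  n6 <- c(FALSE, rep(TRUE, 6))
  call <- classify_truncation(n6)
  expect_equal(call$category, "N_trunc_6TM")
  expect_equal(call$n_tm, 6L)
  expect_false(call$de_novo_helix_rescue)

  expect_equal(classify_truncation(c(rep(TRUE, 6), FALSE))$category, "C_trunc_6TM")
  expect_equal(classify_truncation(c(FALSE, FALSE, rep(TRUE, 5)))$category,
               "N_trunc_5TM")
  expect_equal(classify_truncation(c(TRUE, FALSE, rep(TRUE, 5)))$category,
               "other")

  # a replaced segment that itself forms a helix rescues the missing TM
  rescue <- classify_truncation(n6, replaced = c(strrep("L", 21), rep("", 6)))
  expect_equal(rescue$category, "full_7TM")
  expect_true(rescue$de_novo_helix_rescue)
  expect_equal(rescue$n_tm, 7L)
  # a hydrophilic replacement does not rescue
  no_rescue <- classify_truncation(n6, replaced = c(strrep("S", 21), rep("", 6)))
  expect_equal(no_rescue$category, "N_trunc_6TM")
})

test_that("the screen recovers planted truncations and excludes fragments", {
  expect_equal(nrow(run_screen(list())$calls), 0L)

  bench <- gen_isoform_benchmark(
    21, c(N_trunc_6TM = 2, C_trunc_6TM = 2, N_trunc_5TM = 1, C_trunc_5TM = 1,
          full = 2, rescue = 1, fragment = 1))
  res <- run_screen(bench$records)
  m <- merge(res$calls, bench$truth, by = c("gene", "isoform_id"))
  expect_equal(m$category.x, m$category.y)

  # fragments are excluded before analysis and never selected
  frag <- m$planted == "fragment"
  expect_true(all(m$category.x[frag] == "excluded_fragment"))
  expect_false(any(res$selected$category == "excluded_fragment"))

  # selection = >= 4 TMs and missing TM1 or TM7
  expect_setequal(res$selected$category,
                  c("N_trunc_6TM", "C_trunc_6TM", "N_trunc_5TM", "C_trunc_5TM"))
  expect_equal(nrow(res$selected), 6L)
})

test_that("lowering the coverage threshold never turns a present TM absent", {
  set.seed(31)
  bench <- gen_isoform_benchmark(4, c(N_trunc_6TM = 1, C_trunc_5TM = 1, full = 1))
  for (rec in bench$records) {
    aln <- align_isoform(rec$canonical$sequence, rec$isoforms$sequence[1L])
    prev <- rep(FALSE, 7)
    for (cov in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
      pres <- tm_presence(aln, rec$canonical$tm, cov)
      expect_true(all(pres[prev]))   # once present, present at lower threshold
      prev <- pres
    }
  }
})
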