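test_that("identical sequences align without gaps at full identity", {
  aln <- global_align("KTRYKLK", "KTRYKLK")
  expect_equal(aln$identities, 7L)
  expect_equal(aln$aligned_columns, 7L)
  expect_false(grepl("-", aln$target_aligned, fixed = TRUE))
  expect_equal(percent_identity(aln), 100)
  expect_identical(aln$column_map, 1:7)
})

test_that("a deleted suffix costs one two-residue gap", {
  aln <- global_align("KTRYKLK", "KTRYK")
  expect_equal(aln$identities, 5L)
  expect_equal(lengths(regmatches(aln$reference_aligned,
                                  gregexpr("-", aln$reference_aligned))), 2L)
  expect_equal(nchar(aln$target_aligned), 7L)
})

test_that("percent identity honours the denominator conventions", {
  aln <- global_align("AAAA", "AATT")
  expect_equal(percent_identity(aln), 50)
  expect_equal(percent_identity(aln, "aligned_columns"), 50)
  long <- global_align("AAAA", "AAAATTTT")
  expect_equal(percent_identity(long, "shorter"), 100)
  expect_equal(percent_identity(long, "alignment_length"), 50)
})

test_that("empty sequences are rejected", {
  expect_error(global_align("", "KTR"), "non-empty")
  expect_error(global_align("KTR", ""), "non-empty")
})

test_that("DP score equals exhaustive enumeration on short random pairs", {
  S <- align_params()$score_matrix
  set.seed(7)
  for (t in 1:20) {
    a <- rand_seq(sample(1:6, 1))
    b <- rand_seq(sample(1:6, 1))
    dp <- global_align(a, b)$score
    br <- brute_force_score(strsplit(a, "")[[1]], strsplit(b, "")[[1]], S)
    expect_equal(dp, br, info = paste(a, "vs", b))
  }
  for (t in 1:2) {  # a pair at the full oracle length
    a <- rand_seq(8)
    b <- rand_seq(8)
    dp <- global_align(a, b)$score
    br <- brute_force_score(strsplit(a, "")[[1]], strsplit(b, "")[[1]], S)
    expect_equal(dp, br, info = paste(a, "vs", b))
  }
})

test_that("score is symmetric and gap removal recovers the inputs", {
  set.seed(21)
  for (t in 1:10) {
    a <- rand_seq(sample(3:30, 1), alphabet = c("A", "C", "D", "K", "W", "S"))
    b <- rand_seq(sample(3:30, 1), alphabet = c("A", "C", "D", "K", "W", "S"))
    f <- global_align(a, b)
    r <- global_align(b, a)
    expect_equal(f$score, r$score)
    expect_identical(gsub("-", "", f$target_aligned), a)
    expect_identical(gsub("-", "", f$reference_aligned), b)
    tg <- strsplit(f$target_aligned, "")[[1]]
    rg <- strsplit(f$reference_aligned, "")[[1]]
    expect_false(any(tg == "-" & rg == "-"))
    expect_lte(f$identities, f$aligned_columns)
  }
})

test_that("interval transfer agrees with an independent column walk", {
  ref <- load_reference()
  set.seed(5)
  for (t in 1:6) {
    rec <- generate_domain(
      synth_params(ridge_positives = sample(0:7, 1),
                   background_mutation_rate = 0.1,
                   conservative_only = FALSE),
      seed = 100 + t)
    aln <- global_align(rec$record$sequence, ref$sequence)
    fm <- map_intervals(aln, ref)
    for (nm in c("loop5", "loop6", "loop7")) {
      iv <- list(ref$loop5, ref$loop6, ref$loop7)[[match(nm, c("loop5",
                                                               "loop6",
                                                               "loop7"))]]
      expect_equal(fm[[nm]], walk_interval(aln, iv), info = nm)
    }
  }
})

test_that("ungapped self-alignment maps every interval onto itself", {
  ref <- load_reference()
  aln <- global_align(ref$sequence, ref$sequence)
  fm <- map_intervals(aln, ref)
  expect_equal(fm$loop5, ref$loop5)
  expect_equal(fm$loop6, ref$loop6)
  expect_equal(fm$loop7, ref$loop7)
  expect_equal(fm$triad, ref$triad_positions)
  expect_equal(fm$loop10, c(ref$loop10_anchor, 228L))
})

test_that("loop-10 mapping keeps target overhang and detects truncation", {
  ref <- load_reference()
  extended <- paste0(ref$sequence, "KKKK")
  fm <- map_intervals(global_align(extended, ref$sequence), ref)
  expect_equal(fm$loop10, c(ref$loop10_anchor, 232L))

  truncated <- substr(ref$sequence, 1, 223)
  fm2 <- map_intervals(global_align(truncated, ref$sequence), ref)
  expect_null(fm2$loop10)

  wrong <- global_align("KTRYKLK", "KTRYKLK")
  expect_error(map_intervals(wrong, ref), "does not match")
})
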