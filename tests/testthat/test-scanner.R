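test_that("cationic counting sees K and R only", {
  expect_equal(unname(count_cationic("KTRYKLK", c(1, 7))), 4L)
  expect_equal(unname(count_cationic("KAKYR", c(1, 5))), 3L)
  expect_equal(unname(count_cationic("TTTTT", c(2, 4))), 0L)
  expect_equal(unname(count_cationic("HHHHH", c(1, 5))), 0L)  # His excluded
  expect_equal(unname(count_cationic("KRKR", list(a = c(1, 2), b = c(3, 4)))),
               c(2L, 2L))
  expect_error(count_cationic("KR", c(1, 5)), "out of bounds")
})

test_that("triad detection distinguishes exact, conservative and absent", {
  ref <- load_reference()
  s <- ref$sequence
  expect_true(detect_triad(s, ref$triad_positions, ref, mode = "exact"))
  # the tenascin-X residues P/L/S are not the triad
  sx <- s
  substr(sx, 157, 157) <- "P"; substr(sx, 160, 160) <- "L"
  substr(sx, 162, 162) <- "S"
  expect_false(detect_triad(sx, ref$triad_positions, ref, mode = "exact"))
  # conservative mode accepts a positively scoring substitution (D->E)
  se <- s
  substr(se, 157, 157) <- "E"
  expect_false(detect_triad(se, ref$triad_positions, ref, mode = "exact"))
  expect_true(detect_triad(se, ref$triad_positions, ref,
                           mode = "conservative"))
  expect_false(detect_triad(sx, ref$triad_positions, ref,
                            mode = "conservative"))
  # a gap-lost position means no triad
  expect_false(detect_triad(s, c(157L, NA, 162L), ref))
})

test_that("cationic tail detection counts the mapped loop-10 region", {
  ct <- detect_ctail("XXXRRKRA", c(4, 8))
  expect_true(ct$present); expect_equal(ct$count, 4L)
  expect_equal(detect_ctail("ANYTHING", NULL), list(present = FALSE,
                                                    count = 0L))
  expect_false(detect_ctail("AAAAA", c(1, 5))$present)
  expect_false(detect_ctail("KRAAA", c(1, 5))$present)  # 2 < 3
})

test_that("the activator rule is a monotone threshold at three charges", {
  expect_false(classify_ridge(2))
  expect_true(classify_ridge(3))
  expect_true(classify_ridge(7))
  expect_error(classify_ridge(-1), "non-negative")
  expect_identical(classify_ridge(0:7), 0:7 >= 3)
  v <- classify_ridge(0:7)
  expect_true(all(diff(v) >= 0))  # monotone non-decreasing
})

test_that("scanning the reference against itself recovers its own profile", {
  ref <- load_reference()
  p <- scan_domain(ref$sequence, ref)
  expect_equal(p$identity, 100)
  expect_equal(c(p$loop5_count, p$loop6_count, p$loop7_count), c(4L, 2L, 1L))
  expect_equal(p$ridge_count, 7L)
  expect_equal(p$ridge_count, p$loop5_count + p$loop6_count + p$loop7_count)
  expect_true(p$triad_present)
  expect_true(p$ctail_present)
  expect_equal(p$ctail_positive_count, 4L)
  expect_true(p$predicted_activator)
  expect_equal(p$predicted_activator, p$ridge_count >= 3)
})

test_that("sequences below the identity floor are rejected", {
  ref <- load_reference()
  set.seed(3)
  noise <- paste(sample(c("G", "P", "W", "H", "M", "C"), 228, TRUE),
                 collapse = "")
  expect_error(scan_domain(noise, ref), "does not look like an FBG domain")
})

test_that("ridge count is monotone under charge implanting and removal", {
  ref <- load_reference()
  base <- scan_domain(ref$sequence, ref)
  # adding a K at a non-slot loop position can only increase the count
  s_add <- ref$sequence
  substr(s_add, 110, 110) <- "K"  # inside loop 5
  expect_equal(scan_domain(s_add, ref)$ridge_count, base$ridge_count + 1L)
  # removing a ridge charge can only decrease it
  s_rm <- ref$sequence
  substr(s_rm, 124, 124) <- "A"
  expect_equal(scan_domain(s_rm, ref)$ridge_count, base$ridge_count - 1L)
})

test_that("residues outside the mapped regions do not change the profile", {
  ref <- load_reference()
  base <- scan_domain(ref$sequence, ref)
  set.seed(17)
  s <- strsplit(ref$sequence, "")[[1]]
  bg <- setdiff(seq_len(200), c(102:169))  # clear of loops and their flanks
  for (p in sample(bg, 25)) s[p] <- sample(c("A", "S", "T", "V", "E"), 1)
  p2 <- scan_domain(paste(s, collapse = ""), ref)
  expect_equal(p2$ridge_count, base$ridge_count)
  expect_equal(p2$triad_present, base$triad_present)
  expect_equal(p2$ctail_present, base$ctail_present)
  expect_equal(p2$predicted_activator, base$predicted_activator)
  expect_lt(p2$identity, base$identity)
})

test_that("peptide tiling reproduces the nine-window design", {
  ref <- load_reference()
  tiles <- tile_peptides(ref$sequence, ref)
  expect_equal(nrow(tiles), 9L)
  expect_equal(tiles$start[1], 1L)
  expect_equal(tiles$end[9], 228L)                 # right-aligned last window
  expect_true(all(nchar(tiles$sequence) == 30L))
  expect_true(all(diff(tiles$start) > 0))
  # full coverage with the configured overlap
  expect_true(all(tiles$start[-1] <= tiles$end[-9]))
  active <- which(tiles$predicted_active)
  expect_identical(active, c(5L, 6L))              # consecutive, two of nine
  expect_error(tile_peptides("KTRYKLK", ref, length = 30), "exceeds")
})

test_that("catalogue scanning reports concordance and skips missing entries", {
  cat24 <- load_catalog()
  parents <- fixture_parents()
  tens <- scan_catalog(cat24[cat24$family == "tenascin", ], parents)
  expect_equal(tens$ridge_count, c(7L, 7L, 6L, 2L))
  expect_true(all(tens$ridge_match))
  expect_equal(unname(attr(tens, "summary")["tenascin_activators"]), 3)

  empty <- data.frame(id = character(0), description = character(0),
                      sequence = character(0))
  warns <- 0L
  res <- withCallingHandlers(
    scan_catalog(cat24, empty),
    warning = function(w) { warns <<- warns + 1L; invokeRestart("muffleWarning") })
  expect_equal(nrow(res), 0L)
  expect_equal(warns, 24L)
  expect_equal(length(attr(res, "skipped")), 24L)
})
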