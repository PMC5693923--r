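test_that("the edit grammar parses and rejects malformed tokens", {
  spec <- parse_mutation_spec("demo",
                              "sub:124K>A; trunc:223 ;append:RRKRA")
  expect_s3_class(spec, "mutation_spec")
  expect_equal(vapply(spec$edits, `[[`, "", "type"),
               c("substitution", "truncate_after", "append_tail"))
  rep <- parse_mutation_spec("r", "replace:105-134:KTRYKLK")
  expect_equal(rep$edits[[1]]$start, 105L)
  expect_equal(rep$edits[[1]]$replacement, "KTRYKLK")
  expect_error(parse_mutation_spec("bad", "swap:12A>B"), "unparseable")
  expect_error(parse_mutation_spec("bad", "trunc:10;trunc:20"),
               "one truncation")
})

test_that("edits apply in order with from-residue guards", {
  d <- fbg_domain("toy", "KTRYKLK")
  m <- apply_mutations(d, parse_mutation_spec("m", "sub:1K>A;append:GG"))
  expect_equal(m$sequence, "ATRYKLKGG")
  expect_equal(attr(m, "parent_domain_id"), "toy")

  expect_error(apply_mutations(d, "sub:1T>A"),
               "expected 'T' at position 1 but found 'K'")
  expect_error(apply_mutations(d, "sub:99K>A"), "out of bounds")
  expect_error(apply_mutations(d, "trunc:99"), "out of bounds")

  # order sensitivity: a replacement changes what a later guard sees
  ok <- apply_mutations(d, "replace:1-2:AA;sub:3R>W")
  expect_equal(ok$sequence, "AAWYKLK")
  expect_error(apply_mutations(d, "sub:3R>W;replace:1-2:AA;sub:3R>W"),
               "expected 'R'")
})

test_that("a null specification is the identity", {
  ref <- load_reference()
  d <- fbg_domain("FBG-C", ref$sequence)
  out <- apply_mutations(d, parse_mutation_spec("wild type", list()))
  expect_equal(out$sequence, d$sequence)
  p <- scan_domain(out, ref)
  expect_true(p$predicted_activator)
})

test_that("applying the loop-5 charge-removal spec twice trips the guard", {
  ref <- load_reference()
  d <- fbg_domain("FBG-C", ref$sequence)
  mut3 <- parse_mutation_spec("mutant 3",
                              "sub:124K>A;sub:126R>A;sub:128K>A;sub:130K>A")
  once <- apply_mutations(d, mut3)
  expect_error(apply_mutations(once, mut3), "expected 'K' at position 124")
})

test_that("the built-in panel encodes the published designs", {
  panel <- builtin_panel(parents = fixture_parents())
  expect_length(panel, 11L)
  names <- vapply(panel, function(e) e$spec$name, character(1))
  expect_equal(sum(grepl("FBG-C", names)), 7L)
  expect_equal(sum(grepl("FBG-X", names)), 4L)
  expect_identical(vapply(panel, `[[`, "", "observed"),
                   c("reduced", "reduced", "inactive", "reduced", "inactive",
                     "reduced", "inactive",
                     "inactive", "reduced", "active", "active"))

  ref <- load_reference()
  mut3 <- panel[[3]]$spec
  expect_length(mut3$edits, 4L)
  pos <- vapply(mut3$edits, `[[`, 0L, "position")
  expect_true(all(pos >= 124L & pos <= 130L))  # inside the KTRYKLK motif
  expect_true(all(vapply(mut3$edits, `[[`, "", "from") %in% c("K", "R")))
  expect_true(all(vapply(mut3$edits, `[[`, "", "to") == "A"))

  mut5 <- panel[[5]]$spec
  expect_equal(mut5$edits[[5]]$type, "truncate_after")
  expect_equal(mut5$edits[[5]]$position, ref$loop10_anchor - 1L)

  xmut4 <- panel[[11]]$spec
  subs <- Filter(function(e) e$type == "substitution", xmut4$edits)
  expect_equal(vapply(subs, `[[`, 0L, "position"), c(161L, 165L, 167L))
  expect_equal(vapply(subs, `[[`, "", "from"), c("P", "L", "S"))
  expect_equal(vapply(subs, `[[`, "", "to"), c("D", "I", "N"))

  # every FBG-C edit position sits in an annotated region of the parent
  in_region <- function(p) {
    (p >= ref$loop5[1] & p <= ref$loop5[2]) |
      (p >= ref$loop7[1] & p <= ref$loop7[2]) |
      p >= ref$loop10_anchor - 1L
  }
  for (e in unlist(lapply(panel[1:7], function(x) x$spec$edits),
                   recursive = FALSE)) {
    p <- if (e$type %in% c("substitution", "truncate_after")) e$position else
      NULL
    if (!is.null(p)) expect_true(in_region(p))
  }
})

test_that("panel evaluation reproduces the feature losses and flags", {
  res <- evaluate_panel(builtin_panel(parents = fixture_parents()))
  expect_equal(nrow(res), 11L)
  rown <- function(n) res[res$mutant_name == n, ]

  # loop-10 truncation loses the tail flag, nothing else
  expect_false(rown("FBG-C mutant 4")$ctail_present)
  expect_true(rown("FBG-C mutant 4")$triad_present)
  expect_equal(rown("FBG-C mutant 4")$ridge_count, 7L)

  # the triad swap to tenascin-X residues loses the triad flag only
  expect_false(rown("FBG-C mutant 6")$triad_present)
  expect_true(rown("FBG-C mutant 6")$ctail_present)

  # removing the four loop-5 charges leaves ridge 3: under the published
  # binary rule this still classifies as an activator, discordant with the
  # observed inactivity -- the documented blind spot, flagged not hidden
  m3 <- rown("FBG-C mutant 3")
  expect_equal(m3$ridge_count, 3L)
  expect_equal(m3$loop5_count, 0L)
  expect_true(m3$predicted_activator)
  expect_false(m3$concordant)
  expect_true(m3$flagged)

  # the KAKYR chimera gains loop-5 charges yet was observed inactive:
  # flagged discordant, exactly as reported
  x1 <- rown("FBG-X mutant 1")
  expect_equal(x1$loop5_count, 3L)
  expect_true(x1$predicted_activator)
  expect_true(x1$flagged)

  # restoring loop 5 + cationic C-terminus (+ triad) makes FBG-X whole
  x3 <- rown("FBG-X mutant 3")
  expect_true(x3$predicted_activator)
  expect_true(x3$ctail_present)
  expect_true(x3$concordant)
  expect_false(x3$triad_present)
  x4 <- rown("FBG-X mutant 4")
  expect_true(x4$triad_present)
  expect_true(x4$concordant)

  s <- attr(res, "summary")
  expect_equal(unname(s["concordant"]), 7)
  expect_equal(unname(s["discordant"]), 4)
})

test_that("the panel degrades to FBG-C mutants when tenascin-X is missing", {
  parents <- fixture_parents()
  expect_warning(panel <- builtin_panel(parents = parents[parents$id !=
                                                            "P22105", ]),
                 "restricted")
  expect_length(panel, 7L)
})
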