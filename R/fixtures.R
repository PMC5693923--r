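# Synthetic stand-in sequences for the 24 human FRePs.
#
# The grading/build environment has no network access, so the UniProt
# sequences behind the published catalogue cannot be fetched. The packaged
# FASTA (inst/extdata/frep_parents_synthetic.fasta) therefore contains
# SYNTHETIC stand-ins, generated here: each parent is a neutral padding
# segment plus an FBG-like domain derived from the reference scaffold with
# the catalogued epitope features implanted (ridge charge count at the
# canonical slots, loop-7 triad, cationic or neutral tail) and background
# divergence calibrated to the documented identity figures (tenascin family
# pairwise 50-60%; FIBCD-1 vs FBG-C 43%). Every header says "SYNTHETIC".
#
# Divergence model: a latent tenascin "ancestor" is drawn once from the
# scaffold; tenascin-R/-W/-X diverge from it independently, which gives all
# six pairwise identities the same expectation -- a star phylogeny, the
# simplest model consistent with the published identity band. Non-tenascins
# diverge from the scaffold independently at a higher rate. Rates below
# were calibrated once against the published identity figures and frozen.

.FIXTURE_SEED <- 42L

# Calibrated divergence rates (fraction of eligible background positions).
.DIV_TENASCIN_HUB <- 0.45  # scaffold -> latent family ancestor
.DIV_TENASCIN_RW  <- 0.45  # ancestor -> tenascin-R / tenascin-W
.DIV_TENASCIN_X   <- 0.28  # ancestor -> tenascin-X
.DIV_OTHER        <- 0.75  # scaffold -> non-tenascin FRePs
.FIBCD1_TOTAL_DIFFS <- 130L  # => 98/228 identities = 43% to the reference

.BG_COMPOSITION <- c(A = 0.075, R = 0.03, N = 0.045, D = 0.055, C = 0.02,
                     E = 0.06, Q = 0.04, G = 0.07, H = 0.02, I = 0.05,
                     L = 0.09, K = 0.04, M = 0.02, F = 0.04, P = 0.045,
                     S = 0.07, T = 0.06, W = 0.015, Y = 0.045, V = 0.07)

# Sample a deviation map over `positions` at `rate`: each hit position gets
# a composition-weighted residue different from the current one.
.sample_deviation <- function(s, positions, rate) {
  hit <- positions[stats::runif(length(positions)) < rate]
  subs <- vapply(hit, function(p) {
    cand <- setdiff(names(.BG_COMPOSITION), s[p])
    sample(cand, 1L, prob = .BG_COMPOSITION[cand])
  }, character(1))
  names(subs) <- hit
  subs
}

.apply_deviation <- function(s, subs) {
  if (length(subs)) s[as.integer(names(subs))] <- subs
  s
}

# Substitute exactly n still-unchanged background positions, preferring
# BLOSUM62-non-negative partners so the alignment stays collinear.
.exact_substitutions <- function(s, scaffold, positions, n,
                                 score_matrix = align_params()$score_matrix) {
  free <- positions[s[positions] == scaffold[positions]]
  if (n > length(free))
    stop("not enough free background positions for exact divergence")
  aas <- names(.BG_COMPOSITION)
  for (p in sample(free, n)) {
    cand <- aas[score_matrix[aas, s[p]] >= 0]
    cand <- setdiff(cand, s[p])
    if (!length(cand)) cand <- setdiff(aas, s[p])
    s[p] <- sample(cand, 1L)
  }
  s
}

# Build the FBG-like domain for one catalogue entry (residue vector).
.build_member_domain <- function(entry, ann, scaffold, hub_dev, bg_ten,
                                 bg_all) {
  s <- scaffold
  k <- entry$published_ridge
  n_slots <- length(.RIDGE_SLOTS)
  fill <- function(m) sample(.NEUTRAL_FILLERS, m, replace = TRUE)

  if (entry$family == "tenascin" && entry$name != "Tenascin-X") {
    off <- .RIDGE_SLOTS[seq_len(n_slots) > k]
    s[off] <- fill(length(off))
    if (entry$name != "Tenascin-C") {
      s <- .apply_deviation(s, hub_dev)
      s <- .apply_deviation(s, .sample_deviation(s, bg_ten, .DIV_TENASCIN_RW))
      ins <- if (entry$name == "Tenascin-R") 4L else 13L
      s <- c(s[1:190], fill(ins), s[191:length(s)])
    }
  } else if (entry$name == "Tenascin-X") {
    # Loop 5 lacks the cationic motif (S-A-T-Y-S at the KTRYK positions, so
    # that exactly three substitutions create KAKYR); its two ridge charges
    # sit in loop 6; triad is the inactive P/L/S; insertions inside loop 7
    # place the triad at the documented X-local positions 161/165/167; the
    # cationic tail is lost (neutral extension instead of RRKRA).
    s[124:130] <- strsplit("SATYSLT", "")[[1]]
    s[154] <- fill(1L)
    s[ann$triad_positions] <- c("P", "L", "S")
    s <- .apply_deviation(s, hub_dev)
    s <- .apply_deviation(s, .sample_deviation(s, bg_ten, .DIV_TENASCIN_X))
    # Loop-7 insertions placing the triad at X-local 161/165/167. The two
    # insertion blocks are separated by three matched columns and filled
    # with residues that mismatch the reference neighbourhood strongly, so
    # merging the gaps (saving one gap-open) can never pay and the triad
    # columns stay in register under the default alignment parameters.
    s <- c(s[1:156], c("W", "G", "W", "G"), s[157:159], "W", s[160:223],
           c("S", "Q", "T"))
  } else {
    on <- .RIDGE_SLOTS[seq_len(n_slots) <= k]
    off <- .RIDGE_SLOTS[seq_len(n_slots) > k]
    s[on] <- .RIDGE_RESIDUES[seq_len(n_slots) <= k]
    s[off] <- fill(length(off))
    # Redraw the loop-5 scaffold between the slots: these loops are not
    # conserved outside the tenascin family, and the redraw guarantees the
    # reference motif cannot reappear (no Y among the fillers).
    inter <- setdiff(ann$loop5[1]:ann$loop5[2], .RIDGE_SLOTS)
    inter <- setdiff(inter, c(106L, 113L, 114L))  # aromatic anchors kept
    redraw <- c(127L, inter[stats::runif(length(inter)) < 0.45])
    redraw <- unique(redraw)
    s[redraw] <- sample(c("T", "S", "N", "Q", "A", "G", "V"),
                        length(redraw), replace = TRUE)
    s[ann$triad_positions] <- if (entry$published_triad) ann$triad_residues else
      c(sample(c("P", "T", "S", "A", "G"), 1L),
        sample(c("L", "V", "T", "A", "F"), 1L),
        sample(c("S", "T", "A", "Q", "G"), 1L))
    s[ann$loop10_anchor:length(s)] <- strsplit("TSQNA", "")[[1]]
    # The pre-tail NFRNLEG strand is kept in every stand-in: it is part of
    # the conserved subdomain-P core and anchors the loop-10 mapping.
    if (entry$name == "FIBCD-1") {
      d0 <- sum(s != scaffold)
      s <- .exact_substitutions(s, scaffold, bg_ten,
                                .FIBCD1_TOTAL_DIFFS - d0)
    } else {
      s <- .apply_deviation(s, .sample_deviation(s, bg_ten, .DIV_OTHER))
    }
  }
  s
}

#' Regenerate the packaged synthetic FReP stand-in sequences
#'
#' Deterministically rebuilds the 24 synthetic full-length parent
#' sequences shipped in `inst/extdata/frep_parents_synthetic.fasta`
#' (N-terminal padding plus an FBG-like domain at the catalogued
#' boundaries). These are labelled stand-ins for the UniProt entries, not
#' database sequences; see the vignette for what they do and do not
#' emulate.
#'
#' @param seed Master seed (default the packaged value; changing it yields
#'   a different but equally valid stand-in set).
#' @param catalog Catalogue data frame.
#' @param annotation Reference annotation.
#' @return A [read_fasta()]-shaped `data.frame` (`id` = UniProt accession,
#'   `description` marks the record as synthetic, `sequence` = parent).
#' @export
synthesize_frep_fixture <- function(seed = .FIXTURE_SEED,
                                    catalog = load_catalog(),
                                    annotation = load_reference()) {
  scaffold <- strsplit(annotation$sequence, "")[[1]]
  bg_all <- .background_positions(annotation)
  bg_ten <- setdiff(bg_all, 217:223)  # pre-tail NFRNLEG conserved in-family
  # Three-residue flanks of each loop are also conserved in every stand-in
  # (loop-adjacent strand residues are structurally constrained); they keep
  # the transferred interval boundaries in register at high divergence.
  bg_ten <- setdiff(bg_ten, c(102:104, 135:137, 149:151, 167:169))
  hub_dev <- with_seed(seed - 1L,
                       .sample_deviation(scaffold, bg_ten, .DIV_TENASCIN_HUB))
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    entry <- catalog[i, ]
    with_seed(seed + 37L * i, {
      dom <- .build_member_domain(entry, annotation, scaffold, hub_dev,
                                  bg_ten, bg_all)
      if (length(dom) != entry$fbg_end - entry$fbg_start + 1L)
        stop("internal error: stand-in domain length mismatch for ",
             entry$name)
      pad <- sample(names(.BG_COMPOSITION), entry$fbg_start - 1L,
                    replace = TRUE, prob = .BG_COMPOSITION)
      parent <- paste(c(pad, dom), collapse = "")
      expected_motif <- if (entry$name %in%
                            c("Tenascin-C", "Tenascin-R", "Tenascin-W"))
        1L else 0L
      hits <- gregexpr(annotation$ridge_motif, parent, fixed = TRUE)[[1]]
      n_hits <- if (hits[1] == -1L) 0L else length(hits)
      if (n_hits != expected_motif)
        stop("internal error: unexpected ridge-motif occurrence in ",
             entry$name)
      data.frame(id = entry$accession,
                 description = paste(entry$name,
                                     "| SYNTHETIC stand-in, not the UniProt sequence"),
                 sequence = parent, stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
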