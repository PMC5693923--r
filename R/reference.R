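# Reference annotation for the tenascin-C fibrinogen-like globe (FBG-C).
#
# The packaged reference sequence is a SYNTHETIC stand-in for the FBG domain
# of human tenascin-C (UniProt P24821, residues 1974-2201). It realises the
# documented properties of that domain -- 228 residues, average mass 26.1 kDa,
# the cationic loop-5 motif KTRYKLK, the loop-7 polar/hydrophobic triad
# D157/I160/N162, the pre-tail segment NFRNLEG and the cationic loop-10 tail
# RRKRA at 224-228 -- on an otherwise artificial globular-composition
# background. It is not the UniProt sequence.

.FBGC_SCAFFOLD <- paste0(
  "QQFYVHSHIVVYGWNDYSKPSGGGDPWEPFMNEQLFRETPQSSGSWVSIDKAVGKYAARI",
  "IAEDRMTECNVGKYWLCGGDGWLNFNKMDVLRDGILSTHRWKQLSWNDPLGEYWLGNDNI",
  "HLLKTRYKLKNQATWTGGSKQDGSRWATQSITAKDSDAQIPNNAESDDQWYENSTLPTQS",
  "ILSCLALTLFFAEDLVAPAKDGRKRITCELMGITVRNFRNLEGRRKRA")

# Canonical ridge slots of the reference: the K/R positions contributed by
# loops 5, 6 and 7 (4 + 2 + 1 = the seven ridge charges of tenascin-C).
.RIDGE_SLOTS    <- c(124L, 126L, 128L, 130L, 140L, 145L, 154L)
.RIDGE_RESIDUES <- c("K", "R", "K", "K", "K", "R", "K")

# Non-cationic polar fillers used wherever a ridge slot is switched off;
# chosen so that switching a slot off can never create a charge, a D/I/N
# triad residue collision is avoided by construction (slots != triad sites).
.NEUTRAL_FILLERS <- c("T", "S", "N", "Q", "A")

#' Load the packaged FBG reference annotation
#'
#' Returns the annotation that parameterises every downstream stage: the
#' reference domain sequence plus the coordinates of the three epitope
#' sites mapped onto targets by alignment. Coordinates are domain-local,
#' 1-based and inclusive.
#'
#' The three sites are:
#' \describe{
#'   \item{cationic ridge}{K/R residues inside loops 5 (105--134, carrying
#'     the KTRYKLK motif at 124--130), 6 (138--148) and 7 (152--166);}
#'   \item{loop-7 triad}{the polar/hydrophobic triad D157, I160, N162;}
#'   \item{cationic tail}{the loop-10 region from residue 224 onwards
#'     (RRKRA in the reference).}
#' }
#'
#' The packaged sequence is a synthetic stand-in emulating the documented
#' properties of the tenascin-C FBG domain (see the package vignette); the
#' annotation intervals are package data, not part of the stand-in.
#'
#' @return An object of class `fbg_reference`: a list with elements
#'   `reference_id`, `sequence`, `loop5`, `loop6`, `loop7` (integer
#'   start/end pairs), `loop10_anchor`, `triad_positions`,
#'   `triad_residues` and `ridge_motif`.
#' @examples
#' ref <- load_reference()
#' nchar(ref$sequence)
#' substr(ref$sequence, ref$loop10_anchor, nchar(ref$sequence))
#' @export
load_reference <- function() {
  ann <- structure(list(
    reference_id    = "FBG-C_synthetic_reference",
    sequence        = .FBGC_SCAFFOLD,
    loop5           = c(105L, 134L),
    loop6           = c(138L, 148L),
    loop7           = c(152L, 166L),
    loop10_anchor   = 224L,
    triad_positions = c(157L, 160L, 162L),
    triad_residues  = c("D", "I", "N"),
    ridge_motif     = "KTRYKLK"
  ), class = "fbg_reference")
  validate_reference(ann)
  ann
}

#' Validate an FBG reference annotation
#'
#' Checks the structural invariants of the annotation: ordered,
#' non-overlapping loops within the sequence; triad residues present at the
#' stated positions; the ridge motif occurring exactly once, inside loop 5;
#' and the loop-10 anchor lying past loop 7.
#'
#' @param ann An `fbg_reference` object.
#' @return `ann`, invisibly; errors on any violated invariant.
#' @export
validate_reference <- function(ann) {
  stopifnot(inherits(ann, "fbg_reference"))
  n <- nchar(ann$sequence)
  ivs <- rbind(ann$loop5, ann$loop6, ann$loop7)
  if (any(ivs < 1L) || any(ivs > n) || any(ivs[, 1] > ivs[, 2]))
    stop("reference annotation corrupt: loop interval out of bounds")
  if (any(diff(as.vector(t(ivs))) < 0))
    stop("reference annotation corrupt: loops overlap or are out of order")
  res <- strsplit(ann$sequence, "")[[1]]
  if (!identical(res[ann$triad_positions], ann$triad_residues))
    stop("reference annotation corrupt: triad residues do not match sequence")
  hits <- gregexpr(ann$ridge_motif, ann$sequence, fixed = TRUE)[[1]]
  if (length(hits) != 1L || hits[1] < 0L)
    stop("reference annotation corrupt: ridge motif must occur exactly once")
  if (hits[1] < ann$loop5[1] ||
      hits[1] + nchar(ann$ridge_motif) - 1L > ann$loop5[2])
    stop("reference annotation corrupt: ridge motif outside loop 5")
  if (ann$loop10_anchor <= ann$loop7[2] || ann$loop10_anchor > n)
    stop("reference annotation corrupt: loop10 anchor misplaced")
  invisible(ann)
}

#' @export
print.fbg_reference <- function(x, ...) {
  cat("FBG reference annotation:", x$reference_id, "\n")
  cat(sprintf("  %d residues; loop5 %d-%d, loop6 %d-%d, loop7 %d-%d, tail %d-%d\n",
              nchar(x$sequence), x$loop5[1], x$loop5[2], x$loop6[1], x$loop6[2],
              x$loop7[1], x$loop7[2], x$loop10_anchor, nchar(x$sequence)))
  cat(sprintf("  ridge motif %s; triad %s at %s\n", x$ridge_motif,
              paste(x$triad_residues, collapse = "/"),
              paste(x$triad_positions, collapse = "/")))
  invisible(x)
}
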