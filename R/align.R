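# Global pairwise alignment (Needleman-Wunsch, affine gaps) and
# alignment-mediated transfer of reference annotation onto targets.
#
# The dynamic programme is written out in full rather than delegated so that
# the traceback tie-break (diagonal > up > left, i.e. match > gap-in-
# reference > gap-in-target) is fixed and the score is testable against
# exhaustive enumeration. A gap of length L costs gap_open + L * gap_extend.

#' Alignment parameters
#'
#' @param matrix Substitution matrix name; `"BLOSUM62"` (from Biostrings)
#'   is the only packaged choice, but any symmetric scoring matrix with
#'   residue dimnames may be passed via `score_matrix`.
#' @param gap_open Gap opening penalty (charged once per gap), positive.
#' @param gap_extend Gap extension penalty per gapped residue, positive.
#' @param score_matrix Optional explicit matrix overriding `matrix`.
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5,
                         score_matrix = NULL) {
  if (is.null(score_matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    score_matrix <- get(matrix, envir = e)
  }
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, score_matrix = score_matrix),
            class = "align_params")
}

#' Global alignment of a target sequence to the reference
#'
#' Needleman-Wunsch with affine gap penalties (Gotoh three-state recursion;
#' a gap of length L costs `gap_open + L * gap_extend`, end gaps are
#' penalised). The traceback is deterministic: on ties, a diagonal step
#' (aligned pair) beats consuming a target residue ("up", gap in the
#' reference row) which beats consuming a reference residue ("left", gap in
#' the target row); the same ordering resolves ties between the three
#' states.
#'
#' @param target,reference Residue strings (non-empty).
#' @param params An [align_params()] object.
#' @return An object of class `pairwise_alignment`: list with
#'   `target_aligned` and `reference_aligned` (equal-length gapped strings),
#'   `score`, `identities`, `aligned_columns` (columns with residues in both
#'   rows) and `column_map` (integer vector over reference positions giving
#'   the aligned target position, `NA` where the reference residue faces a
#'   gap).
#' @examples
#' aln <- global_align("KTRYKLK", "KTRYK")
#' aln$identities
#' @export
global_align <- function(target, reference, params = align_params()) {
  if (!nzchar(target) || !nzchar(reference))
    stop("global_align: sequences must be non-empty")
  a <- strsplit(target, "")[[1]]     # rows (i)
  b <- strsplit(reference, "")[[1]]  # columns (j)
  m <- length(a); n <- length(b)
  S <- params$score_matrix
  if (any(!(a %in% rownames(S))) || any(!(b %in% rownames(S))))
    stop("global_align: residue not covered by the substitution matrix")
  go <- params$gap_open; ge <- params$gap_extend
  NEG <- -1e9

  M <- matrix(NEG, m + 1L, n + 1L)  # a_i aligned to b_j
  X <- matrix(NEG, m + 1L, n + 1L)  # gap in reference (consumes target)
  Y <- matrix(NEG, m + 1L, n + 1L)  # gap in target (consumes reference)
  M[1L, 1L] <- 0
  if (m > 0L) X[2L:(m + 1L), 1L] <- -(go + ge * seq_len(m))
  if (n > 0L) Y[1L, 2L:(n + 1L)] <- -(go + ge * seq_len(n))

  sub <- S[a, b, drop = FALSE]  # m x n local scores
  jj <- seq_len(n)
  for (i in seq_len(m)) {
    ip <- i; ic <- i + 1L
    Mp <- M[ip, ]; Xp <- X[ip, ]; Yp <- Y[ip, ]
    best_prev <- pmax(Mp, Xp, Yp)
    M[ic, jj + 1L] <- sub[i, ] + best_prev[jj]
    X[ic, ] <- pmax(Mp - go - ge, Xp - ge, Yp - go - ge)
    # Y along the row is a running maximum over (M|X) starts:
    AX <- pmax(M[ic, ], X[ic, ])
    Y[ic, jj + 1L] <- cummax(AX[jj] + jj * ge)[jj] - go - (jj + 1L) * ge
  }

  states <- c("M", "X", "Y")
  pick <- function(vals) states[which(vals == max(vals))[1L]]
  # Final state: tie order M > X > Y matches diagonal > up > left.
  st <- pick(c(M[m + 1L, n + 1L], X[m + 1L, n + 1L], Y[m + 1L, n + 1L]))
  score <- max(M[m + 1L, n + 1L], X[m + 1L, n + 1L], Y[m + 1L, n + 1L])

  ta <- character(0); ra <- character(0)
  i <- m; j <- n
  while (i > 0L || j > 0L) {
    if (st == "M") {
      ta <- c(a[i], ta); ra <- c(b[j], ra)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      st <- pick(prev)
    } else if (st == "X") {
      ta <- c(a[i], ta); ra <- c("-", ra)
      prev <- c(M[i, j + 1L] - go - ge, X[i, j + 1L] - ge,
                Y[i, j + 1L] - go - ge)
      i <- i - 1L
      st <- pick(prev)
    } else {
      ta <- c("-", ta); ra <- c(b[j], ra)
      prev <- c(M[i + 1L, j] - go - ge, X[i + 1L, j] - go - ge,
                Y[i + 1L, j] - ge)
      j <- j - 1L
      st <- pick(prev)
    }
  }

  new_alignment(paste(ta, collapse = ""), paste(ra, collapse = ""), score,
                target, reference)
}

# Assemble and validate a pairwise_alignment object from gapped rows.
new_alignment <- function(target_aligned, reference_aligned, score,
                          target, reference) {
  tg <- strsplit(target_aligned, "")[[1]]
  rg <- strsplit(reference_aligned, "")[[1]]
  stopifnot(length(tg) == length(rg))
  if (any(tg == "-" & rg == "-"))
    stop("invalid alignment: column gapped in both rows")
  if (paste(tg[tg != "-"], collapse = "") != target ||
      paste(rg[rg != "-"], collapse = "") != reference)
    stop("invalid alignment: rows do not recover the input sequences")
  both <- tg != "-" & rg != "-"
  tpos <- cumsum(tg != "-")
  column_map <- ifelse(tg[rg != "-"] != "-", tpos[rg != "-"], NA_integer_)
  structure(list(
    target_aligned = target_aligned,
    reference_aligned = reference_aligned,
    score = score,
    identities = sum(both & tg == rg),
    aligned_columns = sum(both),
    column_map = as.integer(column_map),
    target = target, reference = reference
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: score %.1f, %d identities / %d aligned columns (%d total)\n",
              x$score, x$identities, x$aligned_columns,
              nchar(x$target_aligned)))
  w <- 60L
  for (k in seq(1L, nchar(x$target_aligned), by = w)) {
    cat(substr(x$target_aligned, k, k + w - 1L), "\n")
    cat(substr(x$reference_aligned, k, k + w - 1L), "\n\n")
  }
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' @param aln A `pairwise_alignment`.
#' @param convention Denominator convention: `"shorter"` (identities over
#'   the shorter input length; the package default for reporting),
#'   `"aligned_columns"` (over columns with residues in both rows) or
#'   `"alignment_length"` (over all columns).
#' @return Percentage (numeric, unrounded; round to integer for reports).
#' @examples
#' percent_identity(global_align("AAAA", "AATT"))  # 50
#' @export
percent_identity <- function(aln, convention = c("shorter", "aligned_columns",
                                                 "alignment_length")) {
  convention <- match.arg(convention)
  den <- switch(convention,
                shorter = min(nchar(aln$target), nchar(aln$reference)),
                aligned_columns = aln$aligned_columns,
                alignment_length = nchar(aln$target_aligned))
  100 * aln$identities / den
}

#' Transfer reference annotation intervals onto the aligned target
#'
#' Each reference loop interval maps to the smallest target interval
#' covering all its non-gap columns (`NULL` when every column is gapped).
#' Triad positions map one-to-one (`NA` when the position faces a gap).
#' The loop-10 region maps to every target residue at or after the column
#' of the loop-10 anchor, explicitly including target overhang beyond the
#' reference C-terminus, so that extended and truncated tails are
#' distinguished.
#'
#' @param aln A `pairwise_alignment` whose reference row is the annotation
#'   sequence.
#' @param annotation An [load_reference()] annotation.
#' @return A list of class `fbg_feature_map`: `loop5`, `loop6`, `loop7`
#'   (integer start/end pairs or `NULL`), `triad` (integer vector of 3,
#'   `NA` = absent), `loop10` (start/end pair or `NULL`).
#' @export
map_intervals <- function(aln, annotation) {
  if (aln$reference != annotation$sequence)
    stop("map_intervals: alignment reference row does not match annotation")
  cm <- aln$column_map
  map_iv <- function(iv) {
    hit <- cm[iv[1]:iv[2]]
    hit <- hit[!is.na(hit)]
    if (!length(hit)) NULL else c(min(hit), max(hit))
  }
  # loop10: target residues aligned at/after the anchor's column, plus
  # overhang. Equivalently: from the smallest mapped target position at or
  # after the anchor (or, if the anchor region is all-gap in the target,
  # past the last mapped position) through the target C-terminus.
  anchor_on <- cm[annotation$loop10_anchor:length(cm)]
  anchor_on <- anchor_on[!is.na(anchor_on)]
  m <- nchar(aln$target)
  loop10 <- if (length(anchor_on)) c(min(anchor_on), m) else {
    before <- cm[seq_len(annotation$loop10_anchor - 1L)]
    before <- before[!is.na(before)]
    start <- if (length(before)) max(before) + 1L else 1L
    if (start <= m) c(start, m) else NULL
  }
  structure(list(
    loop5 = map_iv(annotation$loop5),
    loop6 = map_iv(annotation$loop6),
    loop7 = map_iv(annotation$loop7),
    triad = as.integer(cm[annotation$triad_positions]),
    loop10 = loop10
  ), class = "fbg_feature_map")
}
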