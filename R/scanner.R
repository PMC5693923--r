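# Feature extraction and classification: cationic ridge count over the
# mapped loops 5/6/7, loop-7 triad detection, cationic C-tail detection,
# and the ">= 3 ridge charges => predicted TLR4 activator" rule; batch
# catalogue scanning and overlapping-peptide tiling.

.CATIONIC <- c("K", "R")  # histidine deliberately excluded

#' Scanner parameters
#'
#' @param threshold Minimum ridge charge count for a predicted activator
#'   (default 3, the published rule).
#' @param triad_mode `"exact"` (mapped residues must equal the reference
#'   triad) or `"conservative"` (each mapped residue must score positively
#'   against its reference residue under the substitution matrix).
#' @param ctail_min Minimum K/R count in the mapped loop-10 region for the
#'   cationic C-tail flag (default 3; the reference tail RRKRA has 4).
#' @param identity_floor Minimum percent identity (shorter-sequence
#'   convention) to the reference below which a sequence is rejected as not
#'   an FBG domain (default 15).
#' @param align An [align_params()] object.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(threshold = 3L, triad_mode = c("exact", "conservative"),
                        ctail_min = 3L, identity_floor = 15,
                        align = align_params()) {
  structure(list(threshold = as.integer(threshold),
                 triad_mode = match.arg(triad_mode),
                 ctail_min = as.integer(ctail_min),
                 identity_floor = identity_floor, align = align),
            class = "scan_params")
}

#' Count cationic residues per interval
#'
#' Counts K and R (histidine excluded) inside each interval of a sequence.
#'
#' @param seq Residue string.
#' @param intervals A single start/end pair, or a (possibly named) list of
#'   them; `NULL` entries (regions lost to gaps) count 0.
#' @return Integer vector, one count per interval.
#' @examples
#' count_cationic("KTRYKLK", c(1, 7))  # 4
#' count_cationic("KAKYR", c(1, 5))    # 3
#' @export
count_cationic <- function(seq, intervals) {
  if (!is.list(intervals)) intervals <- list(intervals)
  res <- strsplit(seq, "")[[1]]
  out <- vapply(intervals, function(iv) {
    if (is.null(iv)) return(0L)
    if (iv[1] < 1L || iv[2] > length(res) || iv[1] > iv[2])
      stop(sprintf("interval %d-%d out of bounds for %d-residue sequence",
                   iv[1], iv[2], length(res)))
    sum(res[iv[1]:iv[2]] %in% .CATIONIC)
  }, integer(1))
  names(out) <- names(intervals)
  out
}

#' Detect the loop-7 polar/hydrophobic triad
#'
#' @param target Residue string of the target domain.
#' @param positions Mapped triad positions on the target (`NA` = the
#'   reference position faces a gap; any absence makes the triad absent).
#' @param annotation Reference annotation supplying the triad residues.
#' @param mode `"exact"` or `"conservative"` (see [scan_params()]).
#' @param score_matrix Substitution matrix for conservative mode.
#' @return `TRUE` iff the triad is present.
#' @export
detect_triad <- function(target, positions, annotation = load_reference(),
                         mode = c("exact", "conservative"),
                         score_matrix = align_params()$score_matrix) {
  mode <- match.arg(mode)
  if (any(is.na(positions))) return(FALSE)
  res <- strsplit(target, "")[[1]]
  if (any(positions < 1L | positions > length(res)))
    stop("triad position out of bounds")
  got <- res[positions]
  want <- annotation$triad_residues
  if (mode == "exact") return(all(got == want))
  all(vapply(seq_along(got), function(k) {
    got[k] %in% rownames(score_matrix) &&
      score_matrix[got[k], want[k]] > 0
  }, logical(1)))
}

#' Detect a cationic C-terminal tail (loop 10)
#'
#' @param target Residue string of the target domain.
#' @param region Mapped loop-10 region (start/end pair) or `NULL` for a
#'   truncated tail.
#' @param min_positive Minimum K/R count for presence (default 3).
#' @return List with `present` (logical) and `count` (K/R in the region).
#' @examples
#' detect_ctail("XXXRRKRA", c(4, 8))  # present, count 4
#' @export
detect_ctail <- function(target, region, min_positive = 3L) {
  if (is.null(region)) return(list(present = FALSE, count = 0L))
  count <- unname(count_cationic(target, region))
  list(present = count >= min_positive, count = count)
}

#' Classify a ridge charge count
#'
#' The published rule: a domain is a predicted TLR4 activator iff its
#' cationic ridge carries at least `threshold` positive charges.
#'
#' @param ridge_count Non-negative integer vector.
#' @param threshold Default 3.
#' @return Logical vector.
#' @examples
#' classify_ridge(c(2, 3, 7))  # FALSE TRUE TRUE
#' @export
classify_ridge <- function(ridge_count, threshold = 3L) {
  if (any(ridge_count < 0)) stop("ridge_count must be non-negative")
  ridge_count >= threshold
}

#' Scan one FBG domain against the reference annotation
#'
#' Pipeline: global alignment to the reference, identity floor check,
#' annotation transfer ([map_intervals()]), cationic-ridge counting over
#' the mapped loops 5/6/7, triad and C-tail detection, and classification.
#' Deterministic throughout.
#'
#' @param domain An `fbg_domain` or residue string.
#' @param annotation An [load_reference()] annotation.
#' @param params A [scan_params()] object.
#' @return A one-row `data.frame` of class `epitope_profile`: `domain_id`,
#'   `identity`, `loop5_count`, `loop6_count`, `loop7_count`, `ridge_count`,
#'   `triad_present`, `ctail_present`, `ctail_positive_count`,
#'   `predicted_activator`. The alignment and feature map are attached as
#'   attributes `alignment` and `feature_map`.
#' @examples
#' ref <- load_reference()
#' scan_domain(ref$sequence, ref)$ridge_count  # 7
#' @export
scan_domain <- function(domain, annotation = load_reference(),
                        params = scan_params()) {
  id <- if (inherits(domain, "fbg_domain")) domain$id else "domain"
  s <- if (inherits(domain, "fbg_domain")) domain$sequence else domain
  # 'X' needs no special handling: BLOSUM62 scores it, it is never cationic
  # and never matches a triad residue.
  aln <- global_align(s, annotation$sequence, params$align)
  ident <- percent_identity(aln, "shorter")
  if (ident < params$identity_floor)
    stop(sprintf(paste0("'%s' does not look like an FBG domain: %.1f%% ",
                        "identity to the reference (floor %.1f%%)"),
         id, ident, params$identity_floor))
  fmap <- map_intervals(aln, annotation)
  loops <- count_cationic(s, fmap[c("loop5", "loop6", "loop7")])
  triad <- detect_triad(s, fmap$triad, annotation, params$triad_mode,
                        params$align$score_matrix)
  ct <- detect_ctail(s, fmap$loop10, params$ctail_min)
  ridge <- sum(loops)
  out <- data.frame(domain_id = id, identity = ident,
                    loop5_count = loops[["loop5"]],
                    loop6_count = loops[["loop6"]],
                    loop7_count = loops[["loop7"]],
                    ridge_count = ridge,
                    triad_present = triad,
                    ctail_present = ct$present,
                    ctail_positive_count = ct$count,
                    predicted_activator =
                      unname(classify_ridge(ridge, params$threshold)),
                    stringsAsFactors = FALSE)
  attr(out, "alignment") <- aln
  attr(out, "feature_map") <- fmap
  class(out) <- c("epitope_profile", "data.frame")
  out
}

#' Scan the whole FReP catalogue
#'
#' Extracts the FBG domain of every catalogue entry from the supplied
#' full-length sequences, scans each, and reports the extracted features
#' next to the packaged published values, with concordance columns.
#' Entries with no matching sequence are skipped with a warning and listed
#' in the `skipped` attribute.
#'
#' @param catalog A [load_catalog()] data frame.
#' @param sequences A [read_fasta()] data frame of full-length parent
#'   sequences whose `id`s are UniProt accessions.
#' @param annotation Reference annotation.
#' @param params Scanner parameters.
#' @return A `data.frame` with one row per scanned entry: the profile
#'   columns plus `name`, `family`, `published_*`, `ridge_match` and
#'   `predicted_match`. Attribute `summary` holds activator counts among
#'   tenascins and non-tenascins.
#' @export
scan_catalog <- function(catalog, sequences, annotation = load_reference(),
                         params = scan_params()) {
  rows <- list(); skipped <- character(0)
  for (k in seq_len(nrow(catalog))) {
    entry <- catalog[k, ]
    hit <- match(entry$accession, sequences$id)
    if (is.na(hit)) {
      warning("no sequence for ", entry$name, " (", entry$accession,
              "); entry skipped", call. = FALSE)
      skipped <- c(skipped, entry$name)
      next
    }
    dom <- extract_domain(sequences[hit, ], entry)
    prof <- scan_domain(dom, annotation, params)
    prof$name <- entry$name
    prof$family <- entry$family
    prof$published_ridge <- entry$published_ridge
    prof$published_predicted <- entry$published_predicted
    prof$ridge_match <- prof$ridge_count == entry$published_ridge
    prof$predicted_match <- prof$predicted_activator == entry$published_predicted
    rows[[length(rows) + 1L]] <- as.data.frame(prof)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(domain_id = character(0))
  rownames(out) <- NULL
  if (nrow(out)) {
    tn <- out$family == "tenascin"
    attr(out, "summary") <- c(
      tenascin_activators = sum(out$predicted_activator[tn]),
      other_activators = sum(out$predicted_activator[!tn]))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Tile a domain into overlapping peptide windows
#'
#' Reconstructs the overlapping ~30-mer peptide mapping strategy: windows
#' of `length` residues every `stride` residues, the last window
#' right-aligned to the C-terminus so the whole domain is covered. A window
#' is predicted active when it contains at least three of the mapped ridge
#' K/R positions. On the 228-residue reference with the defaults this gives
#' nine windows, of which exactly windows 5 and 6 are predicted active.
#'
#' @param domain An `fbg_domain` or residue string.
#' @param annotation Reference annotation (used to map the ridge).
#' @param length,stride Window length and step (defaults 30 and 25).
#' @param params Scanner parameters.
#' @return A `data.frame`: `index`, `start`, `end`, `sequence`,
#'   `ridge_overlap_count`, `predicted_active`.
#' @export
tile_peptides <- function(domain, annotation = load_reference(), length = 30L,
                          stride = 25L, params = scan_params()) {
  s <- if (inherits(domain, "fbg_domain")) domain$sequence else domain
  n <- nchar(s)
  if (length > n)
    stop(sprintf("window length %d exceeds domain length %d", length, n))
  stopifnot(stride >= 1L)
  aln <- global_align(s, annotation$sequence, params$align)
  fmap <- map_intervals(aln, annotation)
  res <- strsplit(s, "")[[1]]
  ridge_pos <- integer(0)
  for (iv in fmap[c("loop5", "loop6", "loop7")])
    if (!is.null(iv))
      ridge_pos <- c(ridge_pos,
                     (iv[1]:iv[2])[res[iv[1]:iv[2]] %in% .CATIONIC])
  starts <- seq(1L, n, by = stride)
  starts <- starts[starts + length - 1L <= n]
  if (!length(starts) || starts[length(starts)] + length - 1L < n)
    starts <- c(starts, n - length + 1L)
  starts <- unique(starts)
  data.frame(
    index = seq_along(starts),
    start = starts,
    end = starts + length - 1L,
    sequence = substring(s, starts, starts + length - 1L),
    ridge_overlap_count = vapply(starts, function(st)
      sum(ridge_pos >= st & ridge_pos <= st + length - 1L), integer(1)),
    predicted_active = vapply(starts, function(st)
      sum(ridge_pos >= st & ridge_pos <= st + length - 1L) >= 3L, logical(1)),
    stringsAsFactors = FALSE)
}
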