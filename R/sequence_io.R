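# FASTA reading/writing (via Biostrings) with strict residue validation,
# domain extraction against catalogue boundaries, and average-mass
# computation.

.AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")

# Average (isotope-averaged) residue masses in Da, plus one water per chain.
.AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

.validate_residues <- function(seqs, ids, allow_x = TRUE) {
  ok <- .AA20
  if (allow_x) ok <- c(ok, "X")
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!(res %in% ok))
    if (length(bad))
      stop(sprintf("record '%s': invalid residue '%s' at position %d",
                   ids[[i]], res[bad[1]], bad[1]))
    if (allow_x && any(res == "X"))
      warning(sprintf("record '%s' contains %d 'X' residue(s); they are ",
                      ids[[i]], sum(res == "X")),
              "rejected by mass computation and counted as non-cationic",
              call. = FALSE)
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Wraps `Biostrings::readAAStringSet()` and enforces the package's
#' record contract: sequences are upper-cased, `*` chain terminators are
#' stripped, and any character outside the 20 standard residues (plus the
#' tolerated ambiguity code `X`) is a fatal error naming the offending
#' record and position.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped, multi-record).
#' @return A `data.frame` with columns `id` (first whitespace-delimited
#'   token of the header), `description` (remainder of the header, possibly
#'   empty) and `sequence`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "KTRYKLK"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  if (any(!nzchar(seqs))) stop("empty sequence in record '",
                               ids[!nzchar(seqs)][1], "'")
  .validate_residues(seqs, ids)
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records A `data.frame` with columns `id`, `sequence` and
#'   optionally `description`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Construct an FBG domain object
#'
#' A domain-local amino-acid sequence together with its provenance: the
#' parent accession and the 1-based coordinates it was cut from.
#'
#' @param id Domain identifier.
#' @param sequence Residue string (domain-local).
#' @param parent_accession,parent_start,parent_end Provenance fields
#'   (optional, `NA` when the domain was constructed in silico).
#' @return An object of class `fbg_domain`.
#' @export
fbg_domain <- function(id, sequence, parent_accession = NA_character_,
                       parent_start = NA_integer_, parent_end = NA_integer_) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  structure(list(id = id, sequence = sequence,
                 parent_accession = parent_accession,
                 parent_start = as.integer(parent_start),
                 parent_end = as.integer(parent_end)),
            class = "fbg_domain")
}

#' @export
print.fbg_domain <- function(x, ...) {
  cat(sprintf("FBG domain %s (%d aa", x$id, nchar(x$sequence)))
  if (!is.na(x$parent_accession))
    cat(sprintf("; %s %d-%d", x$parent_accession, x$parent_start, x$parent_end))
  cat(")\n")
  invisible(x)
}

#' Cut the FBG domain out of a full-length FReP sequence
#'
#' @param record A one-row slice of a [read_fasta()] data frame (or any list
#'   with `id` and `sequence`).
#' @param entry A one-row slice of the [load_catalog()] data frame supplying
#'   `accession`, `fbg_start` and `fbg_end`.
#' @return An `fbg_domain` of length `fbg_end - fbg_start + 1`.
#' @examples
#' rec <- list(id = "P24821", sequence = strrep("A", 2201))
#' entry <- list(name = "Tenascin-C", accession = "P24821",
#'               fbg_start = 1974, fbg_end = 2201)
#' nchar(extract_domain(rec, entry)$sequence)
#' @export
extract_domain <- function(record, entry) {
  len <- nchar(record$sequence)
  if (entry$fbg_end > len || entry$fbg_start < 1L)
    stop(sprintf(paste0("FBG boundaries %d-%d exceed sequence '%s' (%d aa); ",
                        "accession/isoform mismatch?"),
                 entry$fbg_start, entry$fbg_end, record$id, len))
  fbg_domain(id = if (!is.null(entry$name)) entry$name else record$id,
             sequence = substr(record$sequence, entry$fbg_start, entry$fbg_end),
             parent_accession = entry$accession,
             parent_start = entry$fbg_start, parent_end = entry$fbg_end)
}

#' Average molecular mass of a domain
#'
#' Sum of isotope-averaged residue masses plus one water, for the 20
#' standard residues. `X` residues are a fatal error here (the answer would
#' be wrong), unlike in the scanner where they count as non-cationic.
#'
#' @param domain An `fbg_domain` or a plain residue string.
#' @param unit `"kDa"` (default; rounded to 0.1) or `"Da"` (unrounded).
#' @return Numeric mass.
#' @examples
#' compute_average_mass("G", unit = "Da")   # 75.07
#' compute_average_mass("GG", unit = "Da")  # 132.12, one water lost
#' @export
compute_average_mass <- function(domain, unit = c("kDa", "Da")) {
  unit <- match.arg(unit)
  s <- if (inherits(domain, "fbg_domain")) domain$sequence else domain
  res <- strsplit(s, "")[[1]]
  if (any(!(res %in% .AA20)))
    stop("mass undefined: sequence contains non-standard residue '",
         res[!(res %in% .AA20)][1], "'")
  da <- sum(.AVG_RESIDUE_MASS[res]) + .WATER_MASS
  if (unit == "Da") da else round(da / 1000, 1)
}
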