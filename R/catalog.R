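# The 24-entry human FReP catalogue mirroring the published comparison of
# FBG-domain epitopes (ridge charge count, loop-7 triad, cationic C-tail,
# predicted TLR4 activator, crystal availability).

#' Load the packaged catalogue of the 24 human fibrinogen-related proteins
#'
#' Each human FReP carries a C-terminal fibrinogen-like globe (FBG) domain.
#' The catalogue stores, per protein: family, UniProt accession, FBG domain
#' boundaries in the parent protein (1-based, inclusive), the published
#' epitope annotation (`published_ridge`, `published_triad`, `published_ctail`,
#' `published_predicted`) and whether a crystal structure was available
#' (`crystal_available`, metadata only).
#'
#' Tenascin-family boundaries are the published ones (e.g. tenascin-C
#' 1974--2201 of P24821); boundaries for the other 20 entries are synthetic
#' placeholders spanning the C-terminus of the packaged synthetic parent
#' sequences, and are editable by supplying a different catalogue file.
#'
#' @param path Path to a catalogue TSV. Defaults to the packaged file.
#' @return A `data.frame` of class `frep_catalog` with 24 rows and columns
#'   `name`, `family`, `accession`, `fbg_start`, `fbg_end`, `published_ridge`,
#'   `published_triad`, `published_ctail`, `published_predicted`,
#'   `crystal_available`.
#' @examples
#' cat24 <- load_catalog()
#' table(cat24$family)
#' sum(cat24$published_predicted)
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "frep_catalog.tsv", package = "fbgscan",
                        mustWork = TRUE)
  cat24 <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "family", "accession", "fbg_start", "fbg_end",
              "published_ridge", "published_triad", "published_ctail",
              "published_predicted", "crystal_available")
  if (!all(needed %in% names(cat24)))
    stop("catalogue file lacks required columns: ",
         paste(setdiff(needed, names(cat24)), collapse = ", "))
  for (col in c("published_triad", "published_ctail", "published_predicted",
                "crystal_available"))
    cat24[[col]] <- as.logical(cat24[[col]])
  validate_catalog(cat24)
  class(cat24) <- c("frep_catalog", "data.frame")
  cat24
}

#' Validate a FReP catalogue
#'
#' Enforces the catalogue contract: unique names and accessions, plausible
#' FBG spans (200--260 residues), non-negative ridge counts, and internal
#' consistency of the published classification with the ridge rule
#' (`published_predicted == (published_ridge >= 3)` for every row).
#'
#' @param cat24 A catalogue `data.frame`.
#' @return `cat24`, invisibly; errors on any violation.
#' @export
validate_catalog <- function(cat24) {
  if (anyDuplicated(cat24$name) || anyDuplicated(cat24$accession))
    stop("catalogue corrupt: duplicate protein names or accessions")
  len <- cat24$fbg_end - cat24$fbg_start + 1L
  if (any(cat24$fbg_start >= cat24$fbg_end) || any(len < 200L | len > 260L))
    stop("catalogue corrupt: FBG span must be 200-260 residues")
  if (any(cat24$published_ridge < 0L))
    stop("catalogue corrupt: negative ridge count")
  if (!all(cat24$published_predicted == (cat24$published_ridge >= 3L)))
    stop("catalogue corrupt: predicted column inconsistent with ridge >= 3 rule")
  invisible(cat24)
}
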