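# Synthetic FBG-like domains with known ground truth, so the whole
# alignment -> transfer -> count -> classify pipeline is testable with no
# download. Domains start from the packaged reference scaffold; epitope
# features are implanted at the canonical slots, and background noise is
# confined (by default) to non-annotated positions so the implanted truth
# stays exact.

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Background (non-annotated) positions of the reference scaffold.
.annotated_positions <- function(ann = load_reference()) {
  sort(unique(c(ann$loop5[1]:ann$loop5[2], ann$loop6[1]:ann$loop6[2],
                ann$loop7[1]:ann$loop7[2],
                ann$loop10_anchor:nchar(ann$sequence))))
}

.background_positions <- function(ann = load_reference()) {
  setdiff(seq_len(nchar(ann$sequence)), .annotated_positions(ann))
}

# For each residue, its BLOSUM62-positive exchange partners (may be empty:
# C, G, H, P and W have none, and such sites are skipped in
# conservative-only mode).
.conservative_partners <- function(score_matrix = align_params()$score_matrix) {
  aas <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  out <- lapply(aas, function(r) {
    p <- aas[score_matrix[aas, r] > 0]
    setdiff(p, r)
  })
  names(out) <- aas
  out
}

#' Parameters for the synthetic-domain generator
#'
#' @param n_domains Number of domains for [generate_benchmark()].
#' @param ridge_positives Either a single integer (every domain gets that
#'   many ridge charges) or an integer vector to sample uniformly from
#'   (default `0:7`, the full capacity of the reference ridge slots).
#' @param triad_prob Probability of implanting the D/I/N triad (default
#'   0.25, the catalogue frequency 6/24).
#' @param ctail_prob Probability of a cationic RRKRA tail (default 0.125,
#'   the catalogue frequency 3/24); absent tails are neutral or truncated
#'   with equal probability.
#' @param background_mutation_rate Per-site substitution probability over
#'   non-annotated positions (default 0).
#' @param conservative_only If `TRUE` (default) background substitutions
#'   only use BLOSUM62-positive exchange partners; sites without one are
#'   left unchanged.
#' @param hard_mode If `TRUE` background noise may also hit annotated
#'   positions and the ground truth is recomputed from the final sequence
#'   (stress testing; default `FALSE`).
#' @param seed Master seed; domain i of a benchmark uses `seed + i`.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_domains = 1L, ridge_positives = 0:7,
                         triad_prob = 0.25, ctail_prob = 0.125,
                         background_mutation_rate = 0,
                         conservative_only = TRUE, hard_mode = FALSE,
                         seed = 1L) {
  stopifnot(n_domains >= 1L,
            triad_prob >= 0, triad_prob <= 1,
            ctail_prob >= 0, ctail_prob <= 1,
            background_mutation_rate >= 0, background_mutation_rate <= 1,
            all(ridge_positives >= 0L))
  structure(list(n_domains = as.integer(n_domains),
                 ridge_positives = as.integer(ridge_positives),
                 triad_prob = triad_prob, ctail_prob = ctail_prob,
                 background_mutation_rate = background_mutation_rate,
                 conservative_only = isTRUE(conservative_only),
                 hard_mode = isTRUE(hard_mode),
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate one synthetic FBG-like domain with known truth
#'
#' Starts from the reference scaffold and (i) sets exactly `k` K/R at the
#' canonical ridge slots (remaining slots become non-cationic polar
#' fillers), (ii) implants the D/I/N triad or the inactive P/L/S variant,
#' (iii) keeps the cationic RRKRA tail or replaces/truncates it, then
#' (iv) applies background substitutions away from the annotated regions.
#' Fully reproducible for a fixed seed.
#'
#' @param params A [synth_params()] object.
#' @param seed Seed for this domain (default `params$seed`).
#' @param annotation Reference annotation.
#' @return A list of class `synthetic_record`: `record` (id, description,
#'   sequence) and `truth` (`ridge_count`, `triad`, `ctail`, `label`,
#'   where `label == (ridge_count >= 3)`).
#' @examples
#' r <- generate_domain(synth_params(ridge_positives = 7), seed = 1)
#' r$truth$ridge_count
#' @export
generate_domain <- function(params = synth_params(), seed = params$seed,
                            annotation = load_reference()) {
  n_slots <- length(.RIDGE_SLOTS)
  if (any(params$ridge_positives > n_slots))
    stop(sprintf("ridge_positives exceeds ridge capacity (%d slots)", n_slots))
  with_seed(seed, {
    s <- strsplit(annotation$sequence, "")[[1]]
    k <- if (length(params$ridge_positives) > 1L)
      sample(params$ridge_positives, 1L) else params$ridge_positives
    on_slots <- seq_len(n_slots) <= k
    s[.RIDGE_SLOTS[on_slots]] <- .RIDGE_RESIDUES[on_slots]
    s[.RIDGE_SLOTS[!on_slots]] <-
      sample(.NEUTRAL_FILLERS, sum(!on_slots), replace = TRUE)
    triad <- stats::runif(1) < params$triad_prob
    s[annotation$triad_positions] <-
      if (triad) annotation$triad_residues else c("P", "L", "S")
    ctail <- stats::runif(1) < params$ctail_prob
    tail_iv <- annotation$loop10_anchor:length(s)
    if (ctail) {
      s[tail_iv] <- strsplit("RRKRA", "")[[1]]
    } else if (stats::runif(1) < 0.5) {
      s[tail_iv] <- sample(.NEUTRAL_FILLERS, length(tail_iv), replace = TRUE)
    } else {
      s <- s[-tail_iv]  # truncated tail
    }
    eligible <- if (params$hard_mode) seq_along(s)
                else intersect(.background_positions(annotation), seq_along(s))
    hit <- eligible[stats::runif(length(eligible)) <
                      params$background_mutation_rate]
    if (length(hit)) {
      if (params$conservative_only) {
        partners <- .conservative_partners()
        for (p in hit) {
          cand <- partners[[s[p]]]
          if (length(cand)) s[p] <- sample(cand, 1L)
        }
      } else {
        for (p in hit)
          s[p] <- sample(setdiff(.AA20, s[p]), 1L)
      }
    }
    seq_out <- paste(s, collapse = "")
    if (params$hard_mode) {
      k <- sum(unname(count_cationic(
        seq_out, list(annotation$loop5, annotation$loop6, annotation$loop7))))
      triad <- all(s[annotation$triad_positions] == annotation$triad_residues)
      ctail <- length(s) >= annotation$loop10_anchor &&
        sum(s[annotation$loop10_anchor:length(s)] %in% .CATIONIC) >= 3L
    }
    structure(list(
      record = list(id = sprintf("synth_seed%d", seed),
                    description = sprintf("ridge=%d triad=%s ctail=%s", k,
                                          triad, ctail),
                    sequence = seq_out),
      truth = list(ridge_count = k, triad = triad, ctail = ctail,
                   label = k >= 3L)
    ), class = "synthetic_record")
  })
}

#' Generate a benchmark set of synthetic domains
#'
#' Domain i uses seed `params$seed + i`, so the whole set is reproducible
#' and any single record can be regenerated in isolation.
#'
#' @param params A [synth_params()] object (`n_domains` sets the size).
#' @param annotation Reference annotation.
#' @return A `data.frame` of class `synthetic_benchmark` with columns `id`,
#'   `sequence`, `ridge_count`, `triad`, `ctail`, `label`; attribute
#'   `label_balance` tabulates the labels.
#' @export
generate_benchmark <- function(params = synth_params(n_domains = 10L),
                               annotation = load_reference()) {
  recs <- lapply(seq_len(params$n_domains), function(i)
    generate_domain(params, seed = params$seed + i, annotation = annotation))
  out <- data.frame(
    id = vapply(recs, function(r) r$record$id, character(1)),
    sequence = vapply(recs, function(r) r$record$sequence, character(1)),
    ridge_count = vapply(recs, function(r) r$truth$ridge_count, integer(1)),
    triad = vapply(recs, function(r) r$truth$triad, logical(1)),
    ctail = vapply(recs, function(r) r$truth$ctail, logical(1)),
    label = vapply(recs, function(r) r$truth$label, logical(1)),
    stringsAsFactors = FALSE)
  attr(out, "label_balance") <- table(out$label)
  class(out) <- c("synthetic_benchmark", "data.frame")
  out
}

#' Scan a synthetic benchmark and score recovery of the implanted truth
#'
#' @param bench A [generate_benchmark()] data frame.
#' @param annotation Reference annotation.
#' @param params Scanner parameters.
#' @return `bench` with appended columns `scanned_ridge`, `scanned_label`,
#'   `label_correct`, `ridge_error`; attributes `label_accuracy` and
#'   `ridge_mae`.
#' @export
evaluate_benchmark <- function(bench, annotation = load_reference(),
                               params = scan_params()) {
  profs <- lapply(bench$sequence, scan_domain, annotation = annotation,
                  params = params)
  bench$scanned_ridge <- vapply(profs, function(p) p$ridge_count, integer(1))
  bench$scanned_label <- vapply(profs, function(p) p$predicted_activator,
                                logical(1))
  bench$label_correct <- bench$scanned_label == bench$label
  bench$ridge_error <- bench$scanned_ridge - bench$ridge_count
  attr(bench, "label_accuracy") <- mean(bench$label_correct)
  attr(bench, "ridge_mae") <- mean(abs(bench$ridge_error))
  bench
}
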