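# Independent oracles used across the suite.

# Exhaustive enumeration over every gapped alignment of a and b (residue
# vectors), scoring each path directly: matches from the substitution
# matrix, every maximal gap run of length L costing open + L * extend.
# Exponential, usable only for short sequences; shares no code with the DP.
brute_force_score <- function(a, b, S, gap_open = 10, gap_extend = 0.5) {
  m <- length(a); n <- length(b)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > m && j > n) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= m && j <= n) rec(i + 1, j + 1, sc + S[a[i], b[j]], "M")
    if (i <= m) rec(i + 1, j, sc - gap_extend - if (last == "X") 0 else gap_open, "X")
    if (j <= n) rec(i, j + 1, sc - gap_extend - if (last == "Y") 0 else gap_open, "Y")
  }
  rec(1, 1, 0, "start")
  best
}

rand_seq <- function(n, alphabet = c("A", "C", "D", "K")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Position-by-position column walk over the two gapped rows: an independent
# re-derivation of reference->target interval transfer.
walk_interval <- function(aln, iv) {
  tg <- strsplit(aln$target_aligned, "")[[1]]
  rg <- strsplit(aln$reference_aligned, "")[[1]]
  rpos <- 0L; tpos <- 0L; hits <- integer(0)
  for (k in seq_along(rg)) {
    if (tg[k] != "-") tpos <- tpos + 1L
    if (rg[k] != "-") {
      rpos <- rpos + 1L
      if (rpos >= iv[1] && rpos <= iv[2] && tg[k] != "-")
        hits <- c(hits, tpos)
    }
  }
  if (!length(hits)) NULL else c(min(hits), max(hits))
}

fixture_parents <- function() {
  read_fasta(system.file("extdata", "frep_parents_synthetic.fasta",
                         package = "fbgscan", mustWork = TRUE))
}
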