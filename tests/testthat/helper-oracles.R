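# Independent oracles, coded from first principles and kept free of the
# package's own scanning / statistics internals.

oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_rc <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# position-by-position brute-force matcher; subject letters must be literal
# members of the pattern position's base set (so subject N never matches)
oracle_match_starts <- function(seq, pat) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pat, "")[[1]]
  L <- length(sc); w <- length(pc)
  if (L < w) return(integer(0))
  out <- integer(0)
  for (i in seq_len(L - w + 1)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!sc[i + j - 1] %in% oracle_sets[[pc[j]]]) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, i)
  }
  out
}

# both-strand brute-force scan with the palindrome rule
oracle_scan <- function(seq, pat) {
  fwd <- oracle_match_starts(seq, pat)
  if (identical(oracle_rc(pat), pat)) {
    data.frame(start = fwd, orientation = rep("forward", length(fwd)))
  } else {
    rev <- oracle_match_starts(seq, oracle_rc(pat))
    data.frame(start = c(fwd, rev),
               orientation = c(rep("forward", length(fwd)),
                               rep("reverse", length(rev))))
  }
}

random_pattern <- function(len, degenerate_frac = 0.3) {
  codes <- names(oracle_sets)
  plain <- c("A", "C", "G", "T")
  paste(vapply(seq_len(len), function(i) {
    if (runif(1) < degenerate_frac) sample(codes, 1) else sample(plain, 1)
  }, character(1)), collapse = "")
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# region_set built directly from sequences (no genome needed)
make_region_set <- function(sequences, kind = "up1k") {
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("g%03d", seq_along(sequences))
  }
  structure(list(kind = kind, sequences = sequences,
                 intervals = vector("list", length(sequences))),
            class = "region_set")
}

# expression matrix whose calls (cutoff 2) are exactly the given state
# counts: M = 2 for induced, -2 for suppressed, 0 for neutral
matrix_with_calls <- function(n_induced, n_suppressed, n_neutral,
                              array_id = "a1") {
  vals <- c(rep(2, n_induced), rep(-2, n_suppressed), rep(0, n_neutral))
  n <- length(vals)
  matrix(vals, n, 1, dimnames = list(sprintf("g%05d", seq_len(n)), array_id))
}

# number of positions (out of w) where the consensus is compatible with the
# planted word, maximised over strand and small alignment shifts
consensus_match_positions <- function(consensus, planted, max_shift = 2) {
  score_one <- function(cons, word) {
    cc <- strsplit(cons, "")[[1]]
    wc <- strsplit(word, "")[[1]]
    best <- 0
    for (sh in -max_shift:max_shift) {
      hits <- 0
      for (j in seq_along(wc)) {
        cj <- j + sh
        if (cj < 1 || cj > length(cc)) next
        if (wc[j] %in% oracle_sets[[cc[cj]]]) hits <- hits + 1
      }
      best <- max(best, hits)
    }
    best
  }
  max(score_one(consensus, planted), score_one(oracle_rc(consensus), planted))
}
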