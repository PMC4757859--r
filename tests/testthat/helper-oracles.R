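# Independent oracles used to cross-check the package implementation.
# These deliberately avoid the code paths (and helper functions) under test.

# Exhaustive path enumeration over the slot grammar: try every ordering of
# every subset of the six edges and keep those whose site pairs chain from
# `start` to `end`.
oracle_enumerate_paths <- function(start, end) {
  edges <- data.frame(
    slot = c("pA", "gA", "pB", "gB", "pC", "gC"),
    from = c(1, 2, 3, 4, 1, 2),
    to = c(2, 3, 4, 5, 4, 5),
    stringsAsFactors = FALSE)
  found <- list()
  n <- nrow(edges)
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    perms <- all_permutations(idx)
    for (p in perms) {
      ok <- edges$from[p[1]] == start &&
        edges$to[p[length(p)]] == end
      if (ok && length(p) > 1) {
        for (i in 1:(length(p) - 1)) {
          if (edges$to[p[i]] != edges$from[p[i + 1]]) { ok <- FALSE; break }
        }
      }
      if (ok) found[[length(found) + 1]] <- edges$slot[p]
    }
  }
  unique(found)
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# Nearest-neighbor Tm by direct summation over the published unified
# dimer table (ten unique entries; the complementary dimer is looked up by
# reverse complementing), with the standard salt and concentration terms.
oracle_tm_nn <- function(seq, mon_M = 0.05, ct_M = 500e-9) {
  tbl <- list(
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9))
  rc2 <- function(d) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  dh <- 0; ds <- 0
  for (i in 1:(n - 1)) {
    d <- paste0(chars[i], chars[i + 1])
    v <- if (!is.null(tbl[[d]])) tbl[[d]] else tbl[[rc2(d)]]
    dh <- dh + v[1]; ds <- ds + v[2]
  }
  for (end in chars[c(1, n)]) {
    if (end %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  ds <- ds + 0.368 * (n - 1) * log(mon_M)
  1000 * dh / (ds + 1.987 * log(ct_M / 4)) - 273.15
}

# Smallest n with 1 - (1-p)^n strictly above the confidence, by looping.
oracle_colonies <- function(p, confidence, n_max = 1000) {
  if (p >= 1) return(1L)
  for (n in 1:n_max) {
    if (1 - (1 - p)^n > confidence) return(n)
  }
  NA_integer_
}

# Rotate-and-scan recognition site search with a hand-rolled IUPAC matcher;
# returns 0-based positions of top-strand matches of `pattern` (and of its
# reverse complement when non-palindromic) on a circular/linear substrate.
oracle_find_sites <- function(seq, pattern, circular = FALSE) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
              D = "H", H = "D", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  scan_one <- function(pat) {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    pchars <- strsplit(pat, "")[[1]]
    m <- length(pchars)
    starts <- if (circular) 0:(n - 1) else 0:(n - m)
    hits <- integer(0)
    for (s in starts) {
      ok <- TRUE
      for (k in 1:m) {
        idx <- (s + k - 1) %% n + 1
        if (!circular && s + k - 1 >= n) { ok <- FALSE; break }
        if (!(chars[idx] %in% iupac[[pchars[k]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s)
    }
    hits
  }
  pat_rc <- rc(pattern)
  plus <- scan_one(pattern)
  minus <- if (identical(pattern, pat_rc)) integer(0) else scan_one(pat_rc)
  list(plus = plus, minus = minus)
}

# Brute-force longest terminal overlap by character comparison.
oracle_overlap <- function(a, b, min_overlap) {
  best <- 0
  for (L in min_overlap:min(nchar(a), nchar(b))) {
    if (substr(a, nchar(a) - L + 1, nchar(a)) == substr(b, 1, L)) best <- L
  }
  best
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
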