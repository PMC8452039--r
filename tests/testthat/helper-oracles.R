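# Independent brute-force oracles; deliberately naive, never shared with
# the implementation paths they check.

# Welch's t from the closed-form formulas
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# N50/L50 by explicit cumulative walk over sorted lengths
n50_oracle <- function(lens, frac = 0.5) {
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  acc <- 0
  for (k in seq_along(lens)) {
    acc <- acc + lens[k]
    if (acc >= total * frac) return(list(n = lens[k], l = k))
  }
}

# windowed mean depth by per-base summation
window_mean_oracle <- function(depth, starts, ends) {
  vapply(seq_along(starts), function(i) {
    s <- 0
    for (p in starts[i]:ends[i]) s <- s + depth[p]
    s / (ends[i] - starts[i] + 1)
  }, numeric(1))
}

# plus-strand CpG positions by character scan
cpg_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  which(ch[-length(ch)] == "C" & ch[-1] == "G")
}

# IUPAC motif scan on both strands; returns methyl-C plus-strand positions
IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
           S = "GC", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
           H = "ACT", V = "ACG", N = "ACGT")
enzyme_oracle <- function(s, motif, offset) {
  ch <- strsplit(s, "")[[1]]
  mt <- strsplit(motif, "")[[1]]
  w <- length(mt)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  hit <- function(x, m) all(mapply(function(b, code)
    b %in% strsplit(IUPAC[[code]], "")[[1]], x, m))
  plus <- integer(); minus <- integer()
  for (i in seq_len(length(ch) - w + 1)) {
    win <- ch[i:(i + w - 1)]
    if (hit(win, mt)) plus <- c(plus, as.integer(i + offset))
    if (hit(rev(unname(comp[win])), mt))
      minus <- c(minus, as.integer(i + (w - 1 - offset)))
  }
  list(plus = plus, minus = minus)
}

# two-sided exact binomial p by direct enumeration of dbinom terms
binom_oracle <- function(x, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}
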