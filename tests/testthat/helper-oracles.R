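# Independent naive oracles used to validate the fast implementations.
# Deliberately written as plain loops over the printed definitions.

# approximate entropy: literal triple-loop counting, self-matches included
apen_oracle <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1
    lc <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0
      for (j in seq_len(n)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      lc[i] <- log(cnt / n)
    }
    mean(lc)
  }
  phi(m) - phi(m + 1)
}

# fuzzy entropy: mean-centered windows, exp(-d^grad / r), j != i,
# N - m windows at both scales
fuzzyen_oracle <- function(x, m, r, grad = 2) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - m
    z <- matrix(0, n, mm)
    for (i in seq_len(n)) {
      w <- x[i:(i + mm - 1)]
      z[i, ] <- w - mean(w)
    }
    tot <- 0
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        d <- max(abs(z[i, ] - z[j, ]))
        s <- s + exp(-d^grad / r)
      }
      tot <- tot + s / (n - 1)
    }
    tot / n
  }
  log(phi(m)) - log(phi(m + 1))
}

# separability: direct per-pair evaluation with population variances
ez_oracle <- function(values, groups) {
  gs <- sort(unique(groups))
  popvar <- function(v) mean((v - mean(v))^2)
  total <- 0
  for (i in seq_along(gs)[-length(gs)]) {
    for (j in (i + 1):length(gs)) {
      a <- values[groups == gs[i]]
      b <- values[groups == gs[j]]
      total <- total + abs((mean(a) - mean(b)) / sqrt(popvar(a) + popvar(b)))
    }
  }
  total
}

# signal band power by direct summation of the raw periodogram
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  sum(p[keep & f >= lo & f <= hi])
}

# small deterministic cohort spec for fast tests
tiny_spec <- function(seed = 42, sizes = rep(3, 8)) {
  cohort_spec(group_sizes = sizes, seed = seed)
}
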