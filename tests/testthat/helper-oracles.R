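# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately naive (explicit loops, direct formulas)
# so it cannot share a bug with the vectorized implementation.

# brute-force Tort MI: explicit loop over samples and bins
brute_mi <- function(phase, amplitude, n_bins = 24) {
  delta <- 2 * pi / n_bins
  sums <- numeric(n_bins)
  counts <- numeric(n_bins)
  for (i in seq_along(phase)) {
    ph <- phase[i]
    if (ph >= pi) ph <- ph - 2 * pi
    j <- floor((ph + pi) / delta) + 1
    if (j > n_bins) j <- n_bins
    sums[j] <- sums[j] + amplitude[i]
    counts[j] <- counts[j] + 1
  }
  means <- ifelse(counts > 0, sums / pmax(counts, 1), 0)
  p <- means / sum(means)
  h <- 0
  for (j in seq_len(n_bins)) if (p[j] > 0) h <- h - p[j] * log(p[j])
  (log(n_bins) - h) / log(n_bins)
}

# brute-force one-way ANOVA F from raw sums of squares
brute_anova_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  k <- length(groups); N <- length(all_v)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# brute-force sliding-window enumeration
brute_windows <- function(n, w, s) {
  starts <- c()
  st <- 1
  while (st + w - 1 <= n) {
    starts <- c(starts, st)
    st <- st + s
  }
  starts
}

groups_to_df <- function(groups) {
  data.frame(
    value = unlist(groups),
    group = rep(paste0("g", seq_along(groups)),
                times = vapply(groups, length, 0L)))
}

# pixel-mask fixtures -------------------------------------------------------

line_mask <- function(len = 50, pad = 5) {
  m <- matrix(FALSE, 2 * pad + 1, len + 2 * pad)
  m[pad + 1, (pad + 1):(pad + len)] <- TRUE
  m
}

# three arms (E, NW, SW) of `arm` pixels each meeting at one centre pixel
y_mask <- function(arm = 20) {
  sz <- 2 * arm + 21
  c0 <- (sz + 1) %/% 2
  m <- matrix(FALSE, sz, sz)
  for (i in 0:arm) {
    m[c0, c0 + i] <- TRUE
    m[c0 - i, c0 - i] <- TRUE
    m[c0 + i, c0 - i] <- TRUE
  }
  m
}

disk_mask <- function(diameter_px, pad = 6) {
  r <- diameter_px / 2
  sz <- 2 * ceiling(r) + 2 * pad + 1
  c0 <- (sz + 1) %/% 2
  m <- matrix(FALSE, sz, sz)
  for (y in 1:sz) for (x in 1:sz)
    if ((x - c0)^2 + (y - c0)^2 <= r^2) m[y, x] <- TRUE
  m
}

# comb tree: horizontal spine with vertical teeth; J 3-way junctions and
# J + 2 endpoints by construction (teeth spaced so junctions never merge)
comb_mask <- function(n_teeth, spine = NULL, tooth = 8, gap = 5) {
  spine <- spine %||% (n_teeth * gap + 2 * gap)
  m <- matrix(FALSE, tooth + 12, spine + 10)
  y0 <- tooth + 6
  m[y0, 6:(5 + spine)] <- TRUE
  for (t in seq_len(n_teeth)) {
    x <- 5 + gap * t
    m[(y0 - tooth):(y0 - 1), x] <- TRUE
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sine_rec <- function(freq, fs = 500, dur = 10, amp = 1) {
  lfp_recording(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / fs)), fs)
}
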