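# Independent oracles used to freeze expected values. These deliberately use
# brute force / literal transcription, not the package's code paths.

# Brute-force peak separation of a two-channel line: integer argmax of each
# channel, difference in samples.
oracle_peak_separation_nm <- function(pm, actin, step_nm) {
  (which.max(actin) - which.max(pm)) * step_nm
}

# Exact two-sided Mann-Whitney p by full enumeration of all rank
# assignments (no ties assumed). Two-sided by symmetry of the null U
# distribution about n1*n2/2.
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Literal transcription of the two-stage linear step-up procedure
# (adaptive step-up with m0 estimated by a first pass at level
# alpha / (1 + alpha)); returns the logical discovery vector.
oracle_two_stage_discoveries <- function(p, alpha = 0.05) {
  m <- length(p)
  q1 <- alpha / (1 + alpha)
  step_up <- function(p, level, m_eff) {
    o <- order(p)
    ps <- p[o]
    crit <- seq_len(m) * level / m_eff
    k <- which(ps <= crit)
    r <- if (length(k)) max(k) else 0L
    rej <- logical(m)
    if (r > 0) rej[o[seq_len(r)]] <- TRUE
    rej
  }
  r1 <- sum(step_up(p, q1, m))
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(p, q1, m - r1)
}

# Exhaustive triangle-threshold construction: scan all 256 candidate bins
# and maximize the perpendicular distance from the histogram point to the
# peak-to-tail chord.
oracle_triangle_bin <- function(v, nb = 256) {
  rng <- range(v)
  brk <- seq(rng[1], rng[2], length.out = nb + 1)
  h <- tabulate(pmin(nb, findInterval(v, brk, rightmost.closed = TRUE)), nb)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- min(nz); hi <- max(nz)
  if ((peak - lo) > (hi - peak)) {     # longer left tail: mirror
    h <- rev(h); peak <- nb - peak + 1; hi <- nb - lo + 1
    mirrored <- TRUE
  } else mirrored <- FALSE
  p1 <- c(peak, h[peak]); p2 <- c(hi, h[hi])
  dvec <- p2 - p1
  best <- peak; bestd <- -Inf
  for (b in peak:hi) {
    # perpendicular distance from (b, h[b]) to the chord
    d <- abs(dvec[1] * (p1[2] - h[b]) - (p1[1] - b) * dvec[2]) /
      sqrt(sum(dvec^2))
    below <- (h[b] < p1[2] + (b - p1[1]) / dvec[1] * dvec[2])
    if (below && d > bestd) { bestd <- d; best <- b }
  }
  if (mirrored) best <- nb - best + 1
  brk[best]
}

# Histogram mode at 1-fL bins, independent of modal_volume()'s binning code.
oracle_hist_mode <- function(v, bin = 1) {
  b <- round(v / bin)
  as.numeric(names(sort(table(b), decreasing = TRUE))[1]) * bin
}
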