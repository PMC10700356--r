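# The study-style statistical procedures: two-sided rank tests, Pearson
# correlation, and the adaptive two-stage step-up FDR.

new_ew_test <- function(statistic, p, method, n) {
  structure(list(statistic = statistic, p_two_sided = p, method = method,
                 n = n),
            class = "ew_test")
}

#' @export
print.ew_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_two_sided,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.ew_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_two_sided,
         method = x$method, n = paste(x$n, collapse = ","))
}

#' @export
glance.ew_test <- function(x, ...) tidy(x)

#' Two-sided Mann-Whitney U test
#'
#' U statistic for the first group; the two-sided p-value is exact (from
#' the null distribution of U, which is symmetric about `n1*n2/2`) when the
#' smaller group has at most 8 observations and there are no ties, and a
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param x,y numeric samples (both non-empty).
#' @return an `ew_test` (see [tidy()]).
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && min(n1, n2) <= 8) {
    mu <- n1 * n2 / 2
    dev <- abs(u1 - mu)
    uu <- 0:(n1 * n2)
    p <- sum(dwilcox(uu[abs(uu - mu) >= dev - 1e-9], n1, n2))
    method <- "Mann-Whitney U (exact)"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sig <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_term))
    if (sig == 0) return(new_ew_test(u1, 1, "Mann-Whitney U (normal approx.)",
                                     c(n1, n2)))
    z <- (abs(u1 - mu) - 0.5) / sig
    p <- min(1, 2 * pnorm(-max(0, z)))
    method <- "Mann-Whitney U (normal approx.)"
  }
  new_ew_test(u1, min(1, p), method, c(n1, n2))
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction; p-value from the chi-square
#' distribution with k - 1 degrees of freedom. All-identical data give
#' H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups), or a data
#'   frame with `value` and `group` columns given via `value`/`group`.
#' @param value,group optional tidy-eval columns when `groups` is a data
#'   frame.
#' @return an `ew_test`.
#' @export
kruskal_wallis <- function(groups, value = NULL, group = NULL) {
  if (is.data.frame(groups)) {
    v <- eval_tidy(enquo(value), groups)
    g <- eval_tidy(enquo(group), groups)
    groups <- split(v, g)
  }
  if (length(groups) < 2 || any(!lengths(groups))) {
    abort("need >= 2 non-empty groups")
  }
  v <- unlist(groups, use.names = FALSE)
  n <- length(v)
  if (diff(range(v)) == 0) {
    return(new_ew_test(0, 1, "Kruskal-Wallis", lengths(groups)))
  }
  r <- rank(v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  tie_tab <- table(v)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  h <- h / corr
  p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  new_ew_test(h, p, "Kruskal-Wallis", lengths(groups))
}

#' Pearson correlation test
#'
#' Pearson r with a two-sided t-test on n - 2 degrees of freedom (the
#' correlation analysis behind the spacing-versus-speed readout; shares
#' its implementation with [spacing_speed_correlation()]).
#'
#' @param x,y paired numeric vectors (>= 3 points, non-constant).
#' @return an `ew_test` with the fitted line in `$fit`.
#' @export
pearson_test <- function(x, y) {
  fit <- pearson_fit(x, y)
  out <- new_ew_test(fit$r, fit$p_value, "Pearson correlation", fit$n)
  out$fit <- fit
  out
}

#' Two-stage step-up FDR (adaptive Benjamini-Krieger-Yekutieli)
#'
#' The two-stage linear step-up procedure: stage 1 applies the
#' Benjamini-Hochberg step-up at level `a' = alpha / (1 + alpha)`; the
#' number of rejections r1 estimates the number of true nulls as
#' `m0 = m - r1`; stage 2 re-applies the step-up with thresholds
#' `i * a' / m0`. If r1 = 0 nothing is rejected; if r1 = m everything is.
#' q-values are the adaptive step-up q-values scaled so that `q <= alpha`
#' exactly reproduces the stage-2 discovery set (like the procedure
#' itself, they depend on the chosen `alpha`); monotonicity in p is
#' enforced.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return a `q_value_set`: list with `p`, `q`, `discovery` (logical),
#'   `m0`, `alpha`.
#' @export
two_stage_fdr <- function(pvals, alpha = 0.05) {
  p <- as.numeric(pvals)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p)
  a1 <- alpha / (1 + alpha)
  bh_reject <- function(p, level, m_eff) {
    o <- order(p)
    ps <- p[o]
    ok <- which(ps <= seq_along(ps) * level / m_eff)
    r <- if (length(ok)) max(ok) else 0
    rej <- logical(length(p))
    if (r > 0) rej[o[seq_len(r)]] <- TRUE
    rej
  }
  r1 <- sum(bh_reject(p, a1, m))
  if (r1 == 0) {
    disc <- logical(m)
    m0 <- m
  } else if (r1 == m) {
    disc <- rep(TRUE, m)
    m0 <- 0
  } else {
    m0 <- m - r1
    disc <- bh_reject(p, a1, m0)
  }
  # adaptive step-up q-values, scaled so that q <= alpha <=> stage-2 rejection
  q <- if (m0 == 0) rep(0, m) else {
    o <- order(p)
    ps <- p[o]
    raw <- m0 * (1 + alpha) * ps / seq_along(ps)
    qs <- rev(cummin(rev(raw)))
    qs <- pmin(1, qs)
    out <- numeric(m)
    out[o] <- qs
    out
  }
  structure(list(p = p, q = q, discovery = disc, m0 = m0, alpha = alpha),
            class = "q_value_set")
}

#' @export
print.q_value_set <- function(x, ...) {
  cat(sprintf("<q_value_set> %d tests, %d discoveries at alpha = %g (m0 = %d)\n",
              length(x$p), sum(x$discovery), x$alpha, x$m0))
  invisible(x)
}

#' @export
tidy.q_value_set <- function(x, ...) {
  tibble(p_value = x$p, q_value = x$q, discovery = x$discovery)
}

#' @export
glance.q_value_set <- function(x, ...) {
  tibble(n = length(x$p), discoveries = sum(x$discovery), m0 = x$m0,
         alpha = x$alpha)
}
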