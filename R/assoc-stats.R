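# Exact and asymptotic statistics for 2x2 group comparisons. Tables are
# oriented rows = groups (high, normal), columns = (has feature, lacks
# feature), i.e. matrix(c(a, c, b, d), nrow = 2) with a = high carriers.

as_2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2)) || any(t < 0) || any(t != round(t)) || anyNA(t)) {
    stop("expected a 2x2 table of non-negative integer counts", call. = FALSE)
  }
  storage.mode(t) <- "double"
  t
}

#' One-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric tail probability under fixed margins, computed with
#' log-gamma arithmetic (stable up to totals of about 1e6). With
#' `direction = "greater"` the p-value is P(X >= a): the probability of at
#' least the observed count of feature carriers in the first (case) row.
#'
#' @param t 2x2 matrix: rows = groups, columns = (has feature, lacks feature).
#' @param direction `"greater"` (default) tests excess in the first row,
#'   `"less"` tests deficit.
#' @return p-value in (0, 1]. Degenerate margins (e.g. no carriers at all)
#'   give p = 1.
#' @examples
#' fisher_one_sided(matrix(c(5, 0, 89, 91), nrow = 2))  # 0.032
#' @export
fisher_one_sided <- function(t, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  t <- as_2x2(t)
  a <- t[1, 1]
  r1 <- sum(t[1, ])
  r2 <- sum(t[2, ])
  k <- sum(t[, 1])
  n <- r1 + r2
  lo <- max(0, k - r2)
  hi <- min(r1, k)
  if (hi < lo) return(1)
  x <- if (direction == "greater") a:hi else lo:a
  lp <- lchoose(r1, x) + lchoose(r2, k - x) - lchoose(n, k)
  m <- max(lp)
  min(1, exp(m) * sum(exp(lp - m)))
}

#' Odds ratio with Haldane-Anscombe zero-cell correction and Wald CI
#'
#' Point estimate and Wald confidence interval for the odds ratio of a 2x2
#' table. When the table contains at least one zero cell and
#' `zero_cell_correction` is enabled, 0.5 is added to all four cells before
#' computing both the OR and the CI (Haldane-Anscombe correction).
#'
#' @param t 2x2 matrix as in [fisher_one_sided()].
#' @param zero_cell_correction Apply the 0.5-to-all-cells correction when any
#'   cell is zero (default `TRUE`).
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return A list with `or`, `ci_low`, `ci_high`, `corrected` (whether the
#'   correction fired) and `conf_level`.
#' @examples
#' odds_ratio(matrix(c(1, 0, 93, 91), nrow = 2))  # OR = 2.94
#' @export
odds_ratio <- function(t, zero_cell_correction = TRUE, conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  t <- as_2x2(t)
  corrected <- FALSE
  if (any(t == 0)) {
    if (!zero_cell_correction) {
      stop("table contains a zero cell, so the odds ratio is undefined; ",
           "enable zero_cell_correction", call. = FALSE)
    }
    t <- t + 0.5
    corrected <- TRUE
  }
  or <- (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  se <- sqrt(sum(1 / t))
  z <- stats::qnorm((1 + conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  list(or = or, ci_low = ci[1], ci_high = ci[2],
       corrected = corrected, conf_level = conf_level)
}

#' Two-sample t-test from raw values or summaries
#'
#' Pooled-variance Student's t-test by default, with Welch's unequal-variance
#' variant available. Each group may be given either as a numeric vector of
#' raw values or as a `list(mean =, sd =, n =)` summary, so published
#' mean +/- SD tables can be re-tested directly.
#'
#' @param x,y Numeric vectors, or `list(mean =, sd =, n =)` summaries.
#' @param variant `"pooled"` (Student, default) or `"welch"`.
#' @param sides 2 (default) for a two-tailed p, 1 for one-tailed
#'   (direction-agnostic: the tail on the side of the observed difference).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch"), sides = 2) {
  variant <- match.arg(variant)
  stopifnot(sides %in% c(1, 2))
  summ <- function(v) {
    if (is.list(v)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(v)), v$n >= 2, v$sd >= 0)
      list(m = v$mean, s = v$sd, n = v$n)
    } else {
      if (length(v) < 2) stop("need at least 2 values per group", call. = FALSE)
      list(m = mean(v), s = stats::sd(v), n = length(v))
    }
  }
  a <- summ(x)
  b <- summ(y)
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$s^2 + (b$n - 1) * b$s^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$s^2 / a$n
    vb <- b$s^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  if (se == 0) {
    # no variance in either group: identical means are uninformative
    tstat <- if (a$m == b$m) 0 else sign(a$m - b$m) * Inf
  } else {
    tstat <- (a$m - b$m) / se
  }
  p <- if (is.infinite(tstat)) 0 else sides * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = min(p, 1))
}
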