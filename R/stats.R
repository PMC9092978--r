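# Nonparametric statistical toolkit: coefficient of variation, Spearman rank
# correlation against zero, Wilcoxon rank-sum and signed-rank tests, and the
# Bonferroni level adjustment. Midranks are used for ties throughout; exact
# null distributions are used at desk scale (permutation enumeration for
# Spearman up to n = 9, the exact signed-rank/rank-sum distributions for
# untied samples up to n = 25), normal or t approximations with tie and
# continuity corrections above.

label_of <- function(expr_chr) {
  lab <- paste(expr_chr, collapse = "")
  if (nchar(lab) > 32) paste0(substr(lab, 1, 29), "...") else lab
}

new_stat_result <- function(test_name, x_label, y_label, n, estimate,
                            statistic, p, alpha_used = 0.05,
                            method = NA_character_) {
  p <- min(max(p, 0), 1)
  structure(list(test_name = test_name, x_label = x_label, y_label = y_label,
                 n = n, estimate = estimate, statistic = statistic, p = p,
                 alpha_used = alpha_used,
                 significant = isTRUE(p < alpha_used),
                 method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: %s vs %s\n", x$test_name, x$x_label,
              x$y_label))
  cat(sprintf("  n = %s, estimate = %.3f, statistic = %.3f, p = %s%s\n",
              paste(x$n, collapse = "/"), x$estimate, x$statistic,
              format_p(x$p, x$alpha_used),
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Render a p-value the way the summary tables print it
#'
#' At alpha = 0.05 p-values are rounded (up) to two decimals and values below
#' 0.01 print as "<0.01"; at the Bonferroni level 0.01 they are rounded to
#' three decimals and values below 0.001 print as "<0.001".
#'
#' @param p p-value.
#' @param alpha significance level in force (0.05 or 0.01).
#' @return character rendering.
#' @export
format_p <- function(p, alpha = 0.05) {
  if (is.na(p)) return("NA")
  if (alpha <= 0.01) {
    if (p < 0.001) "<0.001" else sprintf("%.3f", ceiling(p * 1000) / 1000)
  } else {
    if (p < 0.01) "<0.01" else sprintf("%.2f", ceiling(p * 100) / 100)
  }
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param values numeric vector (NAs dropped), n >= 2, nonzero mean.
#' @return dimensionless CV.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("CV needs at least two values")
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero")
  stats::sd(values) / m
}

midrank <- function(x) rank(x, ties.method = "average")

# all permutations of 1..n, one per row (n <= 9)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

spearman_rho <- function(x, y) {
  rx <- midrank(x); ry <- midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Spearman rank correlation test against zero
#'
#' r_s is the Pearson correlation of the midranks. Two-sided p-value: for
#' n <= `exact_limit` the full permutation distribution of r_s is enumerated
#' (valid under ties); above, the t approximation
#' t = r_s sqrt((n-2)/(1-r_s^2)) on n-2 degrees of freedom.
#'
#' @param x,y paired numeric vectors; pairs with NA in either are dropped.
#' @param alpha significance level recorded in the result.
#' @param exact_limit largest n for which the exact permutation branch is
#'   used (default 9).
#' @param x_label,y_label variable names for reporting.
#' @return a `stat_result` with estimate = statistic = r_s.
#' @export
spearman_test <- function(x, y, alpha = 0.05, exact_limit = 9L,
                          x_label = label_of(deparse(substitute(x))),
                          y_label = label_of(deparse(substitute(y)))) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman_test needs at least 3 complete pairs")
  r <- spearman_rho(x, y)
  if (is.na(r)) stop("correlation undefined: constant x or y")
  if (n <= exact_limit) {
    perms <- permutations_of(n)
    rxc <- midrank(x) - (n + 1) / 2
    ryc <- midrank(y) - (n + 1) / 2
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    # correlation of the fixed x ranks with each permutation of the y ranks
    M <- ryc[perms]
    dim(M) <- dim(perms)
    stats_all <- as.numeric(M %*% rxc) / denom
    p <- mean(abs(stats_all) >= abs(r) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  new_stat_result("spearman", x_label, y_label, n, estimate = r,
                  statistic = r, p = p, alpha_used = alpha, method = method)
}

# tie correction term sum(t^3 - t) over tie groups
tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Wilcoxon rank-sum test (two independent samples)
#'
#' Two-sided test of equal location. The reported statistic Z is the normal
#' approximation with midrank tie correction and continuity correction
#' (positive when `x` tends to exceed `y`). The p-value uses the exact
#' rank-sum distribution when both samples are small and untied, otherwise
#' the same normal approximation.
#'
#' @param x,y numeric samples (NAs dropped), each of size >= 2.
#' @param alpha significance level recorded in the result.
#' @param exact_limit largest per-group n for the exact branch (default 25).
#' @param x_label,y_label labels for reporting.
#' @return a `stat_result`; `estimate` is the difference of medians
#'   (median(x) - median(y)), `statistic` is Z.
#' @export
rank_sum_test <- function(x, y, alpha = 0.05, exact_limit = 25L,
                          x_label = label_of(deparse(substitute(x))),
                          y_label = label_of(deparse(substitute(y)))) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  N <- n1 + n2
  r <- midrank(c(x, y))
  W <- sum(r[seq_len(n1)])                    # rank sum of x
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- tie_term(r)
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - ties / (N * (N - 1))))
  d <- U - mu
  z <- if (sigma == 0) 0 else (d - sign(d) * 0.5) / sigma
  has_ties <- ties > 0
  if (!has_ties && n1 <= exact_limit && n2 <= exact_limit) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    p <- min(p, 1)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  new_stat_result("rank_sum", x_label, y_label, c(n1, n2),
                  estimate = stats::median(x) - stats::median(y),
                  statistic = z, p = p, alpha_used = alpha, method = method)
}

#' Wilcoxon signed-rank test (one sample against mu0)
#'
#' Two-sided test that the differences `d - mu0` are symmetric about zero.
#' Exact differences of zero are dropped (Wilcoxon convention); if all are
#' zero the test returns p = 1 with a warning. The statistic Z is the
#' normal approximation with tie and continuity correction, positive when
#' the differences tend to be positive. The p-value uses the exact
#' signed-rank distribution for untied samples up to `exact_limit`.
#'
#' @param d numeric differences (NAs dropped).
#' @param mu0 hypothesized center, default 0.
#' @param alpha significance level recorded in the result.
#' @param exact_limit largest n for the exact branch (default 25).
#' @param x_label label for reporting.
#' @return a `stat_result`; `estimate` is median(d) - mu0, `statistic` Z.
#' @export
signed_rank_test <- function(d, mu0 = 0, alpha = 0.05, exact_limit = 25L,
                             x_label = label_of(deparse(substitute(d)))) {
  d <- d[!is.na(d)] - mu0
  est <- stats::median(d)
  d_nz <- d[d != 0]
  n <- length(d_nz)
  if (n == 0L) {
    warning("all differences are zero; p = 1 by convention")
    return(new_stat_result("signed_rank", x_label, "0", length(d),
                           estimate = est, statistic = 0, p = 1,
                           alpha_used = alpha, method = "degenerate"))
  }
  if (n < 2L) stop("signed_rank_test needs >= 2 nonzero differences")
  r <- midrank(abs(d_nz))
  Wp <- sum(r[d_nz > 0])
  mu <- n * (n + 1) / 4
  ties <- tie_term(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - ties / 48)
  dev <- Wp - mu
  z <- if (sigma == 0) 0 else (dev - sign(dev) * 0.5) / sigma
  if (ties == 0 && n <= exact_limit) {
    p <- 2 * min(stats::psignrank(Wp, n), 1 - stats::psignrank(Wp - 1, n))
    p <- min(p, 1)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  new_stat_result("signed_rank", x_label, as.character(mu0), n,
                  estimate = est, statistic = z, p = p, alpha_used = alpha,
                  method = method)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level.
#' @param k number of tests (>= 1).
#' @return alpha / k.
#' @export
bonferroni_alpha <- function(alpha, k) {
  stopifnot(k >= 1)
  alpha / k
}

#' Turn stat results into a table row set
#'
#' @param results list of `stat_result` objects.
#' @return data.frame with one row per result, rendering p-values with
#'   [format_p()] and flagging significance ("bold" column).
#' @export
stat_results_table <- function(results) {
  do.call(rbind, lapply(results, function(s) {
    data.frame(test = s$test_name, x = s$x_label, y = s$y_label,
               n = paste(s$n, collapse = "/"),
               estimate = round(s$estimate, 3),
               statistic = round(s$statistic, 3),
               p = s$p, p_shown = format_p(s$p, s$alpha_used),
               alpha = s$alpha_used, bold = s$significant,
               stringsAsFactors = FALSE)
  }))
}
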