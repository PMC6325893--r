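new_group_comparison <- function(test_name, statistic, p_value, group_sizes,
                                 continuity = NA, ties = NA, extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, group_sizes = group_sizes,
                   continuity_correction = continuity,
                   tie_correction = ties), extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt_p <- function(p) if (is.na(p)) "NA"
    else if (p < 2.2e-16) "< 2.2e-16" else format(signif(p, 5))
  if (is.matrix(x$p_value)) {
    cat(sprintf("<group_comparison> %s, %d groups; pairwise p-values:\n",
                x$test_name, length(x$group_sizes)))
    print(signif(x$p_value, 5))
  } else {
    cat(sprintf("<group_comparison> %s: statistic = %.6g, p = %s\n",
                x$test_name, x$statistic, fmt_p(x$p_value)))
  }
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with midranks for ties. In exact mode the null
#' distribution of the rank sum is obtained by complete enumeration of all
#' group assignments of the pooled (possibly tied) ranks; `mode = "auto"`
#' enumerates whenever both groups have at most 10 observations. Otherwise a
#' normal approximation with tie-corrected variance and an optional 0.5
#' continuity correction is used. The reported statistic is the Mann-Whitney
#' U for the first group.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default `TRUE`; ignored in exact mode).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A `group_comparison` with fields `statistic` (U), `p_value`,
#'   `mode_used` and `z` (normal deviate, `NA` in exact mode).
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE,
                              mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])                 # rank sum of x
  U <- W - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (mode == "auto") mode <- if (n1 <= 10 && n2 <= 10) "exact" else "normal"
  if (mode == "exact") {
    if (choose(N, n1) > 5e6)
      stop("exact enumeration infeasible for these group sizes")
    combs <- utils::combn(N, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    mu <- n1 * (N + 1) / 2
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    return(new_group_comparison("wilcoxon_rank_sum", U, p, c(n1, n2),
                                continuity = FALSE, ties = has_ties,
                                extra = list(mode_used = "exact",
                                             z = NA_real_)))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  cc <- if (continuity) sign(U - mu) * 0.5 else 0
  z <- (U - mu - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  new_group_comparison("wilcoxon_rank_sum", U, p, c(n1, n2),
                       continuity = continuity, ties = has_ties,
                       extra = list(mode_used = "normal", z = z))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on
#' `length(groups) - 1` degrees of freedom, via [stats::kruskal.test()]. The
#' degenerate case in which every pooled value is identical is defined as
#' `H = 0, p = 1` (no evidence of any difference).
#'
#' @param groups List of at least two numeric vectors, total n at least 3.
#' @return A `group_comparison` with `statistic` (H), `p_value` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("all groups must be nonempty")
  if (sum(sizes) < 3) stop("need a total of at least 3 observations")
  pooled <- unlist(groups)
  if (max(pooled) == min(pooled))
    return(new_group_comparison("kruskal_wallis", 0, 1, sizes, ties = TRUE,
                                extra = list(df = length(groups) - 1)))
  kt <- stats::kruskal.test(groups)
  new_group_comparison("kruskal_wallis", unname(kt$statistic),
                       kt$p.value, sizes,
                       ties = anyDuplicated(pooled) > 0,
                       extra = list(df = unname(kt$parameter)))
}

#' Nemenyi post-hoc pairwise comparisons
#'
#' All-pairs follow-up to a Kruskal-Wallis test: mean ranks of the pooled
#' sample are compared pairwise through the studentized-range distribution
#' (infinite degrees of freedom), with the variance tie-corrected by the
#' usual factor `1 - sum(t^3 - t) / (N^3 - N)`.
#'
#' @param groups List of at least two (three recommended) numeric vectors.
#' @return A `group_comparison` whose `p_value` is a symmetric matrix with
#'   unit diagonal; `statistic` holds the pairwise studentized-range
#'   statistics.
#' @export
nemenyi_posthoc <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups")
  k <- length(groups)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("all groups must be nonempty")
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_len(k), sizes)
  mean_ranks <- tapply(r, grp, mean)
  tie_tab <- table(r)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (C <= 0) C <- NA_real_                # all values identical
  q <- matrix(0, k, k)
  p <- matrix(1, k, k)
  nm <- if (!is.null(names(groups))) names(groups) else
    paste0("group", seq_len(k))
  dimnames(q) <- dimnames(p) <- list(nm, nm)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (is.na(C)) { qij <- 0 } else {
      se <- sqrt(N * (N + 1) / 12 * C * (1 / sizes[i] + 1 / sizes[j]))
      qij <- abs(mean_ranks[i] - mean_ranks[j]) / se * sqrt(2)
    }
    pij <- stats::ptukey(qij, nmeans = k, df = Inf, lower.tail = FALSE)
    q[i, j] <- q[j, i] <- qij
    p[i, j] <- p[j, i] <- pij
  }
  new_group_comparison("nemenyi", q, p, sizes,
                       ties = anyDuplicated(pooled) > 0)
}
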