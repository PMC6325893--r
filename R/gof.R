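#' Empirical-distribution-function goodness-of-fit statistics
#'
#' With `u_(i) = cdf(x_(i))` on the sorted sample of size `n`:
#' \deqn{A^2 = -n - \frac{1}{n}\sum_i (2i-1)[\ln u_{(i)} + \ln(1-u_{(n+1-i)})]}
#' \deqn{D = \max_i \max(i/n - u_{(i)},\ u_{(i)} - (i-1)/n)}
#' \deqn{W^2 = \sum_i (u_{(i)} - (2i-1)/(2n))^2 + 1/(12n)}
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]` before taking logs;
#' clamping is reported via the `clamped` field.
#'
#' @param sample A [cell_sample()] or numeric vector.
#' @param cdf A vectorized distribution function mapping the sample into
#'   `[0, 1]`.
#' @return List with `A2`, `D`, `W2`, `n` and `clamped` (count of clamped
#'   points).
#' @export
edf_statistics <- function(sample, cdf) {
  x <- sort(sample_values(sample))
  n <- length(x)
  u <- cdf(x)
  if (anyNA(u) || any(u < 0) || any(u > 1))
    stop("contract error: cdf returned values outside [0, 1]")
  clamped <- sum(u < 1e-12 | u > 1 - 1e-12)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  D <- max(pmax(i / n - u, u - (i - 1) / n))
  W2 <- sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n)
  list(A2 = A2, D = D, W2 = W2, n = n, clamped = clamped)
}

## Asymptotic (fully specified null) CDF of the Anderson-Darling statistic,
## from the classical alternating series with numerically integrated inner
## terms. Accurate to ~1e-8 across the support.
ad_asymptotic_cdf <- function(z) {
  vapply(z, function(zz) {
    if (!is.finite(zz)) return(if (zz > 0) 1 else 0)
    if (zz <= 0.01) return(0)
    if (zz >= 32) return(1)
    tot <- 0
    for (j in 0:40) {
      lam <- (4 * j + 1)^2 * pi^2 / (8 * zz)
      inner <- stats::integrate(function(w)
        exp(zz / (8 * (w^2 + 1)) - lam * w^2), 0, Inf,
        rel.tol = 1e-10)$value
      term <- exp(lgamma(j + 0.5) - lgamma(j + 1)) / sqrt(pi) *
        (4 * j + 1) * exp(-lam) * inner
      tot <- tot + (-1)^j * term
      if (abs(term) < 1e-14 && j > 2) break
    }
    min(max(tot * sqrt(2 * pi) / zz, 0), 1)
  }, numeric(1))
}

new_gof_result <- function(statistic_name, statistic, null_spec, p_value,
                           calibration) {
  structure(list(statistic_name = statistic_name, statistic = statistic,
                 null_spec = null_spec, p_value = p_value,
                 calibration = calibration),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  p <- if (is.null(x$p_value) || is.na(x$p_value)) "NA"
    else if (x$p_value < 2.2e-16) "< 2.2e-16"
    else signif(x$p_value, 5)
  cat(sprintf("<gof_result> %s = %.6g vs %s %s null, p = %s (%s)\n",
              x$statistic_name, x$statistic,
              if (isTRUE(x$null_spec$composite)) "composite" else "fixed",
              x$null_spec$family, p, x$calibration$method))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Computes the W statistic and p-value by the standard published
#' approximation (Royston's algorithm, as implemented in
#' [stats::shapiro.test()]). Ties — unavoidable when resampling at bin
#' centers without jitter — are allowed with a warning.
#'
#' @param sample A [cell_sample()] or numeric vector with `3 <= n <= 5000`.
#' @return A `gof_result` with `statistic_name = "SW"`.
#' @export
shapiro_wilk <- function(sample) {
  x <- sample_values(sample)
  n <- length(x)
  if (n < 3) stop("Shapiro-Wilk requires n >= 3 (got ", n, ")")
  if (n > 5000) stop("Shapiro-Wilk requires n <= 5000 (got ", n, ")")
  if (anyDuplicated(x))
    warning("tied values present; Shapiro-Wilk computed on the tied sample")
  sw <- stats::shapiro.test(x)
  new_gof_result("SW", unname(sw$statistic),
                 list(family = "normal", params = NULL, composite = TRUE),
                 sw$p.value, list(method = "analytic"))
}

#' Shapiro-Wilk test of log-transformed values
#'
#' Lognormality screen: values are lognormal exactly when their logs are
#' normal, so the Shapiro-Wilk test is applied to `log(values)`. Note the
#' check is not shift-equivariant: `log(x + c)` is not `log(x) + c`.
#'
#' @inheritParams shapiro_wilk
#' @return A `gof_result` (null family `"lognormal"`).
#' @export
lognormality_check <- function(sample) {
  x <- sample_values(sample)
  res <- shapiro_wilk(log(x))
  res$null_spec$family <- "lognormal"
  res
}

#' Anderson-Darling test of a fitted (composite) gamma null
#'
#' Fits a gamma by maximum likelihood, computes the Anderson-Darling
#' statistic at the fitted CDF, and calibrates the p-value by parametric
#' bootstrap: `B` samples of size `n` are drawn from the fitted gamma, each
#' is refitted and its statistic recomputed, and
#' `p = (1 + #\{A^2_b >= A^2_obs\}) / (B + 1)`, which is strictly in (0, 1].
#' Refitting each bootstrap replicate is what accounts for the parameter
#' estimation of the composite null.
#'
#' @param sample A [cell_sample()] or positive numeric vector.
#' @param B Number of bootstrap replicates (`>= 99`; default 999).
#' @param seed Integer seed for the bootstrap stream.
#' @return A `gof_result` carrying the fit in `fit` and bootstrap metadata in
#'   `calibration`.
#' @export
ad_test_fitted_gamma <- function(sample, B = 999, seed = NULL) {
  if (B < 99) stop("B must be >= 99: refusing an uncalibrated p-value")
  x <- sample_values(sample)
  fit <- fit_gamma(x)
  obs <- edf_statistics(x, fitted_cdf(fit))$A2
  n <- length(x)
  shape <- unname(fit$params["shape"]); rate <- unname(fit$params["rate"])
  boot <- with_seed(seed, {
    draws <- matrix(stats::rgamma(n * B, shape = shape, rate = rate),
                    nrow = n, ncol = B)
    gamma_ad_matrix(draws)
  })
  p <- (1 + sum(boot >= obs)) / (B + 1)
  res <- new_gof_result("AD", obs,
                        list(family = "gamma",
                             params = c(shape = shape, rate = rate),
                             composite = TRUE),
                        p, list(method = "bootstrap", B = B, seed = seed))
  res$fit <- fit
  res
}

## vectorized over columns: MLE gamma refit + AD statistic per column.
## Newton on the profile score for all columns simultaneously.
gamma_ad_matrix <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  s <- log(mu) - colMeans(log(m))
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:50) {
    f <- log(a) - digamma(a) - s
    if (max(abs(f)) < 1e-10) break
    a <- pmax(a - f / (1 / a - trigamma(a)), 1e-8)
  }
  rate <- a / mu
  ms <- apply(m, 2, sort)
  u <- matrix(stats::pgamma(as.vector(ms), shape = rep(a, each = n),
                            rate = rep(rate, each = n)),
              nrow = n)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  w <- 2 * i - 1
  -n - (colSums(w * log(u)) + colSums(w * log(1 - u[n:1, , drop = FALSE]))) / n
}

#' Anderson-Darling test against a fully specified gamma null
#'
#' Computes the Anderson-Darling statistic against the given gamma CDF (no
#' refitting). The p-value comes from the classical asymptotic distribution
#' of the statistic under a fully specified null; for small samples
#' (`n < 50` under `method = "auto"`) a parametric bootstrap from the null
#' is used instead.
#'
#' @param sample A [cell_sample()] or positive numeric vector.
#' @param shape,rate Positive gamma null parameters.
#' @param method `"auto"` (asymptotic for `n >= 50`, else bootstrap),
#'   `"asymptotic"`, or `"bootstrap"`.
#' @param B Bootstrap replicates when bootstrapping (default 999).
#' @param seed Integer seed for the bootstrap stream.
#' @return A `gof_result` with `statistic_name = "AD"` and
#'   `null_spec$composite = FALSE`.
#' @export
ad_test_fixed <- function(sample, shape, rate,
                          method = c("auto", "asymptotic", "bootstrap"),
                          B = 999, seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(shape) || !is.numeric(rate) || shape <= 0 || rate <= 0)
    stop("null gamma parameters must be positive")
  x <- sample_values(sample)
  n <- length(x)
  cdf <- function(q) stats::pgamma(q, shape = shape, rate = rate)
  obs <- edf_statistics(x, cdf)$A2
  if (method == "auto") method <- if (n >= 50) "asymptotic" else "bootstrap"
  if (method == "asymptotic") {
    p <- 1 - ad_asymptotic_cdf(obs)
    calib <- list(method = "analytic")
  } else {
    if (B < 99) stop("B must be >= 99: refusing an uncalibrated p-value")
    boot <- with_seed(seed, vapply(seq_len(B), function(b) {
      edf_statistics(stats::rgamma(n, shape = shape, rate = rate), cdf)$A2
    }, numeric(1)))
    p <- (1 + sum(boot >= obs)) / (B + 1)
    calib <- list(method = "bootstrap", B = B, seed = seed)
  }
  new_gof_result("AD", obs,
                 list(family = "gamma", params = c(shape = shape, rate = rate),
                      composite = FALSE),
                 p, calib)
}
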