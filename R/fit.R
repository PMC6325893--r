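#' Maximum-likelihood fits of right-skewed size distributions
#'
#' `fit_gamma()`, `fit_lognormal()`, `fit_weibull()` and `fit_gengamma()`
#' fit their families to a [cell_sample()] (or bare positive numeric vector)
#' by maximum likelihood and return a `fit_result` carrying the estimates,
#' maximized log-likelihood, AIC and BIC (`-2 loglik + k log n`), a
#' convergence flag and the iteration count.
#'
#' The gamma fit solves the profile score
#' `log(alpha) - digamma(alpha) = log(mean x) - mean(log x)` by Newton
#' iteration from the Minka closed-form initializer, then sets
#' `rate = alpha / mean(x)`; by the first-order condition the fitted mean
#' `alpha/rate` equals the sample mean exactly. The Weibull fit applies the
#' analogous Newton iteration to its profile score in the shape parameter.
#' The lognormal estimates are the closed-form moments of `log x` (MLE
#' convention, divisor `n`). The generalized gamma — density proportional to
#' `x^(alpha*p - 1) exp(-(rate*x)^p)`, which reduces to the gamma at
#' `p = 1` — is fitted by an outer one-dimensional profile search on the
#' power `p` with an inner gamma fit on `x^p`; `p = 1` is always evaluated,
#' so its log-likelihood can never fall below the gamma fit's.
#'
#' @param sample A [cell_sample()] or positive numeric vector with `n >= 8`,
#'   not all values equal.
#' @return A `fit_result` list: `family`, `params` (named), `loglik`, `n`,
#'   `aic`, `bic`, `converged`, `iterations`.
#' @seealso [model_select()]
#' @name distribution_fits
NULL

new_fit_result <- function(family, params, loglik, n, converged, iterations) {
  k <- length(params)
  structure(list(family = family, params = params, loglik = loglik, n = n,
                 aic = -2 * loglik + 2 * k,
                 bic = -2 * loglik + k * log(n),
                 converged = converged, iterations = iterations),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (n = %d%s): %s | loglik %.4f, BIC %.4f\n",
              x$family, x$n, if (x$converged) "" else ", NOT converged",
              paste(names(x$params), signif(x$params, 7), sep = " = ",
                    collapse = ", "),
              x$loglik, x$bic))
  invisible(x)
}

check_fit_sample <- function(x) {
  if (length(x) < 8) stop("need n >= 8 values to fit (got ", length(x), ")")
  if (any(x <= 0)) stop("domain error: all values must be > 0")
  if (max(x) == min(x)) stop("degenerate sample: all values equal")
  x
}

#' @rdname distribution_fits
#' @export
fit_gamma <- function(sample) {
  x <- check_fit_sample(sample_values(sample))
  m <- mean(x)
  s <- log(m) - mean(log(x))
  alpha <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  it <- 0L
  converged <- FALSE
  for (it in 1:100) {
    f <- log(alpha) - digamma(alpha) - s
    if (abs(f) < 1e-10) { converged <- TRUE; break }
    step <- f / (1 / alpha - trigamma(alpha))
    alpha_new <- alpha - step
    while (alpha_new <= 0) { step <- step / 2; alpha_new <- alpha - step }
    alpha <- alpha_new
  }
  if (!converged && abs(log(alpha) - digamma(alpha) - s) < 1e-10)
    converged <- TRUE
  rate <- alpha / m
  ll <- sum(stats::dgamma(x, shape = alpha, rate = rate, log = TRUE))
  new_fit_result("gamma", c(shape = alpha, rate = rate), ll, length(x),
                 converged, it)
}

#' @rdname distribution_fits
#' @export
fit_lognormal <- function(sample) {
  x <- check_fit_sample(sample_values(sample))
  l <- log(x)
  mu <- mean(l)
  sd_ <- sqrt(mean((l - mu)^2))          # MLE convention: divisor n
  ll <- sum(stats::dlnorm(x, meanlog = mu, sdlog = sd_, log = TRUE))
  new_fit_result("lognormal", c(meanlog = mu, sdlog = sd_), ll, length(x),
                 TRUE, 0L)
}

#' @rdname distribution_fits
#' @export
fit_weibull <- function(sample) {
  x <- check_fit_sample(sample_values(sample))
  l <- log(x)
  k <- 1.2 / sqrt(mean((l - mean(l))^2))  # common log-moment initializer
  ml <- mean(l)
  it <- 0L
  converged <- FALSE
  for (it in 1:100) {
    xk <- x^k
    s0 <- sum(xk); s1 <- sum(xk * l); s2 <- sum(xk * l * l)
    g <- 1 / k + ml - s1 / s0
    if (abs(g) < 1e-10) { converged <- TRUE; break }
    gp <- -1 / k^2 - (s2 * s0 - s1^2) / s0^2
    step <- g / gp
    k_new <- k - step
    while (k_new <= 0) { step <- step / 2; k_new <- k - step }
    k <- k_new
  }
  scale <- mean(x^k)^(1 / k)
  ll <- sum(stats::dweibull(x, shape = k, scale = scale, log = TRUE))
  new_fit_result("weibull", c(shape = k, scale = scale), ll, length(x),
                 converged, it)
}

## generalized-gamma profile log-likelihood in the power p:
## with y = x^p, y ~ gamma(shape, rate_y) and the Jacobian term
## sum(log p + (p-1) log x)
gengamma_profile <- function(x, p) {
  y <- x^p
  fit <- fit_gamma(y)
  list(fit = fit,
       loglik = fit$loglik + length(x) * log(p) + (p - 1) * sum(log(x)))
}

#' @rdname distribution_fits
#' @export
fit_gengamma <- function(sample) {
  x <- check_fit_sample(sample_values(sample))
  prof <- function(lp) {
    tryCatch(gengamma_profile(x, exp(lp))$loglik,
             error = function(e) -Inf)
  }
  opt <- stats::optimize(prof, interval = log(c(0.15, 6)), maximum = TRUE,
                         tol = 1e-8)
  cand <- c(exp(opt$maximum), 1)          # always consider the gamma limit
  lls <- vapply(cand, function(p) prof(log(p)), numeric(1))
  if (all(!is.finite(lls)))
    stop("generalized-gamma fit failed to converge: inner gamma fit ",
         "errored for every trial power")
  p <- cand[which.max(lls)]
  pr <- gengamma_profile(x, p)
  shape <- unname(pr$fit$params["shape"])
  rate <- unname(pr$fit$params["rate"])^(1 / p)
  new_fit_result("gengamma", c(shape = shape, rate = rate, power = p),
                 pr$loglik, length(x), pr$fit$converged, pr$fit$iterations)
}

## generalized-gamma density/cdf in the (shape, rate, power) parameterization
dgengamma_ <- function(x, shape, rate, power, log = FALSE) {
  lf <- log(power) + shape * power * log(rate) +
    (shape * power - 1) * log(x) - (rate * x)^power - lgamma(shape)
  if (log) lf else exp(lf)
}

pgengamma_ <- function(q, shape, rate, power) {
  stats::pgamma(pmax(q, 0)^power, shape = shape, rate = rate^power)
}

#' Cumulative distribution function of a fitted family
#'
#' @param fit A `fit_result`.
#' @return A function of `q` evaluating the fitted CDF.
#' @export
fitted_cdf <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  p <- fit$params
  switch(fit$family,
    gamma = function(q) stats::pgamma(q, shape = p["shape"], rate = p["rate"]),
    lognormal = function(q) stats::plnorm(q, meanlog = p["meanlog"],
                                          sdlog = p["sdlog"]),
    weibull = function(q) stats::pweibull(q, shape = p["shape"],
                                          scale = p["scale"]),
    gengamma = function(q) pgengamma_(q, p["shape"], p["rate"], p["power"]),
    stop("unknown family: ", fit$family))
}

#' Fit candidate families and rank them
#'
#' Fits each requested family, computes the empirical-distribution-function
#' statistics (Anderson-Darling, Kolmogorov-Smirnov, Cramer-von Mises) at
#' each fitted CDF, and declares a winner per criterion. A failing family is
#' recorded with `NA` entries rather than aborting the remaining families.
#'
#' @param sample A [cell_sample()] or positive numeric vector.
#' @param families Character subset of
#'   `c("gamma", "lognormal", "weibull", "gengamma")`.
#' @return A data frame (one row per family, ranked by AD statistic) with
#'   attributes `winner_ad` and `winner_bic`; fitted objects are in the
#'   `fits` attribute.
#' @export
model_select <- function(sample,
                         families = c("gamma", "lognormal", "weibull",
                                      "gengamma")) {
  families <- match.arg(families, several.ok = TRUE)
  x <- sample_values(sample)
  fitters <- list(gamma = fit_gamma, lognormal = fit_lognormal,
                  weibull = fit_weibull, gengamma = fit_gengamma)
  rows <- lapply(families, function(fam) {
    fit <- tryCatch(fitters[[fam]](x), error = function(e) e)
    if (inherits(fit, "error"))
      return(list(fit = NULL,
                  row = data.frame(family = fam, loglik = NA_real_,
                                   aic = NA_real_, bic = NA_real_,
                                   ad = NA_real_, ks = NA_real_,
                                   cvm = NA_real_, converged = FALSE,
                                   error = conditionMessage(fit))))
    st <- edf_statistics(x, fitted_cdf(fit))
    list(fit = fit,
         row = data.frame(family = fam, loglik = fit$loglik, aic = fit$aic,
                          bic = fit$bic, ad = st$A2, ks = st$D, cvm = st$W2,
                          converged = fit$converged, error = NA_character_))
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  tab <- tab[order(tab$ad), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- stats::setNames(lapply(rows, `[[`, "fit"), families)
  attr(tab, "winner_ad") <- if (any(!is.na(tab$ad)))
    tab$family[which.min(tab$ad)] else NA_character_
  attr(tab, "winner_bic") <- if (any(!is.na(tab$bic)))
    tab$family[which.min(tab$bic)] else NA_character_
  tab
}
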