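# brute-force 2-D grid oracle: refine a log-likelihood grid around a start
grid_mle <- function(x, ll_fun, start, spans = c(0.5, 0.1, 0.02, 0.004)) {
  best <- start
  for (span in spans) {
    g1 <- seq(best[1] * (1 - span), best[1] * (1 + span), length.out = 41)
    g2 <- seq(best[2] * (1 - span), best[2] * (1 + span), length.out = 41)
    ll <- outer(g1, g2, Vectorize(function(a, b) ll_fun(x, a, b)))
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- c(g1[idx[1]], g2[idx[2]])
  }
  best
}

test_that("gamma MLE matches a dense grid search on a fixed 50-point sample", {
  x <- gamma_sample(50, shape = 6.6, rate = 0.06, seed = 42)$values
  fit <- fit_gamma(x)
  ll <- function(x, a, b) sum(dgamma(x, shape = a, rate = b, log = TRUE))
  ref <- grid_mle(x, ll, unname(fit$params) * c(1.2, 0.8))
  expect_lt(abs(fit$params["shape"] - ref[1]), 1e-3)
  expect_lt(abs(fit$params["rate"] - ref[2]), 1e-3)
})

test_that("gamma MLE agrees with an independent ML fitter", {
  skip_if_not_installed("MASS")
  for (seed in 1:3) {
    x <- gamma_sample(400, shape = 4 + seed, rate = 0.07, seed = seed)$values
    ours <- fit_gamma(x)
    ref <- suppressWarnings(MASS::fitdistr(x, "gamma"))
    expect_equal(unname(ours$params["shape"]), unname(ref$estimate["shape"]),
                 tolerance = 1e-4)
    expect_equal(unname(ours$params["rate"]), unname(ref$estimate["rate"]),
                 tolerance = 1e-4)
    expect_equal(ours$loglik, as.numeric(ref$loglik), tolerance = 1e-6)
  }
})

test_that("fitted gamma mean equals the sample mean exactly", {
  x <- gamma_sample(500, 6.6, 0.06, seed = 5)$values
  fit <- fit_gamma(x)
  expect_equal(unname(fit$params["shape"] / fit$params["rate"]), mean(x),
               tolerance = 1e-10)
  # the printed rich-medium wild-type estimates obey the same identity:
  # shape/rate is the sample mean, ~110 fL for a diploid in 2% dextrose
  expect_equal(6.624628 / 0.060432, 109.62, tolerance = 1e-4)
})

test_that("fit errors are explicit for degenerate and out-of-domain samples", {
  expect_error(fit_gamma(rep(5, 50)), "degenerate")
  expect_error(fit_gamma(c(-1, rexp(49))), "domain|positive")
  expect_error(fit_gamma(rexp(5)), "n >= 8")
})

test_that("lognormal fit is the closed-form log-moment MLE", {
  x <- exp(c(-1, 0, 1) + 2)
  # n = 3 sample whose logs are symmetric: meanlog = 2, sdlog with divisor n
  fit <- fit_lognormal(rep(x, 3))  # repeat to clear the n >= 8 gate
  expect_equal(unname(fit$params["meanlog"]), 2, tolerance = 1e-12)
  expect_equal(unname(fit$params["sdlog"]), sqrt(2 / 3), tolerance = 1e-12)
})

test_that("weibull MLE matches the grid oracle and recovers parameters", {
  x <- gamma_sample(50, shape = 6.6, rate = 0.06, seed = 11)$values
  fit <- fit_weibull(x)
  ll <- function(x, k, s) sum(dweibull(x, shape = k, scale = s, log = TRUE))
  ref <- grid_mle(x, ll, unname(fit$params) * c(1.2, 0.9))
  expect_lt(abs(fit$params["shape"] - ref[1]), 1e-3)
  # scale is O(100); compare on a relative basis at the same stringency
  expect_lt(abs(fit$params["scale"] - ref[2]) / ref[2], 1e-3)

  old <- .Random.seed; on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(123)
  y <- rweibull(500, shape = 2, scale = 100)
  wf <- fit_weibull(y)
  expect_lt(abs(wf$params["shape"] - 2) / 2, 0.15)
})

test_that("all families are scale-equivariant", {
  x <- gamma_sample(300, 6.6, 0.06, seed = 2)$values
  for (c_ in c(0.1, 3.7)) {
    g1 <- fit_gamma(x); g2 <- fit_gamma(c_ * x)
    expect_equal(unname(g2$params["shape"]), unname(g1$params["shape"]),
                 tolerance = 1e-7)
    expect_equal(unname(g2$params["rate"]), unname(g1$params["rate"]) / c_,
                 tolerance = 1e-7)
    w1 <- fit_weibull(x); w2 <- fit_weibull(c_ * x)
    expect_equal(unname(w2$params["shape"]), unname(w1$params["shape"]),
                 tolerance = 1e-6)
    expect_equal(unname(w2$params["scale"]), unname(w1$params["scale"]) * c_,
                 tolerance = 1e-6 * unname(w1$params["scale"]) * c_)
    l1 <- fit_lognormal(x); l2 <- fit_lognormal(c_ * x)
    expect_equal(unname(l2$params["meanlog"]),
                 unname(l1$params["meanlog"]) + log(c_), tolerance = 1e-10)
    expect_equal(unname(l2$params["sdlog"]), unname(l1$params["sdlog"]),
                 tolerance = 1e-10)
    gg1 <- fit_gengamma(x); gg2 <- fit_gengamma(c_ * x)
    expect_equal(unname(gg2$params["power"]), unname(gg1$params["power"]),
                 tolerance = 1e-3)
    expect_equal(unname(gg2$params["rate"]) * c_, unname(gg1$params["rate"]),
                 tolerance = 1e-3 * unname(gg1$params["rate"]))
  }
})

test_that("BIC is -2 loglik + k log n with the right parameter counts", {
  x <- gamma_sample(200, 5, 0.05, seed = 31)$values
  g <- fit_gamma(x)
  expect_equal(g$bic, -2 * g$loglik + 2 * log(200), tolerance = 1e-10)
  gg <- fit_gengamma(x)
  expect_equal(gg$bic, -2 * gg$loglik + 3 * log(200), tolerance = 1e-10)
})

test_that("generalized gamma nests the gamma: identical density at power 1,
           profile log-likelihood never below the gamma fit", {
  x <- gamma_sample(200, 6.6, 0.06, seed = 8)$values
  g <- fit_gamma(x)
  # density identity at power = 1
  d1 <- sizescreen:::dgengamma_(x, g$params["shape"], g$params["rate"], 1)
  expect_equal(d1, dgamma(x, shape = g$params["shape"],
                          rate = g$params["rate"]), tolerance = 1e-12)
  for (seed in 1:5) {
    y <- gamma_sample(150, 4, 0.08, seed = 100 + seed)$values
    expect_gte(fit_gengamma(y)$loglik, fit_gamma(y)$loglik - 1e-6)
  }
})

test_that("on gamma data the profile-likelihood interval for the power covers 1", {
  # likelihood-ratio check: 2*(ll_gengamma - ll_gamma) <= chisq_{1,0.95}
  # should hold in at least ~95% of draws; require >= 80/100
  cover <- vapply(1:100, function(s) {
    y <- gamma_sample(1000, 6.6, 0.06, seed = 4000 + s)$values
    lr <- 2 * (fit_gengamma(y)$loglik - fit_gamma(y)$loglik)
    lr <= qchisq(0.95, df = 1)
  }, logical(1))
  expect_gte(sum(cover), 80)
})

test_that("model_select ranks families, survives per-family failure,
           and honours a single-family request", {
  x <- gamma_sample(500, 6.6, 0.06, seed = 77)$values
  tab <- model_select(x)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$ad, sort(tab$ad))
  expect_true(attr(tab, "winner_ad") %in% tab$family)

  one <- model_select(x, families = "weibull")
  expect_equal(nrow(one), 1)
  expect_equal(one$family, "weibull")
})

test_that("lognormal-simulated data are won by lognormal on BIC", {
  old <- .Random.seed; on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(600)
  wins <- vapply(1:50, function(i) {
    x <- rlnorm(1000, meanlog = 4.6, sdlog = 0.4)
    attr(model_select(x, c("gamma", "lognormal", "weibull")),
         "winner_bic") == "lognormal"
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("gamma parameter recovery is unbiased at screen scale", {
  shapes <- c(4, 6.6, 8)
  for (a0 in shapes) {
    est <- vapply(1:60, function(s) {
      smp <- gamma_sample(1000, a0, 0.06, seed = s + 1e4 * a0)
      unname(fit_gamma(smp)$params["shape"])
    }, numeric(1))
    expect_lt(abs(median(est) - a0) / a0, 0.05)
  }
})
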