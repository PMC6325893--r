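#' Reference gamma null from wild-type fits
#'
#' Averages the fitted gamma parameters of one or more wild-type samples:
#' the reference shape and rate are the arithmetic means of the per-sample
#' maximum-likelihood estimates. This is the fully specified null against
#' which every mutant strain in a screen is tested and ranked.
#'
#' @param wt_fits A list of converged gamma `fit_result` objects (a single
#'   `fit_result` is accepted), or a data frame with columns `gamma_shape`
#'   and `gamma_rate` (and optionally `strain`) holding previously fitted
#'   estimates, such as the packaged wild-type reference table.
#' @return A `reference_null` list: `shape`, `rate`, `source_strain_ids`.
#' @export
reference_null <- function(wt_fits) {
  if (is.data.frame(wt_fits)) {
    if (!all(c("gamma_shape", "gamma_rate") %in% colnames(wt_fits)))
      stop("data-frame input needs gamma_shape and gamma_rate columns")
    if (nrow(wt_fits) == 0) stop("need at least one wild-type gamma fit")
    return(structure(list(shape = mean(wt_fits$gamma_shape),
                          rate = mean(wt_fits$gamma_rate),
                          source_strain_ids = if ("strain" %in%
                                                  colnames(wt_fits))
                            wt_fits$strain else rep(NA_character_,
                                                    nrow(wt_fits))),
                     class = "reference_null"))
  }
  if (inherits(wt_fits, "fit_result")) wt_fits <- list(wt_fits)
  if (length(wt_fits) == 0) stop("need at least one wild-type gamma fit")
  fam <- vapply(wt_fits, `[[`, character(1), "family")
  if (!all(fam == "gamma"))
    stop("mixed families in reference null: ",
         paste(unique(fam), collapse = ", "))
  if (!all(vapply(wt_fits, `[[`, logical(1), "converged")))
    stop("all wild-type fits must have converged")
  ids <- vapply(wt_fits, function(f)
    if (is.null(f$strain_id)) NA_character_ else f$strain_id, character(1))
  structure(list(shape = mean(vapply(wt_fits, function(f)
                   unname(f$params["shape"]), numeric(1))),
                 rate = mean(vapply(wt_fits, function(f)
                   unname(f$params["rate"]), numeric(1))),
                 source_strain_ids = ids),
            class = "reference_null")
}

#' @export
print.reference_null <- function(x, ...) {
  cat(sprintf("<reference_null> gamma(shape = %.6g, rate = %.6g) from %d fit(s)\n",
              x$shape, x$rate, length(x$source_strain_ids)))
  invisible(x)
}

#' Screening configuration
#'
#' Defaults reproduce the study settings: resamples of `n = 1000` cells,
#' `B = 999` bootstrap replicates, significance `alpha = 0.01`, the 50
#' worst-fitting samples, and 5% size-class tails.
#'
#' @param n Cells per resample.
#' @param seed Master seed; per-strain seeds are derived with
#'   [derive_seed()], so cohort order does not affect results.
#' @param B Bootstrap replicates for the composite gamma test.
#' @param jitter Uniform within-bin jitter of resampled values.
#' @param null_shape,null_rate Fixed gamma null parameters; if `NULL` they
#'   are built from `wild_type_ids` via [reference_null()].
#' @param wild_type_ids Strain ids whose fitted gammas are averaged into the
#'   reference null when `null_shape`/`null_rate` are not given.
#' @param tests Character subset of `c("sw", "fits", "composite", "fixed")`
#'   selecting which statistics to compute (ranking only needs `"fixed"`).
#' @param top_k Size of the deviant set reported by [rank_deviants()].
#' @param tail_q Tail fraction for [classify_size()].
#' @param alpha Screening significance level.
#' @param min_size Optional minimum-size cutoff in fL; resampled cells below
#'   it are discarded (debris trimming, off by default).
#' @param replicate_pattern Regular expression recognizing replicate
#'   suffixes appended to systematic strain names.
#' @return A `screen_config` list.
#' @export
screen_config <- function(n = 1000, seed = 1L, B = 999, jitter = FALSE,
                          null_shape = NULL, null_rate = NULL,
                          wild_type_ids = NULL,
                          tests = c("sw", "fits", "composite", "fixed"),
                          top_k = 50, tail_q = 0.05, alpha = 0.01,
                          min_size = NULL,
                          replicate_pattern = "\\.r?[0-9]+$") {
  tests <- match.arg(tests, several.ok = TRUE)
  if (n < 8) stop("config field 'n': need n >= 8 for downstream fits")
  if (B < 99) stop("config field 'B': bootstrap needs B >= 99")
  if (tail_q <= 0 || tail_q >= 0.5)
    stop("config field 'tail_q': must be in (0, 0.5)")
  if (alpha <= 0 || alpha >= 1)
    stop("config field 'alpha': must be in (0, 1)")
  structure(list(n = as.integer(n), seed = as.integer(seed), B = as.integer(B),
                 jitter = jitter, null_shape = null_shape,
                 null_rate = null_rate, wild_type_ids = wild_type_ids,
                 tests = tests, top_k = top_k, tail_q = tail_q, alpha = alpha,
                 min_size = min_size, replicate_pattern = replicate_pattern),
            class = "screen_config")
}

resolve_null <- function(cohort, config) {
  if (!is.null(config$null_shape) && !is.null(config$null_rate))
    return(list(shape = config$null_shape, rate = config$null_rate))
  if (is.null(config$wild_type_ids))
    stop("fixed-null test requested but no null parameters: supply ",
         "null_shape/null_rate or wild_type_ids in the config")
  missing <- setdiff(config$wild_type_ids, names(cohort))
  if (length(missing) > 0)
    stop("wild_type_ids not found in cohort: ",
         paste(missing, collapse = ", "))
  fits <- lapply(config$wild_type_ids, function(id) {
    smp <- resample_cells(cohort[[id]], n = config$n,
                          seed = derive_seed(config$seed, id),
                          jitter = config$jitter)
    fit_gamma(smp)
  })
  rn <- reference_null(fits)
  list(shape = rn$shape, rate = rn$rate)
}

#' Screen a cohort of size histograms against a reference gamma
#'
#' For each strain: derive a seed, resample `n` cells, run the Shapiro-Wilk
#' test on raw and log values, fit the candidate families, compute
#' per-family Anderson-Darling (plus gamma Kolmogorov-Smirnov and
#' Cramer-von Mises) statistics, calibrate the composite gamma p-value by
#' parametric bootstrap, test against the fixed reference null, and record
#' the BIC of the gamma and generalized-gamma fits and the weighted median
#' size. Strains whose fits fail are kept with a `status` message and ranked
#' last. Rows are returned in input order with deviant ranks (1 = worst
#' fixed-null fit, ties broken by strain id) and `lge`/`whi`/`normal` size
#' classes attached. Fully reproducible for a fixed master seed.
#'
#' @param cohort Named list of [size_histogram()] objects (names are strain
#'   ids), as returned by [read_frequency_table()] or [simulate_cohort()].
#' @param config A [screen_config()].
#' @return Data frame with the columns documented in [write_screen_table()].
#' @export
screen_cohort <- function(cohort, config = screen_config()) {
  if (length(cohort) == 0) stop("cohort must be nonempty")
  stopifnot(inherits(config, "screen_config"))
  if (is.null(names(cohort)))
    names(cohort) <- vapply(cohort, `[[`, character(1), "strain_id")
  null <- if ("fixed" %in% config$tests) resolve_null(cohort, config) else NULL

  rows <- lapply(names(cohort), function(id) {
    h <- cohort[[id]]
    seed <- derive_seed(config$seed, id)
    row <- list(strain = id, condition = h$condition, n = config$n,
                seed = seed, status = "ok", sw_p = NA_real_,
                sw_log_p = NA_real_, gamma_shape = NA_real_,
                gamma_rate = NA_real_, lognormal_ad = NA_real_,
                weibull_ad = NA_real_, gamma_ad = NA_real_,
                gamma_ks = NA_real_, gamma_cvm = NA_real_,
                gamma_ad_p = NA_real_, fixed_null_ad = NA_real_,
                fixed_null_p = NA_real_, bic_gamma = NA_real_,
                bic_gengamma = NA_real_, median_fl = weighted_median(h))
    res <- tryCatch({
      smp <- resample_cells(h, n = config$n, seed = seed,
                            jitter = config$jitter)
      if (!is.null(config$min_size)) {
        keep <- smp$values >= config$min_size
        if (sum(keep) < 8) stop("fewer than 8 cells above min_size cutoff")
        smp <- cell_sample(smp$values[keep], seed = seed)
      }
      if ("sw" %in% config$tests) {
        row$sw_p <- suppressWarnings(shapiro_wilk(smp)$p_value)
        row$sw_log_p <- suppressWarnings(lognormality_check(smp)$p_value)
      }
      if ("fits" %in% config$tests) {
        gfit <- fit_gamma(smp)
        row$gamma_shape <- unname(gfit$params["shape"])
        row$gamma_rate <- unname(gfit$params["rate"])
        row$bic_gamma <- gfit$bic
        g_edf <- edf_statistics(smp, fitted_cdf(gfit))
        row$gamma_ad <- g_edf$A2
        row$gamma_ks <- g_edf$D
        row$gamma_cvm <- g_edf$W2
        row$lognormal_ad <- edf_statistics(smp,
                                           fitted_cdf(fit_lognormal(smp)))$A2
        row$weibull_ad <- edf_statistics(smp, fitted_cdf(fit_weibull(smp)))$A2
        row$bic_gengamma <- tryCatch(fit_gengamma(smp)$bic,
                                     error = function(e) NA_real_)
      }
      if ("composite" %in% config$tests)
        row$gamma_ad_p <- ad_test_fitted_gamma(smp, B = config$B,
                                               seed = seed)$p_value
      if ("fixed" %in% config$tests) {
        ft <- ad_test_fixed(smp, shape = null$shape, rate = null$rate)
        row$fixed_null_ad <- ft$statistic
        row$fixed_null_p <- ft$p_value
      }
      row
    }, error = function(e) { row$status <- conditionMessage(e); row })
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ## deviant rank: descending fixed-null AD, failures last, ties by strain id
  key <- tab$fixed_null_ad
  ord <- order(is.na(key), -ifelse(is.na(key), -Inf, key), tab$strain)
  tab$deviant_rank <- NA_integer_
  tab$deviant_rank[ord] <- seq_len(nrow(tab))
  tab <- classify_size(tab, q = config$tail_q)
  attr(tab, "null") <- null
  attr(tab, "config") <- config
  tab
}

#' Select the top-k gamma-deviant strains
#'
#' Sorts screening rows by descending fixed-null Anderson-Darling statistic
#' (worst fit first), takes the `k` worst samples, then collapses replicate
#' samples of the same strain — recognized by a replicate suffix on the
#' systematic name — to unique strains, so `k` samples can yield fewer
#' strains.
#'
#' @param rows Screening table from [screen_cohort()].
#' @param k Number of worst-fitting samples to take (`k <= nrow(rows)`).
#' @param replicate_pattern Regular expression for the replicate suffix.
#' @return The selected rows (one per unique strain, worst first) with a
#'   `base_strain` column.
#' @export
rank_deviants <- function(rows, k, replicate_pattern = "\\.r?[0-9]+$") {
  if (!is.data.frame(rows) || !"fixed_null_ad" %in% colnames(rows))
    stop("rows must carry fixed-null AD statistics")
  if (k > nrow(rows))
    stop("k (", k, ") exceeds the number of rows (", nrow(rows), ")")
  key <- rows$fixed_null_ad
  ord <- order(is.na(key), -ifelse(is.na(key), -Inf, key), rows$strain)
  top <- rows[ord[seq_len(k)], , drop = FALSE]
  top$base_strain <- sub(replicate_pattern, "", top$strain)
  top <- top[!duplicated(top$base_strain), , drop = FALSE]
  rownames(top) <- NULL
  top
}

#' Annotate size classes
#'
#' Marks the top `q` fraction of strains by median size as `lge` (large) and
#' the bottom `q` fraction as `whi` (small), everything else `normal`.
#' Exactly `ceiling(q * N)` strains land in each tail; quantiles are ordinal
#' ranks with ties broken by strain id, so the classification is
#' deterministic even for all-equal medians.
#'
#' @param rows Screening table with a `median_fl` column.
#' @param q Tail fraction in (0, 0.5).
#' @return `rows` with a `size_class` column.
#' @export
classify_size <- function(rows, q = 0.05) {
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  if (!"median_fl" %in% colnames(rows) || anyNA(rows$median_fl))
    stop("missing medians: classify_size needs a complete median_fl column")
  n <- nrow(rows)
  k <- ceiling(q * n)
  asc <- order(rows$median_fl, rows$strain)
  cls <- rep("normal", n)
  cls[asc[seq_len(k)]] <- "whi"
  cls[asc[seq(n - k + 1, n)]] <- "lge"
  rows$size_class <- cls
  rows
}
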