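#' Binned cell-size frequency histogram
#'
#' A `size_histogram` holds one strain's (or replicate's) binned cell-size
#' frequency distribution as exported by a Coulter-type channelyzer: a vector
#' of strictly increasing size values in femtoliters, interpreted as channel
#' (bin) centers, and one nonnegative relative frequency per bin.
#'
#' @param bin_values Numeric vector of strictly increasing, positive size
#'   values in fL (bin centers).
#' @param frequencies Numeric vector of nonnegative frequencies, one per bin;
#'   at least one must be strictly positive. Frequencies need not sum to one
#'   (see [normalize_histogram()]).
#' @param strain_id Character label for the strain/sample.
#' @param replicate Optional replicate label.
#' @param condition Optional condition label (e.g. carbon source).
#' @return An object of class `size_histogram`.
#' @examples
#' h <- size_histogram(c(10, 20, 30), c(1, 2, 3), strain_id = "wt")
#' weighted_median(h)
#' @export
size_histogram <- function(bin_values, frequencies, strain_id = "sample",
                           replicate = NA_character_,
                           condition = NA_character_) {
  bin_values <- as.numeric(bin_values)
  frequencies <- as.numeric(frequencies)
  if (length(bin_values) != length(frequencies))
    stop("bin_values and frequencies must have equal length")
  if (anyNA(bin_values) || anyNA(frequencies))
    stop("bin_values and frequencies must not contain NA")
  if (any(bin_values <= 0))
    stop("all bin_values must be > 0 (sizes in fL)")
  if (length(bin_values) > 1 && any(diff(bin_values) <= 0))
    stop("bin_values must be strictly increasing")
  if (any(frequencies < 0))
    stop("frequencies must be nonnegative")
  if (!any(frequencies > 0))
    stop("at least one frequency must be strictly positive")
  structure(
    list(strain_id = as.character(strain_id),
         replicate = as.character(replicate),
         condition = as.character(condition),
         bin_values = bin_values,
         frequencies = frequencies),
    class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("<size_histogram> %s%s: %d bins, %.1f-%.1f fL, median %.1f fL\n",
              x$strain_id,
              if (!is.na(x$condition)) paste0(" [", x$condition, "]") else "",
              length(x$bin_values), min(x$bin_values), max(x$bin_values),
              weighted_median(x)))
  invisible(x)
}

#' Rescale histogram frequencies to sum to one
#'
#' Idempotent; bins are unchanged. Errors on an all-zero histogram (which the
#' constructor already refuses).
#'
#' @param hist A [size_histogram()].
#' @return A `size_histogram` whose frequencies sum to 1 (within 1e-12).
#' @export
normalize_histogram <- function(hist) {
  stopifnot(inherits(hist, "size_histogram"))
  tot <- sum(hist$frequencies)
  if (tot <= 0) stop("cannot normalize an all-zero histogram")
  hist$frequencies <- hist$frequencies / tot
  hist
}

#' Bin edges inferred from channel centers
#'
#' Channelyzers export channel centers; edges are taken at the midpoints of
#' consecutive centers, with the two edge bins given the width of their
#' nearest interior edge (symmetric extension about the first and last
#' center).
#'
#' @param hist A [size_histogram()].
#' @return Numeric vector of `length(bin_values) + 1` edges.
#' @export
bin_edges <- function(hist) {
  b <- hist$bin_values
  n <- length(b)
  if (n == 1) stop("bin width undefined for a single-bin histogram")
  mid <- (b[-n] + b[-1]) / 2
  c(b[1] - (mid[1] - b[1]), mid, b[n] + (b[n] - mid[n - 1]))
}

#' Resample per-cell size values from a histogram
#'
#' Draws `n` cells by multinomial sampling over bins with probability
#' proportional to frequency. Each drawn value is the bin center; with
#' `jitter = TRUE` a uniform offset within the bin interval is added, which
#' removes the massive ties that center-resampling produces.
#' `mode = "deterministic"` instead assigns `round(freq_i * n)` cells per bin
#' with a largest-remainder correction so counts total exactly `n`.
#'
#' @param hist A [size_histogram()].
#' @param n Number of cells to draw (default 1000).
#' @param seed Integer seed; the sample is reproducible for a fixed seed and
#'   the caller's RNG state is left untouched.
#' @param jitter Logical; uniform jitter within each bin (default `FALSE`).
#' @param mode `"multinomial"` (default) or `"deterministic"`.
#' @return A [cell_sample()].
#' @export
resample_cells <- function(hist, n = 1000, seed = NULL, jitter = FALSE,
                           mode = c("multinomial", "deterministic")) {
  stopifnot(inherits(hist, "size_histogram"))
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a count >= 1")
  n <- as.integer(n)
  hist <- normalize_histogram(hist)
  p <- hist$frequencies
  b <- hist$bin_values
  if (jitter && length(b) == 1) {
    warning("bin width undefined for single-bin histogram; jitter disabled")
    jitter <- FALSE
  }
  counts <- if (mode == "deterministic") {
    largest_remainder(p * n)
  } else {
    with_seed(seed, as.integer(stats::rmultinom(1, n, p)))
  }
  values <- rep(b, counts)
  if (jitter) {
    e <- bin_edges(hist)
    lo <- rep(e[-length(e)], counts)
    hi <- rep(e[-1], counts)
    values <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                        stats::runif(length(values), lo, hi))
  }
  values <- with_seed(if (is.null(seed)) NULL else seed + 2L, sample(values))
  cell_sample(values, seed = if (is.null(seed)) NA_integer_ else seed)
}

## round to integer counts totalling sum(x) via largest remainders
largest_remainder <- function(x) {
  n <- round(sum(x))
  fl <- floor(x)
  rem <- n - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Ordered collection of per-cell size values
#'
#' @param values Positive per-cell sizes in fL.
#' @param seed Integer seed used to generate the sample, or `NA` for measured
#'   data.
#' @return An object of class `cell_sample` with fields `values`, `n`, `seed`.
#' @export
cell_sample <- function(values, seed = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("a cell_sample needs at least one value")
  if (anyNA(values) || any(values <= 0))
    stop("all cell size values must be positive and non-missing")
  structure(list(values = values, n = length(values),
                 seed = as.integer(seed)),
            class = "cell_sample")
}

#' @export
print.cell_sample <- function(x, ...) {
  cat(sprintf("<cell_sample> n = %d, mean %.1f fL, median %.1f fL\n",
              x$n, mean(x$values), stats::median(x$values)))
  invisible(x)
}

## accept a cell_sample or bare numeric vector
sample_values <- function(sample) {
  if (inherits(sample, "cell_sample")) return(sample$values)
  if (is.numeric(sample)) return(as.numeric(sample))
  stop("expected a cell_sample or a numeric vector")
}

#' Weighted median size of a histogram
#'
#' The smallest bin value at which the cumulative normalized frequency
#' exceeds one half. A bin at which the cumulative sum equals exactly 0.5
#' does not yet contain the median cell, so the median falls in the next
#' occupied bin (the upper discrete-median convention).
#'
#' @param hist A [size_histogram()].
#' @return Median size in fL.
#' @export
weighted_median <- function(hist) {
  hist <- normalize_histogram(hist)
  hist$bin_values[which(cumsum(hist$frequencies) > 0.5 + 1e-12)[1]]
}

## run expr with a private RNG stream; caller's .Random.seed is untouched.
## seed = NULL advances the global stream instead (non-reproducible path).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-strain seed from a master seed
#'
#' Deterministic in `(master, strain_id)` only, so cohort order never affects
#' per-strain results. Uses a 31-ary polynomial string hash modulo
#' 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param strain_id Character strain label.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, strain_id) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(as.character(strain_id))) h <- (h * 31 + c) %% m
  as.integer((h + (as.numeric(master) %% m) * 7919) %% (m - 1) + 1)
}
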