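#' Default channelyzer-like bin grid
#'
#' 256 linear channels spanning 5-250 fL, approximating a Z2-type
#' channelyzer window configured for budding yeast.
#'
#' @param min_fl,max_fl Grid limits in fL.
#' @param n_bins Number of channels.
#' @return Numeric vector of bin centers.
#' @export
default_bin_grid <- function(min_fl = 5, max_fl = 250, n_bins = 256) {
  if (max_fl <= min_fl || n_bins < 2) stop("invalid bin grid")
  seq(min_fl, max_fl, length.out = n_bins)
}

## bin raw cell sizes onto a center grid; out-of-grid draws accumulate in
## the edge bins and their count is attached as attribute "edge_clamped"
bin_cells <- function(cells, bins, strain_id, condition = NA_character_) {
  h0 <- size_histogram(bins, rep(1, length(bins)), strain_id = strain_id)
  e <- bin_edges(h0)
  clamped <- sum(cells < e[1] | cells >= e[length(e)])
  idx <- findInterval(cells, e, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(bins))
  cnt <- tabulate(idx, nbins = length(bins))
  h <- size_histogram(bins, cnt / sum(cnt), strain_id = strain_id,
                      condition = condition)
  attr(h, "edge_clamped") <- clamped
  h
}

#' Simulate a wild-type gamma size histogram
#'
#' Draws `cells` volumes from a gamma distribution and bins them onto the
#' grid; frequencies are normalized. Defaults are the fitted rich-medium
#' (2% dextrose) diploid wild-type parameters. Draws falling outside the
#' grid accumulate in the edge bins, with the count recorded in the
#' `edge_clamped` attribute; a warning is raised if the grid fails to cover
#' the central 99% of the target gamma.
#'
#' @param shape,rate Gamma parameters (`rate` per fL).
#' @param cells Number of cells counted (default 50000, a typical Coulter
#'   acquisition).
#' @param bins Bin-center grid (default [default_bin_grid()]).
#' @param seed Integer seed.
#' @param strain_id Label for the histogram.
#' @return A [size_histogram()].
#' @export
simulate_wildtype <- function(shape = 6.624628, rate = 0.060432,
                              cells = 50000, bins = default_bin_grid(),
                              seed = NULL, strain_id = "wildtype") {
  if (shape <= 0 || rate <= 0) stop("gamma parameters must be positive")
  qq <- stats::qgamma(c(0.005, 0.995), shape = shape, rate = rate)
  if (qq[1] < min(bins) || qq[2] > max(bins))
    warning("bin grid does not cover the central 99% of gamma(",
            signif(shape, 4), ", ", signif(rate, 4), ")")
  draws <- with_seed(seed, stats::rgamma(cells, shape = shape, rate = rate))
  bin_cells(draws, bins, strain_id)
}

#' Simulate a mutant-class size histogram
#'
#' Four mutant histogram classes emulate the departures seen in deletion
#' screens:
#'
#' * `shifted_gamma`: same shape, rate divided by `params$shift` (mean
#'   scaled up; `shift = 1` reproduces the wild-type generator draw for the
#'   same seed).
#' * `left_skew`: a negatively skewed distribution built as a large location
#'   minus a gamma draw (`params$location - gamma(params$shape, params$rate)`),
#'   with nonpositive values rejected — the mirror-image construction keeps
#'   the left tail heavy while support stays positive.
#' * `multimodal`: a gamma mixture with separated component means
#'   (`params$weights`, `params$shapes`, `params$rates`).
#' * `debris`: a base histogram (wild-type gamma by default, overridable via
#'   `params$base`) plus a point-mass spike of `params$mass` (default 3% of
#'   cells) spread over the `params$n_bins` (default 3) smallest bins.
#'
#' @param class One of `"shifted_gamma"`, `"left_skew"`, `"multimodal"`,
#'   `"debris"`.
#' @param params Named list of class parameters; unset entries take the
#'   defaults above.
#' @param cells,bins,seed,strain_id As in [simulate_wildtype()].
#' @return A [size_histogram()].
#' @export
simulate_mutant <- function(class, params = list(), cells = 50000,
                            bins = default_bin_grid(), seed = NULL,
                            strain_id = class) {
  defaults <- switch(class,
    shifted_gamma = list(shape = 6.624628, rate = 0.060432, shift = 1.6),
    left_skew = list(location = 170, shape = 4, rate = 0.08),
    multimodal = list(weights = c(0.5, 0.5), shapes = c(30, 30),
                      rates = c(30 / 60, 30 / 150)),
    debris = list(mass = 0.03, n_bins = 3,
                  base = list(shape = 6.624628, rate = 0.060432)),
    stop("unknown mutant class '", class, "'"))
  params <- utils::modifyList(defaults, params)
  draws <- with_seed(seed, switch(class,
    shifted_gamma = {
      if (params$shift <= 0) stop("shift factor must be positive")
      stats::rgamma(cells, shape = params$shape,
                    rate = params$rate / params$shift)
    },
    left_skew = {
      out <- numeric(0)
      while (length(out) < cells) {
        d <- params$location - stats::rgamma(cells, shape = params$shape,
                                             rate = params$rate)
        out <- c(out, d[d > 0])
      }
      out[seq_len(cells)]
    },
    multimodal = {
      w <- params$weights
      if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
      if (length(unique(c(length(w), length(params$shapes),
                          length(params$rates)))) != 1)
        stop("weights, shapes and rates must have equal length")
      comp <- sample.int(length(w), cells, replace = TRUE, prob = w)
      stats::rgamma(cells, shape = params$shapes[comp],
                    rate = params$rates[comp])
    },
    debris = {
      stats::rgamma(cells, shape = params$base$shape,
                    rate = params$base$rate)
    }))
  h <- bin_cells(draws, bins, strain_id)
  if (class == "debris") {
    nb <- params$n_bins
    f <- h$frequencies * (1 - params$mass)
    f[seq_len(nb)] <- f[seq_len(nb)] + params$mass / nb
    h$frequencies <- f
  }
  h
}

#' Specification for a synthetic cohort
#'
#' @param classes Named integer vector of strains per class; names from
#'   `c("wildtype_gamma", "shifted_gamma", "left_skew", "multimodal",
#'   "debris")`.
#' @param params Optional named list of per-class parameter overrides
#'   (passed to [simulate_mutant()]; for `wildtype_gamma`, a list with
#'   `shape` and `rate`).
#' @param cells_per_strain Cells counted per histogram.
#' @param bins Bin-center grid.
#' @param seed Master seed; per-strain seeds are derived with
#'   [derive_seed()].
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(classes = c(wildtype_gamma = 90, multimodal = 10),
                           params = list(), cells_per_strain = 50000,
                           bins = default_bin_grid(), seed = 1L) {
  known <- c("wildtype_gamma", "shifted_gamma", "left_skew", "multimodal",
             "debris")
  if (is.null(names(classes)) || !all(names(classes) %in% known))
    stop("classes must be named from: ", paste(known, collapse = ", "))
  if (sum(classes) < 1) stop("spec must request at least one strain")
  structure(list(classes = classes, params = params,
                 cells_per_strain = cells_per_strain, bins = bins,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a cohort of histograms with known ground truth
#'
#' Generates every strain requested by the spec, deriving each strain's seed
#' from the master seed and its id, and returns the cohort together with a
#' label table recording the true class of every strain — sufficient to
#' compute spike-in sensitivity and specificity of a screen.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `cohort` (named list of [size_histogram()]) and
#'   `labels` (data frame: `strain_id`, `class`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cohort <- list()
  labels <- list()
  for (cls in names(spec$classes)) {
    n_cls <- spec$classes[[cls]]
    if (n_cls == 0) next
    for (i in seq_len(n_cls)) {
      id <- sprintf("%s_%03d", cls, i)
      sd <- derive_seed(spec$seed, id)
      cohort[[id]] <- if (cls == "wildtype_gamma") {
        p <- utils::modifyList(list(shape = 6.624628, rate = 0.060432),
                               if (is.null(spec$params[[cls]])) list()
                               else spec$params[[cls]])
        simulate_wildtype(shape = p$shape, rate = p$rate,
                          cells = spec$cells_per_strain, bins = spec$bins,
                          seed = sd, strain_id = id)
      } else {
        simulate_mutant(cls,
                        params = if (is.null(spec$params[[cls]])) list()
                        else spec$params[[cls]],
                        cells = spec$cells_per_strain, bins = spec$bins,
                        seed = sd, strain_id = id)
      }
      labels[[id]] <- data.frame(strain_id = id, class = cls)
    }
  }
  list(cohort = cohort,
       labels = do.call(rbind, c(labels, list(make.row.names = FALSE))))
}
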