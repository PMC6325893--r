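# shared fixtures, built in code at test time

# small asymmetric histogram used across modules
toy_hist <- function(strain = "toy") {
  size_histogram(c(10, 20, 30, 40), c(0.1, 0.4, 0.3, 0.2), strain_id = strain)
}

# a gamma cell sample with a private seed (does not disturb the global RNG)
gamma_sample <- function(n, shape, rate, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cell_sample(rgamma(n, shape = shape, rate = rate), seed = seed)
}

# sample skewness
skewness <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3

# the two published haploid wild-type gamma fits, used to build the fixed
# reference null (shape 3.8277, rate 0.078949)
reference_table <- function() {
  read.delim(system.file("extdata", "wildtype_fit_reference.tsv",
                         package = "sizescreen"))
}

fit_from_params <- function(shape, rate, n = 1000) {
  structure(list(family = "gamma", params = c(shape = shape, rate = rate),
                 loglik = NA_real_, n = n, aic = NA_real_, bic = NA_real_,
                 converged = TRUE, iterations = 0L),
            class = "fit_result")
}
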