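# Shared fixtures, built in code at test time.

unit_square <- function() rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))

offset_square <- function() rbind(c(0.5, 0), c(1.5, 0), c(0.5, 1), c(1.5, 1))

simplex_4d <- function() rbind(rep(0, 4), diag(4))

## a small well-formed two-population trait table
toy_table <- function(n_per_pop = 8L, seed = 99L) {
  d <- synthetic_design(
    base_mean = c(1.05, 0.78, 0.13, 0.46, 0.72, 1.32),
    base_cov = diag(6) * (0.05 * c(1.05, 0.78, 0.13, 0.46, 0.72, 1.32))^2,
    populations = list(population_spec("A", n_per_pop),
                       population_spec("B", n_per_pop)),
    seed = seed)
  generate_traits(d)
}

## a fast analysis configuration for end-to-end tests
fast_config <- function(seed = 1L, ...) {
  morphospace_config(n_subsamples = 20L, n_null = 60L, n_perm = 19L,
                     mc_points = 10000L, perm_mc_points = 2000L,
                     seed = seed, ...)
}

## a homogeneous variant of the default seven-population design: same counts
## and base distribution, no designed effects
homogeneous_design <- function(seed = 1L) {
  d <- default_design()
  d$populations <- lapply(d$populations, function(p) {
    population_spec(p$label, p$n)
  })
  d$seed <- as.integer(seed)
  d$roles <- NULL
  d
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", object, tol, expected))
}
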