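# Synthetic multi-cohort expression studies with a known size boundary.
#
# The three built-in presets emulate microarray-style studies in which a
# fixed fraction of features is differentially expressed between small and
# large tumors: expression for the large-size samples of DE rows is drawn
# from a block-specific distribution (normal / gamma / Poisson), everything
# else from the study's background distribution. Tumor sizes are uniform on
# disjoint ranges whose boundary (3.0 cm) is the truth the threshold search
# should recover.

.SIMDAT_PRESETS <- list(
  simdat1 = list(
    n_small = 55L, n_large = 45L,
    size_small_range = c(1.0, 2.9), size_large_range = c(3.0, 5.0),
    de_blocks = list(
      list(n_rows = 3500L, distribution = "normal", params = list(mean = 10, sd = 10)),
      list(n_rows = 3500L, distribution = "normal", params = list(mean = -2, sd = 10))
    ),
    background = list(distribution = "normal", params = list(mean = 3, sd = 1))
  ),
  simdat2 = list(
    n_small = 35L, n_large = 45L,
    size_small_range = c(1.0, 2.9), size_large_range = c(3.0, 5.0),
    de_blocks = list(
      list(n_rows = 2000L, distribution = "gamma", params = list(shape = 5, scale = 10)),
      list(n_rows = 4500L, distribution = "gamma", params = list(shape = 3, scale = 6))
    ),
    background = list(distribution = "normal", params = list(mean = 0.5, sd = 10))
  ),
  simdat3 = list(
    n_small = 120L, n_large = 80L,
    size_small_range = c(1.0, 2.9), size_large_range = c(3.0, 5.0),
    de_blocks = list(
      list(n_rows = 2500L, distribution = "poisson", params = list(lambda = 10)),
      list(n_rows = 3500L, distribution = "poisson", params = list(lambda = 8))
    ),
    background = list(distribution = "normal", params = list(mean = 0.1, sd = 20))
  )
)

.draw <- function(dist, params, n) {
  switch(dist,
    normal = rnorm(n, mean = params$mean, sd = params$sd),
    gamma = rgamma(n, shape = params$shape, scale = params$scale),
    poisson = as.numeric(rpois(n, lambda = params$lambda)),
    stop(sprintf("unknown distribution '%s'", dist))
  )
}

#' Simulation specification for a synthetic study
#'
#' Returns the full parameterization of one of the three built-in presets,
#' optionally rescaled to a given overall DE-gene fraction. Each preset has
#' 10,000 features, uniform tumor sizes on (1.0, 2.9) cm for the small group
#' and (3.0, 5.0) cm for the large group (generative boundary 3.0 cm), and
#' two DE blocks applied to the large-size samples:
#'
#' * `simdat1`: 55 + 45 samples; N(10, 10) x 3500 rows and N(-2, 10) x 3500
#'   rows; background N(3, 1).
#' * `simdat2`: 35 + 45 samples; Gamma(shape 5, scale 10) x 2000 and
#'   Gamma(3, 6) x 4500; background N(0.5, 10).
#' * `simdat3`: 120 + 80 samples; Poisson(10) x 2500 and Poisson(8) x 3500;
#'   background N(0.1, 20).
#'
#' Normal parameters are mean and standard deviation. When `de_fraction` is
#' given, block row counts are rescaled to total `round(de_fraction *
#' n_features)` preserving the block proportions; the distributions are
#' unchanged.
#'
#' @param preset one of `"simdat1"`, `"simdat2"`, `"simdat3"`.
#' @param de_fraction optional overall DE fraction in (0, 1].
#' @param n_features number of features (default 10,000).
#' @param seed integer seed stored in the spec and consumed by
#'   [simulate_dataset()].
#' @return Object of class `simulation_spec`.
#' @export
simdat_spec <- function(preset = c("simdat1", "simdat2", "simdat3"),
                        de_fraction = NULL, n_features = 10000L, seed = 1L) {
  preset <- match.arg(preset)
  sp <- .SIMDAT_PRESETS[[preset]]
  sp$preset <- preset
  sp$n_features <- as.integer(n_features)
  sp$seed <- as.integer(seed)
  if (!is.null(de_fraction)) {
    if (de_fraction <= 0 || de_fraction > 1)
      stop("'de_fraction' must lie in (0, 1]")
    tot <- vapply(sp$de_blocks, `[[`, integer(1), "n_rows")
    new_n <- round(de_fraction * sp$n_features * tot / sum(tot))
    if (any(new_n < 1))
      stop("'de_fraction' yields an empty DE block")
    if (sum(new_n) > sp$n_features)
      stop("DE blocks exceed the number of features")
    for (b in seq_along(sp$de_blocks)) sp$de_blocks[[b]]$n_rows <- as.integer(new_n[b])
  }
  if (sum(vapply(sp$de_blocks, `[[`, integer(1), "n_rows")) > sp$n_features)
    stop("DE blocks exceed the number of features")
  stopifnot(sp$size_small_range[2] <= sp$size_large_range[1])
  class(sp) <- "simulation_spec"
  sp
}

#' @export
print.simulation_spec <- function(x, ...) {
  nde <- sum(vapply(x$de_blocks, `[[`, integer(1), "n_rows"))
  cat(sprintf("<simulation_spec '%s'> %d features (%d DE), %d + %d samples, boundary %.1f cm, seed %d\n",
              x$preset, x$n_features, nde, x$n_small, x$n_large,
              x$size_large_range[1], x$seed))
  invisible(x)
}

#' Simulate tumor sizes for two groups
#'
#' Draws `n_small` sizes uniformly on `small_range` followed by `n_large`
#' sizes uniformly on `large_range` (cm). Reproducible by seed.
#'
#' @param n_small,n_large positive group counts.
#' @param small_range,large_range length-2 numeric intervals with
#'   `small_range` entirely below `large_range`.
#' @param seed integer seed.
#' @return Numeric vector of length `n_small + n_large`.
#' @export
simulate_sizes <- function(n_small, n_large, small_range = c(1.0, 2.9),
                           large_range = c(3.0, 5.0), seed = 1L) {
  if (n_small < 1 || n_large < 1) stop("both group counts must be >= 1")
  stopifnot(small_range[2] <= large_range[1])
  withr::with_seed(as.integer(seed), {
    c(runif(n_small, small_range[1], small_range[2]),
      runif(n_large, large_range[1], large_range[2]))
  })
}

#' Simulate an expression study from a specification
#'
#' Sizes are drawn first (small group, then large group), then a full
#' background matrix, then each DE block's rows are overwritten with draws
#' from the block distribution for the large-group samples only — small-group
#' entries of DE rows keep their background draws, which is what creates the
#' group difference. Feature ids are `g000001`, `g000002`, ...; DE blocks
#' occupy the leading rows. Fully deterministic given `spec$seed`.
#'
#' @param spec a [simdat_spec()] (or compatible `simulation_spec`).
#' @return An [expression_study()] whose `study_id` is the preset name.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  I <- spec$n_features
  n <- spec$n_small + spec$n_large
  withr::with_seed(spec$seed, {
    sizes <- c(runif(spec$n_small, spec$size_small_range[1], spec$size_small_range[2]),
               runif(spec$n_large, spec$size_large_range[1], spec$size_large_range[2]))
    X <- matrix(.draw(spec$background$distribution, spec$background$params, I * n), I, n)
    large_cols <- spec$n_small + seq_len(spec$n_large)
    r0 <- 0L
    for (b in spec$de_blocks) {
      rows <- r0 + seq_len(b$n_rows)
      r0 <- r0 + b$n_rows
      X[rows, large_cols] <- .draw(b$distribution, b$params, b$n_rows * spec$n_large)
    }
  })
  expression_study(X, sizes = sizes, study_id = spec$preset,
                   feature_ids = sprintf("g%06d", seq_len(I)),
                   sample_ids = sprintf("%s_s%03d", spec$preset, seq_len(n)))
}

#' Simulate a suite of studies at a common DE fraction
#'
#' Rebuilds each base specification with its DE blocks rescaled to the given
#' overall fraction (block proportions preserved) and simulates each study
#' with a seed derived deterministically from `seed` and the preset name.
#'
#' @param base_specs list of `simulation_spec` objects (default: the three
#'   presets).
#' @param fraction overall DE fraction in (0, 1].
#' @param seed base integer seed.
#' @return List of [expression_study()] objects.
#' @export
simulate_de_fraction_suite <- function(base_specs = lapply(c("simdat1", "simdat2", "simdat3"), simdat_spec),
                                       fraction, seed = 1L) {
  lapply(base_specs, function(sp) {
    sp2 <- simdat_spec(sp$preset, de_fraction = fraction,
                       n_features = sp$n_features,
                       seed = .derive_seed(seed, sp$preset, fraction))
    simulate_dataset(sp2)
  })
}

#' Simulate the three-preset study collection
#'
#' Convenience wrapper generating simdat1-3 (optionally at a common DE
#' fraction) and assembling them into a matched [study_collection()].
#'
#' @param de_fraction optional overall DE fraction in (0, 1]; `NULL` keeps
#'   each preset's original block sizes.
#' @param seed base integer seed.
#' @param n_features number of features per study.
#' @return A [study_collection()] with K = 3 studies.
#' @export
simulate_collection <- function(de_fraction = NULL, seed = 1L, n_features = 10000L) {
  studies <- lapply(c("simdat1", "simdat2", "simdat3"), function(p) {
    sp <- simdat_spec(p, de_fraction = de_fraction, n_features = n_features,
                      seed = .derive_seed(seed, p, if (is.null(de_fraction)) 1 else de_fraction))
    simulate_dataset(sp)
  })
  match_features(studies)
}
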