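# Fixtures are built in code: small studies with a known boundary at 2.5 cm
# (8 small + 8 large samples, the first `de_rows` genes shifted in the large
# group), plus independent oracles used across test files.

make_toy_study <- function(id, I = 30, n_small = 8, n_large = 8, de_rows = 10,
                           shift = 3, seed = 42) {
  withr::with_seed(seed + sum(utf8ToInt(id)), {
    n <- n_small + n_large
    X <- matrix(rnorm(I * n), I, n,
                dimnames = list(sprintf("g%03d", seq_len(I)),
                                sprintf("%s_s%02d", id, seq_len(n))))
    large <- n_small + seq_len(n_large)
    X[seq_len(de_rows), large] <- X[seq_len(de_rows), large] + shift
    sizes <- c(runif(n_small, 1.0, 2.4), runif(n_large, 2.6, 4.0))
  })
  expression_study(X, sizes = sizes, study_id = id)
}

toy_collection <- function(ids = c("a", "b"), ...) {
  match_features(lapply(ids, make_toy_study, ...))
}

# Brute-force two-sided WMW p-value: enumerate every assignment of the pooled
# ranks to a group of size n1 and compare rank-sum tail masses.
wmw_enum_pvalue <- function(x_small, x_large) {
  x <- c(x_small, x_large)
  n1 <- length(x_small)
  r <- rank(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(x), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# a stat_matrix built directly from a values matrix (for distance tests)
make_stat_matrix <- function(values, stat_names = colnames(values),
                             study_id = "toy", q = 2, folded = FALSE) {
  structure(list(values = values, stat_names = stat_names,
                 study_id = study_id, threshold_q = q, folded = folded),
            class = "stat_matrix")
}

# scaled-down simdat collection for unit tests (full block proportions kept)
small_simdat_collection <- function(seed = 1, n_features = 400, de_fraction = 0.7) {
  studies <- lapply(c("simdat1", "simdat2", "simdat3"), function(p) {
    sp <- simdat_spec(p, de_fraction = de_fraction, n_features = n_features,
                      seed = seed + sum(utf8ToInt(p)))
    simulate_dataset(sp)
  })
  match_features(studies)
}
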