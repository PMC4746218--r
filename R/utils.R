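# internal helpers shared across modules

# p-values are clamped away from exact zero before taking logs
.P_FLOOR <- 1e-300
# standard-error floor guarding constant genes in t-type statistics
.SE_FLOOR <- 1e-12

.stop_invalid_split <- function(q, study_id) {
  stop(errorCondition(
    sprintf("threshold q = %g yields an invalid split (group-size floor) in study '%s'",
            q, study_id),
    class = c("tcut_invalid_split", "error")
  ))
}

# Deterministic 32-bit seed derived from a base seed, a study identifier and a
# threshold. Using the study *id* (not its position) keeps permutation draws
# invariant under reordering of the studies in a collection.
.derive_seed <- function(base, study_id, q) {
  h <- sum(utf8ToInt(as.character(study_id)) * seq_along(utf8ToInt(as.character(study_id))))
  v <- (abs(as.double(base)) %% 1e6) * 48271 + (h %% 1e6) * 2654 + round(q * 1000) * 97
  as.integer(v %% 2147483629) + 1L
}

# unscaled median absolute deviation (no 1.4826 consistency factor)
.mad0 <- function(x) median(abs(x - median(x)))

# Per-statistic scale used in DEDS distances: unscaled MAD, falling back to the
# standard deviation when the MAD is zero; a doubly degenerate (constant)
# column gets scale Inf so it contributes 0 to every distance.
.col_scale <- function(x) {
  m <- .mad0(x)
  if (m > 0) return(m)
  s <- sd(x)
  if (is.finite(s) && s > 0) return(s)
  Inf
}

# number of decimal places needed to print x exactly (bounded)
.decimals <- function(x) {
  for (d in 0:10) if (abs(x - round(x, d)) < 1e-9) return(d)
  10L
}

# modal value of a numeric vector; ties go to the smallest value
.mode_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}
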