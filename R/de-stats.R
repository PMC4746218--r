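# Per-gene two-group differential-expression statistics.
#
# All signed statistics are oriented small-group minus large-group. The
# distance synthesis consumes folded (absolute) values of t, SAM, FC and
# moderated t, because a coordinate-wise "most extreme" corner only makes
# sense when larger means more differentially expressed; B and moderated F
# are already monotone in evidence and are used raw.

.STAT_NAMES <- c("t", "SAM", "FC", "B", "modT", "modF")
.FOLDED_STATS <- c("t", "SAM", "FC", "modT")

#' Names of the supported differential-expression statistics
#'
#' The vocabulary used by `stat_names` arguments throughout the package:
#' ordinary t (`t`), SAM with fudge factor (`SAM`), fold change as difference
#' of group means (`FC`), log posterior odds of differential expression (`B`),
#' empirical-Bayes moderated t (`modT`) and moderated F (`modF`).
#'
#' @return Character vector of the six statistic names in canonical order.
#' @export
deds_stats <- function() .STAT_NAMES

#' Two-sided Wilcoxon-Mann-Whitney p-value
#'
#' Exact (distributional enumeration via the Wilcoxon rank-sum null) when the
#' pooled sample has at most 12 observations and no ties; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x_small,x_large numeric vectors, the two groups (non-empty).
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' wmw_pvalue(c(1, 2), c(3, 4)) # 1/3, from the 6 possible rank assignments
wmw_pvalue <- function(x_small, x_large) {
  if (!length(x_small) || !length(x_large)) stop("both groups must be non-empty")
  x <- c(x_small, x_large)
  mask <- c(rep(TRUE, length(x_small)), rep(FALSE, length(x_large)))
  ri <- .wmw_rank_info(matrix(x, nrow = 1))
  .wmw_p_rows(ri, mask)[1]
}

# Precompute per-row rank information for a features x samples matrix:
# average ranks, the tie-correction term sum(t^3 - t), and a ties flag.
.wmw_rank_info <- function(X) {
  I <- nrow(X); n <- ncol(X)
  rk <- matrix(0, I, n)
  tie_term <- numeric(I)
  has_ties <- logical(I)
  for (i in seq_len(I)) {
    x <- X[i, ]
    r <- rank(x)
    rk[i, ] <- r
    if (anyDuplicated(x)) {
      tl <- rle(sort.int(x, method = "quick"))$lengths
      tie_term[i] <- sum(tl^3 - tl)
      has_ties[i] <- TRUE
    }
  }
  list(rk = rk, tie_term = tie_term, has_ties = has_ties, n = n)
}

# Vectorized two-sided WMW p-values for all rows given a small-group mask.
.wmw_p_rows <- function(ri, mask) {
  n <- ri$n
  n1 <- sum(mask); n2 <- n - n1
  W <- as.vector(ri$rk %*% as.numeric(mask))
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig2 <- (n1 * n2 / 12) * ((n + 1) - ri$tie_term / (n * (n - 1)))
  sig <- sqrt(pmax(sig2, 0))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sig
  p <- pmin(1, 2 * pnorm(-abs(z)))
  p[!is.finite(z)] <- 1 # constant rows: no evidence
  if (n <= 12) {
    ex <- which(!ri$has_ties)
    for (i in ex) {
      u <- U[i]
      p[i] <- min(1, 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2)))
    }
  }
  p
}

#' Ordinary two-sample pooled-variance t statistic
#'
#' Oriented small-group minus large-group. A 0/0 case (both groups constant
#' and equal) returns 0 by convention; the pooled standard error is floored at
#' 1e-12 so constant genes never divide by zero.
#'
#' @param x_small,x_large numeric vectors with at least 2 observations each.
#' @return The t statistic.
#' @export
ordinary_t <- function(x_small, x_large) {
  stopifnot(length(x_small) >= 2, length(x_large) >= 2)
  d <- mean(x_small) - mean(x_large)
  se <- .pooled_se(x_small, x_large)
  if (d == 0) return(0)
  d / se
}

.pooled_se <- function(x_small, x_large) {
  n1 <- length(x_small); n2 <- length(x_large)
  s2 <- ((n1 - 1) * var(x_small) + (n2 - 1) * var(x_large)) / (n1 + n2 - 2)
  max(sqrt(s2 * (1 / n1 + 1 / n2)), .SE_FLOOR)
}

#' Fold change as difference of group means
#'
#' `mean(x_small) - mean(x_large)`, the appropriate fold-change measure for
#' log-scale expression data.
#'
#' @param x_small,x_large numeric vectors (non-empty).
#' @return Difference of means.
#' @export
fold_change <- function(x_small, x_large) {
  if (!length(x_small) || !length(x_large)) stop("both groups must be non-empty")
  mean(x_small) - mean(x_large)
}

#' Estimate the SAM fudge factor s0
#'
#' The published SAM recipe: candidate values are the percentiles
#' 0, 5, ..., 100 of the per-gene standard errors; for each candidate the SAM
#' statistics d = diff / (se + s0) are formed, genes are binned by deciles of
#' se, and the candidate minimizing the coefficient of variation of the
#' within-bin MADs of d is chosen. The result is floored at a small positive
#' value so zero standard errors never divide by zero.
#'
#' @param per_gene_means_diff numeric vector of per-gene mean differences.
#' @param per_gene_se numeric vector of per-gene standard errors (>= 0).
#' @return Positive scalar s0.
#' @export
estimate_sam_s0 <- function(per_gene_means_diff, per_gene_se) {
  d <- per_gene_means_diff; se <- per_gene_se
  stopifnot(length(d) == length(se))
  if (any(se < 0)) stop("standard errors must be non-negative")
  if (all(se <= 0)) return(.SE_FLOOR)
  cand <- quantile(se, probs = seq(0, 1, by = 0.05), names = FALSE)
  br <- unique(quantile(se, probs = seq(0, 1, by = 0.1), names = FALSE))
  bins <- if (length(br) > 2) cut(se, breaks = br, include.lowest = TRUE) else factor(rep(1L, length(se)))
  cv <- vapply(cand, function(s0) {
    dd <- d / (se + s0)
    m <- tapply(dd, bins, .mad0)
    m <- m[is.finite(m)]
    if (length(m) < 2) return(0)
    mm <- mean(m)
    if (mm == 0) return(Inf)
    sd(m) / mm
  }, numeric(1))
  max(cand[which.min(cv)], .SE_FLOOR)
}

#' SAM statistic with fudge factor
#'
#' `(mean(x_small) - mean(x_large)) / (se + s0)` with the pooled standard
#' error; reduces to [ordinary_t()] at `s0 = 0` and shrinks to 0 as
#' `s0` grows.
#'
#' @param x_small,x_large numeric vectors with at least 2 observations each.
#' @param s0 non-negative fudge factor, typically from [estimate_sam_s0()].
#' @return The SAM statistic.
#' @export
sam_stat <- function(x_small, x_large, s0) {
  stopifnot(length(x_small) >= 2, length(x_large) >= 2, s0 >= 0)
  d <- mean(x_small) - mean(x_large)
  if (d == 0) return(0)
  d / (.pooled_se(x_small, x_large) + s0)
}

#' Estimate empirical-Bayes moderation priors
#'
#' Fits a scaled inverse chi-square model to the per-gene sample variances by
#' moment matching on log variances (trigamma inversion), delegating to
#' `limma::fitFDist()`. With fewer than 2 usable genes the function falls
#' back to no moderation (`prior_df = 0`) with a warning. A non-positive
#' empirical excess spread yields `prior_df = Inf` (complete shrinkage to the
#' common variance).
#'
#' @param per_gene_var numeric vector of per-gene sample variances.
#' @param residual_df residual degrees of freedom of each variance
#'   (n1 + n2 - 2 for the two-group case).
#' @param de_proportion prior probability that a gene is differentially
#'   expressed, used by [b_stat()].
#' @param effect_var_scale variance-inflation ratio of differential effects
#'   relative to the coefficient variance, used by [b_stat()]; `NULL` until
#'   estimated from data.
#' @return An object of class `moderation_priors`: list with `prior_df`,
#'   `prior_var`, `de_proportion`, `effect_var_scale`.
#' @export
estimate_eb_priors <- function(per_gene_var, residual_df,
                               de_proportion = 0.01, effect_var_scale = NULL) {
  v <- per_gene_var[is.finite(per_gene_var) & per_gene_var > 0]
  if (length(v) < 2) {
    warning("fewer than 2 genes with positive variance; falling back to no moderation")
    pv <- if (length(v) == 1) v else 1
    return(moderation_priors(0, pv, de_proportion, effect_var_scale))
  }
  fit <- limma::fitFDist(v, df1 = residual_df)
  d0 <- fit$df2
  if (is.na(d0)) d0 <- 0
  moderation_priors(d0, fit$scale, de_proportion, effect_var_scale)
}

#' @rdname estimate_eb_priors
#' @param prior_df,prior_var prior degrees of freedom (possibly `Inf`) and
#'   prior variance of the scaled inverse chi-square variance model.
#' @export
moderation_priors <- function(prior_df, prior_var, de_proportion = 0.01,
                              effect_var_scale = NULL) {
  stopifnot(prior_df >= 0, prior_var > 0,
            de_proportion > 0, de_proportion < 1)
  structure(list(prior_df = prior_df, prior_var = prior_var,
                 de_proportion = de_proportion,
                 effect_var_scale = effect_var_scale),
            class = "moderation_priors")
}

#' Empirical-Bayes moderated t and F statistics
#'
#' The gene's sample variance is shrunk towards the prior:
#' `s_tilde^2 = (prior_df * prior_var + df * s^2) / (prior_df + df)`, and the
#' moderated t is the mean difference over `s_tilde * sqrt(1/n1 + 1/n2)`.
#' In the two-group case the moderated F is the square of the moderated t.
#' `prior_df = 0` reproduces [ordinary_t()]; `prior_df = Inf` replaces every
#' gene's variance by `prior_var`.
#'
#' @param x_small,x_large numeric vectors with at least 2 observations each.
#' @param priors a [moderation_priors()] object.
#' @return List with elements `modT` and `modF`.
#' @export
moderated_t <- function(x_small, x_large, priors) {
  stopifnot(inherits(priors, "moderation_priors"),
            length(x_small) >= 2, length(x_large) >= 2)
  n1 <- length(x_small); n2 <- length(x_large)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * var(x_small) + (n2 - 1) * var(x_large)) / df
  st2 <- .posterior_var(s2, df, priors$prior_df, priors$prior_var)
  se <- max(sqrt(st2 * (1 / n1 + 1 / n2)), .SE_FLOOR)
  d <- mean(x_small) - mean(x_large)
  modT <- if (d == 0) 0 else d / se
  list(modT = modT, modF = modT^2)
}

.posterior_var <- function(s2, df, d0, v0) {
  if (!is.finite(d0)) return(s2 * 0 + v0)
  if (d0 == 0) return(s2)
  (d0 * v0 + df * s2) / (d0 + df)
}

#' B statistic: log posterior odds of differential expression
#'
#' Under the standard hierarchical model, with moderated t statistic `modT`
#' on `total_df` degrees of freedom, prior DE probability `p` and
#' effect-variance ratio `c = effect_var_scale` (variance inflation of true
#' effects relative to the coefficient variance), the log posterior odds are
#' `log(p/(1-p)) + log(r)/2 + ((d+1)/2) * log((t^2 + d) / (r t^2 + d))` with
#' `r = 1/(1+c)`. Symmetric in `modT` and strictly increasing in `|modT|`.
#' The value is clamped below at `floor`.
#'
#' @param modT moderated t statistic(s); vector or matrix.
#' @param total_df total degrees of freedom (residual + prior).
#' @param priors a [moderation_priors()] with `de_proportion` in (0,1) and a
#'   positive `effect_var_scale`.
#' @param floor lower clamp for the log odds (default -745, about
#'   `log(.Machine$double.xmin)`).
#' @return Log posterior odds, same shape as `modT`.
#' @export
b_stat <- function(modT, total_df, priors, floor = -745) {
  stopifnot(inherits(priors, "moderation_priors"))
  p <- priors$de_proportion
  cc <- priors$effect_var_scale
  if (is.null(cc) || !is.finite(cc) || cc <= 0)
    stop("priors$effect_var_scale must be a positive number")
  r <- 1 / (1 + cc)
  d <- min(total_df, 1e6)
  t2 <- modT^2
  b <- log(p / (1 - p)) + 0.5 * log(r) +
    ((d + 1) / 2) * log((t2 + d) / (r * t2 + d))
  pmax(b, floor)
}

# ---------------------------------------------------------------------------
# Fast block engine: evaluates all requested statistics for every column of a
# mask matrix (observed labelling first, permuted relabelings after) in one
# pass, using BLAS group sums. Calibration quantities (SAM s0, moderation
# priors, B effect-variance scale) are estimated from the first (observed)
# mask and reused for permuted masks, so permuted and observed statistics
# share one scale.
# ---------------------------------------------------------------------------
.stat_block <- function(X, masks, stat_names, fold, calib = NULL) {
  stat_names <- match.arg(stat_names, .STAT_NAMES, several.ok = TRUE)
  stat_names <- .STAT_NAMES[.STAT_NAMES %in% stat_names]
  n <- ncol(X)
  n1 <- sum(masks[, 1])
  n2 <- n - n1
  stopifnot(n1 >= 2, n2 >= 2)
  M <- matrix(as.numeric(masks), n, ncol(masks))
  rs <- rowSums(X)
  X2 <- X * X
  rss <- rowSums(X2)
  S1 <- X %*% M
  SS1 <- X2 %*% M
  m1 <- S1 / n1
  m2 <- (rs - S1) / n2
  df <- n - 2
  s2 <- pmax((SS1 - n1 * m1^2) + ((rss - SS1) - n2 * m2^2), 0) / df
  vfac <- 1 / n1 + 1 / n2
  se <- pmax(sqrt(s2 * vfac), .SE_FLOOR)
  dm <- m1 - m2

  need_mod <- any(c("modT", "modF", "B") %in% stat_names)
  if (is.null(calib)) {
    calib <- list()
    if ("SAM" %in% stat_names)
      calib$sam_s0 <- estimate_sam_s0(dm[, 1], se[, 1])
    if (need_mod) {
      pri <- estimate_eb_priors(s2[, 1], df)
      if ("B" %in% stat_names) {
        st2 <- .posterior_var(s2[, 1], df, pri$prior_df, pri$prior_var)
        mt1 <- dm[, 1] / pmax(sqrt(st2 * vfac), .SE_FLOOR)
        pri$effect_var_scale <- max(quantile(mt1^2, 0.9, names = FALSE) - 1, 0.1)
      }
      calib$priors <- pri
    }
  }

  out <- list()
  if ("t" %in% stat_names) out$t <- dm / se
  if ("SAM" %in% stat_names) out$SAM <- dm / (se + calib$sam_s0)
  if ("FC" %in% stat_names) out$FC <- dm
  if (need_mod) {
    pri <- calib$priors
    st2 <- .posterior_var(s2, df, pri$prior_df, pri$prior_var)
    modT <- dm / pmax(sqrt(st2 * vfac), .SE_FLOOR)
    if ("B" %in% stat_names)
      out$B <- b_stat(modT, df + pri$prior_df, pri)
    if ("modT" %in% stat_names) out$modT <- modT
    if ("modF" %in% stat_names) out$modF <- modT^2
  }
  out <- out[stat_names]
  if (fold)
    for (nm in intersect(stat_names, .FOLDED_STATS)) out[[nm]] <- abs(out[[nm]])
  list(stats = out, calib = calib, n1 = n1, n2 = n2)
}

#' Compute the per-gene statistic matrix for one study and split
#'
#' Evaluates each requested statistic for every gene. The SAM fudge factor and
#' the empirical-Bayes moderation priors are estimated once per (study, split)
#' from the observed labelling. With `fold = TRUE` (the default, as consumed
#' by the distance synthesis) the signed columns t, SAM, FC and modT are
#' replaced by absolute values; B and modF are always used raw.
#'
#' @param study an [expression_study()].
#' @param split a valid [split_by_threshold()] result.
#' @param stat_names subset of [deds_stats()] (canonical order is enforced).
#' @param fold replace signed columns by absolute values?
#' @return An object of class `stat_matrix`: list with `values` (features x J
#'   matrix, columns named by statistic), `stat_names`, `study_id`,
#'   `threshold_q`, `folded`.
#' @export
compute_stat_matrix <- function(study, split, stat_names = deds_stats(),
                                fold = TRUE) {
  stopifnot(inherits(study, "expression_study"), inherits(split, "group_split"))
  if (!split$valid) stop("split is invalid (group-size floor violated)")
  blk <- .stat_block(study$expression,
                     matrix(split$small_mask, ncol = 1),
                     stat_names, fold)
  values <- do.call(cbind, lapply(blk$stats, function(m) m[, 1]))
  colnames(values) <- names(blk$stats)
  rownames(values) <- study$feature_ids
  structure(
    list(values = values, stat_names = names(blk$stats),
         study_id = study$study_id, threshold_q = split$threshold_q,
         folded = fold, calib = blk$calib),
    class = "stat_matrix"
  )
}

#' @export
print.stat_matrix <- function(x, ...) {
  cat(sprintf("<stat_matrix '%s'> %d genes x %d statistics (%s) at q = %g%s\n",
              x$study_id, nrow(x$values), length(x$stat_names),
              paste(x$stat_names, collapse = ", "), x$threshold_q,
              if (x$folded) ", folded" else ""))
  invisible(x)
}
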