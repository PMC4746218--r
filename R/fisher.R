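# Fisher's inverse chi-square meta-score and its genome-wide objective.

#' Fisher's inverse chi-square combination of p-values
#'
#' `S = -2 * sum(log(p_k))` over K studies; chi-square with 2K degrees of
#' freedom under the joint null. p-values are clamped at 1e-300 before the
#' log so exact-zero approximations cannot produce infinite scores.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (one per study).
#' @return Non-negative Fisher score.
#' @export
#' @examples
#' fisher_score(c(0.5, 0.5, 0.5)) # -2 * 3 * log(0.5) = 4.159
fisher_score <- function(pvals) {
  if (any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  -2 * sum(log(pmax(pvals, .P_FLOOR)))
}

# Per-gene WMW p-value matrix (I x K) for the collection at threshold q.
# rank_infos, when supplied, carries precomputed per-study rank information.
.pvalue_matrix <- function(collection, q, min_group, rank_infos = NULL) {
  K <- length(collection$studies)
  pm <- matrix(NA_real_, length(collection$feature_ids), K)
  for (k in seq_len(K)) {
    st <- collection$studies[[k]]
    sp <- split_by_threshold(st, q, min_group)
    if (!sp$valid) .stop_invalid_split(q, st$study_id)
    ri <- if (is.null(rank_infos)) .wmw_rank_info(st$expression) else rank_infos[[k]]
    pm[, k] <- .wmw_p_rows(ri, sp$small_mask)
  }
  colnames(pm) <- names(collection$studies)
  pm
}

#' Genome-wide Fisher objective at a threshold
#'
#' Computes the per-gene WMW p-value in every study at the split induced by
#' `q`, combines them per gene with [fisher_score()], and returns the sum of
#' the scores over all genes. An invalid split in any study raises a
#' classed error (`tcut_invalid_split`) rather than returning silently.
#'
#' @param collection a [study_collection()].
#' @param q candidate threshold (cm).
#' @param min_group minimum per-group sample count.
#' @return The objective value (to be maximized over thresholds).
#' @export
fisher_objective <- function(collection, q, min_group = 3L) {
  stopifnot(inherits(collection, "study_collection"))
  pm <- .pvalue_matrix(collection, q, min_group)
  sum(-2 * log(pmax(pm, .P_FLOOR)))
}
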