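# DEDS distance synthesis: extreme points, MAD-scaled distances, and the
# mDEDS cross-study objective.

#' Construct an extreme point
#'
#' A length-J vector of coordinate-wise maxima of statistic values, the "most
#' differentially expressed corner" of statistic space.
#'
#' @param coords numeric vector, one coordinate per statistic.
#' @param stat_names character vector naming the statistics (same length).
#' @param provenance one of `"observed"`, `"permuted"`, `"overall"`, `"tep"`.
#' @return Object of class `extreme_point`.
#' @export
extreme_point <- function(coords, stat_names,
                          provenance = c("observed", "permuted", "overall", "tep")) {
  provenance <- match.arg(provenance)
  stopifnot(length(coords) == length(stat_names), all(is.finite(coords)))
  structure(list(coords = stats::setNames(as.numeric(coords), stat_names),
                 stat_names = stat_names, provenance = provenance),
            class = "extreme_point")
}

#' @export
print.extreme_point <- function(x, ...) {
  cat(sprintf("<extreme_point: %s>\n", x$provenance))
  print(x$coords)
  invisible(x)
}

#' Permutation configuration
#'
#' @param n_permutations number of random group relabelings (B).
#' @param seed base integer seed; every permutation draw in the package is a
#'   deterministic function of this seed, the study id and the threshold.
#' @return Object of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 200L, seed = 1L) {
  stopifnot(n_permutations >= 0)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "perm_config")
}

#' Observed coordinate-wise extreme point
#'
#' The per-statistic maximum over all genes of a [compute_stat_matrix()]
#' result.
#'
#' @param stats a `stat_matrix`.
#' @return An [extreme_point()] with provenance `"observed"`.
#' @export
observed_extreme <- function(stats) {
  stopifnot(inherits(stats, "stat_matrix"), nrow(stats$values) >= 1)
  extreme_point(apply(stats$values, 2, max), stats$stat_names, "observed")
}

# Build the n x B logical mask matrix of group relabelings preserving
# (n_small, n_large). The full space is enumerated when it has at most
# `enumerate_limit` elements; otherwise B uniform draws with replacement.
.perm_masks <- function(n, n_small, B, seed, enumerate_limit = 500) {
  space <- choose(n, n_small)
  if (space <= enumerate_limit) {
    idx <- utils::combn(n, n_small)
  } else {
    idx <- withr::with_seed(seed,
      replicate(B, sample.int(n, n_small)))
    idx <- matrix(idx, nrow = n_small)
  }
  masks <- matrix(FALSE, n, ncol(idx))
  for (b in seq_len(ncol(idx))) masks[idx[, b], b] <- TRUE
  masks
}

#' Permutation extreme point
#'
#' For each of B random relabelings of the small/large mask (preserving the
#' group sizes; the full relabeling space is enumerated when it has at most
#' 500 elements), recomputes the statistics and their observed extreme, and
#' returns the coordinate-wise maximum over the relabelings. Calibration
#' (SAM s0, moderation priors) is taken from the observed labelling so
#' permuted statistics live on the same scale. Deterministic given the
#' configuration seed.
#'
#' @param study an [expression_study()].
#' @param split a valid [split_by_threshold()] result.
#' @param stat_names subset of [deds_stats()].
#' @param perm a [perm_config()] with `n_permutations >= 1`.
#' @param fold fold signed statistics? (must match the observed analysis).
#' @param masks optional explicit logical mask matrix (n x B) overriding the
#'   random draws — used for oracles and degenerate checks.
#' @return An [extreme_point()] with provenance `"permuted"`.
#' @export
permuted_extreme <- function(study, split, stat_names = deds_stats(),
                             perm = perm_config(), fold = TRUE, masks = NULL) {
  stopifnot(inherits(study, "expression_study"), inherits(split, "group_split"),
            inherits(perm, "perm_config"))
  if (!split$valid) stop("split is invalid (group-size floor violated)")
  if (is.null(masks) && perm$n_permutations < 1)
    stop("n_permutations must be >= 1 (use observed_extreme() alone for B = 0)")
  n <- length(split$small_mask)
  if (is.null(masks))
    masks <- .perm_masks(n, split$n_small, perm$n_permutations,
                         .derive_seed(perm$seed, study$study_id, split$threshold_q))
  calib <- .stat_block(study$expression, matrix(split$small_mask, ncol = 1),
                       stat_names, fold)$calib
  blk <- .stat_block(study$expression, masks, stat_names, fold, calib = calib)
  coords <- vapply(blk$stats, function(m) max(apply(m, 2, max)), numeric(1))
  extreme_point(coords, names(blk$stats), "permuted")
}

#' Overall extreme point
#'
#' Coordinate-wise maximum of the observed and permutation extreme points.
#'
#' @param e0,ep [extreme_point()] objects with matching `stat_names`.
#' @return An [extreme_point()] with provenance `"overall"`.
#' @export
overall_extreme <- function(e0, ep) {
  stopifnot(inherits(e0, "extreme_point"), inherits(ep, "extreme_point"))
  if (!identical(e0$stat_names, ep$stat_names))
    stop("extreme points have mismatched stat_names")
  extreme_point(pmax(e0$coords, ep$coords), e0$stat_names, "overall")
}

# Scaled squared distances of each gene's statistics row to extreme-point
# coordinates e, with per-column scales (Inf scale => zero contribution).
.deds_dist <- function(values, e, scales) {
  d <- numeric(nrow(values))
  for (j in seq_len(ncol(values))) {
    if (!is.finite(scales[j])) next
    d <- d + ((values[, j] - e[j]) / scales[j])^2
  }
  d
}

#' MAD-scaled distances to an extreme point
#'
#' Per-gene distance `d_i = sum_j (t_ij - E_j)^2 / MAD_j^2`, where MAD_j is
#' the unscaled median absolute deviation of statistic column j over genes
#' (no 1.4826 consistency factor). A zero MAD falls back to the column's
#' standard deviation; a constant column carries no ranking information and
#' contributes 0 to all distances.
#'
#' @param stats a `stat_matrix`.
#' @param e an [extreme_point()] sharing the statistics.
#' @return Object of class `deds_distances`: list with `d` (non-negative,
#'   length I) and `mad_scales` (length J).
#' @export
deds_distances <- function(stats, e) {
  stopifnot(inherits(stats, "stat_matrix"), inherits(e, "extreme_point"))
  if (!identical(stats$stat_names, e$stat_names))
    stop("statistics and extreme point have mismatched stat_names")
  scales <- vapply(seq_along(e$coords),
                   function(j) .col_scale(stats$values[, j]), numeric(1))
  names(scales) <- e$stat_names
  structure(list(d = .deds_dist(stats$values, e$coords, scales),
                 mad_scales = scales),
            class = "deds_distances")
}

# One study's full per-threshold summary: observed statistics, MAD scales and
# the per-threshold extreme point E_q = max(E_0, E_p). The workhorse shared by
# mdeds_objective(), tep_extreme(), tep_objective() and scan_thresholds().
.study_summary <- function(study, q, min_group, stat_names, B, base_seed, fold,
                           need_perms = TRUE) {
  sp <- split_by_threshold(study, q, min_group)
  if (!sp$valid)
    return(list(valid = FALSE, n_small = sp$n_small, n_large = sp$n_large))
  n <- length(sp$small_mask)
  masks <- matrix(sp$small_mask, ncol = 1)
  if (need_perms && B >= 1) {
    pm <- .perm_masks(n, sp$n_small, B, .derive_seed(base_seed, study$study_id, q))
    masks <- cbind(masks, pm)
  }
  blk <- .stat_block(study$expression, masks, stat_names, fold)
  J <- length(blk$stats)
  obs <- do.call(cbind, lapply(blk$stats, function(m) m[, 1]))
  colnames(obs) <- names(blk$stats)
  mads <- vapply(seq_len(J), function(j) .col_scale(obs[, j]), numeric(1))
  names(mads) <- names(blk$stats)
  E0 <- vapply(blk$stats, function(m) max(m[, 1]), numeric(1))
  if (ncol(masks) > 1) {
    Ep <- vapply(blk$stats, function(m) max(m[, -1, drop = FALSE]), numeric(1))
    Eq <- pmax(E0, Ep)
  } else {
    Ep <- NULL
    Eq <- E0
  }
  list(valid = TRUE, stats = obs, mads = mads, E0 = E0, Ep = Ep, Eq = Eq,
       n_small = sp$n_small, n_large = sp$n_large,
       stat_names = names(blk$stats))
}

#' mDEDS objective at a threshold
#'
#' For every study: split at `q`, compute the statistics, form the overall
#' extreme point `E = max(E_0, E_p)` from the observed data and B permuted
#' relabelings, and take MAD-scaled distances of every gene to E. The
#' objective is the distance summed over genes and studies (to be minimized
#' over thresholds). Genes are aggregated by the collection's shared matched
#' ordering. An invalid split in any study raises a classed error.
#'
#' @param collection a [study_collection()].
#' @param q candidate threshold (cm).
#' @param stat_names subset of [deds_stats()].
#' @param perm a [perm_config()].
#' @param min_group minimum per-group sample count.
#' @param fold fold signed statistics?
#' @return The objective value.
#' @export
mdeds_objective <- function(collection, q, stat_names = deds_stats(),
                            perm = perm_config(), min_group = 3L, fold = TRUE) {
  stopifnot(inherits(collection, "study_collection"), inherits(perm, "perm_config"))
  total <- 0
  for (st in collection$studies) {
    s <- .study_summary(st, q, min_group, stat_names,
                        perm$n_permutations, perm$seed, fold)
    if (!s$valid) .stop_invalid_split(q, st$study_id)
    total <- total + sum(.deds_dist(s$stats, s$Eq, s$mads))
  }
  total
}
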