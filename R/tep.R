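# Totally extreme point (TEP): one extreme point maximized across the whole
# threshold grid and all studies, so distances are comparable across the scan.

#' Totally extreme point over a threshold grid
#'
#' For every threshold q in `grid` yielding a valid split in a study, the
#' per-threshold extreme point `E_q = max(E_0^(q), E_p^(q))` is computed
#' (observed plus B permuted relabelings); the TEP is the coordinate-wise
#' maximum of all these E_q over thresholds *and* studies. Invalid (q, study)
#' combinations are skipped; an error is raised only if no threshold is valid
#' in any study.
#'
#' @param collection a [study_collection()].
#' @param grid numeric vector of candidate thresholds (see [make_grid()]).
#' @param stat_names subset of [deds_stats()].
#' @param perm a [perm_config()].
#' @param min_group minimum per-group sample count.
#' @param fold fold signed statistics?
#' @return An [extreme_point()] with provenance `"tep"`.
#' @export
tep_extreme <- function(collection, grid, stat_names = deds_stats(),
                        perm = perm_config(), min_group = 3L, fold = TRUE) {
  stopifnot(inherits(collection, "study_collection"), length(grid) >= 1)
  best <- NULL
  nms <- NULL
  for (q in grid) {
    for (st in collection$studies) {
      s <- .study_summary(st, q, min_group, stat_names,
                          perm$n_permutations, perm$seed, fold)
      if (!s$valid) next
      best <- if (is.null(best)) s$Eq else pmax(best, s$Eq)
      nms <- s$stat_names
    }
  }
  if (is.null(best)) stop("no threshold in the grid yields a valid split")
  extreme_point(best, nms, "tep")
}

#' TEP objective at a threshold
#'
#' MAD-scaled distance sum `sum_i sum_k sum_j (t_ikj(q) - Emax_j)^2 /
#' MAD_kj(q)^2` against a single totally extreme point precomputed once for
#' the whole scan with [tep_extreme()]. MAD scales are per study, statistic
#' and threshold, as in the per-threshold synthesis. No permutations are
#' drawn here: the extreme point is fixed.
#'
#' @param collection a [study_collection()].
#' @param q candidate threshold (cm).
#' @param e_max the shared [extreme_point()] (provenance `"tep"`).
#' @param stat_names subset of [deds_stats()]; must match `e_max`.
#' @param min_group minimum per-group sample count.
#' @param fold fold signed statistics?
#' @return The objective value (to be minimized over thresholds).
#' @export
tep_objective <- function(collection, q, e_max, stat_names = deds_stats(),
                          min_group = 3L, fold = TRUE) {
  stopifnot(inherits(collection, "study_collection"), inherits(e_max, "extreme_point"))
  total <- 0
  for (st in collection$studies) {
    s <- .study_summary(st, q, min_group, stat_names, B = 0,
                        base_seed = 0L, fold = fold, need_perms = FALSE)
    if (!s$valid) .stop_invalid_split(q, st$study_id)
    if (!identical(s$stat_names, e_max$stat_names))
      stop("stat_names of the collection summary and e_max differ")
    total <- total + sum(.deds_dist(s$stats, e_max$coords, s$mads))
  }
  total
}
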