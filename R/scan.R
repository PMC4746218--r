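# Threshold grid construction, objective scanning, optimum selection and
# fine-grid refinement.

#' Build an arithmetic threshold grid
#'
#' Inclusive grid `lo, lo + step, ..., hi`; the endpoint is included when it
#' lies within half a step of the last point. Values are rounded to the
#' decimal places of `lo`/`step` so grid labels never carry floating-point
#' drift (no `2.0000000001` artifacts).
#'
#' @param lo,hi grid range (lo < hi).
#' @param step positive increment, smaller than `hi - lo`.
#' @return Strictly ascending numeric vector.
#' @export
#' @examples
#' make_grid(1.5, 3.5, 0.1) # the 21 candidate thresholds 1.5, 1.6, ..., 3.5
make_grid <- function(lo, hi, step) {
  stopifnot(is.finite(lo), is.finite(hi), is.finite(step))
  if (lo >= hi) stop("'lo' must be smaller than 'hi'")
  if (step <= 0) stop("'step' must be positive")
  if (step >= hi - lo) stop("'step' must be smaller than hi - lo")
  k <- floor((hi - lo) / step + 1e-9)
  g <- lo + step * (0:k)
  if (hi - g[length(g)] > step / 2 + 1e-12) g <- c(g, hi)
  round(g, max(.decimals(lo), .decimals(step)))
}

#' Select the optimal threshold from a scan
#'
#' Returns the grid point attaining the extremum of the defined objective
#' values in the scan's direction (max for Fisher, min for mDEDS/TEP).
#' Exact ties are broken to the largest tied threshold: thresholds tied
#' because they induce the identical sample partition differ only in label,
#' and the largest one marks the upper edge of the interval of cut points
#' realizing that partition.
#'
#' @param scan a `threshold_scan` from [scan_thresholds()].
#' @return The selected threshold q0 (cm).
#' @export
optimal_threshold <- function(scan) {
  stopifnot(inherits(scan, "threshold_scan"))
  tab <- scan$table
  ok <- tab$valid & is.finite(tab$objective)
  if (!any(ok)) stop("scan has no defined objective values")
  vals <- tab$objective[ok]
  qs <- tab$q[ok]
  best <- if (scan$direction == "max") max(vals) else min(vals)
  max(qs[vals == best])
}

#' Scan an objective over a threshold grid
#'
#' Evaluates the chosen objective at every grid point with a valid split in
#' all studies; invalid points are flagged and excluded from optimization.
#' For `method = "tep"` the totally extreme point is computed once up front
#' and the same coordinates are shared by every grid point. With identical
#' inputs and seed the scan table is byte-identical across runs.
#'
#' @param collection a [study_collection()].
#' @param grid ascending numeric vector of candidate thresholds (cm).
#' @param method `"fisher"` (maximize the summed Fisher score), `"mdeds"` or
#'   `"tep"` (minimize the summed distance).
#' @param min_group minimum per-group sample count for a valid split.
#' @param stat_names statistics used by the distance-based methods.
#' @param B number of permutations per (study, threshold) for `mdeds`/`tep`.
#' @param seed base integer seed for permutation draws.
#' @param fold fold signed statistics?
#' @return Object of class `threshold_scan`: list with `table` (data.frame
#'   with q, objective, valid, and per-study group sizes), `method`,
#'   `direction`, `q0`, `grid`, `e_max` (TEP only) and the configuration.
#' @export
scan_thresholds <- function(collection, grid,
                            method = c("fisher", "mdeds", "tep"),
                            min_group = 3L, stat_names = deds_stats(),
                            B = 200L, seed = 1L, fold = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(collection, "study_collection"), length(grid) >= 1,
            !is.unsorted(grid, strictly = TRUE))
  K <- length(collection$studies)
  ids <- names(collection$studies)
  nq <- length(grid)
  obj <- rep(NA_real_, nq)
  valid <- logical(nq)
  gsz <- matrix(NA_integer_, nq, 2 * K,
                dimnames = list(NULL, c(paste0("n_small_", ids), paste0("n_large_", ids))))

  splits <- lapply(seq_len(nq), function(iq)
    lapply(collection$studies, split_by_threshold, q = grid[iq], min_group = min_group))
  for (iq in seq_len(nq)) {
    ns <- vapply(splits[[iq]], `[[`, numeric(1), "n_small")
    nl <- vapply(splits[[iq]], `[[`, numeric(1), "n_large")
    gsz[iq, ] <- as.integer(c(ns, nl))
    valid[iq] <- all(vapply(splits[[iq]], `[[`, logical(1), "valid"))
  }

  e_max <- NULL
  if (method == "fisher") {
    rank_infos <- lapply(collection$studies, function(s) .wmw_rank_info(s$expression))
    for (iq in which(valid)) {
      pm <- .pvalue_matrix(collection, grid[iq], min_group, rank_infos)
      obj[iq] <- sum(-2 * log(pmax(pm, .P_FLOOR)))
    }
    direction <- "max"
  } else {
    # one pass over (q, study): observed statistics, MAD scales, E_q
    summ <- vector("list", nq)
    for (iq in which(valid)) {
      summ[[iq]] <- lapply(collection$studies, .study_summary, q = grid[iq],
                           min_group = min_group, stat_names = stat_names,
                           B = B, base_seed = seed, fold = fold)
    }
    if (method == "mdeds") {
      for (iq in which(valid))
        obj[iq] <- sum(vapply(summ[[iq]], function(s)
          sum(.deds_dist(s$stats, s$Eq, s$mads)), numeric(1)))
    } else {
      eq_all <- unlist(lapply(summ[which(valid)], function(byst)
        lapply(byst, `[[`, "Eq")), recursive = FALSE)
      coords <- Reduce(pmax, eq_all)
      e_max <- extreme_point(coords, summ[[which(valid)[1]]][[1]]$stat_names, "tep")
      for (iq in which(valid))
        obj[iq] <- sum(vapply(summ[[iq]], function(s)
          sum(.deds_dist(s$stats, e_max$coords, s$mads)), numeric(1)))
    }
    direction <- "min"
  }

  tab <- data.frame(q = grid, objective = obj, valid = valid)
  tab <- cbind(tab, as.data.frame(gsz))
  scan <- structure(
    list(table = tab, method = method, direction = direction, grid = grid,
         q0 = NA_real_, e_max = e_max,
         config = list(min_group = min_group, stat_names = stat_names,
                       B = as.integer(B), seed = as.integer(seed), fold = fold)),
    class = "threshold_scan"
  )
  scan$q0 <- optimal_threshold(scan)
  scan
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan: %s> %d grid points in [%g, %g], %d valid\n",
              x$method, nrow(x$table), min(x$grid), max(x$grid),
              sum(x$table$valid)))
  cat(sprintf("  q0 = %g cm (%simum objective %s)\n", x$q0,
              substr(x$direction, 1, 3),
              format(x$table$objective[match(x$q0, x$table$q)])))
  invisible(x)
}

#' Refine a scan around its optimum
#'
#' Rescans the window `[q0 - half_width, q0 + half_width]` at a finer step
#' with the same method and configuration as the coarse scan.
#'
#' @param collection a [study_collection()].
#' @param coarse a `threshold_scan` whose `q0` is defined.
#' @param half_width half-width of the refinement window (cm).
#' @param step fine step, smaller than `2 * half_width`.
#' @return A new `threshold_scan` over the fine grid.
#' @export
refine_scan <- function(collection, coarse, half_width, step) {
  stopifnot(inherits(coarse, "threshold_scan"), is.finite(coarse$q0))
  if (step >= 2 * half_width) stop("'step' must be smaller than 2 * half_width")
  grid <- make_grid(coarse$q0 - half_width, coarse$q0 + half_width, step)
  cf <- coarse$config
  scan_thresholds(collection, grid, method = coarse$method,
                  min_group = cf$min_group, stat_names = cf$stat_names,
                  B = cf$B, seed = cf$seed, fold = cf$fold)
}

#' Write a scan table to a tab-delimited file
#'
#' One row per grid point (q, objective, valid flag, per-study group sizes),
#' preceded by comment lines recording the method, configuration and q0; for
#' TEP scans the shared extreme-point coordinates are included.
#'
#' @param scan a `threshold_scan`.
#' @param path output path.
#' @return `scan`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "threshold_scan"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# method=%s direction=%s q0=%g B=%d seed=%d",
                     scan$method, scan$direction, scan$q0,
                     scan$config$B, scan$config$seed), con)
  if (!is.null(scan$e_max))
    writeLines(sprintf("# e_max %s", paste(scan$e_max$stat_names, "=",
                                           format(scan$e_max$coords),
                                           collapse = " ")), con)
  utils::write.table(scan$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(scan)
}
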