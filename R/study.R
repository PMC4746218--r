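#' Construct an expression study
#'
#' Bundles a features x samples expression matrix with per-sample tumor sizes.
#' The matrix may hold log-scale or raw intensities; downstream statistics are
#' scale-agnostic. Missing or non-finite expression values are not supported.
#'
#' @param expression numeric matrix, features in rows, samples in columns.
#'   Row and column names are used as feature/sample identifiers unless
#'   `feature_ids` / `sample_ids` are given.
#' @param sizes numeric vector of tumor sizes in cm, one per sample (matrix
#'   column order), strictly positive and finite.
#' @param study_id single string identifying the study.
#' @param feature_ids,sample_ids optional character vectors overriding the
#'   matrix dimnames.
#' @return An object of class `expression_study`: a list with elements
#'   `expression`, `sizes` (named by sample), `feature_ids`, `sample_ids`,
#'   `study_id`.
#' @export
#' @examples
#' x <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' expression_study(x, sizes = c(1.4, 3.2), study_id = "demo")
expression_study <- function(expression, sizes, study_id,
                             feature_ids = rownames(expression),
                             sample_ids = colnames(expression)) {
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("'expression' must be a numeric matrix")
  if (is.null(feature_ids)) stop("feature identifiers are required (rownames or 'feature_ids')")
  if (is.null(sample_ids)) stop("sample identifiers are required (colnames or 'sample_ids')")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(expression))
    stop("length of 'feature_ids' must equal nrow(expression)")
  if (length(sample_ids) != ncol(expression))
    stop("length of 'sample_ids' must equal ncol(expression)")
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop(sprintf("duplicate feature id(s): %s", paste(unique(dup), collapse = ", ")))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  if (!all(is.finite(expression)))
    stop("expression matrix contains missing or non-finite values; complete matrices are required")
  sizes <- as.numeric(sizes)
  if (length(sizes) != ncol(expression))
    stop("length of 'sizes' must equal the number of samples")
  if (!all(is.finite(sizes) & sizes > 0))
    stop("'sizes' must be strictly positive and finite (cm)")
  dimnames(expression) <- list(feature_ids, sample_ids)
  names(sizes) <- sample_ids
  structure(
    list(expression = expression, sizes = sizes,
         feature_ids = feature_ids, sample_ids = sample_ids,
         study_id = as.character(study_id)[1]),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study '%s'> %d features x %d samples; sizes %.2f-%.2f cm\n",
              x$study_id, nrow(x$expression), ncol(x$expression),
              min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Read an expression study from tab-delimited files
#'
#' The matrix file is tab-delimited with a header row of sample identifiers
#' and a first column of feature identifiers. The sizes file is a two-column
#' tab-delimited table (`sample_id`, `size_cm`) with a header row; sizes are
#' reordered to the matrix column order. Samples present in the matrix but
#' absent from the sizes table are an error.
#'
#' @param matrix_path path to the expression matrix file.
#' @param sizes_path path to the sizes file.
#' @param study_id study identifier for the returned object.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(matrix_path, sizes_path, study_id) {
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file must have a feature-id column plus at least one sample column")
  feature_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  expr <- matrix(NA_real_, nrow(raw), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed numeric value '%s' at feature '%s', sample '%s'",
                   col[bad[1]], feature_ids[bad[1]], sample_ids[j]))
    expr[, j] <- v
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop(sprintf("duplicate feature id(s) in matrix file: %s",
                 paste(unique(dup), collapse = ", ")))
  st <- read.delim(sizes_path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(st) < 2) stop("sizes file must have two columns: sample_id, size_cm")
  size_map <- suppressWarnings(as.numeric(st[[2]]))
  names(size_map) <- as.character(st[[1]])
  missing <- setdiff(sample_ids, names(size_map))
  if (length(missing))
    stop(sprintf("sizes file is missing sample(s): %s", paste(missing, collapse = ", ")))
  expression_study(expr, sizes = unname(size_map[sample_ids]), study_id = study_id,
                   feature_ids = feature_ids, sample_ids = sample_ids)
}

#' Write an expression study to tab-delimited files
#'
#' Writes the same dialect [read_expression_study()] reads. Numbers are
#' printed with 17 significant digits so a round trip reproduces the matrix
#' bit-exactly.
#'
#' @param study an [expression_study()].
#' @param matrix_path,sizes_path output paths.
#' @return `study`, invisibly.
#' @export
write_expression_study <- function(study, matrix_path, sizes_path) {
  stopifnot(inherits(study, "expression_study"))
  con <- file(matrix_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("feature_id", study$sample_ids), collapse = "\t"), con)
  body <- apply(study$expression, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(study$feature_ids, body, sep = "\t"), con)
  con2 <- file(sizes_path, "w")
  on.exit(close(con2), add = TRUE)
  writeLines(c("sample_id\tsize_cm",
               paste(study$sample_ids, sprintf("%.17g", unname(study$sizes)), sep = "\t")),
             con2)
  invisible(study)
}

#' Construct a study collection
#'
#' A collection holds K >= 1 studies sharing an identical, identically ordered
#' feature list — the unit of meta-analysis. Use [match_features()] to build
#' one from studies with differing feature sets.
#'
#' @param studies list of [expression_study()] objects.
#' @return An object of class `study_collection` with elements `studies` and
#'   `feature_ids`.
#' @export
study_collection <- function(studies) {
  if (!length(studies)) stop("a collection needs at least one study")
  if (!all(vapply(studies, inherits, logical(1), "expression_study")))
    stop("all elements must be expression_study objects")
  ids <- studies[[1]]$feature_ids
  for (s in studies[-1])
    if (!identical(s$feature_ids, ids))
      stop("all studies must share identical, identically ordered feature ids; see match_features()")
  names(studies) <- vapply(studies, `[[`, character(1), "study_id")
  structure(list(studies = studies, feature_ids = ids), class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("<study_collection> K = %d studies, %d matched features\n",
              length(x$studies), length(x$feature_ids)))
  for (s in x$studies) print(s)
  invisible(x)
}

#' Match features across studies
#'
#' Restricts every study to the intersection of feature identifiers and
#' reorders rows to a canonical (lexicographic, C-locale) order identical
#' across studies, so gene indices align for meta-analysis.
#'
#' @param studies list of [expression_study()] objects (or a single study).
#' @return A [study_collection()].
#' @export
match_features <- function(studies) {
  if (inherits(studies, "expression_study")) studies <- list(studies)
  if (!length(studies)) stop("need at least one study")
  common <- Reduce(intersect, lapply(studies, `[[`, "feature_ids"))
  if (!length(common)) stop("no features are shared by all studies")
  ord <- sort(common, method = "radix")
  matched <- lapply(studies, function(s) {
    expression_study(s$expression[match(ord, s$feature_ids), , drop = FALSE],
                     sizes = unname(s$sizes), study_id = s$study_id,
                     feature_ids = ord, sample_ids = s$sample_ids)
  })
  study_collection(matched)
}

#' Split a study's samples at a size threshold
#'
#' Samples with size less than or equal to `q` form the "small" group (the
#' clinical T1-style convention where a tumor exactly at the cut point is the
#' lower category). A split whose smaller group falls below `min_group` is
#' flagged invalid rather than raising an error, so threshold scans can skip
#' it.
#'
#' @param study an [expression_study()].
#' @param q threshold in cm (finite).
#' @param min_group minimum per-group sample count for a valid split
#'   (default 3, the smallest group giving a non-degenerate rank test).
#' @return An object of class `group_split`: list with `threshold_q`,
#'   `small_mask` (logical, named by sample), `n_small`, `n_large`, `valid`.
#' @export
#' @examples
#' s <- expression_study(matrix(rnorm(8), 2, 4,
#'        dimnames = list(c("a", "b"), paste0("s", 1:4))),
#'        sizes = c(1, 2, 3, 4), study_id = "demo")
#' split_by_threshold(s, 2.5)
split_by_threshold <- function(study, q, min_group = 3L) {
  stopifnot(inherits(study, "expression_study"), is.finite(q), min_group >= 2)
  mask <- study$sizes <= q
  n_small <- sum(mask)
  n_large <- sum(!mask)
  structure(
    list(threshold_q = q, small_mask = mask,
         n_small = n_small, n_large = n_large,
         valid = min(n_small, n_large) >= min_group),
    class = "group_split"
  )
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("<group_split> q = %g cm: n_small = %d, n_large = %d (%s)\n",
              x$threshold_q, x$n_small, x$n_large,
              if (x$valid) "valid" else "invalid"))
  invisible(x)
}
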