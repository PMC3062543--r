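#' Clotting-time prolongation ratio
#'
#' A compound's effect in a clotting assay (aPTT, PT or TT) is expressed as the
#' relative prolongation of the clot time over the vehicle control:
#' `(t_sample - t_control) / t_control`. Zero means no effect; positive values
#' mean anticoagulant prolongation; values below -1 are impossible since clot
#' times are positive.
#'
#' @param t_sample clot time with the compound (seconds); vectorized.
#' @param t_control vehicle-control clot time (seconds, > 0).
#' @return Dimensionless ratio(s).
#' @examples
#' delta_ratio(45, 30)  # 0.5
#' @export
delta_ratio <- function(t_sample, t_control) {
  if (any(!is.finite(t_control)) || any(t_control <= 0)) {
    stop("`t_control` must be finite and > 0")
  }
  (t_sample - t_control) / t_control
}

#' Assay records
#'
#' Builds per-compound clotting-assay records from the three prolongation
#' ratios. The overall activity of a compound is the sum of its aPTT, PT and TT
#' ratios: the three assays probe the intrinsic, extrinsic and final common
#' pathway respectively, so their sum is taken to represent the compound's
#' whole-cascade effect. Rows with a missing ratio are dropped with a message
#' (a blank cell is unknown, not zero).
#'
#' @param x a data frame with columns `compound`, `delta_aptt`, `delta_pt`,
#'   `delta_tt`, or raw long format `compound`, `assay` (one of
#'   `"aptt"`, `"pt"`, `"tt"`), `t_sample`, `t_control` from which ratios are
#'   computed via [delta_ratio()].
#' @param path for `read_assays()`, a CSV/TSV file in either layout.
#' @return A data frame of class `assay_records` with columns `compound`,
#'   `delta_aptt`, `delta_pt`, `delta_tt`, `activity_sum`.
#' @export
assay_records <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (all(c("compound", "assay", "t_sample", "t_control") %in% names(x))) {
    x$assay <- tolower(x$assay)
    bad <- setdiff(unique(x$assay), c("aptt", "pt", "tt"))
    if (length(bad)) stop("unknown assay name(s): ", paste(bad, collapse = ", "))
    x$ratio <- delta_ratio(x$t_sample, x$t_control)
    wide <- stats::reshape(x[, c("compound", "assay", "ratio")],
                           idvar = "compound", timevar = "assay",
                           direction = "wide")
    names(wide) <- sub("^ratio\\.", "delta_", names(wide))
    x <- wide
  }
  need <- c("compound", "delta_aptt", "delta_pt", "delta_tt")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x <- x[, union(need, names(x)), drop = FALSE]
  complete <- stats::complete.cases(x[, need[-1L]])
  if (any(!complete)) {
    message(sum(!complete), " record(s) with missing ratios dropped")
    x <- x[complete, , drop = FALSE]
  }
  if (any(x[, need[-1L]] < -1)) stop("prolongation ratios below -1 are impossible")
  x$activity_sum <- x$delta_aptt + x$delta_pt + x$delta_tt
  rownames(x) <- NULL
  structure(x, class = c("assay_records", "data.frame"))
}

#' @rdname assay_records
#' @export
read_assays <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "#")
  assay_records(df)
}

#' Whole-cascade activity of an assay record
#'
#' @param record an [assay_records()] data frame (or any data frame with the
#'   three ratio columns).
#' @return Numeric vector of per-compound activity sums.
#' @export
activity_sum <- function(record) {
  need <- c("delta_aptt", "delta_pt", "delta_tt")
  miss <- setdiff(need, names(record))
  if (length(miss)) stop("missing ratio column(s): ", paste(miss, collapse = ", "))
  if (anyNA(record[, need])) stop("missing ratio value(s)")
  record$delta_aptt + record$delta_pt + record$delta_tt
}

#' Published clotting-assay reference table
#'
#' The fourteen experimentally assayed compounds (seven natural products,
#' L-glutamine, and six argatroban intermediates) with their published aPTT,
#' PT and TT prolongation ratios, the published activity sum, and the published
#' network-efficiency decrease computed by the original study from its
#' (unpublished) multi-target docking scores. These NE decreases are reference
#' data for validation; they cannot be recomputed ab initio without the
#' original docking runs.
#'
#' Note the published component ratios and sum column were rounded
#' independently to three decimals: for five of the fourteen rows the components
#' re-sum to within 0.001 of, but not exactly to, the printed sum.
#'
#' @return A data frame with columns `compound`, `delta_aptt`, `delta_pt`,
#'   `delta_tt`, `published_sum`, `ne_decrease`.
#' @examples
#' tab <- table1_assays()
#' cor(tab$published_sum, tab$ne_decrease)
#' @export
table1_assays <- function() {
  path <- system.file("extdata", "table1_assays.tsv", package = "cascadeNE",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
}

#' Pearson product-moment correlation
#'
#' Thin, precondition-checked wrapper around [stats::cor()] used by
#' [validate_estimates()]: both series must have the same length (at least 3)
#' and non-zero variance.
#'
#' @param x,y numeric series.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in series")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in a series")
  stats::cor(x, y, method = "pearson")
}

#' Validate NE-decrease estimates against assay activities
#'
#' Joins per-compound network-efficiency decreases with experimental
#' whole-cascade activities (sum of aPTT/PT/TT prolongation ratios) on compound
#' identifier and reports their Pearson correlation. Unmatched compounds on
#' either side are reported via `message()` and excluded.
#'
#' @param estimates an [estimate_compounds()] result, or a data frame with
#'   columns `compound` and `ne_decrease`.
#' @param assays an [assay_records()] data frame (or any data frame with
#'   `compound` and `activity_sum`).
#' @return An object of class `ne_validation`: list with `n`, `pearson_r`, and
#'   `pairs` (data frame `compound`, `activity_sum`, `ne_decrease`).
#' @export
validate_estimates <- function(estimates, assays) {
  if (inherits(estimates, "ne_estimate")) estimates <- estimates$estimates
  estimates <- as.data.frame(estimates)
  assays <- as.data.frame(assays)
  stopifnot(all(c("compound", "ne_decrease") %in% names(estimates)))
  if (!"activity_sum" %in% names(assays)) assays <- assay_records(assays)
  pairs <- merge(assays[, c("compound", "activity_sum")],
                 estimates[, c("compound", "ne_decrease")], by = "compound")
  lost <- setdiff(union(estimates$compound, assays$compound), pairs$compound)
  if (length(lost)) {
    message("unmatched compound(s) excluded: ", paste(lost, collapse = ", "))
  }
  if (nrow(pairs) < 3L) {
    stop("fewer than 3 compounds in common between estimates and assays")
  }
  pairs <- pairs[order(pairs$compound), , drop = FALSE]
  rownames(pairs) <- NULL
  r <- pearson_correlation(pairs$activity_sum, pairs$ne_decrease)
  structure(list(n = nrow(pairs), pearson_r = r, pairs = pairs),
            class = "ne_validation")
}

#' @export
print.ne_validation <- function(x, ...) {
  cat(sprintf("validation: n = %d compounds, Pearson r = %.3f\n",
              x$n, x$pearson_r))
  invisible(x)
}

#' @export
plot.ne_validation <- function(x, ...) {
  graphics::plot(x$pairs$ne_decrease, x$pairs$activity_sum,
                 xlab = "NE decrease", ylab = "activity sum (aPTT+PT+TT)",
                 pch = 19, ...)
  graphics::abline(stats::lm(activity_sum ~ ne_decrease, data = x$pairs),
                   lty = 2)
  invisible(x)
}

#' Single-target comparison of docking scores with assay activity
#'
#' The single-target counterpart of [validate_estimates()]: correlates the
#' magnitude of compounds' binding energies against one chosen target with
#' their whole-cascade assay activity. Used to contrast the multi-target
#' network estimate with what a conventional one-target docking ranking would
#' give.
#'
#' @param table a [docking_scores()] table.
#' @param assays an [assay_records()] data frame.
#' @param target the target identifier to score against.
#' @return An `ne_validation` object (pairs hold `|binding_energy|` in the
#'   `ne_decrease` column, named `score` as well).
#' @export
validate_single_target <- function(table, assays, target) {
  stopifnot(inherits(table, "docking_scores"))
  rows <- table[table$target == target, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no scores for target: ", target)
  est <- data.frame(compound = rows$compound,
                    ne_decrease = abs(rows$binding_energy))
  out <- validate_estimates(est, assays)
  out$target <- target
  out
}
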