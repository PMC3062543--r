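#' Estimate compound activities by network-efficiency decrease
#'
#' The central estimator of the package. For each compound, the network is
#' reweighted from that compound's docking scores ([reweight_network()]), the
#' network efficiency is recomputed, and the compound is scored by the
#' *decrease* of efficiency relative to the intact network. The larger the
#' decrease, the more strongly the compound is predicted to shut down the
#' cascade -- for the clotting network, the more potent an anticoagulant it is
#' estimated to be. Compounds are ranked by decreasing `ne_decrease`, ties
#' broken by compound identifier.
#'
#' @param net a [pathway_network()] with baseline line values.
#' @param table a [docking_scores()] table.
#' @param compounds optional subset of compound identifiers (default: all in
#'   `table`).
#' @param refs optional fixed [reference_energies()]; by default per-target
#'   references are computed from `table`, i.e. within the analyzed compound
#'   set.
#' @param exponent_factor,lv_floor passed to [line_value()].
#' @return An object of class `ne_estimate`: a list with elements
#'   \describe{
#'     \item{estimates}{data frame `compound`, `ne_after`, `ne_decrease`,
#'       `rank`, ordered by rank}
#'     \item{baseline_ne}{efficiency of the intact network}
#'     \item{call}{the matched call}
#'   }
#'   with `print()`, `summary()`, `coef()` (named `ne_decrease` vector) and
#'   `plot()` methods.
#' @examples
#' net <- clotting_cascade()
#' sc <- docking_scores(data.frame(
#'   compound = c("c1", "c1", "c2"),
#'   target = c("thrombin", "factor_xa", "thrombin"),
#'   binding_energy = c(-9, -8, -4)))
#' est <- estimate_compounds(net, sc)
#' est
#' @export
estimate_compounds <- function(net, table, compounds = NULL, refs = NULL,
                               exponent_factor = 2.3, lv_floor = 10) {
  stopifnot(inherits(net, "pathway_network"),
            inherits(table, "docking_scores"))
  baseline <- network_efficiency(net)
  if (is.null(refs)) refs <- reference_energies(table)
  if (is.null(compounds)) compounds <- sort(unique(table$compound))
  unknown <- setdiff(compounds, table$compound)
  if (length(unknown)) {
    stop("compound(s) not in score table: ", paste(unknown, collapse = ", "))
  }
  ne_after <- vapply(compounds, function(cp) {
    rows <- table[table$compound == cp, , drop = FALSE]
    if (!any(rows$target %in% net$nodes)) {
      warning("compound ", cp, " has no scored target in the network; ",
              "ne_decrease = 0")
      return(baseline)
    }
    rw <- reweight_network(net, table, cp, refs = refs,
                           exponent_factor = exponent_factor,
                           lv_floor = lv_floor)
    network_efficiency(rw)
  }, numeric(1))
  est <- data.frame(compound = as.character(compounds), ne_after = ne_after,
                    ne_decrease = baseline - ne_after)
  est <- est[order(-est$ne_decrease, est$compound), , drop = FALSE]
  est$rank <- seq_len(nrow(est))
  rownames(est) <- NULL
  structure(list(estimates = est, baseline_ne = baseline,
                 call = match.call()),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, n = 10L, ...) {
  cat(sprintf("Network-efficiency estimates for %d compounds (baseline NE = %.3f)\n",
              nrow(x$estimates), x$baseline_ne))
  print.data.frame(utils::head(x$estimates, n), row.names = FALSE,
                   digits = 4, ...)
  if (nrow(x$estimates) > n) {
    cat("... (", nrow(x$estimates) - n, " more)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.ne_estimate <- function(object, ...) {
  est <- object$estimates
  cat(sprintf("Baseline NE: %.3f\n", object$baseline_ne))
  cat(sprintf("Compounds:   %d\n", nrow(est)))
  cat(sprintf("NE decrease: min %.3f, median %.3f, max %.3f\n",
              min(est$ne_decrease), stats::median(est$ne_decrease),
              max(est$ne_decrease)))
  cat(sprintf("Top compound: %s (decrease %.3f, relative NE %.1f%%)\n",
              est$compound[1L], est$ne_decrease[1L],
              relative_efficiency(est$ne_after[1L], object$baseline_ne)))
  invisible(object)
}

#' @export
coef.ne_estimate <- function(object, ...) {
  stats::setNames(object$estimates$ne_decrease, object$estimates$compound)
}

#' @export
plot.ne_estimate <- function(x, ...) {
  est <- x$estimates
  op <- graphics::par(mar = c(8, 4, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(est$ne_decrease, names.arg = est$compound, las = 2,
                    ylab = "NE decrease", cex.names = 0.7, ...)
  invisible(x)
}

#' Two-stage hierarchical screening
#'
#' Mirrors a dual-step virtual-screening protocol in which a fast docking
#' stage scores the whole library, the top fraction of compounds (by
#' network-efficiency decrease) is carried forward, and a slower, more accurate
#' stage re-scores and re-ranks the survivors. Per-target reference energies
#' are recomputed within each stage, since each docking program has its own
#' energy scale.
#'
#' @param net a [pathway_network()].
#' @param stage1,stage2 [docking_scores()] tables for the two stages; `stage2`
#'   must cover every survivor of stage 1.
#' @param keep_fraction fraction of compounds carried forward
#'   (default 0.10); `ceiling(keep_fraction * n)` compounds survive, so at
#'   least one always does.
#' @param ... passed to [estimate_compounds()] (e.g. `lv_floor`).
#' @return An object of class `ne_screen`: list with `stage1` and `stage2`
#'   [estimate_compounds()] results, `survivors` (character) and
#'   `keep_fraction`.
#' @export
hierarchical_screen <- function(net, stage1, stage2, keep_fraction = 0.10,
                                ...) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  e1 <- estimate_compounds(net, stage1, ...)
  n <- nrow(e1$estimates)
  n_keep <- ceiling(keep_fraction * n)
  survivors <- e1$estimates$compound[seq_len(n_keep)]
  missing <- setdiff(survivors, stage2$compound)
  if (length(missing)) {
    stop("stage-2 scores missing for survivor(s): ",
         paste(missing, collapse = ", "))
  }
  e2 <- estimate_compounds(net, stage2, compounds = survivors, ...)
  structure(list(stage1 = e1, stage2 = e2, survivors = survivors,
                 keep_fraction = keep_fraction),
            class = "ne_screen")
}

#' @export
print.ne_screen <- function(x, ...) {
  cat(sprintf("Hierarchical screen: %d compounds -> kept %d (%.0f%%)\n",
              nrow(x$stage1$estimates), length(x$survivors),
              100 * x$keep_fraction))
  cat("Stage-2 ranking of survivors:\n")
  print.data.frame(x$stage2$estimates, row.names = FALSE, digits = 4, ...)
  invisible(x)
}

#' Drug-target network
#'
#' Builds the bipartite compound-target network in which a compound is linked
#' to a target when it forms a "strong" predicted interaction, i.e. when the
#' magnitude of its binding energy reaches `threshold`. There is no canonical
#' threshold; it must be supplied explicitly.
#'
#' @param table a [docking_scores()] table.
#' @param threshold strong-interaction threshold on `|binding_energy|`
#'   (kcal/mol, > 0); required.
#' @return An object of class `drug_target_network`: a data frame of bipartite
#'   edges (`compound`, `target`, `binding_energy`) with per-compound degrees
#'   in `attr(x, "degree")` (named vector over all compounds in `table`,
#'   including zero-degree ones).
#' @examples
#' sc <- docking_scores(data.frame(compound = c("c1", "c1", "c2"),
#'                                 target = c("t1", "t2", "t1"),
#'                                 binding_energy = c(-9, -5, -2)))
#' dtn <- drug_target_network(sc, threshold = 4)
#' attr(dtn, "degree")
#' @export
drug_target_network <- function(table, threshold) {
  stopifnot(inherits(table, "docking_scores"))
  if (missing(threshold) || !is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` (kcal/mol magnitude, > 0) must be given explicitly")
  }
  strong <- abs(table$binding_energy) >= threshold
  edges <- table[strong, c("compound", "target", "binding_energy"),
                 drop = FALSE]
  edges <- edges[order(edges$compound, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  all_compounds <- sort(unique(table$compound))
  deg <- vapply(all_compounds,
                function(cp) sum(edges$compound == cp), integer(1))
  structure(edges, degree = deg, threshold = threshold,
            class = c("drug_target_network", "data.frame"))
}

#' @export
print.drug_target_network <- function(x, ...) {
  deg <- attr(x, "degree")
  cat(sprintf("drug-target network: %d edges, |BE| >= %g kcal/mol\n",
              nrow(x), attr(x, "threshold")))
  cat("compound degrees:\n")
  print(deg)
  invisible(x)
}
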