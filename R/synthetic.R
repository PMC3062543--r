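# Seed handling: generators set the RNG locally and restore the caller's
# .Random.seed on exit, so simulation code can call them without side effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Specification for synthetic cascade data
#'
#' Bundles the knobs of the synthetic generators. The defaults emulate the
#' study conditions of the clotting-cascade analysis: a 41-node cascade with
#' about 53 edges (density 53 of 820 possible ordered pairs), 14 docking
#' targets, 14 assayed compounds, a planted potency gradient spanning the
#' realistic docking range -12 to -5 kcal/mol, and 0.5 kcal/mol Gaussian
#' docking noise.
#'
#' @param n_nodes number of cascade nodes.
#' @param edge_density fraction of the `n*(n-1)/2` possible forward pairs that
#'   carry an edge (in (0, 1]).
#' @param n_compounds number of synthetic compounds.
#' @param n_targets number of docking targets (`<= n_nodes`); defaults to 14
#'   or `n_nodes`, whichever is smaller.
#' @param potency_gradient ordered per-compound mean binding energies
#'   (kcal/mol); compound `k` is planted at `potency_gradient[k]`, most potent
#'   first.
#' @param noise_sd Gaussian noise on binding energies (kcal/mol, >= 0).
#' @param seed integer seed; all generators are deterministic given the spec.
#' @param allow_feedback if `TRUE`, [generate_cascade()] adds a few backward
#'   (feedback) edges, mimicking the amplification loops of the real cascade;
#'   the default is a pure feed-forward DAG.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 41, edge_density = 53 / 820,
                           n_compounds = 14, n_targets = min(14, n_nodes),
                           potency_gradient = seq(-12, -5,
                                                  length.out = n_compounds),
                           noise_sd = 0.5, seed = 1, allow_feedback = FALSE) {
  stopifnot(n_nodes >= 2, edge_density > 0, edge_density <= 1,
            n_targets <= n_nodes, n_targets >= 1, n_compounds >= 1,
            noise_sd >= 0, length(potency_gradient) == n_compounds)
  structure(list(n_nodes = n_nodes, edge_density = edge_density,
                 n_compounds = n_compounds, n_targets = n_targets,
                 potency_gradient = potency_gradient, noise_sd = noise_sd,
                 seed = as.integer(seed), allow_feedback = allow_feedback),
            class = "synthetic_spec")
}

#' Generate a random cascade network
#'
#' Draws a weakly connected, feed-forward (acyclic) directed cascade: nodes are
#' placed in topological order, each node after the first receives an edge from
#' a random earlier node (guaranteeing weak connectivity), and extra forward
#' edges are added until the density target is met. All line values are the
#' baseline 10. With `allow_feedback = TRUE` roughly 5% of the edges are
#' redirected backwards to create amplification loops.
#'
#' @param spec a [synthetic_spec()].
#' @return A [pathway_network()]; node names are `"n01"`, `"n02"`, ...
#' @examples
#' net <- generate_cascade(synthetic_spec(n_nodes = 10, seed = 7))
#' @export
generate_cascade <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  n_edges <- max(n - 1L, round(spec$edge_density * n * (n - 1) / 2))
  if (n_edges > n * (n - 1) / 2) {
    stop("edge_density too high for an acyclic cascade")
  }
  with_seed(spec$seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    src <- integer(0); tgt <- integer(0)
    for (i in 2:n) {                       # spanning backbone
      src <- c(src, sample.int(i - 1L, 1L)); tgt <- c(tgt, i)
    }
    # candidate forward pairs not yet used
    all_pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    used <- paste(src, tgt)
    avail <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% used, ,
                       drop = FALSE]
    extra <- n_edges - length(src)
    if (extra > 0) {
      pick <- avail[sample.int(nrow(avail), min(extra, nrow(avail))), ,
                    drop = FALSE]
      src <- c(src, pick[, 1]); tgt <- c(tgt, pick[, 2])
    }
    if (spec$allow_feedback && length(src) >= 20L) {
      flip <- sample(seq_along(src), max(1L, round(0.05 * length(src))))
      # reverse a few non-backbone edges to create loops
      flip <- flip[flip > n - 1L]
      if (length(flip)) {
        tmp <- src[flip]; src[flip] <- tgt[flip]; tgt[flip] <- tmp
      }
    }
    edges <- unique(data.frame(source = nodes[src], target = nodes[tgt],
                               line_value = 10))
    pathway_network(edges, nodes = nodes)
  })
}

#' Generate a docking-score table with a planted potency gradient
#'
#' Selects `n_targets` target nodes (preferring nodes with out-edges, so that
#' scores can actually perturb the network) and draws compound `k`'s binding
#' energy against each target as `potency_gradient[k] + N(0, noise_sd)`,
#' clamped to be non-positive. At `noise_sd = 0` every compound is uniformly
#' ordered across targets, so the planted potency order is exactly recoverable
#' from the network-efficiency decrease ranking.
#'
#' @param spec a [synthetic_spec()].
#' @param net a [pathway_network()] generated from (or compatible with) `spec`.
#' @return A [docking_scores()] table; compound ids `"cmpd01"`, ... in planted
#'   potency order (most potent first). The chosen targets are in
#'   `attr(x, "targets")`.
#' @export
generate_scores <- function(spec, net) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(net, "pathway_network"))
  with_seed(spec$seed + 1L, {
    out_deg <- table(factor(net$edges$source, levels = net$nodes))
    cand <- names(out_deg)[out_deg > 0]
    if (length(cand) < spec$n_targets) cand <- net$nodes
    targets <- sort(sample(cand, spec$n_targets))
    compounds <- sprintf("cmpd%02d", seq_len(spec$n_compounds))
    grid <- expand.grid(compound = compounds, target = targets,
                        stringsAsFactors = FALSE)
    mu <- spec$potency_gradient[match(grid$compound, compounds)]
    be <- mu + stats::rnorm(nrow(grid), 0, spec$noise_sd)
    grid$binding_energy <- pmin(be, 0)
    tab <- docking_scores(grid)
    attr(tab, "targets") <- targets
    tab
  })
}

#' Generate matched synthetic assay records
#'
#' Links assay activity to docking strength: a compound's activity sum is
#' `link_strength * mean(|binding_energy|)` over its targets, plus Gaussian
#' noise (clamped at 0), split into three non-negative aPTT/PT/TT components
#' that sum exactly to it. With `link_strength = 0` activity is pure noise,
#' giving a null dataset.
#'
#' @param table a [docking_scores()] table.
#' @param link_strength non-negative coupling between mean docking strength
#'   and activity.
#' @param noise_sd Gaussian noise on the activity sum.
#' @param seed integer seed.
#' @return An [assay_records()] data frame.
#' @export
generate_assays <- function(table, link_strength = 1, noise_sd = 0,
                            seed = 1) {
  stopifnot(inherits(table, "docking_scores"), link_strength >= 0,
            noise_sd >= 0)
  with_seed(seed, {
    sp <- split(abs(table$binding_energy), table$compound)
    compounds <- names(sp)
    act <- link_strength * vapply(sp, mean, numeric(1)) +
      stats::rnorm(length(sp), 0, noise_sd)
    act <- pmax(act, 0)
    w <- matrix(stats::runif(3 * length(act)), ncol = 3)
    w <- w / rowSums(w)
    comp <- w * act
    # guarantee exact decomposition: last component absorbs rounding
    comp[, 3] <- act - comp[, 1] - comp[, 2]
    assay_records(data.frame(compound = compounds,
                             delta_aptt = comp[, 1],
                             delta_pt = comp[, 2],
                             delta_tt = comp[, 3]))
  })
}
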