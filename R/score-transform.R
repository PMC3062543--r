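#' Build or load a docking-score table
#'
#' A docking-score table holds predicted binding free energies (kcal/mol,
#' negative = favourable) for compound-target pairs. Positive energies are
#' non-binding artefacts and are clamped to 0, so that after loading every
#' stored energy is `<= 0`. Duplicate (compound, target, stage) rows are an
#' error.
#'
#' @param x for `docking_scores()`, a data frame with columns `compound`,
#'   `target`, `binding_energy` and optionally `stage`.
#' @param path for `load_scores()`, a CSV/TSV file with a header naming those
#'   columns (delimiter auto-detected).
#' @param clamp_positive clamp positive energies to 0 (default `TRUE`; the
#'   number clamped is reported via `message()`). If `FALSE`, positive energies
#'   are an error.
#' @return An object of class `docking_scores` (a data frame with columns
#'   `compound`, `target`, `binding_energy`, `stage`).
#' @examples
#' sc <- docking_scores(data.frame(compound = "c1", target = "thrombin",
#'                                 binding_energy = -7.5))
#' @export
docking_scores <- function(x, clamp_positive = TRUE) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("compound", "target", "binding_energy")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(x$stage)) x$stage <- rep("other", nrow(x))
  be <- x$binding_energy
  if (is.character(be)) be <- suppressWarnings(as.numeric(be))
  bad <- which(is.na(be))
  if (length(bad)) stop("non-numeric binding_energy in row ", bad[1L])
  pos <- be > 0
  if (any(pos)) {
    if (!clamp_positive) stop("positive binding energies present")
    message(sum(pos), " positive binding energ",
            if (sum(pos) == 1L) "y" else "ies", " clamped to 0")
    be[pos] <- 0
  }
  x$binding_energy <- be
  x$compound <- as.character(x$compound)
  x$target <- as.character(x$target)
  x$stage <- as.character(x$stage)
  key <- paste(x$compound, x$target, x$stage, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), ][1L, ]
    stop("duplicate score row: (", d$compound, ", ", d$target, ", ",
         d$stage, ")")
  }
  x <- x[, c("compound", "target", "binding_energy", "stage")]
  rownames(x) <- NULL
  structure(x, class = c("docking_scores", "data.frame"))
}

#' @rdname docking_scores
#' @export
load_scores <- function(path, clamp_positive = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "#")
  docking_scores(df, clamp_positive = clamp_positive)
}

#' Per-target reference binding energies
#'
#' For each docking target, the most potent (most negative) binding energy in
#' the table is the reference energy `bes` against which every other compound's
#' energy is scaled by [line_value()]. Targets whose best energy is 0 (no
#' compound binds at all) are flagged degenerate and cannot anchor the line
#' value transformation.
#'
#' @param table a [docking_scores()] table.
#' @return A data frame of class `reference_energies` with columns `target`,
#'   `bes` and `degenerate`.
#' @export
reference_energies <- function(table) {
  stopifnot(inherits(table, "docking_scores"))
  if (nrow(table) == 0L) stop("empty score table")
  sp <- split(table$binding_energy, table$target)
  bes <- vapply(sp, min, numeric(1))
  out <- data.frame(target = names(bes), bes = unname(bes),
                    degenerate = unname(bes) == 0)
  out <- out[order(out$target), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("reference_energies", "data.frame"))
}

#' Transform a binding energy into an edge line value
#'
#' The core reweighting rule of the estimation scheme. A compound whose binding
#' energy to a target equals the target's reference energy (`be == bes`) should
#' lengthen the target's out-edges from the baseline 10 to about 200; the
#' exponent factor 2.3 achieves this because `10^2.3 = 199.53 ~ 200`. In
#' general
#' \deqn{LV = 10^{\,2.3\,|BE| / |BE_s|},}
#' a value between 1 (non-binder) and 199.53 (reference-strength binder),
#' monotone increasing in binding strength. Raw values below the baseline line
#' value would *shorten* edges -- a non-binder strengthening the cascade -- so
#' they are floored at `lv_floor` (default 10, the baseline); set
#' `lv_floor = NULL` to disable the floor.
#'
#' @param be binding energy of the compound (kcal/mol, `<= 0`); vectorized.
#' @param bes reference (most potent) binding energy for the target
#'   (kcal/mol, `< 0`).
#' @param exponent_factor exponent scale; default 2.3.
#' @param lv_floor minimum line value (default 10); `NULL` or 0 disables.
#' @return Positive line value(s).
#' @examples
#' line_value(-9, -9)          # 10^2.3 = 199.53
#' line_value(0, -9)           # floored at the baseline 10
#' line_value(-4.5, -9)        # 10^1.15 = 14.13
#' @export
line_value <- function(be, bes, exponent_factor = 2.3, lv_floor = 10) {
  if (any(bes == 0)) stop("degenerate reference energy (bes = 0)")
  if (any(be > 0)) stop("binding energies must be <= 0 (clamp first)")
  lv <- 10^(exponent_factor * abs(be) / abs(bes))
  if (!is.null(lv_floor) && lv_floor > 0) lv <- pmax(lv, lv_floor)
  lv
}

#' Reweight a network for one compound
#'
#' Applies a compound's docking scores to the network: for every target the
#' compound was docked against, all out-edges of that target node get the line
#' value [line_value()]`(be, bes)`; every other edge keeps the baseline 10.
#' Lengthening a target's out-edges models inhibition: paths through the
#' inhibited enzyme become longer, so downstream nodes are harder to reach and
#' the network efficiency falls.
#'
#' Scored targets that are not nodes of the network are skipped with a warning.
#' Complexes are treated as distinct nodes: a score against `factor_ixa` does
#' not implicitly reweight `factor_viiia:factor_ixa`.
#'
#' @param net a [pathway_network()] (unmodified; a reweighted copy is
#'   returned).
#' @param table a [docking_scores()] table.
#' @param compound compound identifier present in `table`.
#' @param refs optional [reference_energies()]; computed from `table` when
#'   omitted (per-target references over the analyzed compound set). Pass a
#'   fixed table to score against an external reference.
#' @param exponent_factor,lv_floor passed to [line_value()].
#' @return A new `pathway_network` with reweighted out-edges.
#' @export
reweight_network <- function(net, table, compound, refs = NULL,
                             exponent_factor = 2.3, lv_floor = 10) {
  stopifnot(inherits(net, "pathway_network"),
            inherits(table, "docking_scores"))
  rows <- table[table$compound == compound, , drop = FALSE]
  if (nrow(rows) == 0L) stop("compound not in score table: ", compound)
  if (is.null(refs)) refs <- reference_energies(table)
  edges <- net$edges
  edges$line_value <- 10
  for (i in seq_len(nrow(rows))) {
    tg <- rows$target[i]
    if (!tg %in% net$nodes) {
      warning("scored target not in network, skipped: ", tg)
      next
    }
    bes <- refs$bes[match(tg, refs$target)]
    if (is.na(bes)) stop("no reference energy for target: ", tg)
    if (bes == 0) {
      warning("degenerate reference for target ", tg, "; out-edges unchanged")
      next
    }
    out <- edges$source == tg
    edges$line_value[out] <- line_value(rows$binding_energy[i], bes,
                                        exponent_factor, lv_floor)
  }
  pathway_network(edges, nodes = net$nodes)
}
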