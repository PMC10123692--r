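# Conversion of expression profiles into reaction expression states, and
# timed metabolite/lipid concentration measurements into exchange-reaction
# flux bounds.

#' Classify genes into low / moderate / high expression
#'
#' Per-gene replicate means are compared against the `lower_pct` and
#' `upper_pct` percentiles of the mean distribution (linear interpolation
#' between order statistics, [stats::quantile()] type 7). Strictly above
#' the upper threshold is high (+1), strictly below the lower threshold is
#' low (-1); genes at or between the thresholds are moderate (0).
#'
#' @param profile numeric matrix of normalized intensities, genes in rows
#'   (rownames required), replicates in columns; a named vector of per-gene
#'   values is also accepted.
#' @param lower_pct,upper_pct percentiles in (0, 100), lower < upper.
#' @param restrict_to optional gene ids over which the percentile
#'   distribution is computed (e.g. the metabolic genes appearing in a
#'   model's GPRs); genes outside it are still classified against the same
#'   thresholds.
#' @return an object of class `GeneClassMap`: list with `class` (named
#'   integer vector in \{-1, 0, +1\}), `thresholds` (values of the two
#'   percentiles) and `percentiles` (the pair used).
#' @export
classifyGenes <- function(profile, lower_pct = 33, upper_pct = 66,
                          restrict_to = NULL) {
  if (is.matrix(profile) || is.data.frame(profile)) {
    profile <- as.matrix(profile)
    if (is.null(rownames(profile))) stop("profile must carry gene rownames")
    means <- rowMeans(profile)
  } else {
    if (is.null(names(profile))) stop("profile must carry gene names")
    means <- profile
  }
  if (length(means) == 0) stop("empty expression profile")
  if (anyDuplicated(names(means))) stop("duplicate gene ids in profile")
  if (!(lower_pct > 0 && lower_pct < upper_pct && upper_pct < 100)) {
    stop("need 0 < lower_pct < upper_pct < 100")
  }
  pool <- if (is.null(restrict_to)) means else means[names(means) %in% restrict_to]
  if (length(pool) == 0) stop("no genes left after restriction")
  thr <- stats::quantile(pool, c(lower_pct, upper_pct) / 100,
                         names = FALSE, type = 7)
  cls <- integer(length(means))
  cls[means > thr[2]] <- 1L
  cls[means < thr[1]] <- -1L
  structure(list(class = stats::setNames(cls, names(means)),
                 thresholds = stats::setNames(thr, c("lower", "upper")),
                 percentiles = c(lower = lower_pct, upper = upper_pct)),
            class = "GeneClassMap")
}

#' @export
print.GeneClassMap <- function(x, ...) {
  tab <- table(factor(x$class, levels = c(-1, 0, 1),
                      labels = c("low", "moderate", "high")))
  cat("GeneClassMap (percentiles ", x$percentiles["lower"], "/",
      x$percentiles["upper"], "): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Derive reaction expression states from gene classes
#'
#' Propagates trinary gene classes through each reaction's GPR
#' ([evaluateGPR()]): the highly expressed set R_H collects reactions with
#' value +1, the lowly expressed set R_L those with value -1. Reactions
#' with an empty GPR always evaluate to 0 and belong to neither set.
#'
#' @param model a [MetabolicModel].
#' @param classes a `GeneClassMap` from [classifyGenes()].
#' @return an object of class `ReactionExpressionState`: list with `RH`,
#'   `RL` (character id vectors), `values` (named integer per reaction) and
#'   `percentiles` carried over from `classes`.
#' @export
reactionStates <- function(model, classes) {
  stopifnot(inherits(classes, "GeneClassMap"))
  vals <- vapply(model@reactions$gpr, evaluateGPR, integer(1),
                 geneValues = classes$class)
  names(vals) <- model@reactions$id
  structure(list(RH = names(vals)[vals == 1L],
                 RL = names(vals)[vals == -1L],
                 values = vals,
                 percentiles = classes$percentiles),
            class = "ReactionExpressionState")
}

#' @export
print.ReactionExpressionState <- function(x, ...) {
  cat("ReactionExpressionState: |R_H| =", length(x$RH),
      " |R_L| =", length(x$RL), "of", length(x$values), "reactions\n")
  invisible(x)
}

#' Exchange-flux bounds from timed concentration measurements
#'
#' From mean +/- SD concentrations at the start (0 h) and end of the
#' sampling interval, the accumulation/consumption of each species is
#' bracketed as `ub = (c5 + Sd5) - (c0 - Sd0)` and
#' `lb = (c5 - Sd5) - (c0 + Sd0)`, so `ub - lb = 2 (Sd0 + Sd5)`. By default
#' the differences are divided by the interval duration to give rate
#' bounds, matching the rate units of exchange fluxes (positive =
#' secretion/accumulation, negative = uptake/consumption); `rate = FALSE`
#' keeps the raw concentration differences.
#'
#' @param ts data.frame with columns `metabolite`, `compartment` (`medium`
#'   or `cell`), `c0`, `Sd0`, `c5`, `Sd5`.
#' @param duration sampling interval in hours (> 0).
#' @param rate divide by `duration` to obtain rate bounds (default TRUE).
#' @param reaction_map optional named character vector metabolite ->
#'   reaction id; by default medium measurements target `EX_<metabolite>`
#'   and cell measurements `sink_<metabolite>`.
#' @return data.frame with columns `reaction`, `metabolite`, `lb`, `ub`.
#' @export
metaboliteBounds <- function(ts, duration = 5, rate = TRUE,
                             reaction_map = NULL) {
  stopifnot(is.data.frame(ts),
            all(c("metabolite", "c0", "Sd0", "c5", "Sd5") %in% names(ts)))
  if (duration <= 0) stop("duration must be positive")
  if (any(ts$Sd0 < 0) || any(ts$Sd5 < 0)) {
    stop("standard deviations must be non-negative")
  }
  ub <- (ts$c5 + ts$Sd5) - (ts$c0 - ts$Sd0)
  lb <- (ts$c5 - ts$Sd5) - (ts$c0 + ts$Sd0)
  if (rate) {
    ub <- ub / duration
    lb <- lb / duration
  }
  if (is.null(reaction_map)) {
    comp <- if ("compartment" %in% names(ts)) ts$compartment else "medium"
    rxn <- ifelse(comp == "cell",
                  paste0("sink_", ts$metabolite),
                  paste0("EX_", ts$metabolite))
  } else {
    rxn <- unname(reaction_map[ts$metabolite])
  }
  data.frame(reaction = rxn, metabolite = ts$metabolite, lb = lb, ub = ub,
             stringsAsFactors = FALSE)
}

#' Impose exchange bounds on a model
#'
#' Sets the bounds of the targeted exchange/sink reactions and verifies by
#' a feasibility LP that the constrained model still admits a steady state.
#' On infeasibility the error reports which of the applied bounds are
#' individually conflicting (removing them restores feasibility).
#'
#' @param model a [MetabolicModel].
#' @param bounds data.frame as returned by [metaboliteBounds()].
#' @param check_feasible run the post-application feasibility LP.
#' @param on_conflict `"error"` (default) aborts with the diagnostic;
#'   `"drop"` discards the individually conflicting measurements with a
#'   warning and keeps the rest -- measurement noise can bracket a
#'   near-zero rate strictly away from zero on the side the network cannot
#'   realize, and a constraint the network rules out carries no usable
#'   information.
#' @return the constrained model; under `"drop"` the discarded reaction
#'   ids are attached as the `dropped_bounds` attribute.
#' @export
applyExchangeBounds <- function(model, bounds, check_feasible = TRUE,
                                on_conflict = c("error", "drop")) {
  on_conflict <- match.arg(on_conflict)
  if (is.null(bounds) || nrow(bounds) == 0) return(model)
  idx <- match(bounds$reaction, model@reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ",
         paste(bounds$reaction[is.na(idx)], collapse = ", "))
  }
  kinds <- model@reactions$kind[idx]
  if (!all(kinds %in% c("exchange", "sink"))) {
    bad <- bounds$reaction[!kinds %in% c("exchange", "sink")]
    stop("bounds may only target exchange or sink reactions; offending: ",
         paste(bad, collapse = ", "))
  }
  out <- setFluxBounds(model, bounds$reaction, bounds$lb, bounds$ub)
  if (check_feasible && !isFeasible(out)) {
    conflicting <- vapply(seq_len(nrow(bounds)), function(i) {
      relaxed <- setFluxBounds(out, bounds$reaction[i],
                               model@reactions$lower_bound[idx[i]],
                               model@reactions$upper_bound[idx[i]])
      isFeasible(relaxed)
    }, logical(1))
    if (on_conflict == "drop") {
      if (!any(conflicting)) conflicting <- rep(TRUE, nrow(bounds))
      warning("dropping ", sum(conflicting), " exchange bound(s) the ",
              "network cannot realize: ",
              paste(bounds$reaction[conflicting], collapse = ", "))
      out <- applyExchangeBounds(model, bounds[!conflicting, , drop = FALSE],
                                 check_feasible = check_feasible,
                                 on_conflict = "drop")
      attr(out, "dropped_bounds") <-
        c(bounds$reaction[conflicting], attr(out, "dropped_bounds"))
      return(out)
    }
    msg <- if (any(conflicting)) {
      paste0("conflicting bounds: ",
             paste(sprintf("%s in [%.4g, %.4g]",
                           bounds$reaction[conflicting],
                           bounds$lb[conflicting], bounds$ub[conflicting]),
                   collapse = "; "))
    } else {
      "bounds are jointly infeasible (no single bound restores feasibility)"
    }
    stop("model infeasible after applying exchange bounds; ", msg)
  }
  out
}
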