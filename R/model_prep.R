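# Model preparation: expansion with a boundary compartment for whole-cell
# lipid measurements, then reduction by blocked-reaction and dead-end
# metabolite removal.

.lipidInstance <- function(model, base, comp) {
  met <- model@metabolites
  cand <- which(met$compartment == comp &
                  (met$id == paste0(base, "_", comp) | met$id == base |
                     met$name == base))
  if (length(cand) == 0) {
    stop("measured lipid '", base, "' not found in compartment '", comp, "'")
  }
  met$id[cand[1]]
}

#' Expand a model with a boundary compartment for measured lipids
#'
#' Whole-cell lipid measurements cannot be attributed to a single
#' intracellular compartment. For every measured lipid present in more than
#' one compartment this adds one boundary metabolite, a
#' transport-to-boundary reaction from each intracellular instance, and a
#' sink on the boundary metabolite; lipids restricted to a single
#' compartment get a sink directly on their intracellular instance. All
#' added reactions are reversible (`[-bound, bound]`) so measurement-derived
#' bounds of either sign can be imposed on them later, and carry a
#' `provenance` tag.
#'
#' @param model a [MetabolicModel].
#' @param measured_lipids named list: names are lipid base identifiers,
#'   values character vectors of compartments where the lipid occurs. An
#'   instance is matched as `<base>_<compartment>`, or as a metabolite whose
#'   id or name equals the base id within that compartment.
#' @param boundary_compartment id of the new compartment (default `"bnd"`).
#' @param bound box bound for the added reactions.
#' @return the expanded [MetabolicModel].
#' @export
expandLipidBoundary <- function(model, measured_lipids,
                                boundary_compartment = "bnd", bound = 1000) {
  if (length(measured_lipids) == 0) return(model)
  stopifnot(!is.null(names(measured_lipids)))
  S <- model@stoichiometry
  new_mets <- list()
  new_rxns <- list()
  entries <- list()
  for (base in names(measured_lipids)) {
    comps <- measured_lipids[[base]]
    inst <- vapply(comps, function(cc) .lipidInstance(model, base, cc),
                   character(1))
    if (length(inst) > 1) {
      bmet <- paste0(base, "_", boundary_compartment)
      new_mets[[bmet]] <- list(id = bmet, compartment = boundary_compartment,
                               name = base)
      for (k in seq_along(inst)) {
        rid <- paste0("TBND_", base, "_", comps[k])
        new_rxns[[rid]] <- list(id = rid, kind = "transport-to-boundary")
        entries[[length(entries) + 1]] <-
          data.frame(rxn = rid, met = inst[k], coef = -1)
        entries[[length(entries) + 1]] <-
          data.frame(rxn = rid, met = bmet, coef = 1)
      }
      rid <- paste0("sink_", base, "_", boundary_compartment)
      new_rxns[[rid]] <- list(id = rid, kind = "sink")
      entries[[length(entries) + 1]] <-
        data.frame(rxn = rid, met = bmet, coef = -1)
    } else {
      rid <- paste0("sink_", base, "_", comps[1])
      new_rxns[[rid]] <- list(id = rid, kind = "sink")
      entries[[length(entries) + 1]] <-
        data.frame(rxn = rid, met = inst[1], coef = -1)
    }
  }
  tr <- do.call(rbind, entries)
  all_mets <- c(model@metabolites$id, names(new_mets))
  all_rxns <- c(model@reactions$id, names(new_rxns))
  Sx <- Matrix::sparseMatrix(
    i = match(tr$met, all_mets),
    j = match(tr$rxn, all_rxns) - ncol(S),
    x = tr$coef, dims = c(length(all_mets), length(new_rxns)))
  Sfull <- rbind(S, Matrix::Matrix(0, length(new_mets), ncol(S), sparse = TRUE))
  Sfull <- cbind(Sfull, Sx)
  dimnames(Sfull) <- list(all_mets, all_rxns)

  rxn_new <- S4Vectors::DataFrame(
    id = names(new_rxns),
    lower_bound = -bound, upper_bound = bound,
    subsystem = "Lipid boundary",
    kind = vapply(new_rxns, `[[`, character(1), "kind"),
    gpr_string = "")
  rxn_new$gpr <- vector("list", nrow(rxn_new))
  rxn_old <- model@reactions
  if (is.null(rxn_old$provenance)) rxn_old$provenance <- "model"
  rxn_new$provenance <- "lipid-boundary-expansion"
  met_new <- S4Vectors::DataFrame(
    id = names(new_mets),
    compartment = vapply(new_mets, `[[`, character(1), "compartment"),
    name = vapply(new_mets, `[[`, character(1), "name"))

  out <- model
  out@stoichiometry <- methods::as(methods::as(Sfull, "generalMatrix"),
                                   "CsparseMatrix")
  out@reactions <- rbind(rxn_old, rxn_new[, colnames(rxn_old)])
  out@metabolites <- rbind(model@metabolites, met_new)
  out@compartments <- unique(c(model@compartments, boundary_compartment))
  methods::validObject(out)
  out
}

#' Flux variability analysis
#'
#' For every reaction (or the requested subset), the minimum and maximum
#' steady-state flux over \{v : S v = 0, lb <= v <= ub\}, one LP per
#' direction. No objective-optimality constraint is imposed: the full
#' feasible space is explored, which is what blocked-reaction detection
#' requires.
#'
#' @param model a [MetabolicModel].
#' @param rxns optional character vector of reaction ids (default all).
#' @return a data.frame with columns `reaction`, `min_flux`, `max_flux`,
#'   `status` (`ok`/`infeasible`).
#' @export
fluxVariability <- function(model, rxns = NULL) {
  ids <- model@reactions$id
  if (is.null(rxns)) rxns <- ids
  idx <- match(rxns, ids)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(rxns[is.na(idx)], collapse = ", "))
  }
  sk <- .lpSkeleton(model)
  n <- length(ids)
  if (!isFeasible(model)) {
    stop("model is infeasible under steady state; no FVA performed")
  }
  groups <- list(list(Aeq = sk$Aeq, beq = sk$beq))
  probs <- list()
  for (j in idx) {
    cj <- rep(0, n); cj[j] <- 1
    probs[[length(probs) + 1]] <- list(c = cj, maximize = FALSE,
                                       lb = sk$lb, ub = sk$ub, group = 1)
    probs[[length(probs) + 1]] <- list(c = cj, maximize = TRUE,
                                       lb = sk$lb, ub = sk$ub, group = 1)
  }
  res <- solveMILPBatch(probs, groups)
  mins <- vapply(res[seq(1, length(res), 2)],
                 function(r) if (identical(r$status, "optimal"))
                   r$objective else NA_real_, numeric(1))
  maxs <- vapply(res[seq(2, length(res), 2)],
                 function(r) if (identical(r$status, "optimal"))
                   r$objective else NA_real_, numeric(1))
  data.frame(reaction = rxns, min_flux = mins, max_flux = maxs,
             status = ifelse(is.na(mins) | is.na(maxs), "infeasible", "ok"),
             stringsAsFactors = FALSE)
}

#' Remove blocked reactions
#'
#' A reaction is blocked when its flux variability range is `[0, 0]` within
#' `tol`: it cannot carry steady-state flux in any feasible state. Blocked
#' reactions are removed; surviving reactions keep their bounds.
#'
#' @param model a [MetabolicModel].
#' @param tol absolute flux tolerance below which a flux counts as zero
#'   (solver noise floor).
#' @return list with elements `model` (reduced) and `report`
#'   (`removed_blocked`, `removed_dead_end`, `iterations`).
#' @export
removeBlocked <- function(model, tol = 1e-9) {
  fva <- fluxVariability(model)
  blocked <- fva$reaction[fva$status == "ok" &
                            abs(fva$min_flux) < tol & abs(fva$max_flux) < tol]
  out <- if (length(blocked)) dropEntities(model, rxns = blocked) else model
  list(model = out,
       report = list(removed_blocked = blocked,
                     removed_dead_end = character(), iterations = 1L))
}

#' Remove dead-end metabolites
#'
#' Deletes metabolites that no longer participate in any reaction, then any
#' reaction left with empty stoichiometry, iterating to a fixed point.
#' Intended to run after [removeBlocked()].
#'
#' @param model a [MetabolicModel].
#' @return list with `model` and `report` as in [removeBlocked()].
#' @export
removeDeadEndMetabolites <- function(model) {
  removed_m <- character()
  removed_r <- character()
  it <- 0L
  repeat {
    it <- it + 1L
    S <- model@stoichiometry
    orphan <- if (nrow(S)) rownames(S)[Matrix::rowSums(S != 0) == 0] else character()
    empty <- if (ncol(S)) colnames(S)[Matrix::colSums(S != 0) == 0 &
                                        model@reactions$kind == "internal"] else character()
    if (length(orphan) == 0 && length(empty) == 0) break
    model <- dropEntities(model, rxns = empty, mets = orphan)
    removed_m <- c(removed_m, orphan)
    removed_r <- c(removed_r, empty)
    if (it > nrow(S) + ncol(S) + 2L) break  # safety net
  }
  list(model = model,
       report = list(removed_blocked = removed_r,
                     removed_dead_end = removed_m, iterations = it))
}

#' Reduce a model: blocked reactions, then dead-end metabolites
#'
#' @param model a [MetabolicModel].
#' @param tol blocked-flux tolerance, see [removeBlocked()].
#' @return list with `model` and a merged `report`.
#' @export
reduceModel <- function(model, tol = 1e-9) {
  b <- removeBlocked(model, tol = tol)
  d <- removeDeadEndMetabolites(b$model)
  list(model = d$model,
       report = list(
         removed_blocked = c(b$report$removed_blocked,
                             d$report$removed_blocked),
         removed_dead_end = d$report$removed_dead_end,
         iterations = d$report$iterations))
}
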