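#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' MetabolicModel: a genome-scale metabolic network
#'
#' Container for a constraint-based metabolic network: the stoichiometric
#' matrix S (metabolites in rows, reactions in columns), per-reaction flux
#' bounds, gene-protein-reaction (GPR) rules as parsed Boolean expression
#' trees, subsystem (pathway) labels and reaction kinds.
#'
#' Fluxes follow the usual convention of the field: units are those of the
#' source model (mmol/gDW/h for genome-scale reconstructions), exchange
#' fluxes are positive for secretion and negative for uptake, and the
#' steady-state assumption S v = 0 defines the feasible space together with
#' the box bounds.
#'
#' @slot stoichiometry sparse numeric matrix, metabolites x reactions, with
#'   dimnames set to metabolite and reaction identifiers.
#' @slot reactions a [S4Vectors::DataFrame] with columns `id`,
#'   `lower_bound`, `upper_bound`, `subsystem`, `kind` (one of `internal`,
#'   `exchange`, `sink`, `transport-to-boundary`), `gpr_string` and a list
#'   column `gpr` holding parsed expression trees (`NULL` when the rule is
#'   empty).
#' @slot metabolites a DataFrame with columns `id`, `compartment`, `name`.
#' @slot genes character vector of gene identifiers.
#' @slot compartments character vector of compartment identifiers.
#'
#' @seealso [metabolicModel()], [readSBML()], [modelFromEquations()]
#' @export
setClass("MetabolicModel",
  slots = c(
    stoichiometry = "Matrix",
    reactions     = "DataFrame",
    metabolites   = "DataFrame",
    genes         = "character",
    compartments  = "character"
  )
)

.validMetabolicModel <- function(object) {
  msg <- character()
  rxn <- object@reactions
  met <- object@metabolites
  S <- object@stoichiometry
  if (nrow(S) != nrow(met)) {
    msg <- c(msg, "stoichiometry row count does not match metabolite count")
  }
  if (ncol(S) != nrow(rxn)) {
    msg <- c(msg, "stoichiometry column count does not match reaction count")
  }
  if (anyDuplicated(rxn$id)) msg <- c(msg, "reaction ids are not unique")
  if (anyDuplicated(met$id)) msg <- c(msg, "metabolite ids are not unique")
  if (nrow(rxn) > 0 && any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
    msg <- c(msg, paste0("lower_bound > upper_bound for: ",
                         paste(bad, collapse = ", ")))
  }
  if (nrow(met) > 0 && !all(met$compartment %in% object@compartments)) {
    msg <- c(msg, "metabolite compartment not in compartment list")
  }
  if (nrow(rxn) > 0) {
    gpr_genes <- unique(unlist(lapply(rxn$gpr, gprGenes)))
    if (length(gpr_genes) && !all(gpr_genes %in% object@genes)) {
      missing <- setdiff(gpr_genes, object@genes)
      msg <- c(msg, paste0("GPR references genes absent from gene list: ",
                           paste(missing, collapse = ", ")))
    }
    ok_kind <- c("internal", "exchange", "sink", "transport-to-boundary")
    if (!all(rxn$kind %in% ok_kind)) {
      msg <- c(msg, "reaction kind must be internal/exchange/sink/transport-to-boundary")
    }
    # boundary pseudo-reactions touch exactly one metabolite
    if (ncol(S) > 0) {
      touched <- Matrix::colSums(S != 0)
      bnd <- rxn$kind %in% c("exchange", "sink")
      if (any(bnd & touched != 1)) {
        msg <- c(msg, "exchange/sink reactions must touch exactly one metabolite")
      }
      if (any(rxn$kind == "internal" & touched == 0)) {
        msg <- c(msg, "internal reactions must have non-empty stoichiometry")
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("MetabolicModel", .validMetabolicModel)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel with", nrow(object@reactions), "reactions,",
      nrow(object@metabolites), "metabolites,",
      length(object@genes), "genes,",
      length(object@compartments), "compartments\n")
  kinds <- table(object@reactions$kind)
  if (length(kinds)) {
    cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  }
  subs <- setdiff(unique(object@reactions$subsystem), "")
  cat("  subsystems:", length(subs), "\n")
})

#' ImatProblem: the iMAT mixed-integer program
#'
#' Encodes the iMAT MILP: maximise the number of highly expressed reactions
#' carrying flux beyond the activity threshold epsilon (in either direction)
#' plus the number of lowly expressed reactions carrying zero flux, subject
#' to steady state and flux bounds. Binary indicators y+/y- mark forward /
#' reverse activity of R_H members; x marks inactivity of R_L members.
#'
#' @slot model the [MetabolicModel] the problem was built from.
#' @slot RH,RL character vectors of reaction ids (highly / lowly expressed).
#' @slot epsilon positive activity threshold flux.
#' @slot forced optional named list of forced reaction states, values in
#'   `active-either`, `active-forward`, `active-reverse`, `inactive`.
#' @slot eq5 direction of the reverse-activity indicator constraint:
#'   `"corrected"` (y- = 1 forces v <= -epsilon) or `"printed"` (the
#'   literal published inequality, kept for comparison only).
#' @export
setClass("ImatProblem",
  slots = c(model = "MetabolicModel", RH = "character", RL = "character",
            epsilon = "numeric", forced = "list", eq5 = "character")
)

setValidity("ImatProblem", function(object) {
  msg <- character()
  if (length(object@epsilon) != 1 || object@epsilon <= 0) {
    msg <- c(msg, "epsilon must be a single positive flux")
  }
  if (length(intersect(object@RH, object@RL))) {
    msg <- c(msg, "R_H and R_L must be disjoint")
  }
  ids <- object@model@reactions$id
  if (!all(c(object@RH, object@RL) %in% ids)) {
    msg <- c(msg, "R_H/R_L contain reactions absent from the model")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ImatProblem", function(object) {
  cat("ImatProblem: |R_H| =", length(object@RH),
      " |R_L| =", length(object@RL),
      " epsilon =", object@epsilon, "\n")
  if (length(object@forced)) {
    cat("  forced:", paste(names(object@forced), unlist(object@forced),
                           sep = "=", collapse = ", "), "\n")
  }
})

#' ImatSolution: an optimal iMAT flux distribution
#'
#' @slot objective the optimal count of expression-consistent reactions.
#' @slot fluxes named numeric flux vector over all model reactions.
#' @slot indicators named list with elements `y_plus`, `y_minus` (named over
#'   R_H) and `x` (named over R_L), each 0/1.
#' @slot status solver status string (`optimal` or `infeasible`).
#' @export
setClass("ImatSolution",
  slots = c(objective = "numeric", fluxes = "numeric", indicators = "list",
            status = "character")
)

setMethod("show", "ImatSolution", function(object) {
  cat("ImatSolution:", object@status, " objective =", object@objective, "\n")
  act <- sum(abs(object@fluxes) > 1e-9)
  cat("  reactions carrying flux:", act, "of", length(object@fluxes), "\n")
})

#' ActivityCallSet: per-reaction activity calls from sensitivity analysis
#'
#' For every reaction, the outcome of the two forced MILPs (forced active,
#' forced inactive) compared against the unconstrained optimum: `active`
#' when only forcing activity preserves optimality, `inactive` when only
#' forcing inactivity does, and `undetermined` when both do (alternative
#' optima exist either way).
#'
#' @slot calls named character vector over reactions, values in `active`,
#'   `inactive`, `undetermined`.
#' @slot objActive,objInactive named numeric vectors with the forced-problem
#'   objectives (`-Inf` where a forced problem was infeasible).
#' @slot optimum the unconstrained optimal objective.
#' @slot thresholds length-2 numeric, the (lower, upper) expression
#'   percentile pair the calls were derived at.
#' @slot fluxes named numeric flux vector of the unconstrained optimum, kept
#'   for downstream exchange-sign prediction.
#' @slot epsilon the activity threshold used.
#' @export
setClass("ActivityCallSet",
  slots = c(calls = "character", objActive = "numeric",
            objInactive = "numeric", optimum = "numeric",
            thresholds = "numeric", fluxes = "numeric", epsilon = "numeric")
)

setMethod("show", "ActivityCallSet", function(object) {
  tab <- table(factor(object@calls,
                      levels = c("active", "inactive", "undetermined")))
  cat("ActivityCallSet (thresholds ",
      paste(object@thresholds, collapse = "/"), "): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
})
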