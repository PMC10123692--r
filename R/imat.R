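# The iMAT mixed-integer program, its sensitivity analysis (two forced
# MILPs per reaction) and the robustness consensus across expression
# percentile threshold pairs.

#' Build the iMAT problem for a model and expression state
#'
#' The program maximises the number of expression-consistent reactions:
#' for each highly expressed reaction i (R_H) binary indicators y+ / y-
#' assert forward (v_i >= epsilon) or reverse (v_i <= -epsilon) activity;
#' for each lowly expressed reaction (R_L) a binary x asserts inactivity
#' (v_i = 0). Constraints: S v = 0, box bounds, and the indicator
#' implications
#' \deqn{v_i + y^+_i (v_{min,i} - \epsilon) \ge v_{min,i}}
#' \deqn{v_i + y^-_i (v_{max,i} + \epsilon) \le v_{max,i}}
#' \deqn{(1 - x_i) v_{min,i} \le v_i \le (1 - x_i) v_{max,i}}
#' The reverse-activity constraint is implemented in the direction that
#' actually encodes reverse flux; `eq5 = "printed"` selects the literal
#' published inequality instead (vacuous for activity, retained only for
#' comparison).
#'
#' @param model a reduced, bounded [MetabolicModel].
#' @param state a `ReactionExpressionState` from [reactionStates()], or a
#'   list with elements `RH` and `RL`.
#' @param epsilon positive activity threshold flux (default 1).
#' @param forced named list of forced reaction states (`active-either`,
#'   `active-forward`, `active-reverse`, `inactive`), used by the
#'   sensitivity analysis.
#' @param eq5 `"corrected"` (default) or `"printed"`.
#' @return an [ImatProblem].
#' @export
buildImat <- function(model, state, epsilon = 1, forced = list(),
                      eq5 = c("corrected", "printed")) {
  eq5 <- match.arg(eq5)
  RH <- as.character(state$RH)
  RL <- as.character(state$RL)
  missing <- setdiff(c(RH, RL, names(forced)), model@reactions$id)
  if (length(missing)) {
    stop("reactions not in model: ", paste(missing, collapse = ", "))
  }
  methods::new("ImatProblem", model = model, RH = RH, RL = RL,
               epsilon = epsilon, forced = forced, eq5 = eq5)
}

# Assemble the MILP matrices of an ImatProblem. Variable order: all fluxes,
# then (y+, y-) per R_H member, x per R_L member, then one auxiliary binary
# per 'active-either' forced reaction.
.imatMatrices <- function(problem) {
  model <- problem@model
  eps <- problem@epsilon
  rxn <- model@reactions
  n <- nrow(rxn)
  ids <- rxn$id
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound

  # forced states that act through bounds
  for (rid in names(problem@forced)) {
    j <- match(rid, ids)
    f <- problem@forced[[rid]]
    if (f == "inactive") {
      lb[j] <- 0; ub[j] <- 0
    } else if (f == "active-forward") {
      lb[j] <- max(lb[j], eps)
    } else if (f == "active-reverse") {
      ub[j] <- min(ub[j], -eps)
    } else if (f != "active-either") {
      stop("unknown forced state '", f, "' for ", rid)
    }
  }
  either <- names(problem@forced)[unlist(problem@forced) == "active-either"]

  iH <- match(problem@RH, ids)
  iL <- match(problem@RL, ids)
  nH <- length(iH); nL <- length(iL); nE <- length(either)
  nvar <- n + 2 * nH + nL + nE
  ycols <- if (nH) n + seq_len(2 * nH) else integer()       # y+_1,y-_1,y+_2,...
  xcols <- if (nL) n + 2 * nH + seq_len(nL) else integer()
  ecols <- if (nE) n + 2 * nH + nL + seq_len(nE) else integer()

  m <- nrow(model@stoichiometry)
  Aeq <- cbind(as.matrix(model@stoichiometry),
               matrix(0, m, nvar - n))
  beq <- rep(0, m)

  rows <- list(); rhs <- c()
  add_row <- function(cols, vals, b) {
    r <- numeric(nvar); r[cols] <- vals
    rows[[length(rows) + 1]] <<- r
    rhs <<- c(rhs, b)
  }
  for (k in seq_len(nH)) {
    j <- iH[k]
    yp <- n + 2 * k - 1
    ym <- n + 2 * k
    # Eq (4): v_j + y+ (lb_j - eps) >= lb_j  <=>  -v_j + y+ (eps - lb_j) <= -lb_j
    add_row(c(j, yp), c(-1, eps - lb[j]), -lb[j])
    if (problem@eq5 == "corrected") {
      # y- = 1 forces v_j <= -eps
      add_row(c(j, ym), c(1, ub[j] + eps), ub[j])
    } else {
      # literal printed direction: v_j + y- (ub_j + eps) >= ub_j
      add_row(c(j, ym), c(-1, -(ub[j] + eps)), -ub[j])
    }
    add_row(c(yp, ym), c(1, 1), 1)  # at most one direction
  }
  for (k in seq_len(nL)) {
    j <- iL[k]
    xc <- n + 2 * nH + k
    # (1 - x) lb_j <= v_j <= (1 - x) ub_j
    add_row(c(j, xc), c(-1, -lb[j]), -lb[j])
    add_row(c(j, xc), c(1, ub[j]), ub[j])
  }
  for (k in seq_len(nE)) {
    j <- match(either[k], ids)
    dc <- n + 2 * nH + nL + k
    # d = 1 -> v_j >= eps ; d = 0 -> v_j <= -eps
    add_row(c(j, dc), c(-1, eps - lb[j]), -lb[j])
    add_row(c(j, dc), c(1, -(ub[j] + eps)), -eps)
  }

  obj <- numeric(nvar)
  obj[c(ycols, xcols)] <- 1
  vlb <- c(lb, rep(0, nvar - n))
  vub <- c(ub, rep(1, nvar - n))
  int <- c(rep(0L, n), rep(1L, nvar - n))
  list(c = obj, Aeq = Aeq, beq = beq,
       Aub = if (length(rows)) do.call(rbind, rows) else NULL,
       bub = if (length(rows)) rhs else NULL,
       lb = vlb, ub = vub, int = int,
       n = n, ids = ids, RH = problem@RH, RL = problem@RL, either = either)
}

.solutionFromRaw <- function(raw, mm) {
  if (!identical(raw$status, "optimal")) {
    return(methods::new("ImatSolution", objective = -Inf,
                        fluxes = numeric(), indicators = list(),
                        status = raw$status))
  }
  x <- unlist(raw$x)
  fluxes <- stats::setNames(x[seq_len(mm$n)], mm$ids)
  nH <- length(mm$RH)
  nL <- length(mm$RL)
  yp <- ym <- stats::setNames(numeric(nH), mm$RH)
  if (nH) {
    yraw <- x[mm$n + seq_len(2 * nH)]
    yp[] <- round(yraw[seq(1, 2 * nH, 2)])
    ym[] <- round(yraw[seq(2, 2 * nH, 2)])
  }
  xv <- stats::setNames(if (nL) round(x[mm$n + 2 * nH + seq_len(nL)])
                        else numeric(0), mm$RL)
  methods::new("ImatSolution",
               objective = round(raw$objective),
               fluxes = fluxes,
               indicators = list(y_plus = yp, y_minus = ym, x = xv),
               status = "optimal")
}

#' Solve an iMAT problem to proven optimality
#'
#' @param problem an [ImatProblem] from [buildImat()].
#' @param seed integer; recorded for provenance. The backend solver is
#'   deterministic for a fixed problem, so identical seeds (indeed any
#'   seeds) reproduce the objective; only objective and activity calls are
#'   contractual, alternative optima may differ in fluxes.
#' @return an [ImatSolution].
#' @export
solveImat <- function(problem, seed = 1L) {
  mm <- .imatMatrices(problem)
  raw <- .solveOne(list(c = mm$c, maximize = TRUE, lb = mm$lb, ub = mm$ub,
                        int = mm$int, Aeq = mm$Aeq, beq = mm$beq,
                        Aub = mm$Aub, bub = mm$bub))
  sol <- .solutionFromRaw(raw, mm)
  if (identical(sol@status, "infeasible")) {
    stop("iMAT problem is infeasible (check bounds and forced states)")
  }
  sol
}

#' Per-reaction sensitivity analysis
#'
#' iMAT optima are typically non-unique. For every reaction of the model,
#' two additional MILPs are solved: one forcing activity
#' (|v_i| >= epsilon through one auxiliary binary, direction-agnostic) and
#' one forcing inactivity (v_i = 0). A reaction is called `active` when
#' only the forced-active problem attains the unconstrained optimum,
#' `inactive` when only the forced-inactive one does, and `undetermined`
#' when both do. An infeasible forced problem counts as objective -Inf.
#'
#' @param model a [MetabolicModel].
#' @param state a `ReactionExpressionState`.
#' @param epsilon activity threshold flux.
#' @param tol absolute tolerance for objective equality (the objective is
#'   integer-valued, so any tol < 0.5 is safe).
#' @param eq5 see [buildImat()].
#' @return an [ActivityCallSet].
#' @export
sensitivityCalls <- function(model, state, epsilon = 1, tol = 1e-6,
                             eq5 = c("corrected", "printed")) {
  eq5 <- match.arg(eq5)
  base <- buildImat(model, state, epsilon = epsilon, eq5 = eq5)
  opt_sol <- solveImat(base)
  opt <- opt_sol@objective
  ids <- model@reactions$id
  probs <- list()
  for (rid in ids) {
    for (f in c("active-either", "inactive")) {
      p <- buildImat(model, state, epsilon = epsilon,
                     forced = stats::setNames(list(f), rid), eq5 = eq5)
      mm <- .imatMatrices(p)
      probs[[length(probs) + 1]] <-
        list(c = mm$c, maximize = TRUE, lb = mm$lb, ub = mm$ub,
             int = mm$int, Aeq = mm$Aeq, beq = mm$beq,
             Aub = mm$Aub, bub = mm$bub)
    }
  }
  res <- solveMILPBatch(probs)
  objs <- vapply(res, function(r) {
    if (identical(r$status, "optimal")) r$objective else -Inf
  }, numeric(1))
  objA <- stats::setNames(objs[seq(1, length(objs), 2)], ids)
  objI <- stats::setNames(objs[seq(2, length(objs), 2)], ids)
  atA <- objA >= opt - tol
  atI <- objI >= opt - tol
  calls <- rep("undetermined", length(ids))
  calls[atA & !atI] <- "active"
  calls[atI & !atA] <- "inactive"
  pct <- if (!is.null(state$percentiles)) as.numeric(state$percentiles)
         else c(NA_real_, NA_real_)
  methods::new("ActivityCallSet",
               calls = stats::setNames(calls, ids),
               objActive = objA, objInactive = objI,
               optimum = opt, thresholds = pct,
               fluxes = opt_sol@fluxes, epsilon = epsilon)
}

#' Consensus of sensitivity calls across threshold pairs
#'
#' A reaction keeps its call only when every per-threshold call set agrees
#' on `active` or on `inactive`; any disagreement, or any `undetermined`
#' member, yields `undetermined`. The per-pair calls are attached as the
#' `perPair` attribute (reactions x pairs character matrix).
#'
#' @param callSets list of >= 2 [ActivityCallSet] objects on the same model.
#' @return an [ActivityCallSet] holding the consensus calls (objective
#'   slots are `NA`; fluxes come from the first member).
#' @export
robustnessConsensus <- function(callSets) {
  if (length(callSets) < 2) stop("need at least two call sets")
  ids <- names(callSets[[1]]@calls)
  for (cs in callSets[-1]) {
    if (!identical(sort(names(cs@calls)), sort(ids))) {
      stop("call sets cover different reaction sets")
    }
  }
  mat <- vapply(callSets, function(cs) cs@calls[ids], character(length(ids)))
  consensus <- apply(mat, 1, function(r) {
    u <- unique(r)
    if (length(u) == 1 && u != "undetermined") u else "undetermined"
  })
  colnames(mat) <- vapply(callSets, function(cs) {
    paste(cs@thresholds, collapse = "/")
  }, character(1))
  out <- methods::new("ActivityCallSet",
                      calls = stats::setNames(consensus, ids),
                      objActive = stats::setNames(rep(NA_real_, length(ids)), ids),
                      objInactive = stats::setNames(rep(NA_real_, length(ids)), ids),
                      optimum = NA_real_,
                      thresholds = c(NA_real_, NA_real_),
                      fluxes = callSets[[1]]@fluxes,
                      epsilon = callSets[[1]]@epsilon)
  attr(out, "perPair") <- mat
  out
}

#' Tabulate activity calls for export
#'
#' @param callSets named list of per-threshold [ActivityCallSet]s.
#' @param consensus optional consensus [ActivityCallSet].
#' @param model optional [MetabolicModel] supplying subsystem labels.
#' @return a data.frame, one row per reaction.
#' @export
activityCallTable <- function(callSets, consensus = NULL, model = NULL) {
  ids <- names(callSets[[1]]@calls)
  out <- data.frame(reaction = ids, stringsAsFactors = FALSE)
  if (!is.null(model)) {
    out$subsystem <- model@reactions$subsystem[match(ids, model@reactions$id)]
  }
  for (i in seq_along(callSets)) {
    nm <- names(callSets)[i]
    if (is.null(nm) || !nzchar(nm)) {
      nm <- paste0("call_", paste(callSets[[i]]@thresholds, collapse = "_"))
    }
    out[[nm]] <- unname(callSets[[i]]@calls[ids])
  }
  if (!is.null(consensus)) out$consensus <- unname(consensus@calls[ids])
  out
}
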