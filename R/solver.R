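# Linear and mixed-integer solves are delegated to the HiGHS solver through
# scipy's `milp` interface, driven in batches by inst/python/milp_backend.py.
# HiGHS runs single-threaded here and is deterministic for a fixed problem,
# which the sensitivity-analysis contract relies on.

.backendScript <- function() {
  system.file("python", "milp_backend.py", package = "FluxActivity",
              mustWork = TRUE)
}

.pythonBin <- function() {
  bin <- getOption("FluxActivity.python", Sys.which("python"))
  if (!nzchar(bin)) {
    stop("no 'python' interpreter found on PATH; the MILP backend needs one ",
         "with scipy installed (set options(FluxActivity.python=...) to ",
         "point at it)")
  }
  bin
}

#' Solve a batch of linear / mixed-integer programs
#'
#' Low-level access to the HiGHS backend. Each problem is a list with
#' elements `c` (objective), `maximize` (logical), `lb`, `ub`, optional
#' `int` (0/1 integrality per variable), and either its own constraint
#' matrices (`Aeq`/`beq`, `Aub`/`bub`, row-wise `A x <= b`) or `group`, a
#' 1-based index into `groups`, a list of shared constraint sets --- used
#' when many problems differ only in objective or bounds (flux variability,
#' enumeration oracles).
#'
#' @param problems list of problem lists.
#' @param groups optional list of shared constraint sets.
#' @return a list per problem: `status` (`optimal`, `infeasible`,
#'   `unbounded`, `error`), `objective`, `x`.
#' @keywords internal
#' @export
solveMILPBatch <- function(problems, groups = NULL) {
  if (length(problems) == 0) return(list())
  clean <- function(p) {
    p$c <- as.numeric(p$c)
    p$lb <- as.numeric(p$lb)
    p$ub <- as.numeric(p$ub)
    if (!is.null(p$int)) p$int <- as.integer(p$int)
    if (!is.null(p$Aeq)) {
      p$Aeq <- unname(as.matrix(p$Aeq))
      p$beq <- as.numeric(p$beq)
    }
    if (!is.null(p$Aub)) {
      p$Aub <- unname(as.matrix(p$Aub))
      p$bub <- as.numeric(p$bub)
    }
    p$maximize <- isTRUE(p$maximize)
    p
  }
  payload <- list(problems = lapply(problems, clean))
  if (!is.null(groups)) {
    payload$groups <- lapply(groups, function(g) {
      g$Aeq <- if (!is.null(g$Aeq)) unname(as.matrix(g$Aeq))
      g$beq <- as.numeric(g$beq)
      if (!is.null(g$Aub)) {
        g$Aub <- unname(as.matrix(g$Aub))
        g$bub <- as.numeric(g$bub)
      }
      g
    })
  }
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  status <- system2(.pythonBin(), c(.backendScript(), fin, fout),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(fout)) {
    stop("MILP backend failed (exit status ", status, ")")
  }
  jsonlite::fromJSON(fout, simplifyVector = FALSE)
}

# Solve a single problem; returns list(status, objective, x).
.solveOne <- function(problem, groups = NULL) {
  solveMILPBatch(list(problem), groups)[[1]]
}

# Steady-state LP skeleton of a model: S v = 0 plus box bounds.
.lpSkeleton <- function(model) {
  list(Aeq = as.matrix(model@stoichiometry),
       beq = rep(0, nrow(model@stoichiometry)),
       lb = model@reactions$lower_bound,
       ub = model@reactions$upper_bound)
}

#' Check steady-state feasibility of a model
#'
#' Solves the zero-objective LP over \{v : S v = 0, lb <= v <= ub\}.
#'
#' @param model a [MetabolicModel].
#' @return `TRUE`/`FALSE`.
#' @export
isFeasible <- function(model) {
  sk <- .lpSkeleton(model)
  n <- ncol(sk$Aeq)
  res <- .solveOne(list(c = rep(0, n), maximize = FALSE, lb = sk$lb,
                        ub = sk$ub, Aeq = sk$Aeq, beq = sk$beq))
  identical(res$status, "optimal")
}
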