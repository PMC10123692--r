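#' Construct a MetabolicModel
#'
#' @param stoichiometry numeric matrix (dense or sparse), metabolites in
#'   rows, reactions in columns, with dimnames giving the identifiers.
#' @param lower_bound,upper_bound numeric flux bounds per reaction,
#'   recycled; default box bounds of +/- 1000 flux units.
#' @param gpr character vector of GPR rule strings per reaction (`""` for
#'   none), or a list of pre-parsed trees.
#' @param subsystem character vector of pathway labels per reaction.
#' @param kind per-reaction kind; when `NULL`, inferred: columns touching a
#'   single metabolite are `exchange` (`sink` when the id starts with
#'   `sink_`/`SK_`), everything else `internal`.
#' @param met_compartment compartment per metabolite (default `"c"`).
#' @param met_name metabolite display names (default the ids).
#' @param compartments compartment universe; default the ones used.
#' @param genes gene universe; default the genes referenced by the GPRs.
#' @return a validated [MetabolicModel].
#' @export
metabolicModel <- function(stoichiometry,
                           lower_bound = -1000, upper_bound = 1000,
                           gpr = "", subsystem = "", kind = NULL,
                           met_compartment = "c", met_name = NULL,
                           compartments = NULL, genes = NULL) {
  S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop("stoichiometry must carry metabolite and reaction ids as dimnames")
  }
  n <- ncol(S)
  m <- nrow(S)
  if (is.list(gpr) && !is.null(gpr$op)) gpr <- list(gpr)
  if (is.list(gpr)) {
    trees <- rep_len(gpr, n)
    gpr_string <- vapply(trees, deparseGPR, character(1))
  } else {
    gpr_string <- rep_len(as.character(gpr), n)
    trees <- lapply(gpr_string, parseGPR)
  }
  if (is.null(kind)) {
    touched <- if (n) Matrix::colSums(S != 0) else integer()
    kind <- ifelse(touched == 1,
                   ifelse(grepl("^(sink_|SK_)", colnames(S)), "sink", "exchange"),
                   "internal")
  }
  rxn <- S4Vectors::DataFrame(
    id = colnames(S),
    lower_bound = rep_len(lower_bound, n),
    upper_bound = rep_len(upper_bound, n),
    subsystem = rep_len(subsystem, n),
    kind = rep_len(kind, n),
    gpr_string = gpr_string
  )
  rxn$gpr <- trees
  met <- S4Vectors::DataFrame(
    id = rownames(S),
    compartment = rep_len(met_compartment, m),
    name = if (is.null(met_name)) rownames(S) else rep_len(met_name, m)
  )
  if (is.null(compartments)) compartments <- unique(met$compartment)
  if (is.null(genes)) genes <- unique(unlist(lapply(trees, gprGenes)))
  if (is.null(genes)) genes <- character()
  methods::new("MetabolicModel", stoichiometry = S, reactions = rxn,
               metabolites = met, genes = as.character(genes),
               compartments = as.character(compartments))
}

#' Build a toy model from reaction equation strings
#'
#' A convenience constructor for small fixtures. Equations use the syntax
#' `"A + 2 B -> C"`; an empty side denotes the system boundary, so
#' `"A ->"` is an exchange/sink for A and `"-> A"` an inflow written with
#' the opposite sign convention (stored as A with coefficient +1).
#'
#' @param equations named character vector, names are reaction ids.
#' @inheritParams metabolicModel
#' @return a [MetabolicModel].
#' @examples
#' modelFromEquations(c(EX_A = "A ->", R1 = "A -> B", EX_B = "B ->"),
#'                    lower_bound = c(-10, 0, 0), upper_bound = 10)
#' @export
modelFromEquations <- function(equations, lower_bound = -1000,
                               upper_bound = 1000, gpr = "", subsystem = "",
                               kind = NULL, met_compartment = "c") {
  stopifnot(length(equations) > 0, !is.null(names(equations)))
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(NULL)
    terms <- strsplit(s, "\\s*\\+\\s*")[[1]]
    out <- lapply(terms, function(t) {
      t <- trimws(t)
      m <- regmatches(t, regexec("^([0-9.]+)\\s+(.*)$", t))[[1]]
      if (length(m) == 3) {
        c(id = m[3], coef = as.numeric(m[2]) * sign)
      } else {
        c(id = t, coef = sign)
      }
    })
    out
  }
  entries <- lapply(seq_along(equations), function(i) {
    eq <- strsplit(equations[[i]], "<?->|<-", perl = TRUE)[[1]]
    lhs <- parse_side(eq[1], -1)
    rhs <- if (length(eq) > 1) parse_side(eq[2], +1) else NULL
    do.call(rbind, lapply(c(lhs, rhs), function(x) {
      data.frame(rxn = names(equations)[i], met = x[["id"]],
                 coef = as.numeric(x[["coef"]]))
    }))
  })
  tr <- do.call(rbind, entries)
  mets <- unique(tr$met)
  S <- Matrix::sparseMatrix(
    i = match(tr$met, mets), j = match(tr$rxn, names(equations)),
    x = tr$coef, dims = c(length(mets), length(equations)),
    dimnames = list(mets, names(equations))
  )
  metabolicModel(S, lower_bound = lower_bound, upper_bound = upper_bound,
                 gpr = gpr, subsystem = subsystem, kind = kind,
                 met_compartment = met_compartment)
}

#' Stoichiometric matrix of a model
#'
#' Returns S with reactions in columns and metabolites in rows; entry
#' (i, j) is the stoichiometric coefficient of metabolite i in reaction j.
#'
#' @param model a [MetabolicModel].
#' @return a sparse numeric matrix.
#' @export
stoichiometricMatrix <- function(model) model@stoichiometry

#' Model accessors
#'
#' Read-only access to the components of a [MetabolicModel].
#'
#' @param model a [MetabolicModel].
#' @name accessors
#' @return the requested component.
NULL

#' @describeIn accessors reaction annotation table
#' @export
reactions <- function(model) model@reactions

#' @describeIn accessors metabolite annotation table
#' @export
metabolites <- function(model) model@metabolites

#' @describeIn accessors gene identifier vector
#' @export
modelGenes <- function(model) model@genes

#' @describeIn accessors compartment identifiers
#' @export
compartments <- function(model) model@compartments

#' @describeIn accessors reaction identifiers
#' @export
reactionIds <- function(model) model@reactions$id

#' @describeIn accessors metabolite identifiers
#' @export
metaboliteIds <- function(model) model@metabolites$id

#' @describeIn accessors two-column matrix of flux bounds
#' @export
fluxBounds <- function(model) {
  cbind(lower = model@reactions$lower_bound,
        upper = model@reactions$upper_bound)
}

#' Replace flux bounds of selected reactions
#'
#' @param model a [MetabolicModel].
#' @param ids reaction identifiers.
#' @param lower,upper new bounds (recycled over `ids`).
#' @return the updated model.
#' @export
setFluxBounds <- function(model, ids, lower, upper) {
  idx <- match(ids, model@reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  model@reactions$lower_bound[idx] <- rep_len(lower, length(idx))
  model@reactions$upper_bound[idx] <- rep_len(upper, length(idx))
  methods::validObject(model)
  model
}

#' Drop reactions or metabolites from a model
#'
#' Removes the named reactions and/or metabolites and the corresponding
#' rows/columns of S. Metabolites still referenced by surviving reactions
#' cannot be dropped.
#'
#' @param model a [MetabolicModel].
#' @param rxns,mets identifiers to remove.
#' @return the reduced model.
#' @export
dropEntities <- function(model, rxns = character(), mets = character()) {
  keep_r <- !(model@reactions$id %in% rxns)
  keep_m <- !(model@metabolites$id %in% mets)
  S <- model@stoichiometry[keep_m, keep_r, drop = FALSE]
  model@stoichiometry <- S
  model@reactions <- model@reactions[keep_r, ]
  model@metabolites <- model@metabolites[keep_m, ]
  methods::validObject(model)
  model
}

#' Serialize a model to JSON
#'
#' A plain JSON document (reactions with stoichiometry maps, bounds, GPR
#' strings, subsystems, kinds; metabolites; genes; compartments) for
#' fixtures and interchange. [modelFromJSON()] inverts it.
#'
#' @param model a [MetabolicModel].
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
modelToJSON <- function(model, path = NULL) {
  S <- model@stoichiometry
  rxns <- lapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    r <- model@reactions[j, ]
    list(id = r$id,
         stoichiometry = as.list(stats::setNames(col[nz], rownames(S)[nz])),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gpr = r$gpr_string, subsystem = r$subsystem, kind = r$kind)
  })
  mets <- lapply(seq_len(nrow(model@metabolites)), function(i) {
    m <- model@metabolites[i, ]
    list(id = m$id, compartment = m$compartment, name = m$name)
  })
  doc <- list(reactions = rxns, metabolites = mets,
              genes = as.list(model@genes),
              compartments = as.list(model@compartments))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read a model from its JSON serialization
#'
#' @param path file path or JSON string produced by [modelToJSON()].
#' @return a [MetabolicModel].
#' @export
modelFromJSON <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rxn_ids <- vapply(doc$reactions, `[[`, character(1), "id")
  met_ids <- vapply(doc$metabolites, `[[`, character(1), "id")
  tr <- do.call(rbind, lapply(seq_along(doc$reactions), function(j) {
    st <- doc$reactions[[j]]$stoichiometry
    if (length(st) == 0) return(NULL)
    data.frame(i = match(names(st), met_ids), j = j,
               x = unlist(st, use.names = FALSE))
  }))
  S <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  model <- metabolicModel(
    S,
    lower_bound = vapply(doc$reactions, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(doc$reactions, `[[`, numeric(1), "upper_bound"),
    gpr = vapply(doc$reactions, `[[`, character(1), "gpr"),
    subsystem = vapply(doc$reactions, `[[`, character(1), "subsystem"),
    kind = vapply(doc$reactions, `[[`, character(1), "kind"),
    met_compartment = vapply(doc$metabolites, `[[`, character(1), "compartment"),
    met_name = vapply(doc$metabolites, `[[`, character(1), "name"),
    compartments = unlist(doc$compartments),
    genes = unlist(doc$genes)
  )
  model
}
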