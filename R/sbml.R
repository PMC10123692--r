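# SBML ingestion and export. Reads Level 2 (kinetic-law LOWER_BOUND /
# UPPER_BOUND parameters, GENE_ASSOCIATION notes) and Level 3 with the FBC
# package (flux-bound parameters, geneProductAssociation trees); when both
# bound encodings are present the FBC one wins. Writes Level 3 + FBC v2.
# Subsystems and reaction kinds travel in COBRA-style notes fields.

.xfind <- function(node, name, first = TRUE) {
  xp <- sprintf(".//*[local-name()='%s']", name)
  if (first) xml2::xml_find_first(node, xp) else xml2::xml_find_all(node, xp)
}

.noteField <- function(node, key) {
  notes <- .xfind(node, "notes")
  if (inherits(notes, "xml_missing")) return(NA_character_)
  ps <- .xfind(notes, "p", first = FALSE)
  txt <- if (length(ps)) xml2::xml_text(ps) else xml2::xml_text(notes)
  for (t in txt) {
    m <- regmatches(t, regexec(paste0("^\\s*", key, ":\\s*(.*)$"), t))[[1]]
    if (length(m) == 2) return(trimws(m[2]))
  }
  NA_character_
}

.fbcTreeToGPR <- function(node, gene_labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lab <- gene_labels[gid]
    return(if (!is.na(lab)) unname(lab) else gid)
  }
  kids <- xml2::xml_children(node)
  args <- lapply(kids, .fbcTreeToGPR, gene_labels = gene_labels)
  if (nm == "and" || nm == "or") {
    if (length(args) == 1) args[[1]] else list(op = nm, args = args)
  } else if (length(args) == 1) {
    args[[1]]
  } else {
    stop("unsupported geneProductAssociation node '", nm, "'")
  }
}

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 2 (legacy kinetic-law bounds, `GENE_ASSOCIATION`
#' notes) and Level 3 with the FBC package. Species flagged
#' `boundaryCondition="true"` are treated as outside the system boundary
#' and dropped, as is conventional for constraint-based analysis.
#'
#' @param path path to an SBML file.
#' @param default_bound box bound applied where the file specifies none
#'   (reversible reactions get `[-default_bound, default_bound]`,
#'   irreversible `[0, default_bound]`).
#' @return a [MetabolicModel].
#' @export
readSBML <- function(path, default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse SBML file '", path, "': ", conditionMessage(e))
  })
  xml2::xml_ns_strip(doc)
  model_node <- .xfind(doc, "model")
  if (inherits(model_node, "xml_missing")) {
    stop("not an SBML document (no <model> element): ", path)
  }

  comp_nodes <- .xfind(.xfind(doc, "listOfCompartments"), "compartment", FALSE)
  comps <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- .xfind(doc, "species", first = FALSE)
  sp <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    name = xml2::xml_attr(sp_nodes, "name"),
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE
  )
  sp$name[is.na(sp$name)] <- sp$id[is.na(sp$name)]
  interior <- sp[!sp$boundary, , drop = FALSE]

  # global parameters (FBC flux bounds refer to these)
  par_nodes <- .xfind(doc, "parameter", first = FALSE)
  par_ids <- xml2::xml_attr(par_nodes, "id")
  par_vals <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  params <- stats::setNames(par_vals, par_ids)

  gp_nodes <- .xfind(doc, "geneProduct", first = FALSE)
  gene_labels <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
           xml2::xml_attr(gp_nodes, "id"),
           xml2::xml_attr(gp_nodes, "label")),
    xml2::xml_attr(gp_nodes, "id"))

  rxn_nodes <- .xfind(doc, "reaction", first = FALSE)
  n <- length(rxn_nodes)
  if (n == 0) stop("SBML file contains no reactions: ", path)

  ids <- xml2::xml_attr(rxn_nodes, "id")
  triplets <- vector("list", n)
  lb <- ub <- numeric(n)
  gpr <- vector("list", n)
  gpr_string <- subsystem <- kind <- character(n)

  for (j in seq_len(n)) {
    rn <- rxn_nodes[[j]]
    stoich <- c()
    for (side in c("listOfReactants", "listOfProducts")) {
      side_node <- .xfind(rn, side)
      if (inherits(side_node, "xml_missing")) next
      refs <- .xfind(side_node, "speciesReference", FALSE)
      if (length(refs) == 0) next
      s <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      s[is.na(s)] <- 1
      if (side == "listOfReactants") s <- -s
      stoich <- c(stoich, stats::setNames(s, xml2::xml_attr(refs, "species")))
    }
    if (length(stoich)) {
      stoich <- tapply(stoich, names(stoich), sum)  # merge duplicate species
      stoich <- stoich[names(stoich) %in% interior$id]
    }
    triplets[[j]] <- stoich

    reversible <- !(xml2::xml_attr(rn, "reversible") %in% "false")
    lb_j <- if (reversible) -default_bound else 0
    ub_j <- default_bound
    # legacy kinetic-law bounds
    kl <- .xfind(rn, "kineticLaw")
    if (!inherits(kl, "xml_missing")) {
      kp <- .xfind(kl, "parameter", FALSE)
      kids <- xml2::xml_attr(kp, "id")
      kvals <- as.numeric(xml2::xml_attr(kp, "value"))
      if ("LOWER_BOUND" %in% kids) lb_j <- kvals[match("LOWER_BOUND", kids)]
      if ("UPPER_BOUND" %in% kids) ub_j <- kvals[match("UPPER_BOUND", kids)]
    }
    # FBC bounds win when present
    lbref <- xml2::xml_attr(rn, "lowerFluxBound")
    ubref <- xml2::xml_attr(rn, "upperFluxBound")
    if (!is.na(lbref) && lbref %in% names(params)) lb_j <- params[[lbref]]
    if (!is.na(ubref) && ubref %in% names(params)) ub_j <- params[[ubref]]
    lb[j] <- lb_j
    ub[j] <- ub_j

    gpa <- .xfind(rn, "geneProductAssociation")
    tree <- NULL
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) {
        tree <- .fbcTreeToGPR(kids[[1]], gene_labels)
      }
    } else {
      ga <- .noteField(rn, "GENE_ASSOCIATION")
      if (!is.na(ga) && nzchar(ga)) {
        tree <- tryCatch(parseGPR(ga), error = function(e) {
          stop("reaction '", ids[j], "': ", conditionMessage(e))
        })
      }
    }
    gpr[[j]] <- tree
    gpr_string[j] <- deparseGPR(tree)

    ss <- .noteField(rn, "SUBSYSTEM")
    subsystem[j] <- if (is.na(ss)) "" else ss
    kd <- .noteField(rn, "KIND")
    kind[j] <- if (is.na(kd)) NA_character_ else kd
  }

  mets_used <- unique(unlist(lapply(triplets, names)))
  met_order <- interior$id[interior$id %in% mets_used]
  tr <- do.call(rbind, lapply(seq_len(n), function(j) {
    st <- triplets[[j]]
    if (length(st) == 0) return(NULL)
    cbind(i = match(names(st), met_order), j = j, x = as.numeric(st))
  }))
  S <- Matrix::sparseMatrix(i = tr[, "i"], j = tr[, "j"], x = tr[, "x"],
                            dims = c(length(met_order), n),
                            dimnames = list(met_order, ids))

  touched <- Matrix::colSums(S != 0)
  infer <- ifelse(touched == 1,
                  ifelse(grepl("^(sink_|SK_|DM_)", ids), "sink", "exchange"),
                  "internal")
  kind <- ifelse(is.na(kind), infer, kind)

  met_rows <- interior[match(met_order, interior$id), , drop = FALSE]
  genes <- unique(c(unname(gene_labels), unlist(lapply(gpr, gprGenes))))
  if (length(comps) == 0) comps <- unique(met_rows$compartment)
  metabolicModel(S, lower_bound = lb, upper_bound = ub, gpr = gpr,
                 subsystem = subsystem, kind = kind,
                 met_compartment = met_rows$compartment,
                 met_name = met_rows$name, compartments = comps,
                 genes = genes)
}

.sanitizeSId <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", x), paste0("x_", x), x)
}

.gprToFBCXML <- function(gpr, gene_sids) {
  if (is.character(gpr)) {
    return(sprintf("<fbc:geneProductRef fbc:geneProduct=\"%s\"/>",
                   gene_sids[gpr]))
  }
  inner <- paste(vapply(gpr$args, .gprToFBCXML, character(1),
                        gene_sids = gene_sids), collapse = "")
  sprintf("<fbc:%s>%s</fbc:%s>", gpr$op, inner, gpr$op)
}

#' Write a model to SBML Level 3 with FBC
#'
#' Bounds are emitted as FBC flux-bound parameters, GPRs as
#' `geneProductAssociation` trees, and subsystem / kind annotations as
#' COBRA-style notes so that [readSBML()] round-trips the model.
#'
#' @param model a [MetabolicModel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSBML <- function(model, path) {
  rxn <- model@reactions
  met <- model@metabolites
  gene_sids <- stats::setNames(paste0("G_", .sanitizeSId(model@genes)),
                               model@genes)
  S <- model@stoichiometry
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) formatC(x, format = "g", digits = 17)

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    "<model id=\"model\" fbc:strict=\"false\">",
    "<listOfCompartments>",
    sprintf("<compartment id=\"%s\" constant=\"true\"/>",
            model@compartments),
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf(paste0("<species id=\"%s\" compartment=\"%s\" name=\"%s\" ",
                   "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
                   "constant=\"false\"/>"),
            met$id, met$compartment, esc(met$name)),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf("<parameter id=\"lb_%s\" value=\"%s\" constant=\"true\"/>",
            .sanitizeSId(rxn$id), num(rxn$lower_bound)),
    sprintf("<parameter id=\"ub_%s\" value=\"%s\" constant=\"true\"/>",
            .sanitizeSId(rxn$id), num(rxn$upper_bound)),
    "</listOfParameters>"
  )
  if (length(model@genes)) {
    out <- c(out, "<fbc:listOfGeneProducts>",
             sprintf("<fbc:geneProduct fbc:id=\"%s\" fbc:label=\"%s\"/>",
                     gene_sids, esc(model@genes)),
             "</fbc:listOfGeneProducts>")
  }
  out <- c(out, "<listOfReactions>")
  for (j in seq_len(nrow(rxn))) {
    col <- S[, j]
    nz <- which(col != 0)
    reactants <- nz[col[nz] < 0]
    products <- nz[col[nz] > 0]
    sid <- .sanitizeSId(rxn$id[j])
    out <- c(out, sprintf(
      paste0("<reaction id=\"%s\" reversible=\"%s\" fast=\"false\" ",
             "fbc:lowerFluxBound=\"lb_%s\" fbc:upperFluxBound=\"ub_%s\">"),
      rxn$id[j], tolower(rxn$lower_bound[j] < 0), sid, sid))
    out <- c(out, paste0(
      "<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
      "<p>SUBSYSTEM: ", esc(rxn$subsystem[j]), "</p>",
      "<p>KIND: ", rxn$kind[j], "</p>",
      "</body></notes>"))
    if (length(reactants)) {
      out <- c(out, "<listOfReactants>",
               sprintf(paste0("<speciesReference species=\"%s\" ",
                              "stoichiometry=\"%s\" constant=\"true\"/>"),
                       rownames(S)[reactants], num(-col[reactants])),
               "</listOfReactants>")
    }
    if (length(products)) {
      out <- c(out, "<listOfProducts>",
               sprintf(paste0("<speciesReference species=\"%s\" ",
                              "stoichiometry=\"%s\" constant=\"true\"/>"),
                       rownames(S)[products], num(col[products])),
               "</listOfProducts>")
    }
    if (!is.null(rxn$gpr[[j]])) {
      out <- c(out, "<fbc:geneProductAssociation>",
               .gprToFBCXML(rxn$gpr[[j]], gene_sids),
               "</fbc:geneProductAssociation>")
    }
    out <- c(out, "</reaction>")
  }
  out <- c(out, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}
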