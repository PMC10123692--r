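# End-to-end orchestration: model preparation, omics integration, iMAT
# sensitivity/robustness analysis per condition and threshold pair,
# pathway-level differential statistics, enrichment, signature extraction
# and hold-out validation, with a provenance manifest.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed integer seed for every stochastic stage.
#' @return a config list; fields can be overridden before [runPipeline()].
#' @export
pipelineConfig <- function(out_dir = tempfile("fluxrun"), seed = 1L) {
  list(
    model = NULL,               # MetabolicModel, or path to SBML/JSON
    expression = NULL,          # list(A=, B=): matrices or TSV paths
    metabolomics = NULL,        # list(A=, B=): data.frames or TSV paths
    gene_sets = NULL,           # named list or GMT path
    exchange_map = NULL,        # named metabolite -> exchange/sink reaction
    threshold_pairs = list(c(30, 70), c(33, 66), c(40, 60)),
    epsilon = 1,
    duration = 5,
    rate_bounds = TRUE,         # divide concentration differences by duration
    holdout_fraction = 0.2,     # measured metabolites reserved for validation
    diff_threshold = 0.10,
    alpha = 0.05,
    gsea_n_perm = 1000,
    vip_threshold = 1.5,
    n_components = 2,
    expand_lipids = NULL,       # named list lipid -> compartments, optional
    reduce = TRUE,
    seed = seed,
    out_dir = out_dir
  )
}

.loadModel <- function(x) {
  if (methods::is(x, "MetabolicModel")) return(x)
  if (is.character(x) && grepl("\\.json$", x)) return(modelFromJSON(x))
  if (is.character(x)) return(readSBML(x))
  stop("config$model must be a MetabolicModel or a path")
}

.loadExpr <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.character(x)) return(readExpressionTSV(x))
  stop("expression entries must be matrices or TSV paths")
}

.loadMetab <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.character(x)) return(readMetaboliteTSV(x))
  stop("metabolomics entries must be data.frames or TSV paths")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: model loading (+ optional lipid-boundary expansion and
#' reduction); metabolite bounds and their application per condition (with
#' a random hold-out reserved for validation); gene classification and
#' iMAT sensitivity analysis per condition and threshold pair; robustness
#' consensus; differential pathway and reaction calls; GSEA and PLS-DA/VIP
#' signature on the expression data; hold-out sign-agreement validation.
#' All stage outputs are written as TSV under `config$out_dir` together
#' with a `manifest.json` recording the configuration, package and solver
#' provenance, and an MD5 hash of every output. A failing stage aborts
#' with the stage name and leaves a `PARTIAL` marker file.
#'
#' @param config list from [pipelineConfig()] or a path to a YAML file with
#'   the same fields.
#' @return invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- pipelineConfig()
  for (nm in names(def)) if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$out_dir, "PARTIAL")
  file.create(marker)
  set.seed(config$seed)

  model <- .stage("model_prep", {
    m <- .loadModel(config$model)
    if (!is.null(config$expand_lipids)) {
      m <- expandLipidBoundary(m, config$expand_lipids)
    }
    if (isTRUE(config$reduce)) {
      red <- reduceModel(m)
      writeReductionReport(red$report,
                           file.path(config$out_dir, "reduction_report.tsv"))
      red$model
    } else m
  })

  expr <- .stage("omics_integration", {
    lapply(config$expression, .loadExpr)
  })
  if (!all(c("A", "B") %in% names(expr))) {
    stop("pipeline stage 'omics_integration' failed: expression needs ",
         "conditions A and B", call. = FALSE)
  }

  metab <- .stage("omics_integration",
                  lapply(config$metabolomics, .loadMetab))
  holdout <- list(A = character(), B = character())
  models <- list()
  bounds_tables <- list()
  for (cond in c("A", "B")) {
    models[[cond]] <- model
    if (!is.null(metab[[cond]])) {
      b <- .stage("omics_integration", {
        bb <- metaboliteBounds(metab[[cond]], duration = config$duration,
                               rate = config$rate_bounds,
                               reaction_map = config$exchange_map)
        bb <- bb[bb$reaction %in% model@reactions$id, , drop = FALSE]
        bb
      })
      n_hold <- floor(config$holdout_fraction * nrow(b))
      hold <- if (n_hold > 0) sample(b$metabolite, n_hold) else character()
      holdout[[cond]] <- hold
      applied <- b[!b$metabolite %in% hold, , drop = FALSE]
      models[[cond]] <- .stage("omics_integration",
                               applyExchangeBounds(model, applied,
                                                   on_conflict = "drop"))
      bounds_tables[[cond]] <- b
      writeTSV(applied, file.path(config$out_dir,
                                  paste0("exchange_bounds_", cond, ".tsv")))
    }
  }

  metabolic_genes <- unique(unlist(lapply(model@reactions$gpr, gprGenes)))
  callsets <- list(A = list(), B = list())
  for (cond in c("A", "B")) {
    for (pair in config$threshold_pairs) {
      cs <- .stage("imat_solver", {
        cls <- classifyGenes(expr[[cond]], pair[1], pair[2],
                             restrict_to = metabolic_genes)
        st <- reactionStates(models[[cond]], cls)
        sensitivityCalls(models[[cond]], st, epsilon = config$epsilon)
      })
      callsets[[cond]][[paste(pair, collapse = "/")]] <- cs
    }
  }
  consensus <- .stage("imat_solver", {
    lapply(callsets, robustnessConsensus)
  })
  for (cond in c("A", "B")) {
    writeTSV(activityCallTable(callsets[[cond]], consensus[[cond]], model),
             file.path(config$out_dir, paste0("activity_calls_", cond, ".tsv")))
  }

  pw <- .stage("pathway_analysis", {
    differentialPathways(callsets$A, callsets$B, model,
                         diff_threshold = config$diff_threshold,
                         alpha = config$alpha)
  })
  writeTSV(pw, file.path(config$out_dir, "pathway_comparison.tsv"))
  writeTSV(pathwayActivityLong(callsets$A, callsets$B, model),
           file.path(config$out_dir, "pathway_activity_long.tsv"))
  dr <- .stage("pathway_analysis",
               differentialReactions(consensus$A, consensus$B))
  writeTSV(dr, file.path(config$out_dir, "differential_reactions.tsv"))

  enr <- NULL
  if (!is.null(config$gene_sets)) {
    enr <- .stage("enrichment", {
      gs <- if (is.character(config$gene_sets)) readGMT(config$gene_sets)
            else config$gene_sets
      gsea(expr$A, expr$B, gs, n_perm = config$gsea_n_perm,
           seed = config$seed)
    })
    writeTSV(enr, file.path(config$out_dir, "gsea_results.tsv"))
  }

  sig <- .stage("enrichment", {
    v <- plsdaVip(expr$A, expr$B, n_components = config$n_components)
    s <- suppressWarnings(selectSignature(v, config$vip_threshold))
    writeGMT(list(vip_signature = s),
             file.path(config$out_dir, "vip_signature.gmt"))
    list(vip = v, signature = s)
  })

  validation <- NULL
  ho <- unique(c(holdout$A, holdout$B))
  if (length(ho) > 0) {
    validation <- .stage("validation", {
      res <- list()
      for (cond in c("A", "B")) {
        hold_cond <- holdout[[cond]]
        if (!length(hold_cond)) next
        b <- bounds_tables[[cond]]
        b <- b[b$metabolite %in% hold_cond, , drop = FALSE]
        emap <- stats::setNames(b$reaction, b$metabolite)
        pred <- predictExchangeSigns(consensus[[cond]], emap)
        obs <- stats::setNames((b$lb + b$ub) / 2, b$metabolite)
        res[[cond]] <- tryCatch(signAgreementTest(pred, obs),
                                error = function(e) NULL)
      }
      res
    })
    for (cond in names(validation)) {
      if (!is.null(validation[[cond]])) {
        writeTSV(validation[[cond]]$table,
                 file.path(config$out_dir,
                           paste0("validation_", cond, ".tsv")))
      }
    }
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, marker)
  manifest <- list(
    config = config[setdiff(names(config),
                            c("model", "expression", "metabolomics",
                              "gene_sets"))],
    package_version = as.character(utils::packageVersion("FluxActivity")),
    r_version = R.version.string,
    solver = "HiGHS (scipy.optimize.milp)",
    seed = config$seed,
    outputs = lapply(stats::setNames(nm = basename(outputs)), function(f) {
      unname(tools::md5sum(file.path(config$out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(marker)
  invisible(list(model = model, callsets = callsets, consensus = consensus,
                 pathways = pw, differential_reactions = dr,
                 enrichment = enr, signature = sig,
                 validation = validation, holdout = holdout,
                 out_dir = config$out_dir))
}
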