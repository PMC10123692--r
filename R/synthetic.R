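# Synthetic data with planted ground truth: toy stoichiometric networks,
# two-condition expression replicates, triplicate timed metabolomics, and
# gene sets with planted enrichment. The generator's defaults mirror the
# study design the package targets: four expression replicates per
# condition, triplicate concentration measurements at 0 and 5 h, and the
# 30/70, 33/66, 40/60 percentile threshold pairs downstream.

#' Generate a toy genome-scale model with planted activity states
#'
#' Builds `n_pathways` linear pathway chains that share one uptake hub
#' metabolite and each end in their own exchange reaction. Per condition
#' (A/B) each pathway is planted `active`, `inactive` or `moderate`; the
#' first and last pathways swap their active/inactive states between the
#' conditions, so they (and their reactions) are the planted differential
#' ground truth. `n_blocked` dangling side reactions producing dead-end
#' metabolites are planted for the model-reduction stage. Internal
#' reactions carry GPRs of 1-3 genes (AND/OR mixes) whose genes all share
#' the reaction's expression stratum, so GPR propagation recovers the
#' planted sets; exchange reactions carry no GPR. Planted states are
#' verified feasible by LP before the model is returned.
#'
#' @param n_pathways number of pathway chains (>= 2; default 4).
#' @param reactions_per_pathway reactions per chain including its exchange
#'   (>= 3; default 6).
#' @param n_blocked dangling blocked reactions to plant (default 2).
#' @param seed integer seed; the same seed reproduces the model exactly.
#' @param flux_active planted rate carried by an active chain (default 2).
#' @return list with `model` ([MetabolicModel]) and `truth`, a list holding
#'   per-reaction planted states per condition (`state_A`, `state_B`),
#'   per-subsystem states and differential flags, planted exchange fluxes
#'   per condition, the metabolite -> exchange map, per-gene strata
#'   (`gene_stratum_A`/`_B`), planted enriched gene sets (`enriched_up_A`,
#'   `enriched_up_B`) and `discriminative_genes`.
#' @export
generateToyGem <- function(n_pathways = 4, reactions_per_pathway = 6,
                           n_blocked = 2, seed = 1, flux_active = 2) {
  stopifnot(n_pathways >= 2, reactions_per_pathway >= 3)
  set.seed(seed)
  n_int <- reactions_per_pathway - 1  # internal reactions per chain

  equations <- c(EX_A = "A ->")
  lb <- c(-100); ub <- c(0)
  subsystem <- c("hub exchange")
  gpr <- c("")
  gene_count <- 0L
  gene_rxn <- list()

  # pathway states per condition: first pathway active in A / inactive in B,
  # last the reverse, the middle ones moderate in both (their genes supply
  # the moderate percentile mass that keeps class thresholds in the gaps
  # between expression strata).
  p_state_A <- c("active", rep("moderate", n_pathways - 2), "inactive")
  p_state_B <- c("inactive", rep("moderate", n_pathways - 2), "active")
  names(p_state_A) <- names(p_state_B) <- paste0("pathway_", seq_len(n_pathways))

  state_A <- c(EX_A = "moderate")
  state_B <- c(EX_A = "moderate")
  new_gene <- function() {
    gene_count <<- gene_count + 1L
    sprintf("g%03d", gene_count)
  }
  # GPR size cycles 1/2/3 deterministically along each chain so the three
  # expression strata keep fixed gene-mass proportions (~1/4 low, ~1/2 mid,
  # ~1/4 high) for every seed; only the AND/OR shape is randomized. All
  # genes of a reaction share its stratum, so any monotone AND/OR mix maps
  # high genes to +1 and low genes to -1.
  make_gpr <- function(ng) {
    form <- sample(3, 1)
    gs <- vapply(seq_len(ng), function(i) new_gene(), character(1))
    if (form == 1 || length(gs) == 1) {
      paste(gs, collapse = " and ")
    } else if (form == 2) {
      paste(gs, collapse = " or ")
    } else if (length(gs) == 3) {
      sprintf("(%s and %s) or %s", gs[1], gs[2], gs[3])
    } else {
      paste(gs, collapse = " or ")
    }
  }

  for (p in seq_len(n_pathways)) {
    prev <- "A"
    for (r in seq_len(n_int)) {
      met <- sprintf("M%d_%d", p, r)
      rid <- sprintf("P%d_R%d", p, r)
      equations[rid] <- paste(prev, "->", met)
      lb <- c(lb, 0); ub <- c(ub, 100)
      subsystem <- c(subsystem, sprintf("pathway_%d", p))
      g <- make_gpr(((r - 1) %% 3) + 1)
      gpr <- c(gpr, g)
      gene_rxn[[rid]] <- gprGenes(parseGPR(g))
      state_A[rid] <- p_state_A[p]
      state_B[rid] <- p_state_B[p]
      prev <- met
    }
    rid <- sprintf("EX_P%d", p)
    equations[rid] <- paste(prev, "->")
    lb <- c(lb, 0); ub <- c(ub, 100)
    subsystem <- c(subsystem, sprintf("pathway_%d", p))
    gpr <- c(gpr, "")
    state_A[rid] <- p_state_A[p]
    state_B[rid] <- p_state_B[p]
  }

  for (bkt in seq_len(n_blocked)) {
    src_p <- ((bkt - 1) %% n_pathways) + 1
    rid <- sprintf("BLK_%d", bkt)
    equations[rid] <- sprintf("M%d_1 -> DEAD_%d", src_p, bkt)
    lb <- c(lb, 0); ub <- c(ub, 100)
    subsystem <- c(subsystem, sprintf("pathway_%d", src_p))
    g <- new_gene()
    gpr <- c(gpr, g)
    gene_rxn[[rid]] <- g
    state_A[rid] <- "blocked"
    state_B[rid] <- "blocked"
  }

  model <- modelFromEquations(equations, lower_bound = lb, upper_bound = ub,
                              gpr = gpr, subsystem = subsystem)

  # per-gene expression strata implied by the planted reaction states
  stratum_of <- function(state) {
    switch(state, active = "high", inactive = "low", "mid")
  }
  gene_stratum <- function(states) {
    out <- c()
    for (rid in names(gene_rxn)) {
      out[gene_rxn[[rid]]] <- stratum_of(states[[rid]])
    }
    out
  }
  gs_A <- gene_stratum(state_A)
  gs_B <- gene_stratum(state_B)

  # measured-metabolite names: hub "A" for EX_A, "X<p>" for pathway products
  exch <- grep("^EX_", names(equations), value = TRUE)
  exch_met <- stats::setNames(exch, ifelse(exch == "EX_A", "A",
                                           sub("^EX_P", "X", exch)))

  planted_flux <- function(p_state) {
    f <- stats::setNames(numeric(length(exch)), exch)
    act <- names(p_state)[p_state == "active"]
    for (pw in act) {
      pid <- sub("pathway_", "", pw)
      f[paste0("EX_P", pid)] <- flux_active
    }
    f["EX_A"] <- -sum(f)
    f
  }
  flux_A <- planted_flux(p_state_A)
  flux_B <- planted_flux(p_state_B)

  truth <- list(
    state_A = state_A, state_B = state_B,
    pathway_state_A = p_state_A, pathway_state_B = p_state_B,
    differential_subsystems =
      names(p_state_A)[p_state_A != p_state_B],
    exchange_flux_A = flux_A, exchange_flux_B = flux_B,
    exchange_metabolite = exch_met,
    genes_by_reaction = gene_rxn,
    gene_stratum_A = gs_A, gene_stratum_B = gs_B,
    enriched_up_A = unname(unlist(
      gene_rxn[names(state_A)[state_A == "active" & state_B == "inactive"]])),
    enriched_up_B = unname(unlist(
      gene_rxn[names(state_B)[state_B == "active" & state_A == "inactive"]])),
    flux_active = flux_active
  )
  truth$discriminative_genes <- c(truth$enriched_up_A, truth$enriched_up_B)

  # verify the planted states admit a steady state in both conditions
  for (cond in c("A", "B")) {
    st <- truth[[paste0("state_", cond)]]
    chk <- model
    act <- names(st)[st == "active" & !grepl("^EX_", names(st))]
    ina <- names(st)[st == "inactive"]
    if (length(act)) chk <- setFluxBounds(chk, act, 1, 100)
    if (length(ina)) chk <- setFluxBounds(chk, ina, 0, 0)
    if (!isFeasible(chk)) {
      stop("internal error: planted states are infeasible for condition ",
           cond)
    }
  }
  list(model = model, truth = truth)
}

#' Generate two-condition expression replicates from planted strata
#'
#' Gene intensities live on a log-like scale with three well-separated
#' strata (low/mid/high at `levels`), a per-gene baseline offset shared by
#' both conditions, and Gaussian replicate noise with coefficient of
#' variation `cv`. A fraction `flip_fraction` of genes per condition is
#' mislabelled into a different stratum to emulate annotation/measurement
#' noise. With `flip_fraction = 0` the planted highly expressed genes sit
#' above the 70th percentile of the pooled distribution and the lowly
#' expressed ones below the 30th, so percentile classification recovers
#' the planted sets at every default threshold pair.
#'
#' @param model the toy [MetabolicModel] (supplies the gene universe).
#' @param truth ground-truth list from [generateToyGem()].
#' @param flip_fraction fraction of genes mislabelled per condition
#'   (0 <= flip < 0.5).
#' @param n_replicates replicates per condition (default 4).
#' @param cv replicate coefficient of variation (default 0.05).
#' @param seed integer seed.
#' @param levels numeric length-3 means of the low/mid/high strata.
#' @return list with matrices `A` and `B` (genes x replicates).
#' @export
generateExpression <- function(model, truth, flip_fraction = 0,
                               n_replicates = 4, cv = 0.05, seed = 1,
                               levels = c(low = 6, mid = 8, high = 10)) {
  stopifnot(flip_fraction >= 0, flip_fraction < 0.5)
  set.seed(seed)
  genes <- model@genes
  baseline <- stats::rnorm(length(genes), 0, 0.15)
  names(baseline) <- genes
  one_condition <- function(strata, tag) {
    strata <- strata[genes]
    n_flip <- floor(flip_fraction * length(genes))
    if (n_flip > 0) {
      pick <- sample(genes, n_flip)
      strata[pick] <- vapply(strata[pick], function(s) {
        sample(setdiff(c("low", "mid", "high"), s), 1)
      }, character(1))
    }
    mu <- levels[strata] + baseline
    mat <- vapply(seq_len(n_replicates), function(r) {
      stats::rnorm(length(genes), mu, cv * abs(mu))
    }, numeric(length(genes)))
    dimnames(mat) <- list(genes, paste0(tag, "_rep", seq_len(n_replicates)))
    mat
  }
  list(A = one_condition(truth$gene_stratum_A, "A"),
       B = one_condition(truth$gene_stratum_B, "B"))
}

#' Generate triplicate timed metabolite measurements from planted fluxes
#'
#' For every exchange metabolite, replicate concentrations at 0 h and at
#' `duration` h are drawn around `c0` and `c0 + rate * duration` with
#' multiplicative log-normal noise of coefficient of variation `cv`
#' (`cv = 0` reproduces the planted rate exactly through
#' [metaboliteBounds()]).
#'
#' @param truth ground-truth list from [generateToyGem()].
#' @param condition `"A"` or `"B"`.
#' @param duration sampling interval in hours (default 5).
#' @param cv multiplicative noise CV (default 0.1).
#' @param n_replicates replicates per time point (default 3).
#' @param seed integer seed.
#' @param c0 baseline concentration (per-cell normalized units).
#' @param include_zero_rates also report species with a planted rate of
#'   zero. Off by default: a species that is neither consumed nor secreted
#'   shows no concentration change and falls below the quantifiable change
#'   a timed-measurement design can report, so emitting it would plant
#'   pure-noise constraints no assay would produce.
#' @param include_hub also report the shared uptake-hub metabolite. Off by
#'   default: its net rate aggregates demand from every pathway, including
#'   those whose planted state is `moderate` (no flux claim), so
#'   constraining it caps total throughput and forces truth-undefined
#'   pathways into determinate calls -- an aggregation artifact, not an
#'   expression signal.
#' @return data.frame with columns `metabolite`, `compartment`, `c0`,
#'   `Sd0`, `c5`, `Sd5`, plus the planted `true_rate`.
#' @export
generateMetabolomics <- function(truth, condition = c("A", "B"),
                                 duration = 5, cv = 0.1, n_replicates = 3,
                                 seed = 1, c0 = 25,
                                 include_zero_rates = FALSE,
                                 include_hub = FALSE) {
  condition <- match.arg(condition)
  stopifnot(cv >= 0)
  set.seed(seed + match(condition, c("A", "B")))
  rates <- truth[[paste0("exchange_flux_", condition)]]
  if (!include_zero_rates) rates <- rates[rates != 0]
  if (!include_hub) rates <- rates[names(rates) != "EX_A"]
  met_of <- stats::setNames(names(truth$exchange_metabolite),
                            truth$exchange_metabolite)
  rows <- lapply(names(rates), function(rid) {
    true0 <- c0
    true5 <- c0 + rates[[rid]] * duration
    if (true5 <= 0) stop("baseline c0 too small for planted rate of ", rid)
    r0 <- true0 * stats::rlnorm(n_replicates, 0, cv)
    r5 <- true5 * stats::rlnorm(n_replicates, 0, cv)
    data.frame(metabolite = met_of[[rid]], compartment = "medium",
               c0 = mean(r0), Sd0 = stats::sd(r0),
               c5 = mean(r5), Sd5 = stats::sd(r5),
               true_rate = rates[[rid]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (cv == 0) out$Sd0 <- out$Sd5 <- 0
  out
}

#' Generate gene sets with planted enrichment plus size-matched null sets
#'
#' One set per planted enrichment direction (genes up in condition A, and
#' up in B when present) plus `n_null_sets` random sets of matched size
#' drawn from the model's gene universe.
#'
#' @param model the toy [MetabolicModel].
#' @param truth ground-truth list from [generateToyGem()].
#' @param n_null_sets number of random sets (default 10).
#' @param seed integer seed.
#' @return named list of character vectors; planted sets are named
#'   `planted_up_A` / `planted_up_B`.
#' @export
generateGeneSets <- function(model, truth, n_null_sets = 10, seed = 1) {
  set.seed(seed)
  sets <- list()
  if (length(truth$enriched_up_A)) sets$planted_up_A <- truth$enriched_up_A
  if (length(truth$enriched_up_B)) sets$planted_up_B <- truth$enriched_up_B
  size <- max(3, length(truth$enriched_up_A))
  for (i in seq_len(n_null_sets)) {
    sets[[sprintf("null_%02d", i)]] <- sample(model@genes,
                                              min(size, length(model@genes)))
  }
  sets
}

#' Generate a flat two-condition expression panel with planted shift
#'
#' A generic panel (independent of any metabolic model) for enrichment and
#' signature benchmarks: `n_genes` genes with unit-variance Gaussian
#' replicate noise, of which the first `n_up` are shifted up by `shift` in
#' condition A.
#'
#' @param n_genes panel size (default 200).
#' @param n_up planted up-shifted genes (default 20).
#' @param n_replicates samples per condition (default 4).
#' @param shift mean shift of the planted genes (default 3, i.e. three
#'   noise standard deviations, so planted genes are individually
#'   separable at small replicate numbers as a recovery benchmark
#'   requires).
#' @param seed integer seed.
#' @return list with matrices `A`, `B` and `up_genes`.
#' @export
generateExpressionPanel <- function(n_genes = 200, n_up = 20,
                                    n_replicates = 4, shift = 3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  base <- stats::rnorm(n_genes, 0, 1)
  draw <- function(mu, tag) {
    mat <- vapply(seq_len(n_replicates), function(r) {
      stats::rnorm(n_genes, mu, 1)
    }, numeric(n_genes))
    dimnames(mat) <- list(genes, paste0(tag, "_rep", seq_len(n_replicates)))
    mat
  }
  muA <- base + c(rep(shift, n_up), rep(0, n_genes - n_up))
  list(A = draw(muA, "A"), B = draw(base, "B"),
       up_genes = genes[seq_len(n_up)])
}
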