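# Pathway-level aggregation of activity calls and differential activity
# statistics between two conditions.

.subsystemOf <- function(model) {
  ss <- model@reactions$subsystem
  ifelse(is.na(ss) | !nzchar(ss), "unassigned", ss)
}

#' Pathway activity from reaction calls
#'
#' The activity state of a pathway (GEM subsystem) is the number of its
#' reactions called `active` divided by its total reaction count;
#' `undetermined` counts as not active. Reactions without a subsystem label
#' are grouped under `"unassigned"`.
#'
#' @param calls an [ActivityCallSet].
#' @param model the [MetabolicModel] supplying subsystem labels.
#' @return data.frame with columns `subsystem`, `n_active`, `n_total`,
#'   `ratio`, `thresholds`.
#' @export
pathwayActivity <- function(calls, model) {
  ids <- model@reactions$id
  cc <- calls@calls[ids]
  ss <- .subsystemOf(model)
  agg <- stats::aggregate(list(n_active = cc == "active"),
                          by = list(subsystem = ss), FUN = sum)
  tot <- stats::aggregate(list(n_total = rep(1L, length(ss))),
                          by = list(subsystem = ss), FUN = sum)
  out <- merge(agg, tot, by = "subsystem")
  out$n_active <- as.integer(out$n_active)
  out$ratio <- out$n_active / out$n_total
  out$thresholds <- paste(calls@thresholds, collapse = "/")
  out[order(out$subsystem), , drop = FALSE]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value by summation of hypergeometric probabilities not
#' exceeding that of the observed table. An all-zero table returns p = 1 by
#' convention.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`[[a, b], [c, d]]`).
#' @return the two-sided p-value.
#' @examples
#' fisherExact2x2(8, 2, 2, 8)  # ~0.0230
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(counts) == 0) return(1)
  stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value
}

#' Differentially activated pathways between two conditions
#'
#' For each subsystem and each threshold pair, the active / not-active
#' counts of the two conditions form a 2x2 table tested by Fisher's exact
#' test; p-values are Bonferroni-corrected by the number of subsystems
#' tested (capped at 1), and the maximum corrected p across threshold pairs
#' is retained. A pathway is differential when the absolute difference of
#' mean activity ratios exceeds `diff_threshold` (default 10%) and the
#' maximum corrected p is below `alpha`.
#'
#' @param callsA,callsB lists of [ActivityCallSet]s for conditions A and B,
#'   one per threshold pair, in matching order.
#' @param model the [MetabolicModel].
#' @param diff_threshold minimum absolute mean-ratio difference.
#' @param alpha significance level for the corrected p-value.
#' @return data.frame with per-subsystem mean ratios, `diff`
#'   (A - B), `max_bonferroni_p`, `differential`, plus `transport` (label
#'   suggests a transport subsystem; such pathways are conventionally
#'   excluded from summary figures) and `threshold_sensitive` (the spread
#'   of per-pair ratios within a condition itself exceeds
#'   `diff_threshold`).
#' @export
differentialPathways <- function(callsA, callsB, model,
                                 diff_threshold = 0.10, alpha = 0.05) {
  if (length(callsA) != length(callsB)) {
    stop("conditions analyzed at different numbers of threshold pairs")
  }
  pairsA <- vapply(callsA, function(x) paste(x@thresholds, collapse = "/"),
                   character(1))
  pairsB <- vapply(callsB, function(x) paste(x@thresholds, collapse = "/"),
                   character(1))
  if (!identical(pairsA, pairsB)) {
    stop("threshold pairs of the two conditions do not match")
  }
  actA <- lapply(callsA, pathwayActivity, model = model)
  actB <- lapply(callsB, pathwayActivity, model = model)
  subsystems <- sort(unique(actA[[1]]$subsystem))
  n_pairs <- length(callsA)
  n_tested <- length(subsystems)

  ratio_mat <- function(acts) {
    vapply(acts, function(df) df$ratio[match(subsystems, df$subsystem)],
           numeric(length(subsystems)))
  }
  rA <- ratio_mat(actA); rB <- ratio_mat(actB)
  if (is.null(dim(rA))) { rA <- matrix(rA, nrow = 1); rB <- matrix(rB, nrow = 1) }

  p_corr <- matrix(NA_real_, n_tested, n_pairs)
  for (k in seq_len(n_pairs)) {
    dfA <- actA[[k]]; dfB <- actB[[k]]
    for (s in seq_len(n_tested)) {
      ia <- match(subsystems[s], dfA$subsystem)
      ib <- match(subsystems[s], dfB$subsystem)
      p <- fisherExact2x2(dfA$n_active[ia], dfA$n_total[ia] - dfA$n_active[ia],
                          dfB$n_active[ib], dfB$n_total[ib] - dfB$n_active[ib])
      p_corr[s, k] <- min(1, p * n_tested)
    }
  }
  mean_A <- rowMeans(rA)
  mean_B <- rowMeans(rB)
  diff <- mean_A - mean_B
  maxp <- apply(p_corr, 1, max)
  spread <- pmax(apply(rA, 1, max) - apply(rA, 1, min),
                 apply(rB, 1, max) - apply(rB, 1, min))
  data.frame(
    subsystem = subsystems,
    mean_ratio_A = mean_A, mean_ratio_B = mean_B, diff = diff,
    max_bonferroni_p = maxp,
    differential = abs(diff) > diff_threshold & maxp < alpha,
    transport = grepl("transport", subsystems, ignore.case = TRUE),
    threshold_sensitive = spread > diff_threshold,
    stringsAsFactors = FALSE)
}

#' Reactions with consistent differential activity
#'
#' Reactions whose consensus call is `active` in exactly one condition and
#' `inactive` in the other; `undetermined` in either condition excludes the
#' reaction.
#'
#' @param consensusA,consensusB consensus [ActivityCallSet]s
#'   ([robustnessConsensus()]) on the same model.
#' @return data.frame with columns `reaction`, `active_in` (`"A"`/`"B"`).
#' @export
differentialReactions <- function(consensusA, consensusB) {
  ids <- names(consensusA@calls)
  if (!identical(sort(ids), sort(names(consensusB@calls)))) {
    stop("consensus call sets cover different reactions")
  }
  a <- consensusA@calls[ids]
  b <- consensusB@calls[ids]
  selA <- a == "active" & b == "inactive"
  selB <- a == "inactive" & b == "active"
  data.frame(reaction = c(ids[selA], ids[selB]),
             active_in = c(rep("A", sum(selA)), rep("B", sum(selB))),
             stringsAsFactors = FALSE)
}

#' Long-format pathway activity table for plotting
#'
#' @param callsA,callsB lists of per-threshold [ActivityCallSet]s.
#' @param model the [MetabolicModel].
#' @return data.frame (subsystem, condition, threshold_pair, ratio).
#' @export
pathwayActivityLong <- function(callsA, callsB, model) {
  rows <- list()
  for (cond in c("A", "B")) {
    calls <- if (cond == "A") callsA else callsB
    for (cs in calls) {
      act <- pathwayActivity(cs, model)
      rows[[length(rows) + 1]] <- data.frame(
        subsystem = act$subsystem, condition = cond,
        threshold_pair = act$thresholds, ratio = act$ratio,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
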