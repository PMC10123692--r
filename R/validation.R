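# Hold-out validation: compare predicted consumption/secretion signs of
# metabolites not used as constraints against measured rates.

#' Predict exchange signs from an activity-consistent solution
#'
#' The sign of each mapped exchange reaction's flux in the optimal solution
#' carried by `calls`: positive = secreted, negative = consumed. Reactions
#' whose consensus call is `undetermined`, or whose |flux| is below
#' `epsilon / 100`, abstain with `"none"`.
#'
#' @param calls an [ActivityCallSet] (its `fluxes` slot holds the optimal
#'   flux vector; its `epsilon` the activity threshold).
#' @param exchange_map named character vector metabolite -> exchange/sink
#'   reaction id.
#' @return named character vector over metabolites with values in
#'   `consumed`, `secreted`, `none`.
#' @export
predictExchangeSigns <- function(calls, exchange_map) {
  missing <- exchange_map[!exchange_map %in% names(calls@fluxes)]
  if (length(missing)) {
    stop("metabolites mapped to unknown reactions: ",
         paste(names(missing), collapse = ", "))
  }
  flux <- calls@fluxes[exchange_map]
  call <- calls@calls[exchange_map]
  out <- ifelse(call == "undetermined" | abs(flux) < calls@epsilon / 100,
                "none", ifelse(flux > 0, "secreted", "consumed"))
  stats::setNames(out, names(exchange_map))
}

#' Sign-agreement test of predicted vs observed exchange rates
#'
#' Metabolites with an abstaining prediction (`none`) or an observed rate
#' of (numerically) zero are excluded and reported. The remainder form a
#' 2x2 contingency table (predicted consumed/secreted x observed
#' consumed/secreted) tested with [fisherExact2x2()]; alternatively a
#' binomial test of the agreement fraction against 0.5.
#'
#' @param predicted named character vector from [predictExchangeSigns()].
#' @param observed named numeric vector of measured rates (positive =
#'   secretion) or character vector in `consumed`/`secreted`/`none`.
#' @param method `"fisher"` (contingency table, default) or `"binomial"`.
#' @param zero_tol observed |rate| below this counts as no observation.
#' @return list with `table` (per-metabolite data.frame), `n_compared`,
#'   `fraction_correct`, `p_value`, `excluded` (metabolite ids).
#' @export
signAgreementTest <- function(predicted, observed,
                              method = c("fisher", "binomial"),
                              zero_tol = 1e-12) {
  method <- match.arg(method)
  mets <- intersect(names(predicted), names(observed))
  if (length(mets) == 0) stop("no metabolites shared between the vectors")
  if (is.numeric(observed)) {
    obs <- ifelse(abs(observed[mets]) < zero_tol, "none",
                  ifelse(observed[mets] > 0, "secreted", "consumed"))
  } else {
    obs <- observed[mets]
  }
  pred <- predicted[mets]
  usable <- pred != "none" & obs != "none"
  if (!any(usable)) stop("no metabolite has both a prediction and an observation")
  tab <- data.frame(metabolite = mets[usable],
                    predicted = unname(pred[usable]),
                    observed = unname(obs[usable]),
                    agree = unname(pred[usable] == obs[usable]),
                    stringsAsFactors = FALSE)
  frac <- mean(tab$agree)
  if (method == "fisher") {
    a <- sum(tab$predicted == "consumed" & tab$observed == "consumed")
    b <- sum(tab$predicted == "consumed" & tab$observed == "secreted")
    cc <- sum(tab$predicted == "secreted" & tab$observed == "consumed")
    d <- sum(tab$predicted == "secreted" & tab$observed == "secreted")
    p <- fisherExact2x2(a, b, cc, d)
  } else {
    p <- stats::binom.test(sum(tab$agree), nrow(tab), p = 0.5,
                           alternative = "greater")$p.value
  }
  list(table = tab, n_compared = nrow(tab), fraction_correct = frac,
       p_value = p, excluded = mets[!usable])
}
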