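# Gene set enrichment analysis with phenotype permutation (Pearson ranking
# metric, weighted running-sum statistic, sign-matched normalization) and
# PLS-DA / VIP signature extraction.

.combineConditions <- function(exprA, exprB) {
  exprA <- as.matrix(exprA); exprB <- as.matrix(exprB)
  if (is.null(rownames(exprA)) || is.null(rownames(exprB))) {
    stop("expression matrices must carry gene rownames")
  }
  common <- intersect(rownames(exprA), rownames(exprB))
  if (length(common) == 0) stop("no genes shared between the two conditions")
  X <- cbind(exprA[common, , drop = FALSE], exprB[common, , drop = FALSE])
  pheno <- c(rep(1, ncol(exprA)), rep(0, ncol(exprB)))
  list(X = X, pheno = pheno)
}

.rankByPearson <- function(X, pheno) {
  sdp <- stats::sd(pheno)
  ctr <- pheno - mean(pheno)
  Xc <- X - rowMeans(X)
  sds <- sqrt(rowSums(Xc^2) / (ncol(X) - 1))
  num <- as.numeric(Xc %*% ctr) / (ncol(X) - 1)
  score <- ifelse(sds > 0, num / (sds * sdp), 0)
  ord <- order(-score, rownames(X))  # stable, deterministic tie-break
  data.frame(gene = rownames(X)[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

#' Rank genes by Pearson correlation with the phenotype
#'
#' Each gene's expression across all samples of the two conditions is
#' correlated with the phenotype vector (condition A encoded 1, condition B
#' encoded 0, so positive scores mean higher in A; an ordinal encoding can
#' be supplied for staged phenotypes). Genes with zero variance score 0.
#' The list is sorted by decreasing score with ties broken by gene id.
#'
#' @param exprA,exprB numeric matrices, genes x samples, with gene
#'   rownames; at least two samples per condition and three overall.
#' @param phenotype optional numeric phenotype vector over the combined
#'   samples (columns of A then B), overriding the 1/0 encoding.
#' @return data.frame with columns `gene`, `score`, sorted.
#' @export
pearsonRank <- function(exprA, exprB, phenotype = NULL) {
  cc <- .combineConditions(exprA, exprB)
  if (ncol(cc$X) < 3) stop("need at least three samples overall")
  if (min(ncol(as.matrix(exprA)), ncol(as.matrix(exprB))) < 2) {
    stop("need at least two samples per condition")
  }
  pheno <- if (is.null(phenotype)) cc$pheno else phenotype
  if (length(pheno) != ncol(cc$X)) stop("phenotype length mismatch")
  .rankByPearson(cc$X, pheno)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; hits (genes in the set) increment the running sum
#' by `|score|^p` normalized by the sum over hits, misses decrement by
#' `1 / (N - N_hits)`. The enrichment score is the signed maximum deviation
#' from zero; the leading edge contains the hits at or before the extremum
#' (after it, for negative ES), and the leading-edge signal is their
#' fraction of the set's in-list genes.
#'
#' @param ranked data.frame from [pearsonRank()] (columns `gene`, `score`).
#' @param gene_set character vector of gene ids.
#' @param weight_p weighting exponent (default 1, the weighted scheme).
#' @return list with `es`, `running` (profile along the list),
#'   `leading_edge` (gene ids), `leading_edge_signal`.
#' @export
enrichmentScore <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  hit <- genes %in% gene_set
  n <- length(genes)
  nh <- sum(hit)
  if (nh == 0) stop("gene set does not intersect the ranked list")
  if (nh == n) stop("gene set covers the entire ranked list")
  w <- abs(ranked$score)^weight_p
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - nh))
  if (sum(w[hit]) == 0) {                       # all-zero hit scores: flat hits
    inc[hit] <- 1 / nh
  }
  running <- cumsum(inc)
  i_max <- which.max(running)
  i_min <- which.min(running)
  es <- if (running[i_max] >= -running[i_min]) running[i_max] else running[i_min]
  if (es >= 0) {
    le <- genes[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    le <- genes[i_min:n][hit[i_min:n]]
  }
  list(es = es, running = running, leading_edge = le,
       leading_edge_signal = length(le) / nh)
}

#' Gene set enrichment analysis with phenotype permutation
#'
#' Ranks genes by the Pearson metric, computes the weighted enrichment
#' score of every set, and builds the null distribution by permuting the
#' phenotype labels `n_perm` times (re-ranking the full list each time).
#' NES divides each ES by the mean |null ES| of matching sign; the nominal
#' p is the matching-sign null tail fraction, and the FDR q-value follows
#' the sign-matched normalization of the original GSEA procedure (ratio of
#' the null and observed NES tail fractions, capped at 1).
#'
#' Two significance conventions are reported as flags:
#' `significant_strict` (FDR <= 0.1, NES > 1.5, leading-edge signal > 50%)
#' and `significant_fdr25` (FDR <= 0.25).
#'
#' @inheritParams pearsonRank
#' @param gene_sets named list of character vectors.
#' @param n_perm number of phenotype permutations (>= 10; default 1000).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @param weight_p weighting exponent for [enrichmentScore()].
#' @return data.frame, one row per gene set: `set`, `size`, `es`, `nes`,
#'   `nominal_p`, `fdr`, `leading_edge_signal`, `leading_edge` (comma
#'   separated), and the two significance flags.
#' @export
gsea <- function(exprA, exprB, gene_sets, n_perm = 1000, seed = 1L,
                 phenotype = NULL, weight_p = 1) {
  if (n_perm < 10) stop("n_perm must be at least 10")
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  cc <- .combineConditions(exprA, exprB)
  if (min(sum(cc$pheno == 1), sum(cc$pheno == 0)) < 2) {
    stop("phenotype permutation needs >= 2 samples per class")
  }
  pheno <- if (is.null(phenotype)) cc$pheno else phenotype
  sets <- lapply(gene_sets, intersect, y = rownames(cc$X))
  keep <- vapply(sets, length, integer(1)) > 0
  if (!all(keep)) {
    warning("dropping gene sets with no genes in the data: ",
            paste(names(sets)[!keep], collapse = ", "))
    sets <- sets[keep]
  }
  ranked <- .rankByPearson(cc$X, pheno)
  obs <- lapply(sets, function(s) enrichmentScore(ranked, s, weight_p))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  set.seed(seed)
  null_es <- matrix(NA_real_, length(sets), n_perm,
                    dimnames = list(names(sets), NULL))
  for (b in seq_len(n_perm)) {
    ph <- sample(pheno)
    rk <- .rankByPearson(cc$X, ph)
    for (i in seq_along(sets)) {
      null_es[i, b] <- enrichmentScore(rk, sets[[i]], weight_p)$es
    }
  }

  norm_one <- function(es, null_row) {
    pos <- null_row[null_row >= 0]
    neg <- null_row[null_row < 0]
    if (es >= 0) {
      m <- mean(pos)
      if (!length(pos) || m == 0) return(NA_real_)
      es / m
    } else {
      m <- mean(abs(neg))
      if (!length(neg) || m == 0) return(NA_real_)
      es / m
    }
  }
  nes_obs <- vapply(seq_along(sets), function(i) {
    norm_one(es_obs[i], null_es[i, ])
  }, numeric(1))
  nes_null <- t(vapply(seq_along(sets), function(i) {
    vapply(null_es[i, ], norm_one, numeric(1), null_row = null_es[i, ])
  }, numeric(n_perm)))

  nominal_p <- vapply(seq_along(sets), function(i) {
    nr <- null_es[i, ]
    if (es_obs[i] >= 0) {
      pos <- nr[nr >= 0]
      if (!length(pos)) return(1 / n_perm)
      mean(pos >= es_obs[i])
    } else {
      neg <- nr[nr < 0]
      if (!length(neg)) return(1 / n_perm)
      mean(neg <= es_obs[i])
    }
  }, numeric(1))

  all_null_nes <- as.numeric(nes_null)
  all_null_nes <- all_null_nes[is.finite(all_null_nes)]
  fdr <- vapply(seq_along(sets), function(i) {
    nes <- nes_obs[i]
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num_pool <- all_null_nes[all_null_nes >= 0]
      num <- if (length(num_pool)) mean(num_pool >= nes) else 0
      obs_pool <- nes_obs[is.finite(nes_obs) & nes_obs >= 0]
      den <- mean(obs_pool >= nes)
    } else {
      num_pool <- all_null_nes[all_null_nes < 0]
      num <- if (length(num_pool)) mean(num_pool <= nes) else 0
      obs_pool <- nes_obs[is.finite(nes_obs) & nes_obs < 0]
      den <- mean(obs_pool <= nes)
    }
    if (is.na(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  les <- vapply(obs, `[[`, numeric(1), "leading_edge_signal")
  data.frame(
    set = names(sets),
    size = vapply(sets, length, integer(1)),
    es = es_obs, nes = nes_obs, nominal_p = nominal_p, fdr = fdr,
    leading_edge_signal = les,
    leading_edge = vapply(obs, function(o) {
      paste(o$leading_edge, collapse = ",")
    }, character(1)),
    significant_strict = !is.na(fdr) & fdr <= 0.1 & nes_obs > 1.5 & les > 0.5,
    significant_fdr25 = !is.na(fdr) & fdr <= 0.25,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' PLS-DA variable importance in projection
#'
#' Fits a partial least squares discriminant model of the (autoscaled)
#' expression matrix against class membership and returns each gene's VIP
#' score over the first `n_components` components:
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a}}
#' with `SS_a` the class variance explained by component a. The scores
#' satisfy the identity `sum(VIP^2) = p` (number of genes).
#'
#' @inheritParams pearsonRank
#' @param n_components number of PLS components (default 2); needs
#'   `n_components + 1 <=` total samples.
#' @param scale autoscale genes to unit variance (default TRUE).
#' @return an object of class `VipScores`: list with `vip` (named numeric),
#'   `n_components`, and the fitted mixOmics model in `fit`.
#' @export
plsdaVip <- function(exprA, exprB, n_components = 2, scale = TRUE) {
  cc <- .combineConditions(exprA, exprB)
  if (length(unique(cc$pheno)) < 2) stop("need two classes")
  if (ncol(cc$X) < n_components + 1) {
    stop("need at least n_components + 1 samples")
  }
  X <- t(cc$X)  # samples x genes
  keep <- apply(X, 2, stats::sd) > 0
  if (!any(keep)) stop("all genes have zero variance")
  y <- factor(ifelse(cc$pheno == 1, "A", "B"))
  fit <- mixOmics::plsda(X[, keep, drop = FALSE], y, ncomp = n_components,
                         scale = scale)
  vip_mat <- mixOmics::vip(fit)
  vip <- stats::setNames(rep(0, ncol(X)), colnames(X))
  vip[rownames(vip_mat)] <- vip_mat[, n_components]
  structure(list(vip = vip, n_components = n_components, fit = fit),
            class = "VipScores")
}

#' @export
print.VipScores <- function(x, ...) {
  cat("VipScores over", length(x$vip), "genes,", x$n_components,
      "components; top:", paste(names(sort(x$vip, decreasing = TRUE))[1:3],
                                collapse = ", "), "\n")
  invisible(x)
}

#' Select a discriminative gene signature by VIP threshold
#'
#' @param vip a `VipScores` object from [plsdaVip()].
#' @param threshold inclusive VIP cutoff (default 1.5).
#' @return character vector of gene ids with VIP >= threshold; a warning
#'   is raised when the signature is empty.
#' @export
selectSignature <- function(vip, threshold = 1.5) {
  stopifnot(inherits(vip, "VipScores"))
  sel <- names(vip$vip)[vip$vip >= threshold]
  if (length(sel) == 0) {
    warning("no gene reaches VIP >= ", threshold, "; empty signature")
  }
  sel
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(gene_sets, path, description = "na") {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  desc <- rep_len(description, length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], desc[i], gene_sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
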