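# Shared fixtures, built in code.

# EX_A => A -> B => EX_B linear chain; interior reaction R1.
chain3_model <- function() {
  modelFromEquations(
    c(EX_A = "A ->", R1 = "A -> B", EX_B = "B ->"),
    lower_bound = c(-10, -1000, 0), upper_bound = c(0, 1000, 10))
}

# The branched chain used throughout the iMAT examples:
# EX_A => A, R1: A -> B (R_H), R2: B -> C (R_H), R3: B -> D (R_L),
# EX_C, EX_D.
branched_model <- function() {
  modelFromEquations(
    c(EX_A = "A ->", R1 = "A -> B", R2 = "B -> C", R3 = "B -> D",
      EX_C = "C ->", EX_D = "D ->"),
    lower_bound = c(-10, -10, -10, -10, 0, 0),
    upper_bound = c(0, 10, 10, 10, 10, 10))
}

# Random small steady-state instance for the MILP oracle tests. Bounds
# always contain 0, so v = 0 is feasible and the base model is never
# infeasible. Sizes of R_H/R_L are drawn with smaller totals more likely,
# spanning up to |R_H| + |R_L| = 10.
random_imat_instance <- function(seed, n_max = 12) {
  set.seed(seed)
  n <- sample(6:n_max, 1)
  m <- sample(3:(n - 2), 1)
  repeat {
    S <- matrix(0, m, n)
    for (j in seq_len(n)) {
      k <- sample(1:2, 1)
      rows <- sample(m, k)
      S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    }
    if (all(rowSums(S != 0) > 0)) break
  }
  dimnames(S) <- list(paste0("m", seq_len(m)), paste0("r", seq_len(n)))
  lb <- ifelse(stats::runif(n) < 0.5, -10, 0)
  ub <- rep(10, n)
  sizes <- 2:10
  total <- min(sample(sizes, 1, prob = 0.5^sizes), n)
  nH <- sample(0:total, 1)
  nL <- total - nH
  picks <- sample(n, total)
  RH <- if (nH) paste0("r", picks[seq_len(nH)]) else character(0)
  RL <- if (nL) paste0("r", picks[nH + seq_len(nL)]) else character(0)
  model <- metabolicModel(S, lower_bound = lb, upper_bound = ub,
                          kind = rep("internal", n))
  list(model = model, RH = RH, RL = RL, epsilon = 1)
}

# Minimal expression-state stand-in.
make_state <- function(RH, RL, percentiles = c(lower = 33, upper = 66)) {
  structure(list(RH = RH, RL = RL, percentiles = percentiles),
            class = "ReactionExpressionState")
}
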