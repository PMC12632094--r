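# Independent oracles used across the suite. These deliberately re-derive
# each quantity with the most literal formulation available (double loops,
# enumeration, closed forms) rather than calling package internals.

# PROMETHEE net flows by explicit outer-product preference tables.
oracle_net_flows <- function(X, w, missing_policy = "renormalize") {
  n <- nrow(X)
  pi_mat <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    S <- which(is.finite(X[a, ]) & is.finite(X[b, ]))
    if (!length(S) || sum(w[S]) == 0) next
    wS <- w[S]
    if (missing_policy == "renormalize") wS <- wS / sum(wS)
    pi_mat[a, b] <- sum(wS * (X[a, S] > X[b, S]))
  }
  phi_plus <- rowSums(pi_mat) / (n - 1)
  phi_minus <- colSums(pi_mat) / (n - 1)
  list(phi = phi_plus - phi_minus, phi_plus = phi_plus,
       phi_minus = phi_minus)
}

# Random criteria instance with a missingness mask (every row keeps at
# least one observation).
random_criteria_instance <- function(n, J, miss_frac = 0.2) {
  X <- matrix(rnorm(n * J), n, J,
              dimnames = list(sprintf("g%03d", seq_len(n)),
                              sprintf("c%d", seq_len(J))))
  if (miss_frac > 0) {
    X[sample(length(X), floor(miss_frac * length(X)))] <- NA
    empty <- rowSums(is.finite(X)) == 0L
    if (any(empty)) X[cbind(which(empty), 1L)] <- rnorm(sum(empty))
  }
  w <- runif(J)
  w <- w / sum(w)
  names(w) <- colnames(X)
  list(X = X, w = w)
}

# Step-by-step running-sum enrichment oracle.
oracle_running_es <- function(stat, set_genes, exponent = 1) {
  stat <- stat[order(-stat, names(stat))]
  N <- length(stat)
  hit <- names(stat) %in% set_genes
  k <- sum(hit)
  sumw <- sum(abs(stat[hit])^exponent)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) {
      if (sumw > 0) abs(stat[[i]])^exponent / sumw else 1 / k
    } else -1 / (N - k)
    run[i] <- cur
  }
  if (max(run) >= -min(run)) max(run) else min(run)
}

# One-sided hypergeometric tail probability by direct enumeration of all
# C(N, m) gene-set placements (feasible for N <= 12).
oracle_hyper_tail <- function(N, m, k, q) {
  placements <- utils::combn(N, m)
  mean(apply(placements, 2L, function(set) sum(set <= k) >= q))
}

# Closed-form OLS via normal equations.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Spearman rho via the classic rank-difference formula (valid without ties).
oracle_spearman_no_ties <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
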