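## Independent oracles used across the suite. Each re-derives a quantity by
## brute force (enumeration, grid search, permutation) without touching the
## package's own code path for that quantity.

## Exact two-sided Wilcoxon rank-sum p by full enumeration of group
## assignments (small n only).
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(length(vals), nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

## Upper-tail hypergeometric p by enumeration over all draws of size n.
oracle_hypergeom_p <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_set <- draws <= K   # first K elements form the set
  mean(colSums(in_set) >= k)
}

## Efron-tied Cox log partial likelihood for a single covariate, and its
## grid-search maximiser.
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    eta <- beta * x
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

oracle_cox_grid <- function(x, times, events, grid = seq(-4, 4, by = 1e-4)) {
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), x = x, times = times,
               events = events)
  grid[which.max(ll)]
}

## Vectorised two-group log-rank chi-square over B label permutations.
## Returns c(observed, perm...) chi-square values.
oracle_logrank_perm <- function(times, events, labels, B, seed = 1) {
  set.seed(seed)
  g1 <- as.numeric(as.factor(labels)) == 1
  L <- cbind(g1, replicate(B, sample(g1)))
  ev_times <- sort(unique(times[events == 1]))
  chisq <- numeric(ncol(L))
  U <- numeric(ncol(L)); V <- numeric(ncol(L))
  for (t in ev_times) {
    at_risk <- times >= t
    ev_here <- times == t & events == 1
    nr <- sum(at_risk); d <- sum(ev_here)
    n1 <- colSums(L[at_risk, , drop = FALSE])
    o1 <- colSums(L[ev_here, , drop = FALSE])
    U <- U + o1 - d * n1 / nr
    if (nr > 1)
      V <- V + d * (n1 / nr) * (1 - n1 / nr) * (nr - d) / (nr - 1)
  }
  unname(U^2 / V)
}

## Brute-force TMM factor of one sample against a reference: weighted
## trimmed mean of M-values (30% trim on M, 5% on A, precision weights).
oracle_tmm_factor <- function(obs, ref) {
  no <- sum(obs); nr <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / no) / (ref / nr))
  a <- (log2(obs / no) + log2(ref / nr)) / 2
  w <- (no - obs) / (no * obs) + (nr - ref) / (nr * ref)
  n <- length(m)
  lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

## BH step-up by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

## Small deterministic survival fixture.
surv_fixture_n8 <- function() {
  list(x = c(1, 1, 1, 1, 0, 0, 0, 0),
       times = c(2, 4, 5.5, 9, 3, 6, 7.5, 10),
       events = c(1, 1, 0, 1, 1, 1, 1, 0))
}
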