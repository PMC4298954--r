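# Independent oracles used across the suite. Each is a deliberately naive
# computation (explicit formulas, exhaustive enumeration, numeric
# integration) kept free of the code paths it checks.

# mid-ranks computed from first principles (count-below + ties)
oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Spearman rho as rank-then-Pearson with the explicit product-moment formula
oracle_spearman_rho <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# exact permutation p-value for Spearman rho by full enumeration
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  perms <- sramtools:::.all_permutations(n)
  obs <- abs(oracle_spearman_rho(x, y))
  hits <- apply(perms, 1, function(idx)
    abs(oracle_spearman_rho(x, y[idx])) >= obs - 1e-12)
  mean(hits)
}

# two-sided Wilcoxon rank-sum p-value by enumeration of all group labelings
oracle_wilcoxon_perm_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- oracle_midrank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# hypergeometric tail P(overlap >= k) by exhaustive enumeration of draws
oracle_hyper_enum_p <- function(k, n_universe, n_marked, n_draw) {
  combos <- utils::combn(n_universe, n_draw)
  marked <- seq_len(n_marked)          # wlog the first n_marked items
  hits <- apply(combos, 2, function(idx) sum(idx %in% marked) >= k)
  mean(hits)
}

# P(p_up > p_down | counts, Dirichlet prior) by numeric double integration
# over the simplex on a fine Simpson grid
oracle_posterior_integral <- function(n_up, n_down, n_const,
                                      prior = c(1, 1, 1), m = 801) {
  a1 <- prior[1] + n_up; a2 <- prior[2] + n_down; a3 <- prior[3] + n_const
  u <- seq(1e-9, 1 - 1e-9, length.out = m)
  wt <- rep(c(2, 4), length.out = m); wt[1] <- 1; wt[m] <- 1   # Simpson
  h <- u[2] - u[1]
  dens <- function(p1, p2) {
    p3 <- 1 - p1 - p2
    ifelse(p3 <= 0, 0,
           exp((a1 - 1) * log(p1) + (a2 - 1) * log(p2) + (a3 - 1) * log(p3)))
  }
  inner <- function(p1, upper) {       # integrate p2 on (0, upper)
    vapply(seq_along(p1), function(i) {
      if (upper[i] <= 0) return(0)
      v <- seq(1e-12, upper[i] - 1e-12, length.out = m)
      hh <- v[2] - v[1]
      sum(wt * dens(p1[i], v)) * hh / 3
    }, numeric(1))
  }
  num <- sum(wt * inner(u, pmin(u, 1 - u))) * h / 3      # region p2 < p1
  den <- sum(wt * inner(u, 1 - u)) * h / 3               # whole simplex
  num / den
}

# Monte-Carlo posterior via Dirichlet sampling (gamma construction)
oracle_posterior_mc <- function(n_up, n_down, n_const, prior = c(1, 1, 1),
                                n_draw = 1e6) {
  g1 <- stats::rgamma(n_draw, prior[1] + n_up)
  g2 <- stats::rgamma(n_draw, prior[2] + n_down)
  mean(g1 > g2)   # p_const cancels from the comparison
}

# BFS distances by explicit frontier expansion on an edge list
oracle_bfs <- function(edges, nodes, from) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  d[from] <- 0
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.infinite(d[nxt])]
    d[nxt] <- d[frontier[1]] + 1
    frontier <- nxt
  }
  d
}

# hand running-sum for the weighted KS enrichment statistic
oracle_running_sum <- function(scores, hit, weight) {
  n <- length(scores)
  w <- abs(scores)^weight
  nr <- sum(w[hit])
  rs <- numeric(n); cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) w[i] / nr else -1 / (n - sum(hit))
    rs[i] <- cur
  }
  rs
}
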