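test_that("probe collapse averages correlated probes and passes singletons", {
  s <- paste0("S", 1:4)
  # two probes tracking each other (R > 0.4) -> per-sample mean
  m <- rbind(p1 = c(1, 2, 3, 4), p2 = c(1.2, 2.1, 3.3, 4.0),
             p3 = c(5, 5.5, 6, 6.5))
  colnames(m) <- s
  map <- c(p1 = "GA", p2 = "GA", p3 = "GB")
  out <- collapse_expression_probes(m, map)
  expect_equal(out["GA", ], colMeans(m[c("p1", "p2"), ]))
  expect_equal(out["GB", ], m["p3", ])

  # three mutually correlated probes -> mean of all three, hand-checked
  m3 <- rbind(a = c(1, 2, 3, 4), b = c(1.1, 2.2, 2.9, 4.2),
              c = c(0.9, 1.8, 3.2, 3.9))
  colnames(m3) <- s
  cm <- cor(t(m3))
  expect_true(all(cm[upper.tri(cm)] >= 0.4))
  out3 <- collapse_expression_probes(m3, c(a = "G", b = "G", c = "G"))
  hand <- (m3["a", ] + m3["b", ] + m3["c", ]) / 3
  expect_equal(out3["G", ], hand, tolerance = 1e-12)
})

test_that("probe collapse tie-break keeps largest correlated subset, else top-expressed probe", {
  s <- paste0("S", 1:6)
  set.seed(1)
  base <- seq(1, 6)
  # a and b correlated; c anti-correlated with both -> subset {a, b}
  m <- rbind(a = base + rnorm(6, 0, 0.1), b = base + rnorm(6, 0, 0.1),
             c = rev(base))
  colnames(m) <- s
  out <- collapse_expression_probes(m, c(a = "G", b = "G", c = "G"))
  expect_equal(out["G", ], colMeans(m[c("a", "b"), ]), tolerance = 1e-12)

  # no correlated pair -> highest-mean probe passes through
  m2 <- rbind(a = c(1, 6, 2, 5, 3, 4), b = c(6, 1, 5, 2, 4, 3) + 10)
  colnames(m2) <- s
  expect_lt(cor(m2["a", ], m2["b", ]), 0.4)
  out2 <- collapse_expression_probes(m2, c(a = "G", b = "G"))
  expect_equal(out2["G", ], m2["b", ])

  # constant probe excluded from screening with warning
  m3 <- rbind(a = rep(5, 6), b = base)
  colnames(m3) <- s
  expect_warning(out3 <- collapse_expression_probes(m3, c(a = "G", b = "G")),
                 "constant")
  expect_equal(out3["G", ], m3["b", ])
})

test_that("Spearman screen matches rank-then-Pearson oracle, including ties", {
  # perfect anti-monotone
  st <- spearman_test(c(0.1, 0.2, 0.3, 0.4, 0.5), c(5, 4, 3, 2, 1))
  expect_equal(st$rho, -1)
  # constant input -> untested
  expect_true(is.na(spearman_test(rep(0.5, 8), rnorm(8))$rho))

  # tied 8-sample fixture vs brute-force mid-rank oracle
  x <- c(0.1, 0.1, 0.3, 0.3, 0.3, 0.7, 0.8, 0.8)
  y <- c(5, 6, 5, 4, 3, 2, 2, 1)
  st <- spearman_test(x, y)
  expect_equal(st$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
  # exact permutation p for n < 10 equals full enumeration
  x6 <- c(1, 2, 2, 3, 4, 5); y6 <- c(3, 1, 4, 2, 6, 5)
  expect_equal(spearman_test(x6, y6)$p_value,
               oracle_spearman_perm_p(x6, y6), tolerance = 1e-12)

  # property: implementation equals oracle on random fixtures with ties
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    xx <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    yy <- rnorm(n) - 2 * xx
    expect_equal(spearman_test(xx, yy)$rho, oracle_spearman_rho(xx, yy),
                 tolerance = 1e-12)
  }
})

test_that("screen handles NA policy, unmapped probes and multi-mapped probes", {
  p <- make_tiny_panel(n_samples = 12)
  p$beta["cg1", 1:2] <- NA                    # pairwise-complete
  p$probe_annot$gene_symbol[2] <- NA          # unmapped
  p$probe_annot$gene_symbol[3] <- "G3;G4"     # multi-mapped
  validate_panel(p)
  tab <- suppressMessages(spearman_screen(p))
  expect_equal(nrow(tab), 5)                  # cg3 tested twice
  expect_equal(tab$n_pairs[tab$probe_id == "cg1"], 10L)
  expect_false(tab$tested[tab$probe_id == "cg2"])
  expect_true(all(tab$multi_mapped[tab$probe_id == "cg3"]))
})

test_that("BUM fit recovers pure null and planted mixtures", {
  set.seed(31)
  # pure uniform: pure-null limit
  fit0 <- fit_bum(runif(10000))
  expect_true(fit0$a_hat > 0.9 || fit0$lambda_hat > 0.9)
  expect_gte(fit0$pi0_upper, 0.95)

  # 30% Beta(0.1, 1) + 70% uniform: lambda recovered within +-0.05
  p <- c(rbeta(3000, 0.1, 1), runif(7000))
  fit <- fit_bum(p)
  expect_lt(abs(fit$lambda_hat - 0.7), 0.05)

  # all p near 1: degenerate flat fit
  fit1 <- fit_bum(rep(1 - 1e-9, 200))
  expect_gt(fit1$pi0_upper, 0.99)

  # local-optimum sanity: fitted likelihood beats 100 random parameter draws
  ll <- function(lambda, a, pv)
    sum(log(lambda + (1 - lambda) * a * pv^(a - 1)))
  set.seed(99)
  rand_ll <- replicate(100, ll(runif(1), runif(1), p))
  expect_gte(fit$log_lik, max(rand_ll))
})

test_that("SRAM calls require both criteria and are monotone in the cutoffs", {
  set.seed(5)
  tab <- data.frame(
    probe_id = paste0("cg", 1:300), gene_symbol = paste0("G", 1:300),
    rho = c(-0.6, -0.6, runif(298, -0.4, 0.4)),
    p_value = c(1e-6, 0.5, runif(298, 0.05, 1)),
    tested = TRUE, cpg_island = TRUE, tss_distance = 0L,
    stringsAsFactors = FALSE)
  bum <- fit_bum(c(tab$p_value, runif(1000)))
  called <- call_srams(tab, bum)
  expect_true(called$is_sram[1])               # rho -0.6, tiny p
  expect_false(called$is_sram[2])              # rho -0.6 but p = 0.5
  # monotonicity: tightening either cutoff never adds calls
  loose <- call_srams(tab, bum, rho_cutoff = -0.4, fdr_cutoff = 0.05)
  tight <- call_srams(tab, bum, rho_cutoff = -0.6, fdr_cutoff = 0.005)
  expect_true(all(!tight$is_sram | loose$is_sram))
  # fdr-only mode drops the rho criterion
  only <- call_srams(tab, bum, fdr_only = TRUE)
  expect_true(all(called$is_sram <= only$is_sram | !called$is_sram))
})

test_that("rho distribution report: null gives no excess, contamination is detected", {
  set.seed(17)
  n <- 4000
  make_tab <- function(rho) data.frame(
    probe_id = paste0("cg", seq_along(rho)),
    gene_symbol = paste0("G", seq_along(rho)), rho = rho,
    p_value = runif(length(rho)), tested = TRUE,
    cpg_island = rep(c(TRUE, FALSE), length.out = length(rho)),
    tss_distance = 0L, stringsAsFactors = FALSE)

  null_tab <- make_tab(rnorm(n, 0, 0.12))
  rep0 <- rho_distribution_report(null_tab)
  expect_lt(abs(rep0$cpgi$excess_at_cutoff), 3 * sqrt(n / 2 * 1e-3) + 3)
  expect_gt(rep0$cpgi$binomial_p, 0.001)

  contaminated <- make_tab(c(rnorm(round(0.97 * n), 0, 0.12),
                             rnorm(n - round(0.97 * n), -0.7, 0.05)))
  rep1 <- rho_distribution_report(contaminated)
  expect_lt(rep1$cpgi$binomial_p, 1e-6)
  expect_gt(rep1$cpgi$excess_at_cutoff, 20)
  expect_lt(rep1$cpgi$crossing_point, 0)

  # identical SRAM fractions across strata -> two-proportion p near 1
  eq_tab <- make_tab(rep(c(-0.6, -0.6, 0.2, 0.3), n / 4))
  eq_tab$is_sram <- eq_tab$rho <= -0.5
  rep2 <- rho_distribution_report(eq_tab)
  expect_gt(rep2$stratum_comparison$p_value, 0.95)
})

test_that("TSS proximity fraction counts SRAM probes inside the window", {
  tab <- data.frame(probe_id = paste0("cg", 1:4),
                    gene_symbol = paste0("G", 1:4),
                    rho = -0.7, p_value = 1e-5, tested = TRUE,
                    cpg_island = TRUE,
                    tss_distance = c(100L, -400L, 900L, NA),
                    is_sram = c(TRUE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  expect_equal(tss_proximity_fraction(tab), 2 / 3)
  tab$tss_distance <- c(0L, 0L, 0L, 5L)
  expect_equal(tss_proximity_fraction(tab), 1)
  tab$is_sram[4] <- TRUE; tab$tss_distance[4] <- NA
  expect_message(f <- tss_proximity_fraction(tab), "missing tss_distance")
  expect_equal(f, 1)
})
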