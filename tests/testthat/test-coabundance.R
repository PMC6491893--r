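test_that("BY adjustment reproduces the hand-evaluated example", {
  q <- by_adjust(c(0.01, 0.02, 0.04))
  expect_equal(q, c(0.055, 0.055, 0.0733333333333333), tolerance = 1e-12)
})

test_that("BY adjustment degenerate cases behave as the formula dictates", {
  expect_equal(by_adjust(0.03, m = 1), 0.03)          # c(1) = 1
  expect_equal(by_adjust(rep(0.2, 5)), rep(by_adjust(rep(0.2, 5))[1], 5))
  expect_error(by_adjust(c(0.1, 0.2), m = 1), "family size")
  # m larger than the vector inflates by the larger family
  expect_equal(by_adjust(0.01, m = 3), min(1, 0.01 * 3 * (11 / 6) / 1))
})

test_that("BY matches a brute-force step-up on random p-vectors", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    p <- round(runif(n), sample(1:4, 1))   # rounding forces ties
    m <- n + sample(0:10, 1)
    expect_equal(by_adjust(p, m), oracle_by(p, m), tolerance = 1e-12)
  }
})

test_that("monotone pairs give Spearman +1 / -1 with p = 0", {
  m <- rbind(up1 = 1:6, up2 = c(2, 4, 8, 16, 32, 64), down = 6:1)
  co <- spearman_matrix(m + 0)
  expect_equal(co$rho["up1", "up2"], 1)
  expect_equal(co$rho["up1", "down"], -1)
  expect_equal(co$pval["up1", "up2"], 0)
})

test_that("ties and zeros follow average-rank Pearson exactly", {
  x <- c(1, 2, 2, 4); y <- c(2, 3, 3, 5)
  co <- spearman_matrix(rbind(a = x, b = y))
  expect_equal(co$rho["a", "b"], oracle_spearman(x, y), tolerance = 1e-12)
  z1 <- c(0, 0, 1, 3, 2, 0); z2 <- c(0, 1, 0, 2, 3, 1)
  co2 <- spearman_matrix(rbind(a = z1, b = z2))
  expect_equal(co2$rho["a", "b"], oracle_spearman(z1, z2), tolerance = 1e-12)
})

test_that("a constant genus is kept with rho 0, p 1 and a warning", {
  m <- rbind(flat = rep(0.2, 5), var = c(1, 2, 3, 4, 5))
  expect_warning(co <- spearman_matrix(m), "constant genus")
  expect_equal(co$rho["flat", "var"], 0)
  expect_equal(co$pval["flat", "var"], 1)
  expect_true(all(co$genera == c("flat", "var")))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(4)
  m <- matrix(rexp(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("S", 1:10)))
  co <- spearman_matrix(m)
  m2 <- m
  m2[1, ] <- exp(m2[1, ])
  m2[2, ] <- log(m2[2, ] + 1)
  m2[3, ] <- 3 * m2[3, ] + 7
  co2 <- spearman_matrix(m2)
  expect_equal(co$rho, co2$rho, tolerance = 1e-12)
  expect_equal(co$qval, co2$qval, tolerance = 1e-12)
})

test_that("q-values dominate p-values and matrices stay symmetric", {
  set.seed(5)
  m <- matrix(runif(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("S", 1:10)))
  co <- spearman_matrix(m)
  ut <- upper.tri(co$rho)
  expect_true(all(co$qval[ut] >= co$pval[ut]))
  expect_equal(co$rho, t(co$rho))
  expect_equal(co$qval, t(co$qval))
  expect_equal(unname(diag(co$rho)), rep(1, 6))
})

test_that("edge significance is strict on both thresholds", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.5        # exactly at the boundary
  rho[1, 3] <- rho[3, 1] <- 0.9
  rho[2, 3] <- rho[3, 2] <- -0.8
  co <- corr_fixture(rho)
  e <- significant_edges(co)
  expect_identical(nrow(e), 2L)        # 0.5 excluded by strict >
  expect_identical(e$sign[e$genus_i == "g1" & e$genus_j == "g3"], 1)
  expect_identical(e$sign[e$genus_i == "g2" & e$genus_j == "g3"], -1)
  all_e <- significant_edges(co, all = TRUE)
  expect_identical(nrow(all_e), 3L)
  expect_false(all_e$significant[all_e$genus_i == "g1" & all_e$genus_j == "g2"])
})

test_that("block-diagonal correlation yields the planted two groups", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[3, 4] <- rho[4, 3] <- 0.9
  co <- corr_fixture(rho)
  prev <- c(g1 = 0.8, g2 = 0.7, g3 = 0.99, g4 = 0.9)
  g <- build_groups(co, prev)
  part <- attr(g, "partition")
  expect_identical(unname(part["g3"]), unname(part["g4"]))
  expect_identical(unname(part["g1"]), unname(part["g2"]))
  expect_false(part[["g1"]] == part[["g3"]])
  # group size ties broken by mean prevalence: {g3,g4} has the higher mean
  expect_identical(unname(part["g3"]), "C1")
})

test_that("uncorrelated genera all end up as singletons", {
  set.seed(6)
  rho <- diag(5)
  rho[upper.tri(rho)] <- runif(10, -0.05, 0.05)
  rho[lower.tri(rho)] <- t(rho)[lower.tri(rho)]
  co <- corr_fixture(rho)
  g <- build_groups(co, setNames(rep(0.8, 5), paste0("g", 1:5)))
  expect_identical(length(unique(g$group)), 5L)
})

test_that("grouping is a partition, stable under genus permutation", {
  set.seed(7)
  cfg <- synthetic_config(n_samples = 60, n_genera = 12,
                          group_sizes = c(4L, 3L), factor_corr = diag(2),
                          dropout = rep(0, 12), noise_sd = 0.4, seed = 3)
  sim <- generate_community(cfg)
  rel <- to_relative(sim$counts)
  co <- spearman_matrix(rel)
  prev <- prevalence(rel)
  g1 <- build_groups(co, prev)
  expect_setequal(g1$genus, rel$genus_ids)
  perm <- sample(rel$genus_ids)
  co2 <- spearman_matrix(rel$rel_abund[perm, ])
  g2 <- build_groups(co2, prev[perm])
  p1 <- attr(g1, "partition"); p2 <- attr(g2, "partition")
  # same partition up to group relabeling
  expect_equal(coregut:::.adjusted_rand(p1[names(p2)], p2), 1)
})

test_that("within-group genus order follows descending prevalence", {
  rho <- diag(3); rho[] <- 0.9; diag(rho) <- 1
  co <- corr_fixture(rho)
  g <- build_groups(co, c(g1 = 0.5, g2 = 0.9, g3 = 0.7))
  expect_identical(g$genus, c("g2", "g3", "g1"))
})

test_that("intergroup summaries count signed significant edges", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[3, 4] <- rho[4, 3] <- 0.9
  rho[1, 3] <- rho[3, 1] <- -0.7
  rho[1, 4] <- rho[4, 1] <- -0.7
  rho[2, 3] <- rho[3, 2] <- -0.7
  rho[2, 4] <- rho[4, 2] <- -0.7
  co <- corr_fixture(rho)
  g <- build_groups(co, c(g1 = 0.9, g2 = 0.9, g3 = 0.8, g4 = 0.8))
  s <- intergroup_summary(g, co)
  expect_identical(nrow(s), 1L)
  expect_equal(s$mean_rho, -0.7)
  expect_identical(s$n_neg_sig, 4L)
  expect_identical(s$n_pos_sig, 0L)
})

test_that("a neutral singleton group has no significant edges to others", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[1, 3] <- rho[3, 1] <- 0.1
  rho[2, 3] <- rho[3, 2] <- -0.15
  co <- corr_fixture(rho)
  g <- build_groups(co, c(g1 = 0.9, g2 = 0.8, g3 = 0.6))
  s <- intergroup_summary(g, co)
  solo <- s[s$group_a == "C2" | s$group_b == "C2", ]
  expect_true(all(solo$n_pos_sig + solo$n_neg_sig == 0))
})

test_that("cross-block correlations track the configured factor coupling", {
  R <- diag(2); R[1, 2] <- R[2, 1] <- -0.6
  cfg <- synthetic_config(n_samples = 300, n_genera = 40,
                          group_sizes = c(5L, 5L), factor_corr = R,
                          dropout = rep(0, 40), noise_sd = 0.3, seed = 5)
  sim <- generate_community(cfg)
  rel <- to_relative(sim$counts)
  co <- spearman_matrix(rel, genera = sprintf("g%03d", 1:10))
  cross <- co$rho[1:5, 6:10]
  expect_lt(mean(cross), -0.25)          # sign and rough magnitude
  within <- co$rho[1:5, 1:5][upper.tri(diag(5))]
  expect_gt(mean(within), 0.5)
})
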