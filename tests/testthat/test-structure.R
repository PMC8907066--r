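# Rank tests, mixture fits, the independent-mixture residual model, and kin
# detection.

# one small simulated dataset shared across several tests
local_sim <- local({
  sc <- cline_scenario(
    sites = data.frame(site_id = c("P", "Q", "R"),
                       cluster = c("p", "q", "r"),
                       lat = c(0, -2, -4), lon = c(33, 34, 35)),
    alpha = rbind(c(0.62, 0.19, 0.19), c(0.3, 0.1, 0.6), c(1, 0, 0)),
    inds_per_site = 1, delta_site = 0, delta_cluster = 0, coverage = 1)
  simulate_cline_dataset(sc, n_snps = 20000, seed = 21)
})
local_blocks <- build_blocks(local_sim$table$snp)
OUTS <- c("Neand", "WAfr", "AkaL", "KhoL", "AgawL")

test_that("rank-test dof arithmetic and saturation", {
  rt <- rank_test(local_sim$table, c("P_I1", "Q_I1", "R_I1"), OUTS,
                  local_blocks)
  expect_equal(rt$ranks$dof, c((3 - 1) * (5 - 1), (3 - 2) * (5 - 2), 0))
  # saturated rank: chisq 0, tail P 1
  expect_equal(rt$ranks$chisq[3], 0, tolerance = 1e-8)
  expect_equal(rt$ranks$tail_p[3], 1)
  # chisq non-increasing in rank
  expect_true(all(diff(rt$ranks$chisq) <= 1e-8))
  expect_true(all(rt$ranks$tail_p >= 0 & rt$ranks$tail_p <= 1))
  # the generic dof formula instance: L = 12, R = 10, k = 2 -> 63
  expect_equal((12 - 1 - 2) * (10 - 1 - 2), 63)
})

test_that("rank test needs enough outgroups", {
  expect_error(rank_test(local_sim$table, c("P_I1", "Q_I1", "R_I1"),
                         OUTS[1:2], local_blocks), "outgroups")
})

test_that("a target identical to a source fits alpha = (1, 0, 0)", {
  # site R was generated unadmixed from S_E
  fit <- fit_mixture(local_sim$table, "R_I1", c("S_E", "S_C", "S_S"),
                     OUTS, local_blocks)
  expect_lt(abs(fit$alpha[["S_E"]] - 1), 2 * fit$se[["S_E"]] + 1e-9)
  expect_equal(sum(fit$alpha), 1, tolerance = 1e-12)
  expect_true(all(fit$se >= 0))
})

test_that("mixture estimates permute with the sources", {
  f1 <- fit_mixture(local_sim$table, "P_I1", c("S_E", "S_C", "S_S"),
                    OUTS, local_blocks)
  f2 <- fit_mixture(local_sim$table, "P_I1", c("S_S", "S_E", "S_C"),
                    OUTS, local_blocks)
  expect_equal(f1$alpha[c("S_S", "S_E", "S_C")], f2$alpha,
               tolerance = 1e-8)
})

test_that("duplicated sources raise an ill-conditioned error", {
  tab <- local_sim$table
  # clone the S_C columns into a fake second source population
  idx <- which(tab$ind$group == "S_C")
  tab$geno <- cbind(tab$geno, tab$geno[, idx])
  tab$ind <- rbind(tab$ind,
                   transform(tab$ind[idx, ],
                             ind_id = paste0(ind_id, "dup"),
                             group = "S_Cdup"))
  tab <- genotype_table(tab$geno, tab$snp, tab$ind)
  expect_error(fit_mixture(tab, "P_I1", c("S_E", "S_C", "S_Cdup"),
                           OUTS, local_blocks), "ill-conditioned")
})

test_that("source-f3 model recovers spiked shared drift, monotonically", {
  recovered <- sapply(c(0.002, 0.005, 0.01), function(delta) {
    sc <- cline_scenario(inds_per_site = 2, delta_site = delta,
                         delta_cluster = 0, coverage = 1)
    sim <- simulate_cline_dataset(sc, n_snps = 15000,
                                  seed = 31 + round(1000 * delta))
    blocks <- build_blocks(sim$table$snp)
    f3 <- outgroup_f3_pairs(sim$table, "Neand", sim$coords$ind_id, blocks)
    model <- fit_source_f3_matrix(f3, sim$truth$alpha)
    m <- merge(model$pairs, sim$truth$pair_excess, by = c("id1", "id2"))
    spike <- m$expected_excess > 0
    # same-site pairs within 2 se of the injected drift on average
    expect_lt(abs(mean(m$excess[spike]) - delta),
              2 * mean(m$se[spike]) / sqrt(sum(spike)) + 0.25 * delta)
    mean(m$excess[spike])
  })
  expect_true(all(diff(recovered) > 0))
})

test_that("K = 1 collapses to a constant fitted value", {
  f3 <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                   est = c(0.101, 0.099, 0.100), var = 1e-6)
  alpha <- matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), "S"))
  model <- fit_source_f3_matrix(f3, alpha)
  expect_equal(unique(round(model$pairs$fitted, 10)),
               round(mean(f3$est), 10))
  expect_lt(max(abs(model$pairs$excess)), 4 * sqrt(1e-6))
  expect_equal(model$pairs$excess, -model$pairs$residual)
})

test_that("underdetermined source-f3 systems error", {
  f3 <- data.frame(id1 = "a", id2 = "b", est = 0.1, var = 1e-6)
  alpha <- matrix(c(0.5, 0.5, 0.4, 0.6), 2, 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(fit_source_f3_matrix(f3, alpha), "underdetermined")
})

test_that("residual records exclude kin pairs and honour no-op locks", {
  sc <- cline_scenario(inds_per_site = 2, delta_site = 0.004,
                       delta_cluster = 0, coverage = 1)
  sim <- simulate_cline_dataset(sc, n_snps = 8000, seed = 41)
  blocks <- build_blocks(sim$table$snp)
  f3 <- outgroup_f3_pairs(sim$table, "Neand", sim$coords$ind_id, blocks)
  model <- fit_source_f3_matrix(f3, sim$truth$alpha)
  kin <- c("WK1_I1", "WK1_I2")
  expect_message(
    pts <- excess_relatedness_residuals(model, sim$coords,
                                        kin_exclude = list(kin)),
    "excluding kin-flagged pair")
  expect_false(any(pts$id1 == kin[1] & pts$id2 == kin[2]))
  expect_equal(nrow(pts), nrow(model$pairs) - 1)
  # same-site pairs sit at the dummy distance
  same <- sub("_I\\d+$", "", pts$id1) == sub("_I\\d+$", "", pts$id2)
  expect_true(all(pts$x[same] == 0.001))
  # locking a component at its current value changes nothing
  lock <- list(WK2_I1 = c(S_E = unname(sim$truth$alpha["WK2_I1", 1])))
  colnames(model$alpha) <- c("S_E", "S_C", "S_S")
  pts2 <- excess_relatedness_residuals(model, sim$coords,
                                       kin_exclude = list(kin),
                                       locked = lock)
  expect_equal(pts2$y, pts$y, tolerance = 1e-12)
  # dropping same-site pairs removes dummy-distance points
  pts3 <- excess_relatedness_residuals(model, sim$coords,
                                       drop_same_site = TRUE)
  expect_true(all(pts3$x > 0.0015))
})

test_that("mismatch ratios separate duplicates, relatives, unrelated", {
  p <- runif(20000, 0.05, 0.95)
  rc_dup <- simulate_kin_reads(p, "duplicate", coverage = 5, seed = 51)
  rc_rel <- simulate_kin_reads(p, "parent_child", coverage = 5, seed = 52)
  rc_unr <- simulate_kin_reads(p, "unrelated", coverage = 5, seed = 53)
  k_dup <- pairwise_mismatch(rc_dup, c("A", "B"), seed = 1)
  k_rel <- pairwise_mismatch(rc_rel, c("A", "B"), seed = 1)
  k_unr <- pairwise_mismatch(rc_unr, c("A", "B"), seed = 1)
  expect_equal(k_dup$band, "duplicate")
  expect_equal(k_rel$band, "related")
  expect_equal(k_unr$band, "unrelated")
  expect_true(k_dup$ratio < k_rel$ratio && k_rel$ratio < k_unr$ratio)
})

test_that("too few overlapping sites is an explicit error", {
  p <- runif(200, 0.2, 0.8)
  rc <- simulate_kin_reads(p, "unrelated", coverage = 5, seed = 54)
  expect_error(pairwise_mismatch(rc, c("A", "B"), min_sites = 1000),
               "insufficient data")
  expect_error(pairwise_mismatch(rc, c("A", "Z"), min_sites = 10),
               "unknown individual")
})
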