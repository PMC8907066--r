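# Synthetic-data generators: drift model moments, coverage and read
# behaviour, truth-record fidelity, reproducibility.

test_that("zero drift and degenerate admixture are identities", {
  g <- graph_spec(data.frame(parent = c("R", "R"), child = c("A", "B"),
                             f = c(0, 0)),
                  admix = list(list(node = "M", sources = c("A", "B"),
                                    alpha = c(1, 0))))
  P <- simulate_frequencies(g, 200, seed = 1)
  expect_equal(P["A", ], P["R", ])
  expect_equal(P["M", ], P["A", ])
})

test_that("graph validation rejects bad specs", {
  expect_error(graph_spec(data.frame(parent = "R", child = "A", f = 1)),
               "\\[0, 1\\)")
  expect_error(graph_spec(data.frame(parent = c("R", "Q"),
                                     child = c("A", "B"),
                                     f = c(0.1, 0.1))),
               "exactly one root")
  expect_error(graph_spec(data.frame(parent = "R", child = "A", f = 0.1),
                          admix = list(list(node = "M",
                                            sources = c("R", "A"),
                                            alpha = c(0.7, 0.7)))),
               "sum to 1")
})

test_that("drift variance matches the Beta parameterization", {
  g <- graph_spec(data.frame(parent = "R", child = "A", f = 0.02),
                  root_freq_range = c(0.5, 0.5))
  P <- simulate_frequencies(g, 1e5, seed = 2)
  # Var = F p (1 - p) = 0.02 * 0.25 = 0.005, within 10%
  expect_equal(var(P["A", ]), 0.005, tolerance = 0.1)
  expect_true(all(P >= 0 & P <= 1))
})

test_that("coverage and frequency limits behave", {
  g <- graph_spec(data.frame(parent = "R", child = "A", f = 0.1),
                  root_freq_range = c(0.999999, 0.999999))
  P <- simulate_frequencies(g, 300, seed = 3)
  P["A", ] <- 1  # force fixation for the limit case
  inds <- data.frame(ind_id = c("x", "y"), node = "A", group = c("x", "y"),
                     coverage = c(0, 2), ploidy = "pseudohaploid")
  sim <- simulate_individuals(P, inds, seed = 4)
  expect_true(all(is.na(sim$table$geno[, 1])))       # lambda = 0
  g2 <- sim$table$geno[, 2]
  expect_true(all(g2[!is.na(g2)] == 2L))             # p = 1 everywhere
  expect_error(simulate_individuals(P, transform(inds, coverage = -1),
                                    seed = 1), "coverage")
})

test_that("full contamination shifts read frequencies to the contaminant", {
  g <- graph_spec(data.frame(parent = c("R", "R"), child = c("A", "B"),
                             f = c(0.3, 0.3)))
  P <- simulate_frequencies(g, 1e5, seed = 5)
  inds <- data.frame(ind_id = "x", node = "A", group = "x", coverage = 2,
                     ploidy = "pseudohaploid", contam_c = 1,
                     contam_node = "B")
  sim <- simulate_individuals(P, inds, seed = 6)
  tot <- sim$counts$n1 + sim$counts$n2
  cov <- tot[, 1] > 0
  # per-site read frequencies track the contaminant node, not the donor:
  # mean squared deviation from B is pure binomial noise, deviation from A
  # carries the drift separation on top
  obs <- sim$counts$n1[cov, 1] / tot[cov, 1]
  msd_b <- mean((obs - P["B", cov])^2)
  msd_a <- mean((obs - P["A", cov])^2)
  noise <- mean(P["B", cov] * (1 - P["B", cov]) / tot[cov, 1])
  expect_equal(msd_b, noise, tolerance = 0.05)
  expect_gt(msd_a, msd_b + 0.02)
})

test_that("cline datasets are pure functions of (spec, seed)", {
  sc <- cline_scenario(inds_per_site = 1, coverage = 0.3)
  a <- simulate_cline_dataset(sc, n_snps = 2000, seed = 77)
  b <- simulate_cline_dataset(sc, n_snps = 2000, seed = 77)
  expect_identical(a$table$geno, b$table$geno)
  expect_identical(a$counts$n1, b$counts$n1)
  c <- simulate_cline_dataset(sc, n_snps = 2000, seed = 78)
  expect_false(identical(a$table$geno, c$table$geno))
})

test_that("truth records store the generating parameters", {
  sc <- cline_scenario(inds_per_site = 2, delta_site = 0.005,
                       delta_cluster = 0, coverage = 0.2)
  sim <- simulate_cline_dataset(sc, n_snps = 1000, seed = 9)
  # the western-Kenya scenario proportions are stored exactly
  wk <- sim$truth$alpha[grepl("^WK", rownames(sim$truth$alpha)), ]
  expect_true(all(wk[, 1] == 0.62 & wk[, 2] == 0.19 & wk[, 3] == 0.19))
  pe <- sim$truth$pair_excess
  same_site <- sub("_I\\d+$", "", pe$id1) == sub("_I\\d+$", "", pe$id2)
  expect_true(all(pe$expected_excess[same_site] == 0.005))
  expect_true(all(pe$expected_excess[!same_site] == 0))
})

test_that("decay-point generator follows the curve", {
  x <- seq(1, 500, length.out = 50)
  noiseless <- simulate_decay_points(0.05, 1, 0.2, x, 0, seed = 1)
  expect_equal(noiseless$y, 1 / (0.05 * x + 1) + 0.2, tolerance = 1e-12)
  # asymptote: large x approaches b
  far <- simulate_decay_points(0.05, 1, 0.2, 1e6, 0, seed = 1)
  expect_equal(far$y, 0.2, tolerance = 1e-4)
  # CLT bound on the seeded noise
  pts <- simulate_decay_points(0.05, 1, 0.2, rep(100, 1000), 1e-4, seed = 2)
  resid <- pts$y - (1 / (0.05 * 100 + 1) + 0.2)
  expect_lt(abs(mean(resid)), 4 * 0.01 / sqrt(1000))
  expect_error(simulate_decay_points(-1, 0.1, 0, x, 0, seed = 1),
               "positive")
})

test_that("ROH block simulation matches its closed-form intensity", {
  # enormous Ne: expected count ~ 0, typical draw empty
  expect_equal(roh_expected_count(1e9, c(4, Inf)), 0, tolerance = 1e-3)
  expect_length(simulate_roh_blocks(1e9, seed = 1), 0)
  # reproducibility
  expect_identical(simulate_roh_blocks(500, seed = 5),
                   simulate_roh_blocks(500, seed = 5))
  # mean count over replicates within 3 se of Lambda
  Lam <- roh_expected_count(500, c(4, Inf))
  counts <- vapply(1:200, function(s)
    length(simulate_roh_blocks(500, seed = s)), 0L)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - Lam), 3 * se)
})
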