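# Block partitioning, f-statistic estimation, jackknife behaviour, and the
# consistent f2-basis solve.

test_that("build_blocks partitions greedily within chromosomes", {
  snp <- data.frame(chrom = "1", genetic_pos = seq(0.0005, 0.2, by = 5e-4))
  b <- build_blocks(snp, 0.05)
  expect_equal(b$n_blocks, 4L)
  expect_equal(sum(b$counts), nrow(snp))
  # two chromosomes: no block spans the boundary
  snp2 <- rbind(snp, transform(snp, chrom = "2"))
  b2 <- build_blocks(snp2, 0.05)
  chr_of_block <- tapply(snp2$chrom, b2$block, function(x) length(unique(x)))
  expect_true(all(chr_of_block == 1))
  # empty input
  b0 <- build_blocks(snp[0, ], 0.05)
  expect_equal(b0$n_blocks, 0L)
})

test_that("f2 of a population against itself is exactly zero", {
  freqs <- make_drift_freqs(400, 1, seed = 2)
  tab <- make_pop_table(freqs, n_per = 1, ploidy = "pseudohaploid",
                        pops = "X")
  # two labels mapping to the same single pseudohaploid individual:
  # identical frequency columns and zero heterozygosity correction
  blocks <- build_blocks(tab$snp)
  st <- compute_fstat(tab, "f2", list(X = "X_1", Y = "X_1"), blocks)
  expect_equal(st$estimate, 0)
  expect_equal(st$se, 0)
})

test_that("f4 equals the brute-force mean of frequency products", {
  freqs <- make_drift_freqs(100, 4, seed = 3)
  tab <- make_pop_table(freqs, n_per = 3, seed = 5)
  blocks <- build_blocks(tab$snp)
  st <- compute_fstat(tab, "f4", c("A", "B", "C", "D"), blocks)
  # independent oracle: sample frequencies computed directly from genotypes
  pfun <- function(g) colMeans(matrix(rowMeans(g) / 2))
  p <- sapply(c("A", "B", "C", "D"), function(pop) {
    g <- tab$geno[, tab$ind$group == pop, drop = FALSE]
    rowMeans(g) / 2
  })
  oracle <- mean((p[, 1] - p[, 2]) * (p[, 3] - p[, 4]))
  expect_equal(st$estimate, oracle, tolerance = 1e-12)
  expect_equal(st$n_snps_used, 100L)
})

test_that("f2 between two samples of one population is unbiased", {
  hits <- 0
  for (r in 1:100) {
    set.seed(1000 + r)
    S <- 1000
    p <- runif(S, 0.1, 0.9)
    geno <- cbind(matrix(rbinom(S * 10, 2, p), S, 10),
                  matrix(rbinom(S * 10, 2, p), S, 10))
    snp <- data.frame(snp_id = sprintf("s%d", 1:S), chrom = "1",
                      genetic_pos = (1:S) * 1e-3,
                      physical_pos = (1:S) * 1000L,
                      allele1 = "A", allele2 = "G")
    ind <- data.frame(ind_id = sprintf("i%02d", 1:20), sex = "U",
                      group = rep(c("X", "Y"), each = 10),
                      ploidy = "diploid")
    tab <- genotype_table(geno, snp, ind)
    blocks <- build_blocks(tab$snp)
    st <- compute_fstat(tab, "f2", c("X", "Y"), blocks)
    if (abs(st$estimate) < 2 * st$se) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("equal-weight jackknife reduces to the delete-one formula", {
  # one block per chromosome, equal SNP counts by construction
  freqs <- make_drift_freqs(1000, 4, seed = 6)
  tab <- make_pop_table(freqs, n_per = 3, seed = 7)
  tab$snp$chrom <- as.character(rep(1:10, each = 100))
  tab$snp$genetic_pos <- rep(seq(1e-4, 1e-2, length.out = 100), 10)
  blocks <- build_blocks(tab$snp)
  expect_true(all(blocks$counts == blocks$counts[1]))
  st <- compute_fstat(tab, "f4", c("A", "B", "C", "D"), blocks)
  B <- length(st$loo)
  se_direct <- sqrt((B - 1) / B * sum((st$loo - mean(st$loo))^2))
  expect_equal(st$se, se_direct, tolerance = 1e-12)
})

test_that("no usable SNPs raises an explicit no-overlap error", {
  freqs <- make_drift_freqs(100, 2, seed = 8)
  tab <- make_pop_table(freqs, n_per = 2, seed = 9)
  tab$geno[, tab$ind$group == "B"] <- NA
  blocks <- build_blocks(tab$snp)
  expect_error(compute_fstat(tab, "f2", c("A", "B"), blocks), "no overlap")
  expect_error(qpfstats_solve(tab, c("A", "B"), blocks), "no overlap")
})

test_that("basis f2 equals direct f2 on complete data", {
  freqs <- make_drift_freqs(1500, 4, seed = 10)
  tab <- make_pop_table(freqs, n_per = 3, seed = 11)
  blocks <- build_blocks(tab$snp)
  basis <- qpfstats_solve(tab, c("A", "B", "C", "D"), blocks)
  for (pair in list(c("A", "B"), c("A", "D"), c("C", "D"))) {
    direct <- compute_fstat(tab, "f2", pair, blocks)
    expect_equal(basis$f2[pair[1], pair[2]], direct$estimate,
                 tolerance = 1e-10)
    db <- derive_stat(basis, "f2", pair)
    expect_equal(db$se, direct$se, tolerance = 1e-8)
  }
})

test_that("derived statistics satisfy the f identities exactly", {
  freqs <- make_drift_freqs(800, 5, seed = 12)
  tab <- make_pop_table(freqs, n_per = 2, seed = 13)
  blocks <- build_blocks(tab$snp)
  basis <- qpfstats_solve(tab, LETTERS[1:5], blocks)
  # f3(O; X, X) = f2(O, X)
  expect_equal(derive_stat(basis, "f3", c("A", "B", "B"))$estimate,
               derive_stat(basis, "f2", c("A", "B"))$estimate,
               tolerance = 1e-14)
  f4 <- function(...) derive_stat(basis, "f4", c(...))$estimate
  # antisymmetry
  expect_equal(f4("A", "B", "C", "D"), -f4("B", "A", "C", "D"),
               tolerance = 1e-14)
  expect_equal(f4("A", "B", "C", "D"), -f4("A", "B", "D", "C"),
               tolerance = 1e-14)
  # additivity, exact in the basis
  expect_equal(f4("A", "B", "C", "D") + f4("A", "B", "D", "E"),
               f4("A", "B", "C", "E"), tolerance = 1e-14)
})

test_that("the basis bridges missing data", {
  freqs <- make_drift_freqs(4000, 4, seed = 14)
  tab <- make_pop_table(freqs, n_per = 3, seed = 15)
  blocks <- build_blocks(tab$snp)
  truth <- compute_fstat(tab, "f4", c("A", "B", "C", "D"), blocks)
  # mask 50% of entries at random
  set.seed(16)
  masked <- tab
  drop <- matrix(runif(length(tab$geno)) < 0.5, nrow(tab$geno))
  masked$geno[drop] <- NA
  basis <- qpfstats_solve(masked, c("A", "B", "C", "D"), blocks)
  est <- derive_stat(basis, "f4", c("A", "B", "C", "D"))
  expect_lt(abs(est$estimate - truth$estimate),
            3 * sqrt(est$se^2 + truth$se^2))
})
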