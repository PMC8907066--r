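# Shared fixture builders. Everything is generated in code; no stored data.

# Genotype table of diploid populations sampled from explicit frequencies.
# freqs: SNPs x pops matrix; n_per: individuals per population.
make_pop_table <- function(freqs, n_per = 3, seed = 1,
                           pops = colnames(freqs), ploidy = "diploid",
                           block_morgans = 5e-4) {
  set.seed(seed)
  S <- nrow(freqs)
  if (is.null(pops)) pops <- LETTERS[seq_len(ncol(freqs))]
  geno <- do.call(cbind, lapply(seq_len(ncol(freqs)), function(k) {
    if (ploidy == "diploid")
      matrix(stats::rbinom(S * n_per, 2, freqs[, k]), S, n_per)
    else
      matrix(2L * stats::rbinom(S * n_per, 1, freqs[, k]), S, n_per)
  }))
  snp <- data.frame(snp_id = sprintf("s%05d", seq_len(S)), chrom = "1",
                    genetic_pos = seq_len(S) * block_morgans,
                    physical_pos = seq_len(S) * 1000L,
                    allele1 = "A", allele2 = "G")
  ind <- data.frame(
    ind_id = sprintf("%s_%d", rep(pops, each = n_per), seq_len(n_per)),
    sex = "U", group = rep(pops, each = n_per), ploidy = ploidy)
  genotype_table(geno, snp, ind)
}

# Random drifted frequencies for npop populations around a shared ancestor.
make_drift_freqs <- function(S, npop, drift = 0.05, seed = 1) {
  set.seed(seed)
  p0 <- stats::runif(S, 0.1, 0.9)
  f <- sapply(seq_len(npop), function(k) {
    k0 <- 1 / drift - 1
    stats::rbeta(S, p0 * k0, (1 - p0) * k0)
  })
  colnames(f) <- LETTERS[seq_len(npop)]
  f
}

# PL table for one diploid individual from explicit genotypes at evenly
# spaced sites (constant 1 cM/Mb, error-free reads at given depth).
pl_from_genotypes <- function(g, depth = 6, spacing_bp = 2e4, seed = 1) {
  set.seed(seed)
  S <- length(g)
  pos <- as.integer(seq(spacing_bp, by = spacing_bp, length.out = S))
  snp <- data.frame(snp_id = sprintf("s%d", 1:S), chrom = "1",
                    genetic_pos = pos / 1e8, physical_pos = pos,
                    allele1 = "A", allele2 = "G")
  dp <- rpois(S, depth)
  r1 <- rbinom(S, dp, g / 2)
  counts <- read_counts(matrix(r1), matrix(dp - r1), snp,
                        data.frame(ind_id = "X", sex = "U", group = "X",
                                   ploidy = "diploid"))
  reads_to_likelihoods(counts)
}

# Write a tiny EIGENSTRAT trio and return the prefix.
write_tiny_trio <- function(dir, geno_lines,
                            n_snp = length(geno_lines),
                            n_ind = nchar(geno_lines[1])) {
  prefix <- file.path(dir, "tiny")
  writeLines(geno_lines, paste0(prefix, ".geno"))
  writeLines(sprintf("rs%d 1 %.6f %d A G", seq_len(n_snp),
                     seq_len(n_snp) * 0.001, seq_len(n_snp) * 1000),
             paste0(prefix, ".snp"))
  writeLines(sprintf("ind%d U Pop%d", seq_len(n_ind), seq_len(n_ind)),
             paste0(prefix, ".ind"))
  prefix
}
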