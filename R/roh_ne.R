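# Runs-of-homozygosity calling from genotype likelihoods and maximum
# likelihood inference of recent effective population size from ROH lengths.

#' Autosomal genome specification
#'
#' Chromosome genetic lengths used by the ROH length model. Defaults to 22
#' human-like autosomes totalling about 35.4 Morgans (sex-averaged map
#' lengths, constant-rate approximation).
#'
#' @param lengths chromosome genetic lengths in Morgans.
#' @return object of class `genome_spec`: `lengths`, `n_chrom`.
#' @export
genome_spec <- function(lengths = c(2.863, 2.686, 2.234, 2.146, 2.041,
                                    1.920, 1.872, 1.680, 1.664, 1.811,
                                    1.582, 1.747, 1.259, 1.185, 1.419,
                                    1.340, 1.285, 1.175, 1.079, 1.083,
                                    0.628, 0.741)) {
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  structure(list(lengths = lengths, n_chrom = length(lengths)),
            class = "genome_spec")
}

#' ROH caller configuration
#'
#' Defaults follow the documented behaviour of the standard HMM caller for
#' unphased low-coverage data: a single default allele frequency of 0.4 (the
#' non-ROH state uses Hardy-Weinberg genotype priors 0.36/0.48/0.16), an
#' in-ROH heterozygote probability of 1e-3, and per-bp switch rates 6.7e-8
#' (non-ROH to ROH) and 5e-9 (ROH to non-ROH).
#'
#' @param default_af default allele frequency.
#' @param het_error in-ROH heterozygote (error) probability.
#' @param rate_hw_to_az,rate_az_to_hw switch rates per bp.
#' @param rate_cm_per_mb constant rate for bp-to-cM conversion when SNP
#'   metadata carries no genetic positions.
#' @return a list of class `roh_config`.
#' @export
roh_config <- function(default_af = 0.4, het_error = 1e-3,
                       rate_hw_to_az = 6.7e-8, rate_az_to_hw = 5e-9,
                       rate_cm_per_mb = 1) {
  stopifnot(default_af > 0, default_af < 1, het_error > 0, het_error < 1)
  structure(list(default_af = default_af, het_error = het_error,
                 rate_hw_to_az = rate_hw_to_az,
                 rate_az_to_hw = rate_az_to_hw,
                 rate_cm_per_mb = rate_cm_per_mb),
            class = "roh_config")
}

#' Call runs of homozygosity from genotype likelihoods
#'
#' Two-state HMM (ROH / non-ROH) decoded by Viterbi, one individual at a
#' time. Emissions marginalize the Phred-scaled genotype likelihoods over
#' genotype priors: Hardy-Weinberg at the default allele frequency in the
#' non-ROH state, and near-zero heterozygosity (probability `het_error`) in
#' the ROH state. The switch probability over a physical gap of d bp is
#' `1 - exp(-rate * d)`. Maximal ROH-state runs are reported with the count
#' of apparently heterozygous sites inside.
#'
#' @param pl a `pl_table` from [reads_to_likelihoods()].
#' @param individual individual id (or column index).
#' @param config a [roh_config()].
#' @param snp optional SNP metadata overriding `pl$snp` (needs `chrom`,
#'   `physical_pos`, and `genetic_pos` if available).
#' @return data.frame of class `roh_blocks`: `chrom`, `start_bp`, `end_bp`,
#'   `start_cm`, `end_cm`, `length_cm`, `n_het`.
#' @export
call_roh <- function(pl, individual = 1, config = roh_config(),
                     snp = NULL) {
  stopifnot(inherits(pl, "pl_table"))
  snp <- snp %||% pl$snp
  if (is.null(snp)) stop("SNP metadata required")
  k <- if (is.character(individual))
    match(individual, pl$ind$ind_id) else individual
  if (is.na(k)) stop("unknown individual: ", individual)
  f <- config$default_af
  prior_hw <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  eaz <- config$het_error
  prior_az <- c((1 - f) * (1 - eaz), eaz, f * (1 - eaz))
  blocks <- list()
  for (chr in unique(snp$chrom)) {
    idx <- which(snp$chrom == chr)
    pos <- snp$physical_pos[idx]
    if (is.unsorted(pos)) stop("sites unsorted on chromosome ", chr)
    # genotype likelihoods on the natural scale, per site
    L <- cbind(10^(-pl$hom1[idx, k] / 10),
               10^(-pl$het[idx, k] / 10),
               10^(-pl$hom2[idx, k] / 10))
    e_hw <- log(pmax(L %*% prior_hw, 1e-300))
    e_az <- log(pmax(L %*% prior_az, 1e-300))
    n <- length(idx)
    # Viterbi, states: 1 = non-ROH (HW), 2 = ROH (AZ)
    d <- diff(pos)
    p_hw_az <- 1 - exp(-config$rate_hw_to_az * d)
    p_az_hw <- 1 - exp(-config$rate_az_to_hw * d)
    # stationary initial distribution of the switch process
    pi_az <- config$rate_hw_to_az /
      (config$rate_hw_to_az + config$rate_az_to_hw)
    v <- matrix(-Inf, n, 2)
    bp <- matrix(0L, n, 2)
    v[1, ] <- c(log(1 - pi_az) + e_hw[1], log(pi_az) + e_az[1])
    for (t in 2:n) {
      lt <- log(rbind(c(1 - p_hw_az[t - 1], p_hw_az[t - 1]),
                      c(p_az_hw[t - 1], 1 - p_az_hw[t - 1])))
      for (s in 1:2) {
        cand <- v[t - 1, ] + lt[, s]
        bp[t, s] <- which.max(cand)
        v[t, s] <- max(cand) + if (s == 1) e_hw[t] else e_az[t]
      }
    }
    state <- integer(n)
    state[n] <- which.max(v[n, ])
    for (t in (n - 1):1) state[t] <- bp[t + 1, state[t + 1]]
    if (n == 1) state <- which.max(v[1, ])
    # extract maximal ROH runs
    r <- rle(state == 2)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    het_call <- pl$het[idx, k] == 0 &
      (pl$hom1[idx, k] > 0 | pl$hom2[idx, k] > 0)
    gpos <- if (!is.null(snp$genetic_pos) && !all(is.na(snp$genetic_pos)))
      snp$genetic_pos[idx] * 100 else pos * config$rate_cm_per_mb / 1e6
    for (run in which(r$values)) {
      a <- starts[run]; b <- ends[run]
      blocks[[length(blocks) + 1]] <- data.frame(
        chrom = chr, start_bp = pos[a], end_bp = pos[b],
        start_cm = gpos[a], end_cm = gpos[b],
        length_cm = gpos[b] - gpos[a],
        n_het = sum(het_call[a:b]))
    }
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(0), start_bp = integer(0),
               end_bp = integer(0), start_cm = numeric(0),
               end_cm = numeric(0), length_cm = numeric(0),
               n_het = integer(0))
  class(out) <- c("roh_blocks", "data.frame")
  out
}

#' Filter and merge ROH blocks
#'
#' Merges adjacent blocks on the same chromosome separated by a gap of less
#' than `max_gap_cm` with at most `max_gap_hets` apparently heterozygous
#' sites in the gap (the merged block spans both blocks and the gap), then
#' drops blocks of length `min_length_cm` or shorter. Idempotent.
#'
#' @param blocks a `roh_blocks` data.frame (one individual, sorted).
#' @param het_cm optional vector of heterozygous-site positions in cM (per
#'   the same scale as the blocks), used to count hets in gaps; with `NULL`
#'   gaps are assumed het-free.
#' @param min_length_cm retain only blocks strictly longer than this
#'   (default 4 cM).
#' @param max_gap_cm,max_gap_hets merge rule parameters (defaults 0.5 cM,
#'   2 sites).
#' @return filtered `roh_blocks`.
#' @export
postprocess_blocks <- function(blocks, het_cm = NULL, min_length_cm = 4,
                               max_gap_cm = 0.5, max_gap_hets = 2) {
  if (nrow(blocks) == 0) return(blocks)
  out <- list()
  for (chr in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == chr, ]
    b <- b[order(b$start_cm), ]
    i <- 1
    while (i < nrow(b)) {
      gap <- b$start_cm[i + 1] - b$end_cm[i]
      ghets <- if (is.null(het_cm)) 0 else
        sum(het_cm > b$end_cm[i] & het_cm < b$start_cm[i + 1])
      if (gap < max_gap_cm && ghets <= max_gap_hets) {
        b$end_cm[i] <- b$end_cm[i + 1]
        b$end_bp[i] <- b$end_bp[i + 1]
        b$length_cm[i] <- b$end_cm[i] - b$start_cm[i]
        b$n_het[i] <- b$n_het[i] + b$n_het[i + 1] + ghets
        b <- b[-(i + 1), ]
      } else i <- i + 1
    }
    out[[chr]] <- b
  }
  res <- do.call(rbind, out)
  res <- res[res$length_cm > min_length_cm, ]
  rownames(res) <- NULL
  class(res) <- c("roh_blocks", "data.frame")
  res
}

#' Flag individuals with excess very long ROH
#'
#' Individuals whose parents were closely related (roughly first-cousin
#' level) carry a large total of very long ROH; their recent-Ne inference
#' should be restricted to the 4-8 cM window. The flag triggers when the
#' total length in blocks longer than `long_cm` exceeds `total_cm`.
#'
#' @param blocks postprocessed `roh_blocks`.
#' @param long_cm block-length threshold (default 12 cM).
#' @param total_cm total-length trigger (default 100 cM, about half the
#'   first-cousin expectation).
#' @return logical.
#' @export
flag_long_roh <- function(blocks, long_cm = 12, total_cm = 100) {
  sum(blocks$length_cm[blocks$length_cm > long_cm]) > total_cm
}

# ROH length intensity (per Morgan) at length l (Morgans) for population
# size N: lambda(l; N) = sum_g pi_g(N) sum_i [(2g)^2 max(G_i - l, 0)
# + 2(2g)] exp(-2 g l), pi_g(N) = (1/2N)(1 - 1/2N)^(g-1).
.roh_lambda <- function(l, N, genome, g_max = 500) {
  g <- seq_len(g_max)
  pig <- (1 / (2 * N)) * (1 - 1 / (2 * N))^(g - 1)
  out <- numeric(length(l))
  for (i in seq_along(l)) {
    li <- l[i]
    per_g <- exp(-2 * g * li) *
      ((2 * g)^2 * sum(pmax(genome$lengths - li, 0)) +
         2 * (2 * g) * genome$n_chrom)
    out[i] <- sum(pig * per_g)
  }
  out
}

# Closed-form integral of .roh_lambda over [u, v] (Morgans); v may be Inf.
.roh_Lambda <- function(N, u, v, genome, g_max = 500) {
  g <- seq_len(g_max)
  pig <- (1 / (2 * N)) * (1 - 1 / (2 * N))^(g - 1)
  c2 <- 2 * g
  total <- 0
  # edge term: 2 * 2g * n_chrom * exp(-2 g l), integral over [u, v]
  ev <- if (is.finite(v)) exp(-c2 * v) else 0
  total <- total + sum(pig * 2 * c2 * genome$n_chrom *
                         (exp(-c2 * u) - ev) / c2)
  # interior term per chromosome: (2g)^2 (G - l) exp(-2 g l) on [u, min(v,G)]
  for (G in genome$lengths) {
    w <- min(v, G)
    if (w <= u) next
    # antiderivative of (G - l) e^{-c l}: -e^{-c l} ((G - l)/c - 1/c^2)
    Fa <- -exp(-c2 * u) * ((G - u) / c2 - 1 / c2^2)
    Fb <- -exp(-c2 * w) * ((G - w) / c2 - 1 / c2^2)
    total <- total + sum(pig * c2^2 * (Fb - Fa))
  }
  total
}

#' Expected ROH count in a length window
#'
#' Closed-form integral of the ROH length intensity over `[u, v]` cM for a
#' population of constant size `N` (diploid effective size), with the
#' chromosome-edge term.
#'
#' @param N effective population size.
#' @param window c(u, v) in cM; `v` may be `Inf`.
#' @param genome a [genome_spec()].
#' @param g_max generations in the truncated sum (default 500; older
#'   generations contribute negligibly to blocks above 4 cM).
#' @return expected block count.
#' @export
roh_expected_count <- function(N, window, genome = genome_spec(),
                               g_max = 500) {
  .roh_Lambda(N, window[1] / 100, window[2] / 100, genome, g_max)
}

#' Simulate ROH block lengths
#'
#' Draws block lengths from the inhomogeneous Poisson process with the same
#' intensity the maximum-likelihood estimator assumes (the generative twin
#' of [estimate_ne()]): the count in the window is Poisson with mean
#' [roh_expected_count()] and lengths follow the normalized intensity.
#'
#' @param Ne effective population size (>= 2).
#' @param genome a [genome_spec()].
#' @param window c(u, v) in cM (default `c(4, Inf)`).
#' @param seed integer seed.
#' @return numeric vector of block lengths in cM.
#' @export
simulate_roh_blocks <- function(Ne, genome = genome_spec(),
                                window = c(4, Inf), seed) {
  if (Ne < 2) stop("Ne must be >= 2")
  restore <- .seed_scope(seed)
  on.exit(restore())
  u <- window[1] / 100
  v_eff <- min(window[2] / 100, max(genome$lengths) + 5)
  Lam <- .roh_Lambda(Ne, u, window[2] / 100, genome)
  n <- stats::rpois(1, Lam)
  if (n == 0) return(numeric(0))
  grid <- seq(u, v_eff, length.out = 4096)
  dens <- .roh_lambda(grid, Ne, genome)
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  uu <- stats::runif(n)
  lens <- stats::approx(cdf, grid, xout = uu, ties = "ordered")$y
  sort(lens) * 100
}

#' Maximum-likelihood recent effective population size from ROH
#'
#' Models ROH block lengths in a window `[u, v]` cM as an inhomogeneous
#' Poisson process whose intensity sums over past generations g the IBD
#' segment density `[(2g)^2 max(G_i - l, 0) + 2(2g)] exp(-2 g l)` weighted
#' by the single-ancestor coalescence probability
#' `pi_g = (1/2N)(1 - 1/2N)^(g-1)`. The log-likelihood is
#' `-Lambda(N) + sum_k log lambda(l_k; N)`, maximized over log N by 1-D
#' search; the 95% confidence interval is the profile-likelihood interval
#' (drop of 1.92 log-units), with the upper limit reported as `Inf`
#' (unbounded) when the likelihood never crosses the threshold before the
#' search bound.
#'
#' @param lengths_cm block lengths in cM (postprocessed, within window), or
#'   a `roh_blocks` data.frame.
#' @param genome a [genome_spec()].
#' @param window c(u, v) in cM, u >= 4.
#' @param N_range search range for N.
#' @return object of class `ne_estimate`: `Ne`, `ci` (lower, upper),
#'   `window`, `n_blocks`, `logLik`.
#' @export
estimate_ne <- function(lengths_cm, genome = genome_spec(),
                        window = c(4, Inf), N_range = c(10, 1e6)) {
  if (is.data.frame(lengths_cm)) lengths_cm <- lengths_cm$length_cm
  if (window[1] > window[2]) stop("window inverted")
  lens <- lengths_cm[lengths_cm >= window[1] & lengths_cm <= window[2]]
  l <- lens / 100
  u <- window[1] / 100; v <- window[2] / 100
  ll <- function(logN) {
    N <- exp(logN)
    -.roh_Lambda(N, u, v, genome) +
      (if (length(l)) sum(log(pmax(.roh_lambda(l, N, genome), 1e-300)))
       else 0)
  }
  lo <- log(N_range[1]); hi <- log(N_range[2])
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  mle <- opt$maximum; llmax <- opt$objective
  # monotone boundary case (e.g. zero blocks): MLE at the search bound
  if (ll(hi) >= llmax - 1e-8 && ll(hi) >= ll(lo)) {
    mle <- hi; llmax <- ll(hi)
  }
  thresh <- llmax - 1.92
  ci_lo <- if (ll(lo) < thresh && mle > lo)
    exp(stats::uniroot(function(x) ll(x) - thresh, c(lo, mle),
                       tol = 1e-8)$root)
  else N_range[1]
  ci_hi <- if (mle < hi && ll(hi) < thresh)
    exp(stats::uniroot(function(x) ll(x) - thresh, c(mle, hi),
                       tol = 1e-8)$root)
  else Inf
  structure(list(Ne = exp(mle), ci = c(lower = ci_lo, upper = ci_hi),
                 window = window, n_blocks = length(lens),
                 logLik = llmax),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  up <- if (is.finite(x$ci[2])) sprintf("%.0f", x$ci[2]) else "unbounded"
  cat(sprintf("ne_estimate: Ne = %.0f, 95%% CI = %.0f-%s (%d blocks in %g-%g cM)\n",
              x$Ne, x$ci[1], up, x$n_blocks, x$window[1], x$window[2]))
  invisible(x)
}
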