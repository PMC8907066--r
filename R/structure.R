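# Rank tests, mixture fitting, the independent-mixture residual model of
# excess relatedness, and kin detection from allele-mismatch rates.

# f4 matrix X_ij = f4(l_i, l_1; r_j, r_1), i = 2..L, j = 2..R, with
# block-jackknife machinery shared by rank_test and fit_mixture.
.f4_matrix <- function(fr, left_idx, right_idx, blocks) {
  L <- length(left_idx); R <- length(right_idx)
  nst <- (L - 1) * (R - 1)
  nb <- blocks$n_blocks
  est <- numeric(nst)
  sums <- matrix(0, nst, nb); counts <- matrix(0L, nst, nb)
  s <- 0
  for (j in 2:R) for (i in 2:L) {  # column-major vec order
    s <- s + 1
    d <- .fstat_contrib("f4", c(left_idx[i], left_idx[1],
                                right_idx[j], right_idx[1]), fr)
    if (all(is.na(d)))
      stop("no overlap for f4 involving populations ",
           colnames(fr$P)[left_idx[i]], " and ",
           colnames(fr$P)[right_idx[j]])
    bs <- .block_sums(d, blocks$block, nb)
    sums[s, ] <- bs$sums; counts[s, ] <- bs$counts
    est[s] <- sum(bs$sums) / sum(bs$counts)
  }
  tot_s <- rowSums(sums); tot_c <- rowSums(counts)
  loo <- matrix(NA_real_, nb, nst)
  for (b in seq_len(nb)) {
    cb <- tot_c - counts[, b]
    loo[b, ] <- ifelse(cb > 0, (tot_s - sums[, b]) / cb, NA_real_)
  }
  list(est = est, loo = loo, L = L, R = R)
}

# Inverse with escalating ridge regularization; warns when regularized.
.safe_inverse <- function(Q) {
  lam <- 0
  d <- mean(diag(Q))
  for (k in 0:8) {
    Qr <- Q + diag(lam, nrow(Q))
    inv <- tryCatch(solve(Qr), error = function(e) NULL)
    if (!is.null(inv) && all(is.finite(inv))) {
      if (lam > 0) warning("covariance singular; ridge-regularized with ",
                           signif(lam, 3))
      return(inv)
    }
    lam <- if (lam == 0) 1e-9 * d else lam * 100
  }
  stop("covariance matrix could not be inverted")
}

#' Rank test for the number of ancestry sources
#'
#' Tests how many distinct streams of ancestry relate a set of `left` test
#' populations to a set of `right` outgroups, via the rank of the matrix
#' `X[i,j] = f4(l_i, l_1; r_j, r_1)`. For each rank k, the quadratic form
#' `(vec(X) - vec(Xk))' Q^-1 (vec(X) - vec(Xk))` is minimized over rank-k
#' matrices `Xk` (alternating generalized least squares on the bilinear
#' factorization), with `Q` the block-jackknife covariance of `vec(X)`.
#' Rank k corresponds to k + 1 ancestry sources. The `tail` P value
#' (chi-squared with `(L-1-k)(R-1-k)` dof) measures absolute fit; `taildiff`
#' P values compare consecutive ranks through the chi-squared difference.
#'
#' @param table a [genotype_table()].
#' @param left character vector of test populations (L >= 2).
#' @param right character vector of outgroups (R >= L).
#' @param blocks a [build_blocks()] partition.
#' @param max_rank highest rank tested (default `L - 1`, the saturated
#'   model).
#' @return object of class `rank_test`: data.frame `ranks` with columns
#'   `rank`, `chisq`, `dof`, `tail_p`, `taildiff_p`.
#' @export
rank_test <- function(table, left, right, blocks, max_rank = NULL) {
  L <- length(left); R <- length(right)
  if (L < 2) stop("need at least 2 test populations")
  if (R < L) stop("need at least as many outgroups as test populations")
  if (is.null(max_rank)) max_rank <- L - 1
  fr <- .pop_freqs(table, c(left, right))
  fm <- .f4_matrix(fr, seq_len(L), L + seq_len(R), blocks)
  Q <- .jackknife_cov(fm$est, fm$loo, blocks$counts)
  Qi <- .safe_inverse(Q)
  v <- fm$est
  nr <- L - 1; nc <- R - 1
  res <- data.frame(rank = 0:max_rank, chisq = NA_real_, dof = NA_integer_,
                    tail_p = NA_real_)
  for (k in 0:max_rank) {
    res$chisq[k + 1] <- .rank_chisq(v, Qi, nr, nc, k)
    res$dof[k + 1] <- (nr - k) * (nc - k)
    res$tail_p[k + 1] <- if (res$dof[k + 1] > 0)
      stats::pchisq(res$chisq[k + 1], res$dof[k + 1], lower.tail = FALSE)
    else 1
  }
  res$taildiff_p <- c(if (nrow(res) > 1)
    stats::pchisq(pmax(res$chisq[-nrow(res)] - res$chisq[-1], 0),
                  pmax(res$dof[-nrow(res)] - res$dof[-1], 1),
                  lower.tail = FALSE), NA_real_)
  structure(list(left = left, right = right, ranks = res),
            class = "rank_test")
}

# Minimized chi-squared over rank <= k matrices, by alternating GLS on
# X = A B' (vec(X) = (B kron I) vec(A) = (I kron A) vec(B')).
.rank_chisq <- function(v, Qi, nr, nc, k) {
  if (k == 0) return(drop(v %*% Qi %*% v))
  if (k >= min(nr, nc)) return(0)
  X <- matrix(v, nr, nc)
  sv <- svd(X)
  A <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k)
  B <- sv$v[, seq_len(k), drop = FALSE]
  gls <- function(M) {
    # minimize (v - M w)' Qi (v - M w) over w
    .pinv_solve(crossprod(M, Qi %*% M), crossprod(M, Qi %*% v))
  }
  chisq_of <- function(fit) drop((v - fit) %*% Qi %*% (v - fit))
  old <- Inf
  for (it in seq_len(500)) {
    MA <- B %x% diag(nr)                   # vec(AB') = (B kron I) vec(A)
    A <- matrix(gls(MA), nr, k)
    MB <- diag(nc) %x% A                   # vec(AB') = (I kron A) vec(B')
    Bt <- matrix(gls(MB), k, nc)
    B <- t(Bt)
    fit <- as.vector(A %*% Bt)
    ch <- chisq_of(fit)
    if (abs(old - ch) < 1e-12 * (1 + ch)) break
    old <- ch
  }
  ch
}

#' @export
print.rank_test <- function(x, ...) {
  cat("rank_test: L =", length(x$left), "test populations, R =",
      length(x$right), "outgroups\n")
  print(transform(x$ranks, chisq = signif(chisq, 5),
                  tail_p = signif(tail_p, 3),
                  taildiff_p = signif(taildiff_p, 3)), row.names = FALSE)
  invisible(x)
}

#' Fit ancestry mixture proportions for a target
#'
#' Models the target as a K-way mixture of the source populations, solving
#' `f4(T, R1; Rj, R1) = sum_k alpha_k f4(S_k, R1; Rj, R1)` for j = 2..M by
#' generalized least squares under the constraint `sum(alpha) = 1`, with the
#' block-jackknife covariance of the left-hand side. Standard errors come
#' from delete-one-block re-solves; fit quality is reported as chi-squared
#' with `(M-1) - (K-1)` degrees of freedom. Negative proportion estimates
#' are reported as-is (with a warning), preserving the unbiasedness of the
#' linear solve.
#'
#' @param table a [genotype_table()].
#' @param target target population label.
#' @param sources character vector of K >= 2 source labels.
#' @param right character vector of M >= K + 1 outgroups (first is the
#'   baseline `R1`).
#' @param blocks a [build_blocks()] partition.
#' @return object of class `mixture_fit`: `alpha`, `se`, `cov`, `chisq`,
#'   `dof`, `p_value`.
#' @export
fit_mixture <- function(table, target, sources, right, blocks) {
  K <- length(sources); M <- length(right)
  if (K < 2) stop("need at least 2 sources")
  if (M < K + 1) stop("need at least K + 1 outgroups")
  pops <- c(target, sources, right)
  fr <- .pop_freqs(table, pops)
  nb <- blocks$n_blocks
  # rows: target then sources; y_kj = f4(P_k, R1; R_j, R1)
  nrows <- K + 1; ncols <- M - 1
  sums <- array(0, c(nrows, ncols, nb)); counts <- array(0L, c(nrows, ncols, nb))
  for (r in seq_len(nrows)) for (j in seq_len(ncols)) {
    d <- .fstat_contrib("f4", c(r, K + 2, K + 2 + j, K + 2), fr)
    if (all(is.na(d)))
      stop("no overlap for f4(", pops[r], ", ", right[1], "; ",
           right[j + 1], ", ", right[1], ")")
    bs <- .block_sums(d, blocks$block, nb)
    sums[r, j, ] <- bs$sums; counts[r, j, ] <- bs$counts
  }
  tot_s <- apply(sums, 1:2, sum); tot_c <- apply(counts, 1:2, sum)
  est <- tot_s / tot_c
  y <- est[1, ]; A <- est[-1, , drop = FALSE]
  # jackknife covariance of y
  yloo <- matrix(NA_real_, nb, ncols)
  for (b in seq_len(nb)) {
    cb <- tot_c[1, ] - counts[1, , b]
    yloo[b, ] <- ifelse(cb > 0, (tot_s[1, ] - sums[1, , b]) / cb, NA_real_)
  }
  Q <- .jackknife_cov(y, yloo, blocks$counts)
  Qi <- .safe_inverse(Q)
  solve_alpha <- function(yv, Am) {
    D <- sweep(Am[-K, , drop = FALSE], 2, Am[K, ])  # (K-1) x (M-1)
    yt <- yv - Am[K, ]
    G <- D %*% Qi %*% t(D)
    sv <- svd(G)$d
    kap <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
    if (!is.finite(kap) || kap > 1e8)
      stop("ill-conditioned: sources are collinear relative to the ",
           "outgroups (condition number ", signif(kap, 3), ")")
    beta <- drop(solve(G, D %*% Qi %*% yt))
    c(beta, 1 - sum(beta))
  }
  alpha <- solve_alpha(y, A)
  fit <- drop(alpha %*% A)
  chisq <- drop((y - fit) %*% Qi %*% (y - fit))
  dof <- (M - 1) - (K - 1)
  # delete-one-block re-solves (Q held fixed)
  aloo <- matrix(NA_real_, nb, K)
  for (b in seq_len(nb)) {
    cb <- tot_c - counts[, , b]
    if (any(cb == 0)) next
    eb <- (tot_s - sums[, , b]) / cb
    aloo[b, ] <- tryCatch(solve_alpha(eb[1, ], eb[-1, , drop = FALSE]),
                          error = function(e) rep(NA_real_, K))
  }
  covA <- .jackknife_cov(alpha, aloo, blocks$counts)
  se <- sqrt(pmax(diag(covA), 0))
  if (any(alpha < 0))
    warning("negative mixture proportion estimate (reported unclipped)")
  names(alpha) <- names(se) <- sources
  structure(list(target = target, sources = sources, right = right,
                 alpha = alpha, se = se, cov = covA, chisq = chisq,
                 dof = dof,
                 p_value = stats::pchisq(chisq, dof, lower.tail = FALSE)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture_fit:", x$target, "~",
      paste(sprintf("%.3f (se %.3f) %s", x$alpha, x$se, x$sources),
            collapse = " + "), "\n")
  cat(sprintf("  chisq = %.3f, dof = %d, P = %.3g\n", x$chisq, x$dof,
              x$p_value))
  invisible(x)
}

#' Outgroup-f3 statistics for all pairs of targets
#'
#' Computes `f3(outgroup; X, Y)` (shared drift of X and Y relative to the
#' outgroup) for every unordered pair of targets, with block-jackknife
#' standard errors, on each pair's maximal SNP set.
#'
#' @param table a [genotype_table()].
#' @param outgroup outgroup population label.
#' @param targets character vector of target labels.
#' @param blocks a [build_blocks()] partition.
#' @return data.frame `id1`, `id2`, `est`, `se`, `var`, `n_snps`.
#' @export
outgroup_f3_pairs <- function(table, outgroup, targets, blocks) {
  fr <- .pop_freqs(table, c(outgroup, targets))
  pairs <- utils::combn(length(targets), 2)
  out <- data.frame(id1 = targets[pairs[1, ]], id2 = targets[pairs[2, ]],
                    est = NA_real_, se = NA_real_, var = NA_real_,
                    n_snps = NA_integer_)
  for (k in seq_len(ncol(pairs))) {
    d <- .fstat_contrib("f3", c(1, 1 + pairs[1, k], 1 + pairs[2, k]), fr)
    if (all(is.na(d))) next
    bs <- .block_sums(d, blocks$block, blocks$n_blocks)
    jk <- .jackknife(bs$sums, bs$counts)
    out$est[k] <- jk$estimate; out$se[k] <- jk$se
    out$var[k] <- jk$se^2; out$n_snps[k] <- sum(bs$counts)
  }
  out
}

#' Fit the independent-mixture source-f3 model
#'
#' Under the hypothesis that each target descends from an independent
#' mixture of K sources (with no excess shared drift), the expected
#' outgroup-f3 between targets X and Y is the bilinear form
#' `alpha_X' M alpha_Y`, where `M` is a symmetric matrix of source-pair
#' shared-drift values. `M` is estimated by weighted least squares over all
#' target pairs; each pair's residual (`fitted - observed`) and excess score
#' (`observed - fitted`, positive when a pair shares more drift than the
#' mixture model predicts) quantify excess relatedness.
#'
#' @param f3_obs data.frame from [outgroup_f3_pairs()] (`id1`, `id2`, `est`,
#'   `var`).
#' @param alpha matrix (targets x K) of mixture proportions, rownames = ids.
#'   May carry extra locked columns for additional admixture components.
#' @param weights per-pair weights (default inverse variance).
#' @return object of class `source_f3_model`: `M`, `alpha`, `pairs`
#'   (data.frame with `fitted`, `residual`, `excess`, `se`).
#' @export
fit_source_f3_matrix <- function(f3_obs, alpha, weights = NULL) {
  alpha <- as.matrix(alpha)
  K <- ncol(alpha)
  use <- stats::complete.cases(f3_obs[, c("est", "var")])
  f3_obs <- f3_obs[use, ]
  npar <- K * (K + 1) / 2
  if (nrow(f3_obs) < npar)
    stop("underdetermined: ", nrow(f3_obs), " usable pairs for ", npar,
         " free parameters")
  if (is.null(weights)) weights <- 1 / f3_obs$var
  i1 <- match(f3_obs$id1, rownames(alpha))
  i2 <- match(f3_obs$id2, rownames(alpha))
  if (anyNA(i1) || anyNA(i2))
    stop("pair ids missing from alpha rownames")
  # design over upper-triangle parametrization of symmetric M
  ut <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  X <- matrix(0, nrow(f3_obs), nrow(ut))
  for (r in seq_len(nrow(ut))) {
    u <- ut[r, 1]; v <- ut[r, 2]
    X[, r] <- if (u == v) alpha[i1, u] * alpha[i2, u]
    else alpha[i1, u] * alpha[i2, v] + alpha[i1, v] * alpha[i2, u]
  }
  beta <- .pinv_solve(crossprod(X * weights, X),
                      crossprod(X * weights, f3_obs$est))
  M <- matrix(0, K, K, dimnames = list(colnames(alpha), colnames(alpha)))
  M[ut] <- beta
  M[ut[, 2:1, drop = FALSE]] <- beta
  fitted <- drop(X %*% beta)
  pairs <- data.frame(id1 = f3_obs$id1, id2 = f3_obs$id2,
                      observed = f3_obs$est, fitted = fitted,
                      residual = fitted - f3_obs$est,
                      excess = f3_obs$est - fitted,
                      se = sqrt(f3_obs$var))
  structure(list(M = M, alpha = alpha, pairs = pairs),
            class = "source_f3_model")
}

#' @export
print.source_f3_model <- function(x, ...) {
  cat("source_f3_model:", nrow(x$pairs), "pairs,", ncol(x$alpha),
      "components\n")
  print(round(x$M, 5))
  invisible(x)
}

#' Excess-relatedness records for the spatial decay fit
#'
#' Emits one (distance, excess score, variance) record per target pair,
#' attaching great-circle distances between burial sites (with the 0.001 km
#' dummy offset) and excluding pairs flagged as close kin. Targets carrying
#' extra admixture components (food-producer-related ancestry,
#' contamination) keep those components locked at the supplied values: pass
#' `locked` to overwrite columns of the model's alpha for named targets, in
#' which case the model is refit with the locked values.
#'
#' @param model a [fit_source_f3_matrix()] result.
#' @param coords data.frame `ind_id`, `lat`, `lon` (and optionally
#'   `site_id`).
#' @param kin_exclude list/character vector of flagged pairs, each
#'   `c(id1, id2)`, excluded from the output.
#' @param drop_same_site drop pairs buried at the same coordinates.
#' @param locked optional named list: target id -> named vector of alpha
#'   entries to lock.
#' @return data.frame `id1`, `id2`, `x` (km), `y` (excess score), `var_y`.
#' @export
excess_relatedness_residuals <- function(model, coords, kin_exclude = NULL,
                                         drop_same_site = FALSE,
                                         locked = NULL) {
  stopifnot(inherits(model, "source_f3_model"))
  if (!is.null(locked) && length(locked)) {
    alpha <- model$alpha
    for (id in names(locked)) {
      comp <- names(locked[[id]])
      alpha[id, comp] <- locked[[id]]
    }
    if (!identical(alpha, model$alpha)) {
      obs <- model$pairs
      model <- fit_source_f3_matrix(
        data.frame(id1 = obs$id1, id2 = obs$id2, est = obs$observed,
                   var = obs$se^2), alpha)
    }
  }
  p <- model$pairs
  j1 <- match(p$id1, coords$ind_id); j2 <- match(p$id2, coords$ind_id)
  if (anyNA(j1) || anyNA(j2)) stop("pair ids missing from coords")
  x <- haversine_km(coords$lat[j1], coords$lon[j1],
                    coords$lat[j2], coords$lon[j2])
  out <- data.frame(id1 = p$id1, id2 = p$id2, x = x, y = p$excess,
                    var_y = p$se^2)
  if (!is.null(kin_exclude)) {
    if (!is.list(kin_exclude)) kin_exclude <- list(kin_exclude)
    for (kp in kin_exclude) {
      hit <- (out$id1 == kp[1] & out$id2 == kp[2]) |
        (out$id1 == kp[2] & out$id2 == kp[1])
      if (any(hit))
        message("excluding kin-flagged pair ", kp[1], "-", kp[2])
      out <- out[!hit, ]
    }
  }
  if (drop_same_site) out <- out[out$x > 0.0015, ]
  rownames(out) <- NULL
  out
}

#' Kin detection from allele-mismatch rates
#'
#' Computes the proportion of mismatching alleles between two individuals
#' when sampling one read at random per site from each, and compares it to
#' the within-individual rate (two reads drawn without replacement at sites
#' with two or more reads). Mismatches are expected to be twice as common
#' for unrelated individuals as for within-individual comparisons, with
#' family relatives intermediate; identical samples or duplicates give a
#' ratio near 1.
#'
#' @param counts a [read_counts()] object.
#' @param pair character vector of two individual ids.
#' @param min_sites minimum overlapping sites required (default 1000).
#' @param seed integer seed for the read sampling.
#' @return object of class `kin_result`: `mismatch`, `within` (per
#'   individual), `ratio`, `band` (duplicate if ratio < 1.25, unrelated if
#'   > 1.75, else related).
#' @export
pairwise_mismatch <- function(counts, pair, min_sites = 1000, seed = 1) {
  stopifnot(inherits(counts, "read_counts"), length(pair) == 2)
  ids <- counts$ind$ind_id %||% colnames(counts$n1)
  k <- match(pair, ids)
  if (anyNA(k)) stop("unknown individual(s): ",
                     paste(pair[is.na(k)], collapse = ", "))
  restore <- .seed_scope(seed)
  on.exit(restore())
  tot <- counts$n1 + counts$n2
  both <- tot[, k[1]] > 0 & tot[, k[2]] > 0
  if (sum(both) < min_sites)
    stop("insufficient data: only ", sum(both), " overlapping sites (need ",
         min_sites, ")")
  draw1 <- function(i, sites) {
    stats::runif(length(sites)) < counts$n1[sites, i] / tot[sites, i]
  }
  sites <- which(both)
  mism <- mean(draw1(k[1], sites) != draw1(k[2], sites))
  within <- vapply(k, function(i) {
    s2 <- which(tot[, i] >= 2)
    n1 <- counts$n1[s2, i]; tt <- tot[s2, i]
    first <- stats::runif(length(s2)) < n1 / tt
    # second read without replacement
    second <- stats::runif(length(s2)) < (n1 - first) / (tt - 1)
    mean(first != second)
  }, 0)
  ratio <- mism / mean(within)
  band <- if (ratio < 1.25) "duplicate" else if (ratio > 1.75)
    "unrelated" else "related"
  structure(list(pair = pair, mismatch = mism, within = within,
                 ratio = ratio, band = band, n_sites = length(sites)),
            class = "kin_result")
}

#' @export
print.kin_result <- function(x, ...) {
  cat(sprintf("kin_result %s-%s: mismatch ratio = %.3f (%s), %d sites\n",
              x$pair[1], x$pair[2], x$ratio, x$band, x$n_sites))
  invisible(x)
}
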