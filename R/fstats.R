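#' Partition SNPs into jackknife blocks
#'
#' Greedy partition of the (position-sorted) panel into contiguous blocks of
#' at least `block_size` Morgans of genetic length. Blocks never span
#' chromosomes; the last block of each chromosome may be short.
#'
#' @param snp SNP data.frame with `chrom` and `genetic_pos` assigned.
#' @param block_size target genetic length in Morgans (default 0.05, the
#'   convention of the ADMIXTOOLS-style jackknife).
#' @return object of class `block_partition`: `block` (integer per SNP),
#'   `n_blocks`, `counts` (SNPs per block).
#' @export
build_blocks <- function(snp, block_size = 0.05) {
  n <- nrow(snp)
  if (n == 0)
    return(structure(list(block = integer(0), n_blocks = 0L,
                          counts = integer(0)),
                     class = "block_partition"))
  block <- integer(n)
  b <- 0L
  for (chr in unique(snp$chrom)) {
    idx <- which(snp$chrom == chr)
    pos <- snp$genetic_pos[idx]
    if (is.unsorted(pos)) stop("genetic positions unsorted on chromosome ", chr)
    b <- b + 1L
    start <- pos[1]
    for (k in seq_along(idx)) {
      if (pos[k] - start >= block_size) {
        b <- b + 1L
        start <- pos[k]
      }
      block[idx[k]] <- b
    }
  }
  structure(list(block = block, n_blocks = b,
                 counts = tabulate(block, b)),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat("block_partition:", x$n_blocks, "blocks,", length(x$block), "SNPs\n")
  invisible(x)
}

# Population allele-frequency summaries.
#
# pops: named list mapping population label -> individual ids, or a character
# vector of group labels. Returns per-SNP matrices: P (frequency of allele1),
# N (allele counts: 2 per non-missing diploid, 1 per pseudohaploid), and H
# (unbiased estimate of p(1-p), zero where n < 2 so that the bias correction
# degrades gracefully for single-pseudohaploid populations).
.pop_freqs <- function(table, pops) {
  stopifnot(inherits(table, "genotype_table"))
  if (!is.list(pops)) {
    labels <- pops
    pops <- lapply(labels, function(g) table$ind$ind_id[table$ind$group == g])
    names(pops) <- labels
  }
  npop <- length(pops)
  S <- nrow(table$geno)
  P <- N <- H <- matrix(NA_real_, S, npop,
                        dimnames = list(NULL, names(pops)))
  for (k in seq_len(npop)) {
    idx <- match(pops[[k]], table$ind$ind_id)
    if (anyNA(idx))
      stop("unknown individual(s) in population ", names(pops)[k])
    if (length(idx) == 0)
      stop("population ", names(pops)[k], " has no individuals")
    dip <- idx[table$ind$ploidy[idx] == "diploid"]
    ph <- idx[table$ind$ploidy[idx] == "pseudohaploid"]
    a <- n <- numeric(S)
    if (length(dip)) {
      gd <- table$geno[, dip, drop = FALSE]
      n <- n + 2 * rowSums(!is.na(gd))
      a <- a + rowSums(gd, na.rm = TRUE)
    }
    if (length(ph)) {
      gp <- table$geno[, ph, drop = FALSE]
      n <- n + rowSums(!is.na(gp))
      a <- a + rowSums(gp, na.rm = TRUE) / 2
    }
    has <- n > 0
    P[has, k] <- a[has] / n[has]
    N[, k] <- n
    h <- numeric(S)
    n2 <- n >= 2
    h[n2] <- P[n2, k] * (1 - P[n2, k]) * n[n2] / (n[n2] - 1)
    h[!has] <- NA_real_
    H[, k] <- h
  }
  list(P = P, N = N, H = H)
}

# Per-SNP contributions of one f-statistic (NA where unusable).
.fstat_contrib <- function(kind, cols, fr) {
  P <- fr$P; N <- fr$N; H <- fr$H
  if (kind == "f2") {
    x <- cols[1]; y <- cols[2]
    (P[, x] - P[, y])^2 - H[, x] / N[, x] - H[, y] / N[, y]
  } else if (kind == "f3") {
    x <- cols[1]; y <- cols[2]; z <- cols[3]
    (P[, x] - P[, y]) * (P[, x] - P[, z]) - H[, x] / N[, x]
  } else if (kind == "f4") {
    (P[, cols[1]] - P[, cols[2]]) * (P[, cols[3]] - P[, cols[4]])
  } else stop("unknown statistic kind: ", kind)
}

# Weighted delete-one-block jackknife (Busing et al. 1999). With equal
# weights this reduces to se^2 = ((B-1)/B) * sum((loo - mean(loo))^2).
.jackknife <- function(sums, counts, weights = counts) {
  use <- counts > 0 & weights > 0
  sums <- sums[use]; counts <- counts[use]; w <- weights[use]
  B <- length(sums)
  tot_s <- sum(sums); tot_c <- sum(counts)
  est <- tot_s / tot_c
  if (B < 2)
    return(list(estimate = est, se = NA_real_, loo = rep(est, B),
                n_blocks = B))
  loo <- (tot_s - sums) / (tot_c - counts)
  W <- sum(w)
  h <- W / w
  theta_j <- B * est - sum((1 - w / W) * loo)
  tau <- h * est - (h - 1) * loo
  v <- sum((tau - theta_j)^2 / (h - 1)) / B
  list(estimate = est, se = sqrt(v), loo = loo, n_blocks = B)
}

# Block-indexed sums/counts of a contribution vector.
.block_sums <- function(d, block, n_blocks) {
  use <- !is.na(d)
  sums <- numeric(n_blocks)
  if (any(use)) {
    rs <- rowsum(d[use], block[use])
    sums[as.integer(rownames(rs))] <- rs[, 1]
  }
  list(sums = sums, counts = tabulate(block[use], n_blocks))
}

#' Compute a block-jackknifed f-statistic
#'
#' Computes f2, f3 or f4 from sample allele frequencies with the standard
#' finite-sample bias corrections (f2 subtracts `h/n` for both populations,
#' f3 for its target population; f4 needs none). The estimate is the
#' SNP-weighted block average; standard errors come from a weighted
#' delete-one-block jackknife with block SNP counts as weights.
#'
#' In `allsnps` mode every SNP at which all populations of this one statistic
#' have data is used; `intersection` mode additionally requires data in all
#' populations of `all_pops` (defaulting to the statistic's own, in which
#' case the two modes coincide).
#'
#' @param table a [genotype_table()].
#' @param kind `"f2"`, `"f3"` (first population is the target) or `"f4"`.
#' @param pops character vector of group labels (2, 3 or 4 of them), or a
#'   named list mapping labels to individual ids.
#' @param blocks a [build_blocks()] partition.
#' @param snp_mode `"allsnps"` or `"intersection"`.
#' @param all_pops populations defining the intersection set.
#' @return object of class `blocked_stat` with fields `estimate`, `se`, `Z`,
#'   `n_snps_used`, `loo`, `kind`, `pops`.
#' @export
compute_fstat <- function(table, kind, pops, blocks,
                          snp_mode = c("allsnps", "intersection"),
                          all_pops = NULL) {
  snp_mode <- match.arg(snp_mode)
  npop <- c(f2 = 2L, f3 = 3L, f4 = 4L)[[kind]]
  if (length(pops) != npop)
    stop(kind, " requires ", npop, " populations")
  fr_pops <- pops
  if (snp_mode == "intersection" && !is.null(all_pops))
    fr_pops <- if (is.list(pops)) c(pops, all_pops[!names(all_pops) %in%
                                                     names(pops)])
               else union(pops, all_pops)
  fr <- .pop_freqs(table, fr_pops)
  d <- .fstat_contrib(kind, seq_len(npop), fr)
  if (snp_mode == "intersection")
    d[rowSums(is.na(fr$P)) > 0] <- NA_real_
  if (all(is.na(d)))
    stop("no overlap: zero usable SNPs for ", kind, "(",
         paste(if (is.list(pops)) names(pops) else pops, collapse = ","), ")")
  bs <- .block_sums(d, blocks$block, blocks$n_blocks)
  jk <- .jackknife(bs$sums, bs$counts)
  structure(list(kind = kind,
                 pops = if (is.list(pops)) names(pops) else pops,
                 estimate = jk$estimate, se = jk$se,
                 Z = if (isTRUE(jk$se > 0)) jk$estimate / jk$se else NA_real_,
                 n_snps_used = sum(bs$counts), loo = jk$loo),
            class = "blocked_stat")
}

#' @export
print.blocked_stat <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  se = %.3g  Z = %.2f  (%d SNPs)\n",
              x$kind, paste(x$pops, collapse = ", "), x$estimate, x$se,
              x$Z, x$n_snps_used))
  invisible(x)
}

# --- consistent f2 basis (qpfstats-style) ----------------------------------

.pair_index <- function(n) {
  # order: (1,2), (1,3), ..., (1,n), (2,3), ...
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Row of the design matrix expressing a raw statistic in the f2 basis:
# f2(i,j) itself; f3(i;j,k) = (f2(ij)+f2(ik)-f2(jk))/2;
# f4(i,j;k,l) = (f2(il)+f2(jk)-f2(ik)-f2(jl))/2.
.basis_row <- function(kind, p, pair_pos, n) {
  row <- numeric(nrow(pair_pos))
  pp <- function(a, b) which(pair_pos[, 1] == min(a, b) &
                               pair_pos[, 2] == max(a, b))
  if (kind == "f2") {
    row[pp(p[1], p[2])] <- 1
  } else if (kind == "f3") {
    row[pp(p[1], p[2])] <- row[pp(p[1], p[2])] + 0.5
    row[pp(p[1], p[3])] <- row[pp(p[1], p[3])] + 0.5
    row[pp(p[2], p[3])] <- row[pp(p[2], p[3])] - 0.5
  } else {
    row[pp(p[1], p[4])] <- row[pp(p[1], p[4])] + 0.5
    row[pp(p[2], p[3])] <- row[pp(p[2], p[3])] + 0.5
    row[pp(p[1], p[3])] <- row[pp(p[1], p[3])] - 0.5
    row[pp(p[2], p[4])] <- row[pp(p[2], p[4])] - 0.5
  }
  row
}

.enumerate_raw_stats <- function(n) {
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out[[length(out) + 1]] <- list(kind = "f2", p = c(i, j))
  if (n >= 3)
    for (x in seq_len(n)) {
      rest <- setdiff(seq_len(n), x)
      cmb <- utils::combn(rest, 2)
      for (c in seq_len(ncol(cmb)))
        out[[length(out) + 1]] <- list(kind = "f3", p = c(x, cmb[, c]))
    }
  if (n >= 4) {
    quads <- utils::combn(seq_len(n), 4)
    for (c in seq_len(ncol(quads))) {
      q <- quads[, c]
      out[[length(out) + 1]] <- list(kind = "f4", p = q[c(1, 2, 3, 4)])
      out[[length(out) + 1]] <- list(kind = "f4", p = q[c(1, 3, 2, 4)])
      out[[length(out) + 1]] <- list(kind = "f4", p = q[c(1, 4, 2, 3)])
    }
  }
  out
}

#' Solve for a consistent f2 basis under missing data
#'
#' Computes every raw f2, f3 and f4 among the populations, each on its own
#' maximal SNP set (`allsnps` behaviour), expresses each as a linear function
#' of the pairwise-f2 basis through the standard f-statistic identities, and
#' solves the overdetermined system by weighted least squares with inverse
#' jackknife-variance weights. The whole solve is repeated deleting each
#' jackknife block to obtain a covariance for the basis. With complete data
#' the identities hold exactly per SNP and the basis reproduces the direct f2
#' estimates.
#'
#' @param table a [genotype_table()].
#' @param pops character vector (>= 2) of group labels, or named list of
#'   individual ids.
#' @param blocks a [build_blocks()] partition.
#' @return object of class `f_basis`: `pops`, `f2` (symmetric matrix),
#'   `vec` (free entries, pair-ordered), `cov`, `pairs`, `loo` (blocks x
#'   pairs), `block_weights`, `n_snps_pair`.
#' @export
qpfstats_solve <- function(table, pops, blocks) {
  labels <- if (is.list(pops)) names(pops) else pops
  n <- length(labels)
  if (n < 2) stop("need at least 2 populations")
  fr <- .pop_freqs(table, pops)
  # overlap sanity: every population must share data with at least one other
  has <- !is.na(fr$P)
  for (k in seq_len(n)) {
    others <- has[, -k, drop = FALSE]
    if (!any(has[, k] & rowSums(others) > 0))
      stop("no overlap: population ", labels[k],
           " shares zero SNPs with all others")
  }
  pair_pos <- .pair_index(n)
  npair <- nrow(pair_pos)
  stats <- .enumerate_raw_stats(n)
  nb <- blocks$n_blocks
  X <- matrix(0, length(stats), npair)
  sums <- matrix(0, length(stats), nb)
  counts <- matrix(0L, length(stats), nb)
  w <- est <- numeric(length(stats))
  keep <- logical(length(stats))
  for (s in seq_along(stats)) {
    st <- stats[[s]]
    d <- .fstat_contrib(st$kind, st$p, fr)
    if (all(is.na(d))) next
    bs <- .block_sums(d, blocks$block, blocks$n_blocks)
    jk <- .jackknife(bs$sums, bs$counts)
    if (is.na(jk$se) || jk$se <= 0) next
    keep[s] <- TRUE
    X[s, ] <- .basis_row(st$kind, st$p, pair_pos, n)
    sums[s, ] <- bs$sums
    counts[s, ] <- bs$counts
    est[s] <- jk$estimate
    w[s] <- 1 / jk$se^2
  }
  if (sum(keep) < npair)
    stop("underdetermined: only ", sum(keep), " usable raw statistics for ",
         npair, " f2 basis entries")
  X <- X[keep, , drop = FALSE]; sums <- sums[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  est <- est[keep]; w <- w[keep]
  solve_wls <- function(y, rows = seq_along(y)) {
    Xr <- X[rows, , drop = FALSE]
    A <- crossprod(Xr * w[rows], Xr)
    b <- crossprod(Xr * w[rows], y)
    .pinv_solve(A, b)
  }
  beta <- solve_wls(est)
  tot_s <- rowSums(sums); tot_c <- rowSums(counts)
  loo <- matrix(NA_real_, nb, npair)
  for (j in seq_len(nb)) {
    cj <- tot_c - counts[, j]
    rows <- which(cj > 0)
    yj <- (tot_s[rows] - sums[rows, j]) / cj[rows]
    loo[j, ] <- solve_wls(yj, rows)
  }
  bw <- blocks$counts
  covb <- .jackknife_cov(beta, loo, bw)
  f2m <- matrix(0, n, n, dimnames = list(labels, labels))
  f2m[pair_pos] <- beta
  f2m <- f2m + t(f2m)
  n_pair_snps <- vapply(seq_len(npair), function(k)
    sum(has[, pair_pos[k, 1]] & has[, pair_pos[k, 2]]), 0L)
  structure(list(pops = labels, f2 = f2m, vec = beta, cov = covb,
                 pairs = pair_pos, loo = loo, block_weights = bw,
                 n_snps_pair = n_pair_snps),
            class = "f_basis")
}

#' @export
print.f_basis <- function(x, ...) {
  cat("f_basis over", length(x$pops), "populations:",
      paste(x$pops, collapse = ", "), "\n")
  print(round(x$f2, 6))
  invisible(x)
}

# Moore-Penrose solve with tolerance 1e-10 (deterministic on degenerate
# systems).
.pinv_solve <- function(A, b, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  drop(s$v[, pos, drop = FALSE] %*%
         ((crossprod(s$u[, pos, drop = FALSE], b)) / s$d[pos]))
}

# Weighted jackknife covariance (vector generalization of .jackknife).
.jackknife_cov <- function(est, loo, weights) {
  ok <- stats::complete.cases(loo) & weights > 0
  loo <- loo[ok, , drop = FALSE]
  w <- weights[ok]
  B <- nrow(loo)
  W <- sum(w)
  h <- W / w
  theta_j <- B * est - colSums((1 - w / W) * loo)
  tau <- matrix(h, B, length(est)) * rep(est, each = B) - (h - 1) * loo
  dev <- sweep(tau, 2, theta_j)
  crossprod(dev / sqrt(h - 1)) / B
}

#' Derive an f-statistic from a consistent basis
#'
#' Expresses the requested statistic as a linear combination of the f2 basis
#' by the standard identities and propagates its standard error from the
#' basis covariance. All statistics derived from one basis are mutually
#' consistent: identities such as f4 additivity hold exactly.
#'
#' @param basis an [qpfstats_solve()] result.
#' @param kind `"f2"`, `"f3"` or `"f4"`.
#' @param pops population labels present in the basis (first is the f3
#'   target). Repeated labels are allowed (e.g. `f3(O; X, X)`).
#' @return a `blocked_stat`.
#' @export
derive_stat <- function(basis, kind, pops) {
  stopifnot(inherits(basis, "f_basis"))
  p <- match(pops, basis$pops)
  if (anyNA(p)) stop("unknown population(s): ",
                     paste(pops[is.na(p)], collapse = ", "))
  n <- length(basis$pops)
  # identities with possibly repeated labels: f2(x,x)=0 terms drop out
  coef <- numeric(nrow(basis$pairs))
  add <- function(a, b, wt) {
    if (a == b) return()
    i <- which(basis$pairs[, 1] == min(a, b) & basis$pairs[, 2] == max(a, b))
    coef[i] <<- coef[i] + wt
  }
  if (kind == "f2") {
    add(p[1], p[2], 1)
  } else if (kind == "f3") {
    add(p[1], p[2], 0.5); add(p[1], p[3], 0.5); add(p[2], p[3], -0.5)
  } else if (kind == "f4") {
    add(p[1], p[4], 0.5); add(p[2], p[3], 0.5)
    add(p[1], p[3], -0.5); add(p[2], p[4], -0.5)
  } else stop("unknown statistic kind: ", kind)
  estv <- sum(coef * basis$vec)
  v <- drop(coef %*% basis$cov %*% coef)
  se <- sqrt(max(v, 0))
  structure(list(kind = kind, pops = pops, estimate = estv, se = se,
                 Z = if (se > 0) estv / se else NA_real_,
                 n_snps_used = NA_integer_,
                 loo = drop(basis$loo %*% coef)),
            class = "blocked_stat")
}
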