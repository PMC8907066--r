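#' Construct a genotype table
#'
#' A `genotype_table` bundles a SNP-by-individual genotype matrix with SNP and
#' individual metadata. Genotype values count copies of `allele1` (the fifth
#' column of the `.snp` file): 0, 1, 2, or `NA` for missing. Pseudohaploid
#' individuals (one sampled allele per site) are encoded with values in
#' \{0, 2, NA\} only, so a genotype of 2 means the single sampled allele was
#' `allele1`.
#'
#' @param geno integer matrix, SNPs in rows, individuals in columns; values in
#'   \{0, 1, 2, NA\}.
#' @param snp data.frame with columns `snp_id`, `chrom`, `genetic_pos`
#'   (Morgans), `physical_pos` (1-based bp), `allele1`, `allele2`.
#' @param ind data.frame with columns `ind_id`, `sex` (`"M"`, `"F"` or `"U"`),
#'   `group`, `ploidy` (`"diploid"` or `"pseudohaploid"`).
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(geno, snp, ind) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(snp), is.data.frame(ind))
  need_snp <- c("snp_id", "chrom", "genetic_pos", "physical_pos",
                "allele1", "allele2")
  miss <- setdiff(need_snp, names(snp))
  if (length(miss))
    stop("snp table missing columns: ", paste(miss, collapse = ", "))
  need_ind <- c("ind_id", "sex", "group", "ploidy")
  miss <- setdiff(need_ind, names(ind))
  if (length(miss))
    stop("ind table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(geno) != nrow(snp))
    stop("geno has ", nrow(geno), " rows but snp table has ", nrow(snp))
  if (ncol(geno) != nrow(ind))
    stop("geno has ", ncol(geno), " columns but ind table has ", nrow(ind))
  if (anyDuplicated(ind$ind_id))
    stop("duplicate individual ids")
  bad <- !(geno %in% c(0L, 1L, 2L)) & !is.na(geno)
  if (any(bad))
    stop("genotype values must be 0, 1, 2 or NA")
  if (any(snp$allele1 == snp$allele2))
    stop("allele1 must differ from allele2")
  ph <- which(ind$ploidy == "pseudohaploid")
  if (length(ph) && any(geno[, ph, drop = FALSE] == 1L, na.rm = TRUE))
    stop("pseudohaploid individuals cannot carry heterozygous (1) calls")
  snp$chrom <- as.character(snp$chrom)
  structure(list(geno = geno, snp = snp, ind = ind),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  nmiss <- sum(is.na(x$geno))
  cat("genotype_table: ", nrow(x$snp), " SNPs x ", nrow(x$ind),
      " individuals (", round(100 * nmiss / length(x$geno), 1),
      "% missing)\n", sep = "")
  cat("  groups: ", paste(unique(x$ind$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$geno)

#' Read an EIGENSTRAT genotype trio
#'
#' Reads the `geno`/`snp`/`ind` text trio of the ADMIXTOOLS ecosystem. The
#' `geno` file is ASCII, one line per SNP, one character per individual from
#' \{0, 1, 2, 9\}; 9 maps to missing. Individuals whose non-missing calls are
#' all homozygous are flagged pseudohaploid (they can only have arisen from
#' single-allele sampling, and downstream allele counting must treat them as
#' contributing one allele).
#'
#' @param geno_path,snp_path,ind_path paths to the three files.
#' @param ploidy optional character vector overriding the per-individual
#'   ploidy auto-detection (`"diploid"`/`"pseudohaploid"`).
#' @return a [genotype_table()].
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path, ploidy = NULL) {
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) stop("file not found: ", p)
  snp <- utils::read.table(snp_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(snp) <- c("snp_id", "chrom", "genetic_pos", "physical_pos",
                  "allele1", "allele2")
  ind <- utils::read.table(ind_path, header = FALSE,
                           colClasses = "character")
  names(ind) <- c("ind_id", "sex", "group")
  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp))
    stop("geno file has ", length(lines), " lines but snp file declares ",
         nrow(snp), " SNPs")
  nind <- nrow(ind)
  nch <- nchar(lines)
  if (any(nch != nind)) {
    bad <- which(nch != nind)[1]
    stop("geno line ", bad, " has ", nch[bad], " characters but ", nind,
         " individuals are declared")
  }
  flat <- strsplit(paste(lines, collapse = ""), "")[[1]]
  ok <- flat %in% c("0", "1", "2", "9")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("invalid genotype character '", flat[bad], "' at geno line ",
         (bad - 1) %/% nind + 1)
  }
  g <- as.integer(flat)
  g[g == 9L] <- NA_integer_
  geno <- matrix(g, nrow = nrow(snp), ncol = nind, byrow = TRUE)
  if (is.null(ploidy)) {
    has_het <- colSums(geno == 1L, na.rm = TRUE) > 0
    ploidy <- ifelse(has_het, "diploid", "pseudohaploid")
  }
  ind$ploidy <- ploidy
  genotype_table(geno, snp, ind)
}

#' Write an EIGENSTRAT genotype trio
#'
#' Inverse of [read_eigenstrat()]; missing genotypes are written as `9`.
#' Genetic positions are written with six decimal places.
#'
#' @param table a [genotype_table()].
#' @param out_prefix path prefix; `<prefix>.geno`, `.snp`, `.ind` are created.
#' @return invisibly, the three file paths.
#' @export
write_eigenstrat <- function(table, out_prefix) {
  stopifnot(inherits(table, "genotype_table"))
  paths <- paste0(out_prefix, c(".geno", ".snp", ".ind"))
  g <- table$geno
  g[is.na(g)] <- 9L
  lines <- if (nrow(g) == 0) character(0) else
    apply(g, 1, paste, collapse = "")
  ok <- tryCatch({
    writeLines(lines, paths[1])
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", paths[1])
  s <- table$snp
  utils::write.table(
    data.frame(s$snp_id, s$chrom, sprintf("%.6f", s$genetic_pos),
               s$physical_pos, s$allele1, s$allele2),
    paths[2], quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(table$ind[, c("ind_id", "sex", "group")],
                     paths[3], quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(paths)
}

#' Read a genetic map
#'
#' Accepts two ubiquitous dialects, auto-detected: PLINK `.map` (four columns,
#' no header: chrom, id, cM, bp) and HapMap-style recombination maps (header
#' line, columns chrom, position bp, rate, cumulative cM).
#'
#' @param path map file.
#' @return data.frame with columns `chrom`, `pos_bp`, `cm` (anchor points).
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(trimws(readLines(path, n = 1)), "[ \t]+")[[1]]
  nums <- suppressWarnings(as.numeric(first))
  # PLINK .map rows are (chrom, id, cM, bp): columns 3-4 numeric, no header;
  # HapMap-style files start with a header line
  hapmap <- !(length(first) == 4 && !is.na(nums[3]) && !is.na(nums[4]))
  if (hapmap) {
    m <- utils::read.table(path, header = TRUE)
    out <- data.frame(chrom = as.character(m[[1]]), pos_bp = as.integer(m[[2]]),
                      cm = as.numeric(m[[4]]))
  } else {
    m <- utils::read.table(path, header = FALSE)
    if (ncol(m) != 4) stop("PLINK .map must have 4 columns")
    out <- data.frame(chrom = as.character(m[[1]]), pos_bp = as.integer(m[[4]]),
                      cm = as.numeric(m[[3]]))
  }
  out[order(out$chrom, out$pos_bp), ]
}

#' Assign genetic positions by map interpolation
#'
#' Fills `genetic_pos` (Morgans) by piecewise-linear interpolation between map
#' anchors; positions beyond the terminal anchors are extrapolated at the
#' terminal interval's rate. With no map, a constant rate (default 1 cM/Mb)
#' is applied to physical positions.
#'
#' @param snp SNP data.frame (as in [genotype_table()]).
#' @param map anchors from [read_genetic_map()], or `NULL` for constant rate.
#' @param rate_cm_per_mb fallback constant rate.
#' @return the SNP data.frame with `genetic_pos` filled (Morgans).
#' @export
assign_genetic_positions <- function(snp, map = NULL, rate_cm_per_mb = 1) {
  if (is.null(map)) {
    snp$genetic_pos <- snp$physical_pos * rate_cm_per_mb / 1e8
    return(snp)
  }
  stopifnot(all(c("chrom", "pos_bp", "cm") %in% names(map)))
  missing_chr <- setdiff(unique(snp$chrom), unique(map$chrom))
  if (length(missing_chr))
    stop("chromosome(s) absent from map: ", paste(missing_chr, collapse = ", "))
  out <- snp
  for (chr in unique(snp$chrom)) {
    a <- map[map$chrom == chr, ]
    idx <- which(snp$chrom == chr)
    x <- snp$physical_pos[idx]
    if (nrow(a) < 2) {
      # single anchor: rate undefined, treat as constant offset
      out$genetic_pos[idx] <- a$cm[1] / 100
      next
    }
    cm <- stats::approx(a$pos_bp, a$cm, xout = x, rule = 1)$y
    # terminal-rate extrapolation
    lo <- x < a$pos_bp[1]
    hi <- x > a$pos_bp[nrow(a)]
    if (any(lo)) {
      r <- (a$cm[2] - a$cm[1]) / (a$pos_bp[2] - a$pos_bp[1])
      cm[lo] <- a$cm[1] + (x[lo] - a$pos_bp[1]) * r
    }
    if (any(hi)) {
      n <- nrow(a)
      r <- (a$cm[n] - a$cm[n - 1]) / (a$pos_bp[n] - a$pos_bp[n - 1])
      cm[hi] <- a$cm[n] + (x[hi] - a$pos_bp[n]) * r
    }
    out$genetic_pos[idx] <- cm / 100
  }
  out
}

#' Construct a read-count table
#'
#' Per-SNP, per-individual counts of reads supporting each of the two panel
#' alleles.
#'
#' @param n1,n2 non-negative integer matrices (SNPs x individuals) of reads
#'   supporting `allele1` and `allele2`.
#' @param snp,ind metadata as in [genotype_table()] (`ind$ploidy` optional).
#' @return object of class `read_counts`.
#' @export
read_counts <- function(n1, n2, snp = NULL, ind = NULL) {
  n1 <- as.matrix(n1); n2 <- as.matrix(n2)
  if (!identical(dim(n1), dim(n2))) stop("count matrices differ in dimension")
  if (any(n1 < 0, na.rm = TRUE) || any(n2 < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  n1[is.na(n1)] <- 0L; n2[is.na(n2)] <- 0L
  storage.mode(n1) <- "integer"; storage.mode(n2) <- "integer"
  structure(list(n1 = n1, n2 = n2, snp = snp, ind = ind),
            class = "read_counts")
}

#' Read a TSV read-count table
#'
#' Long format with header `snp_id ind_id n_allele1 n_allele2`; cells absent
#' from the file have zero reads.
#'
#' @param path TSV file.
#' @param snp,ind optional metadata fixing row/column order.
#' @return a [read_counts()] object.
#' @export
read_counts_tsv <- function(path, snp = NULL, ind = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character",
                                        "integer", "integer"))
  need <- c("snp_id", "ind_id", "n_allele1", "n_allele2")
  if (!all(need %in% names(d)))
    stop("read-count TSV needs header: ", paste(need, collapse = " "))
  snps <- if (is.null(snp)) unique(d$snp_id) else snp$snp_id
  inds <- if (is.null(ind)) unique(d$ind_id) else ind$ind_id
  n1 <- n2 <- matrix(0L, length(snps), length(inds))
  i <- match(d$snp_id, snps); j <- match(d$ind_id, inds)
  keep <- !is.na(i) & !is.na(j)
  n1[cbind(i[keep], j[keep])] <- d$n_allele1[keep]
  n2[cbind(i[keep], j[keep])] <- d$n_allele2[keep]
  read_counts(n1, n2, snp, ind)
}

#' Pseudohaploid genotypes from read counts
#'
#' Implements random-allele genotype calling: at each covered site one read is
#' drawn uniformly at random and the genotype is set homozygous for its
#' allele (2 if `allele1`, 0 otherwise). Sites with zero reads are missing.
#'
#' @param counts a [read_counts()] object.
#' @param seed integer; the draw is reproducible under it. Required.
#' @return a [genotype_table()] with all individuals pseudohaploid; if
#'   `counts` carries no metadata, minimal placeholder metadata is built.
#' @export
reads_to_pseudohaploid <- function(counts, seed) {
  stopifnot(inherits(counts, "read_counts"))
  if (missing(seed)) stop("an explicit seed is required")
  tot <- counts$n1 + counts$n2
  g <- matrix(NA_integer_, nrow(tot), ncol(tot))
  cov <- tot > 0
  withr_seed <- .seed_scope(seed)
  on.exit(withr_seed())
  u <- matrix(stats::runif(length(tot)), nrow(tot))
  g[cov] <- ifelse(u[cov] < counts$n1[cov] / tot[cov], 2L, 0L)
  snp <- counts$snp %||% .placeholder_snp(nrow(tot))
  ind <- counts$ind %||% .placeholder_ind(ncol(tot))
  ind$ploidy <- "pseudohaploid"
  genotype_table(g, snp, ind)
}

#' Genotype likelihoods from read counts
#'
#' Converts allele read counts to normalized Phred-scaled genotype
#' likelihoods (PL) under a symmetric per-read error model:
#' `L(hom1) = (1-e)^n1 e^n2`, `L(het) = 0.5^(n1+n2)`,
#' `L(hom2) = e^n1 (1-e)^n2`, Phred-scaled and shifted so the per-site
#' minimum is 0. Zero-coverage sites give the uninformative triple (0,0,0).
#'
#' @param counts a [read_counts()] object.
#' @param base_error per-read error rate, in (0, 0.5).
#' @return object of class `pl_table`: matrices `hom1`, `het`, `hom2`
#'   (SNPs x individuals) plus the metadata carried by `counts`.
#' @export
reads_to_likelihoods <- function(counts, base_error = 0.01) {
  stopifnot(inherits(counts, "read_counts"))
  if (base_error <= 0 || base_error >= 0.5)
    stop("base_error must be in (0, 0.5)")
  n1 <- counts$n1; n2 <- counts$n2
  # log10 likelihoods
  l1 <- n1 * log10(1 - base_error) + n2 * log10(base_error)
  lh <- (n1 + n2) * log10(0.5)
  l2 <- n1 * log10(base_error) + n2 * log10(1 - base_error)
  p1 <- -10 * l1; ph <- -10 * lh; p2 <- -10 * l2
  m <- pmin(p1, ph, p2)
  structure(list(hom1 = p1 - m, het = ph - m, hom2 = p2 - m,
                 snp = counts$snp, ind = counts$ind),
            class = "pl_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.placeholder_snp <- function(n) {
  data.frame(snp_id = sprintf("snp%06d", seq_len(n)), chrom = "1",
             genetic_pos = seq_len(n) * 1e-6, physical_pos = seq_len(n) * 100L,
             allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
}

.placeholder_ind <- function(n) {
  data.frame(ind_id = sprintf("ind%03d", seq_len(n)), sex = "U",
             group = sprintf("ind%03d", seq_len(n)), ploidy = "pseudohaploid",
             stringsAsFactors = FALSE)
}

# Run code under a local RNG seed, restoring the caller's RNG state.
.seed_scope <- function(seed) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
}
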