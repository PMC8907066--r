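#' Specify an admixture graph for simulation
#'
#' Drift along each edge is Balding–Nichols style: a child's allele frequency
#' is Beta-distributed around the parent's with variance `F * p * (1 - p)`.
#' Admixture nodes take a linear mixture of their sources' frequencies.
#'
#' @param edges data.frame with columns `parent`, `child`, `f` (drift, in
#'   `[0, 1)`).
#' @param admix optional list of `list(node =, sources =, alpha =)` entries;
#'   `alpha` must be non-negative and sum to 1.
#' @param root_freq_range law of the root frequency (uniform on this range).
#' @return object of class `graph_spec`.
#' @export
graph_spec <- function(edges, admix = list(),
                       root_freq_range = c(0.05, 0.95)) {
  stopifnot(all(c("parent", "child", "f") %in% names(edges)))
  if (any(edges$f < 0 | edges$f >= 1))
    stop("edge drift F must be in [0, 1)")
  for (a in admix) {
    if (any(a$alpha < 0) || abs(sum(a$alpha) - 1) > 1e-12)
      stop("admixture proportions must be non-negative and sum to 1")
    if (length(a$alpha) != length(a$sources))
      stop("admixture sources/alpha length mismatch")
  }
  children <- c(edges$child, vapply(admix, `[[`, "", "node"))
  if (anyDuplicated(children))
    stop("a node may have only one parent or admixture definition")
  parents <- unique(edges$parent)
  roots <- setdiff(parents, children)
  all_sources <- unique(unlist(lapply(admix, `[[`, "sources")))
  roots <- setdiff(unique(c(parents, all_sources)), children)
  if (length(roots) != 1)
    stop("graph must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  nodes <- unique(c(roots, children, parents, all_sources))
  structure(list(nodes = nodes, edges = edges, admix = admix,
                 root = roots, root_freq_range = root_freq_range),
            class = "graph_spec")
}

# Topological order of graph nodes.
.topo_order <- function(graph) {
  deps <- c(
    lapply(seq_len(nrow(graph$edges)), function(i)
      list(node = graph$edges$child[i], parents = graph$edges$parent[i])),
    lapply(graph$admix, function(a)
      list(node = a$node, parents = a$sources)))
  order <- graph$root
  remaining <- deps
  while (length(remaining)) {
    ready <- vapply(remaining, function(d) all(d$parents %in% order), TRUE)
    if (!any(ready)) stop("graph is cyclic or disconnected")
    order <- c(order, vapply(remaining[ready], `[[`, "", "node"))
    remaining <- remaining[!ready]
  }
  order
}

#' Simulate allele frequencies down an admixture graph
#'
#' @param graph a [graph_spec()].
#' @param n_snps number of variants.
#' @param seed integer seed (the generator is a pure function of spec and
#'   seed).
#' @return numeric matrix, nodes x SNPs, frequencies of allele1 in `[0, 1]`.
#' @export
simulate_frequencies <- function(graph, n_snps, seed) {
  stopifnot(inherits(graph, "graph_spec"))
  restore <- .seed_scope(seed)
  on.exit(restore())
  ord <- .topo_order(graph)
  P <- matrix(NA_real_, length(ord), n_snps, dimnames = list(ord, NULL))
  P[graph$root, ] <- stats::runif(n_snps, graph$root_freq_range[1],
                                  graph$root_freq_range[2])
  admix_nodes <- vapply(graph$admix, `[[`, "", "node")
  for (nd in ord[-1]) {
    ai <- match(nd, admix_nodes)
    if (!is.na(ai)) {
      a <- graph$admix[[ai]]
      P[nd, ] <- drop(a$alpha %*% P[a$sources, , drop = FALSE])
    } else {
      e <- which(graph$edges$child == nd)
      p <- P[graph$edges$parent[e], ]
      P[nd, ] <- .beta_drift(p, graph$edges$f[e])
    }
  }
  P
}

# Beta drift step with mean p and variance F * p * (1 - p).
.beta_drift <- function(p, f) {
  if (f == 0) return(p)
  out <- p
  interior <- p > 0 & p < 1
  k <- 1 / f - 1
  out[interior] <- stats::rbeta(sum(interior), p[interior] * k,
                                (1 - p[interior]) * k)
  out
}

# Shared drift step with *absolute* variance delta (f2 units), common across
# all frequency vectors in `plist` (the same Gaussian innovation is applied
# to each, so any two of them acquire covariance delta). Clipped to [0, 1];
# with delta on the 0.001-0.01 scale clipping is negligible.
.shared_drift <- function(plist, delta, n_snps) {
  if (delta <= 0) return(plist)
  z <- stats::rnorm(n_snps, 0, sqrt(delta))
  lapply(plist, function(p) pmin(pmax(p + z, 0), 1))
}

#' Default demographic graph for the synthetic forager panel
#'
#' A deep outgroup (`Neand`), a west-African-related outgroup (`WAfr`) and
#' three deeply diverged African source lineages: `S_E` (eastern,
#' Mota-related), `S_C` (central-forager-related) and `S_S`
#' (southern-forager-related), each paired with a cousin outgroup (`AgawL`,
#' `AkaL`, `KhoL`) splitting from the same ancestral lineage. The cousin
#' outgroups make the sources distinguishable in f4 space, as required by
#' rank tests and mixture fitting.
#'
#' @return a [graph_spec()].
#' @export
default_forager_graph <- function() {
  edges <- data.frame(
    parent = c("Root", "Root", "AFR", "AfrW", "AFR",
               "AfrE", "CAanc", "CAanc",
               "AfrE", "SAanc", "SAanc",
               "AfrE", "EAanc", "EAanc"),
    child = c("Neand", "AFR", "AfrW", "WAfr", "AfrE",
              "CAanc", "AkaL", "S_C",
              "SAanc", "KhoL", "S_S",
              "EAanc", "AgawL", "S_E"),
    f = c(0.5, 0.05, 0.10, 0.05, 0.05,
          0.08, 0.06, 0.06,
          0.08, 0.06, 0.06,
          0.08, 0.06, 0.06))
  graph_spec(edges)
}

#' Simulate genotype and read-count data for individuals
#'
#' Each individual is tied to a node of a frequency matrix. Diploid
#' genotypes are Binomial(2, p); per-SNP read depth is Poisson(coverage);
#' each read carries the individual's allele (sampled from its genotype)
#' except with probability `contam_c`, when it is drawn from the contaminant
#' node's frequency. Pseudohaploid individuals get genotypes via
#' [reads_to_pseudohaploid()]; diploid individuals keep their true genotypes
#' (emulating high-coverage diploid calls).
#'
#' @param freqs node x SNP frequency matrix from [simulate_frequencies()].
#' @param inds data.frame with columns `ind_id`, `node`, `group`, `coverage`,
#'   `ploidy`, and optionally `contam_c`, `contam_node`.
#' @param snp optional SNP metadata (placeholder built if absent).
#' @param seed integer seed.
#' @return list with `table` ([genotype_table()]), `counts`
#'   ([read_counts()]), and `truth` (generating parameters).
#' @export
simulate_individuals <- function(freqs, inds, snp = NULL, seed) {
  stopifnot(is.matrix(freqs))
  if (is.null(inds$contam_c)) inds$contam_c <- 0
  if (is.null(inds$contam_node)) inds$contam_node <- NA_character_
  if (any(inds$coverage < 0)) stop("coverage must be non-negative")
  bad <- setdiff(inds$node, rownames(freqs))
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  S <- ncol(freqs)
  n <- nrow(inds)
  restore <- .seed_scope(seed)
  on.exit(restore())
  snp <- snp %||% .placeholder_snp(S)
  geno <- matrix(NA_integer_, S, n)
  n1 <- n2 <- matrix(0L, S, n)
  gtrue <- matrix(NA_integer_, S, n)
  for (k in seq_len(n)) {
    p <- freqs[inds$node[k], ]
    g <- stats::rbinom(S, 2, p)
    gtrue[, k] <- g
    depth <- stats::rpois(S, inds$coverage[k])
    cvr <- depth > 0
    if (any(cvr)) {
      pr_read <- g[cvr] / 2
      cc <- inds$contam_c[k]
      if (cc > 0) {
        pc <- freqs[inds$contam_node[k], cvr]
        pr_read <- (1 - cc) * pr_read + cc * pc
      }
      r1 <- stats::rbinom(sum(cvr), depth[cvr], pr_read)
      n1[cvr, k] <- r1
      n2[cvr, k] <- depth[cvr] - r1
    }
  }
  ind_meta <- data.frame(ind_id = inds$ind_id, sex = "U",
                         group = inds$group, ploidy = inds$ploidy,
                         stringsAsFactors = FALSE)
  counts <- read_counts(n1, n2, snp, ind_meta)
  ph_seed <- stats::runif(1)  # consumed from the scoped stream
  ph <- reads_to_pseudohaploid(counts, seed = floor(ph_seed * 2^31))
  is_dip <- inds$ploidy == "diploid"
  geno <- ph$geno
  geno[, is_dip] <- gtrue[, is_dip]
  table <- genotype_table(geno, snp, ind_meta)
  truth <- list(inds = inds, seed = seed, genotypes = gtrue)
  list(table = table, counts = counts, truth = truth)
}

#' Describe a geographic ancestry-cline scenario
#'
#' Defaults emulate the structure of an eastern/south-central African forager
#' panel: three regional clusters whose three-way ancestry proportions match
#' the study region's pattern (western-Kenya-like 62/19/19,
#' north-central-Tanzania-like 54/12/34, Malawi/Zambia-like 25/7.5/67.5,
#' ordered eastern/central/southern), sites spread over realistic
#' coordinates, and per-individual capture coverage drawn log-normally with
#' median 0.06x, truncated to [0.001, 3.2].
#'
#' @param sites data.frame `site_id`, `cluster`, `lat`, `lon`.
#' @param alpha matrix (sites x 3) of per-site source proportions
#'   (`S_E`, `S_C`, `S_S`), rows summing to 1.
#' @param inds_per_site individuals simulated per site.
#' @param delta_site,delta_cluster shared-drift increments (f2 units) for
#'   same-site and same-cluster pairs.
#' @param coverage `NULL` to draw from the default coverage law, or a single
#'   number / per-individual vector of Poisson depths.
#' @param n_ref diploid reference individuals per source/outgroup population.
#' @return object of class `cline_scenario`.
#' @export
cline_scenario <- function(sites = NULL, alpha = NULL, inds_per_site = 2,
                           delta_site = 0.005, delta_cluster = 0.002,
                           coverage = NULL, n_ref = 4) {
  if (is.null(sites)) {
    sites <- data.frame(
      site_id = c("WK1", "WK2", "WK3", "TZ1", "TZ2", "TZ3",
                  "MW1", "MW2", "MW3", "ZM1"),
      cluster = c("westKenya", "westKenya", "westKenya",
                  "Tanzania", "Tanzania", "Tanzania",
                  "Malawi", "Malawi", "Malawi", "Malawi"),
      lat = c(-0.1, -0.3, 0.4, -4.4, -4.9, -7.9,
              -11.6, -13.8, -14.1, -14.3),
      lon = c(34.3, 34.7, 34.5, 35.4, 35.8, 36.5,
              33.6, 33.8, 34.9, 32.1))
  }
  if (is.null(alpha)) {
    by_cluster <- rbind(westKenya = c(0.62, 0.19, 0.19),
                        Tanzania = c(0.54, 0.12, 0.34),
                        Malawi = c(0.25, 0.075, 0.675))
    alpha <- by_cluster[sites$cluster, , drop = FALSE]
    rownames(alpha) <- sites$site_id
  }
  if (any(abs(rowSums(alpha) - 1) > 1e-9))
    stop("per-site alpha must sum to 1")
  if (delta_site < 0 || delta_cluster < 0) stop("delta values must be >= 0")
  structure(list(sites = sites, alpha = alpha,
                 inds_per_site = inds_per_site,
                 delta_site = delta_site, delta_cluster = delta_cluster,
                 coverage = coverage, n_ref = n_ref),
            class = "cline_scenario")
}

# Coverage law of the emulated capture panel: log-normal, median 0.06x,
# truncated to the observed range 0.001-3.2x.
.draw_coverage <- function(n) {
  pmin(pmax(stats::rlnorm(n, log(0.06), 1.3), 0.001), 3.2)
}

#' Simulate a full cline dataset
#'
#' Generates source/outgroup frequencies down [default_forager_graph()],
#' mixes them per site with the scenario's proportions, layers hierarchical
#' shared drift (cluster level, then site level) so that same-cluster and
#' same-site pairs carry known excess relatedness, and simulates
#' pseudohaploid target individuals plus diploid reference panels.
#'
#' @param scenario a [cline_scenario()].
#' @param n_snps panel size (default 100000; a scaled-down stand-in for a
#'   ~1.2M-SNP capture panel).
#' @param seed integer seed.
#' @return list: `table`, `counts`, `coords` (data.frame `ind_id`,
#'   `site_id`, `lat`, `lon`), `truth` (alphas, deltas, per-pair expected
#'   excess, seeds).
#' @export
simulate_cline_dataset <- function(scenario, n_snps = 100000, seed) {
  stopifnot(inherits(scenario, "cline_scenario"))
  restore <- .seed_scope(seed)
  on.exit(restore())
  graph <- default_forager_graph()
  freqs <- simulate_frequencies(graph, n_snps,
                                seed = floor(stats::runif(1) * 2^31))
  sites <- scenario$sites
  sources <- c("S_E", "S_C", "S_S")
  site_freq <- lapply(seq_len(nrow(sites)), function(s)
    drop(scenario$alpha[s, ] %*% freqs[sources, , drop = FALSE]))
  names(site_freq) <- sites$site_id
  # hierarchical shared drift: cluster level, then site level
  for (cl in unique(sites$cluster)) {
    member <- which(sites$cluster == cl)
    site_freq[member] <- .shared_drift(site_freq[member],
                                       scenario$delta_cluster, n_snps)
  }
  site_freq <- lapply(site_freq, function(p)
    .shared_drift(list(p), scenario$delta_site, n_snps)[[1]])
  freqs2 <- rbind(freqs, do.call(rbind, site_freq))
  rownames(freqs2) <- c(rownames(freqs), paste0("site_", sites$site_id))
  # individuals: pseudohaploid targets per site + diploid reference panels
  tg <- do.call(rbind, lapply(seq_len(nrow(sites)), function(s)
    data.frame(site = sites$site_id[s],
               ind_id = sprintf("%s_I%d", sites$site_id[s],
                                seq_len(scenario$inds_per_site)))))
  ncov <- nrow(tg)
  coverage <- scenario$coverage %||% .draw_coverage(ncov)
  if (length(coverage) == 1) coverage <- rep(coverage, ncov)
  targets <- data.frame(ind_id = tg$ind_id,
                        node = paste0("site_", tg$site),
                        group = tg$ind_id,  # one population per individual
                        coverage = coverage,
                        ploidy = "pseudohaploid")
  refs <- do.call(rbind, lapply(
    c("Neand", "WAfr", "AkaL", "KhoL", "AgawL", sources),
    function(p) data.frame(
      ind_id = sprintf("%s_%d", p, seq_len(scenario$n_ref)),
      node = p, group = p, coverage = 0, ploidy = "diploid")))
  inds <- rbind(targets, refs)
  sim <- simulate_individuals(freqs2, inds, snp = .uniform_panel(n_snps),
                              seed = floor(stats::runif(1) * 2^31))
  coords <- data.frame(ind_id = tg$ind_id, site_id = tg$site,
                       lat = sites$lat[match(tg$site, sites$site_id)],
                       lon = sites$lon[match(tg$site, sites$site_id)])
  # per-pair expected excess shared drift (f2 units)
  if (nrow(tg) >= 2) {
    pairs <- utils::combn(tg$ind_id, 2)
    s1 <- tg$site[match(pairs[1, ], tg$ind_id)]
    s2 <- tg$site[match(pairs[2, ], tg$ind_id)]
    c1 <- sites$cluster[match(s1, sites$site_id)]
    c2 <- sites$cluster[match(s2, sites$site_id)]
    excess <- ifelse(c1 == c2, scenario$delta_cluster, 0) +
      ifelse(s1 == s2, scenario$delta_site, 0)
  } else {
    pairs <- matrix(character(0), 2, 0)
    excess <- numeric(0)
  }
  truth <- list(scenario = scenario, seed = seed,
                alpha = scenario$alpha[match(tg$site, sites$site_id), ,
                                       drop = FALSE],
                pair_excess = data.frame(id1 = pairs[1, ], id2 = pairs[2, ],
                                         expected_excess = excess),
                sources = sources,
                outgroups = c("Neand", "WAfr", "AkaL", "KhoL", "AgawL"))
  rownames(truth$alpha) <- tg$ind_id
  list(table = sim$table, counts = sim$counts, coords = coords,
       truth = truth)
}

# Uniformly spaced marker panel over 22 autosomes with human-like genetic
# lengths (constant 1 cM/Mb).
.uniform_panel <- function(n_snps, genome = genome_spec()) {
  G <- genome$lengths
  per <- pmax(1L, floor(n_snps * G / sum(G)))
  # distribute the remainder over the longest chromosomes
  short <- n_snps - sum(per)
  if (short > 0) {
    ord <- order(G, decreasing = TRUE)
    per[ord[seq_len(short)]] <- per[ord[seq_len(short)]] + 1L
  } else if (short < 0) {
    ord <- order(per, decreasing = TRUE)
    for (i in ord) {
      take <- min(per[i] - 1L, -short)
      per[i] <- per[i] - take; short <- short + take
      if (short == 0) break
    }
  }
  chrom <- rep(seq_along(G), per)
  gpos <- unlist(lapply(seq_along(G), function(i)
    seq(0, G[i], length.out = per[i] + 1)[-1]))
  data.frame(snp_id = sprintf("snp%07d", seq_along(chrom)),
             chrom = as.character(chrom),
             genetic_pos = gpos,
             physical_pos = as.integer(round(gpos * 1e8)),
             allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
}

#' Simulate read counts for a pair of relatives
#'
#' Generates two individuals from one panmictic population with a specified
#' relationship, plus Poisson read coverage, for exercising the
#' allele-mismatch kin test: `duplicate` shares both chromosomes,
#' `parent_child` shares exactly one allele per site by Mendelian
#' transmission, `unrelated` individuals are independent draws.
#'
#' @param p vector of population allele frequencies.
#' @param relationship one of `"duplicate"`, `"parent_child"`, `"unrelated"`.
#' @param coverage mean read depth per site (same for both individuals).
#' @param seed integer seed.
#' @return a [read_counts()] with two individuals.
#' @export
simulate_kin_reads <- function(p, relationship = c("duplicate",
                                                   "parent_child",
                                                   "unrelated"),
                               coverage = 5, seed) {
  relationship <- match.arg(relationship)
  restore <- .seed_scope(seed)
  on.exit(restore())
  S <- length(p)
  a1 <- stats::rbinom(S, 1, p); a2 <- stats::rbinom(S, 1, p)
  g1 <- a1 + a2
  g2 <- switch(relationship,
               duplicate = g1,
               parent_child = ifelse(stats::runif(S) < 0.5, a1, a2) +
                 stats::rbinom(S, 1, p),
               unrelated = stats::rbinom(S, 2, p))
  n1 <- n2 <- matrix(0L, S, 2)
  for (k in 1:2) {
    g <- if (k == 1) g1 else g2
    depth <- stats::rpois(S, coverage)
    r1 <- stats::rbinom(S, depth, g / 2)
    n1[, k] <- r1
    n2[, k] <- depth - r1
  }
  read_counts(n1, n2, .placeholder_snp(S),
              data.frame(ind_id = c("A", "B"), sex = "U",
                         group = c("A", "B"), ploidy = "pseudohaploid"))
}

#' Simulate noisy decay-curve points
#'
#' Generative twin of the excess-relatedness decay model:
#' `y = 1 / (m x + a) + b` plus Gaussian noise with the stated per-point
#' variance.
#'
#' @param m,a,b curve constants; `m * x + a` must stay positive.
#' @param distances vector of distances x (km).
#' @param noise_vars per-point variances (recycled).
#' @param seed integer seed.
#' @return data.frame `x`, `y`, `var_y`.
#' @export
simulate_decay_points <- function(m, a, b, distances, noise_vars, seed) {
  if (any(m * distances + a <= 0))
    stop("m * x + a must be positive over the supplied distances")
  restore <- .seed_scope(seed)
  on.exit(restore())
  v <- rep_len(noise_vars, length(distances))
  y <- 1 / (m * distances + a) + b +
    stats::rnorm(length(distances), 0, sqrt(v))
  data.frame(x = distances, y = y, var_y = v)
}
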