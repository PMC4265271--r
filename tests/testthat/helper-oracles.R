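# Independent oracles used to cross-check the package implementations.
# They share no code with the package: the DBSCAN oracle goes through an
# explicit neighbor graph and igraph's connected components, and the F_ST
# oracle is a direct transcription of the per-allele variance components of
# the Weir & Cockerham (1984) estimator in its general r-population form.

# Brute-force DBSCAN: neighbor graph, core points, connected components of
# the core subgraph, then border points attached to the cluster of their
# lowest-index core neighbor (the same tie rule the implementation uses).
oracle_dbscan <- function(points, eps, min_pts) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  adj <- d <= eps
  core <- rowSums(adj) >= min_pts
  labels <- integer(n)
  if (any(core)) {
    core_idx <- which(core)
    sub <- adj[core_idx, core_idx, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[core_idx] <- comp
    for (i in which(!core)) {
      cn <- which(adj[i, ] & core)
      if (length(cn)) labels[i] <- labels[min(cn)]
    }
  }
  labels
}

# Renumber cluster ids by order of first appearance so two labelings of the
# same partition compare exactly; noise (0) is left alone.
canon_labels <- function(lab) {
  pos <- lab > 0
  u <- unique(lab[pos])
  lab[pos] <- match(lab[pos], u)
  lab
}

# Weir & Cockerham (1984) theta-hat, general form: per-locus, per-allele
# variance components a, b, c summed over alleles and loci. For two
# populations and two alleles this must agree with the streamlined
# implementation to floating-point accuracy.
oracle_wc_theta <- function(counts_list) {
  # counts_list: list of matrices (pop x 3 genotype counts), one per locus
  num <- 0; den <- 0
  for (cnt in counts_list) {
    r <- nrow(cnt)
    n_i <- rowSums(cnt)
    if (any(n_i == 0)) next
    p_i <- (2 * cnt[, 3] + cnt[, 2]) / (2 * n_i)   # freq of allele B
    h_i <- cnt[, 2] / n_i
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (freqs in list(p_i, 1 - p_i)) {            # sum over both alleles
      pbar <- sum(n_i * freqs) / (r * nbar)
      s2 <- sum(n_i * (freqs - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)          # het involves this allele
      a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
             (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
             (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Two Gaussian blobs plus optional uniform background, for clustering tests.
make_blobs <- function(n_per, centers, sd, n_noise = 0) {
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  if (n_noise > 0)
    x <- rbind(x, cbind(runif(n_noise), runif(n_noise)))
  x
}

# A compressed two-cluster assay at the published step parameters: angular
# centers `sep` apart, lognormal intensity around a common level. Returns
# points in clustering coordinates plus the true split.
make_compressed_assay <- function(n_per = 50, sep = 0.10, theta_sd = 0.02,
                                  r_cv = 0.1, r_weight = 0.25) {
  truth <- rep(1:2, each = n_per)
  centers <- 0.45 + c(0, sep)
  theta <- pmin(1, pmax(0, rnorm(2 * n_per, centers[truth], theta_sd)))
  r <- exp(rnorm(2 * n_per, 0, sqrt(log(1 + r_cv^2))))
  rs <- r / quantile(r, 0.95, names = FALSE)
  list(x = cbind(theta, r_weight * rs), theta = theta, r_scaled = rs,
       truth = truth)
}
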