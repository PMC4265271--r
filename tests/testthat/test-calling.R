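# small helper: cluster model for one marker built directly from labeled
# points in clustering coordinates
mk_model <- function(theta, r_scaled, labels, r_scale = 1) {
  mm <- polyclust:::marker_model(theta, r_scaled, labels, r_scale)
  mm <- detect_null_clusters(mm)
  label_clusters(mm)
}

wrap_model <- function(mm, marker = "m1") {
  structure(list(markers = setNames(list(mm), marker), params = NULL),
            class = "cluster_model")
}

panel_from <- function(theta, r, marker = "m1") {
  ids <- sprintf("s%03d", seq_along(theta))
  structure(list(theta = matrix(theta, 1, dimnames = list(marker, ids)),
                 r = matrix(r, 1, dimnames = list(marker, ids)),
                 samples = data.frame(sample_id = ids, population = "panel",
                                      stringsAsFactors = FALSE)),
            class = "intensity_panel")
}

test_that("confidence scoring has the right limiting behavior", {
  set.seed(11)
  theta <- c(rnorm(30, 0.1, 0.01), rnorm(30, 0.9, 0.01))
  rs <- rep(1, 60)
  mm <- mk_model(theta, rs, rep(1:2, each = 30))
  # at a cluster center with the other cluster far away: confidence ~ 1
  a <- polyclust:::assign_marker(mm, c(0.1, 0.9), c(1, 1), 0.8)
  expect_true(all(a$confidence > 0.999))
  expect_equal(a$call, c("C1", "C2"))
  # exactly midway between clusters of identical spread: confidence 1/2, NC
  mm$clusters$spread_theta <- c(0.02, 0.02)
  mm$clusters$spread_r <- c(0.02, 0.02)
  mm$clusters$center_theta <- c(0.1, 0.9)
  mm$clusters$center_r <- c(1, 1)
  mid <- polyclust:::assign_marker(mm, 0.5, 1, 0.8)
  expect_equal(mid$confidence, 0.5, tolerance = 1e-9)
  expect_equal(mid$call, "NC")
  # a single-cluster model gives every finite point confidence 1
  one <- mk_model(theta[1:30], rs[1:30], rep(1L, 30))
  a1 <- polyclust:::assign_marker(one, c(0.1, 0.12), c(1, 1), 0.8)
  expect_equal(a1$confidence, c(1, 1))
})

test_that("points far from every stored cluster are not force-called", {
  set.seed(12)
  theta <- c(rnorm(30, 0.1, 0.01), rnorm(30, 0.9, 0.01))
  mm <- mk_model(theta, rep(1, 60), rep(1:2, each = 30))
  # relative responsibility would call it, the absolute distance cutoff not
  far <- polyclust:::assign_marker(mm, 0.1, 0.2, 0.8)
  expect_equal(far$call, "NC")
})

test_that("lowering the confidence limit never removes calls", {
  set.seed(13)
  theta <- pmin(1, pmax(0, c(rnorm(60, 0.45, 0.03), rnorm(60, 0.58, 0.03))))
  mm <- mk_model(theta, rep(1, 120), rep(1:2, each = 60))
  model <- wrap_model(mm)
  panel <- panel_from(theta, rep(1, 120))
  called <- vapply(c(0.95, 0.8, 0.6, 0.5), function(lim)
    sum(assign_samples(model, panel, lim)$calls != "NC"), numeric(1))
  expect_true(all(diff(called) >= 0))
})

test_that("maf covers allele, cluster and degenerate cases", {
  expect_equal(as.numeric(maf(rep("AA", 10))), 0)
  expect_equal(as.numeric(maf(c(rep("AA", 3), "BB"))), 0.25)
  expect_equal(as.numeric(maf(c("AA", "AB", "AB", "BB"))), 0.5)
  expect_error(maf(rep("NC", 5)), "no non-NC")
  # A/B label swap symmetry
  set.seed(14)
  for (i in 1:20) {
    calls <- sample(c("AA", "AB", "BB", "NC"), 50, replace = TRUE)
    if (all(calls == "NC")) next
    swapped <- chartr("AB", "BA", calls)
    swapped[calls == "AB"] <- "AB"
    swapped[calls == "NC"] <- "NC"
    expect_equal(as.numeric(maf(calls)), as.numeric(maf(swapped)))
  }
  # multi-cluster calls fall back to minimum cluster frequency
  mc <- maf(c(rep("C1", 6), rep("C2", 3), "C3"))
  expect_equal(as.numeric(mc), 0.1)
  expect_equal(attr(mc, "method"), "cluster_frequency")
})

test_that("assay filters enforce cluster number, call rate and MAF by mode", {
  calls <- c(rep("AA", 40), rep("AB", 30), rep("BB", 25), rep("NC", 5))
  pass <- filter_assay(calls, 3, c(2, 6), 0.9, 0.35)
  expect_true(pass$pass)
  lowmaf <- c(rep("AA", 80), rep("BB", 15), rep("NC", 5))
  f1 <- filter_assay(lowmaf, 2, c(2, 6), 0.9, 0.35)  # mapping threshold
  expect_false(f1$pass)
  expect_equal(f1$reasons, "maf")
  f2 <- filter_assay(lowmaf, 2, c(2, 6), 0.9, 0.05)  # diversity threshold
  expect_true(f2$pass)
  f3 <- filter_assay(calls, 1, c(2, 6), 0.9, 0.05)
  expect_equal(f3$reasons, "cluster_number")
  # per-population MAF: a marker monomorphic in one cross but 1:1 in another
  pops <- rep(c("p1", "p2"), each = 50)
  cc <- c(rep("AA", 50), rep(c("AA", "BB"), 25))
  f4 <- filter_assay(cc, 2, c(2, 6), 0.9, 0.35, populations = pops)
  expect_true(f4$pass)
  f5 <- filter_assay(cc, 2, c(2, 6), 0.9, 0.35)
  expect_false(f5$pass)
})

test_that("cluster labeling orders by theta and withholds genotypes correctly", {
  mk <- function(centers_theta, centers_r = NULL, nulls = NULL) {
    n <- length(centers_theta)
    if (is.null(centers_r)) centers_r <- rep(1, n)
    cl <- data.frame(cluster = 1:n, center_theta = centers_theta,
                     center_r = centers_r, spread_theta = 0.02,
                     spread_r = 0.02, median_r = centers_r, n = 50,
                     null = if (is.null(nulls)) rep(FALSE, n) else nulls,
                     label = NA_character_, genotype = NA_character_)
    label_clusters(list(clusters = cl, r_scale = 1))
  }
  m3 <- mk(c(0.95, 0.05, 0.48))
  expect_equal(m3$clusters$label, c("C3", "C1", "C2"))
  expect_equal(m3$clusters$genotype, c("BB", "AA", "AB"))
  m4 <- mk(c(0.05, 0.3, 0.6, 0.95))
  expect_equal(sort(m4$clusters$label), c("C1", "C2", "C3", "C4"))
  expect_true(all(is.na(m4$clusters$genotype)))
  m2 <- mk(c(0.05, 0.95))
  expect_equal(m2$clusters$label, c("C1", "C2"))
  # a null cluster is excluded from ordinal/genotype labeling
  mn <- mk(c(0.05, 0.5, 0.95), centers_r = c(1, 0.05, 1),
           nulls = c(FALSE, TRUE, FALSE))
  expect_equal(mn$clusters$label, c("C1", "NULL", "C2"))
  expect_true(all(is.na(mn$clusters$genotype)))
})

test_that("null flagging uses the relative median-intensity rule", {
  mk <- function(med) list(clusters = data.frame(
    cluster = seq_along(med), center_theta = seq_along(med) / 10,
    center_r = med, spread_theta = 0.02, spread_r = 0.02, median_r = med,
    n = 50, null = FALSE, label = NA_character_,
    genotype = NA_character_), r_scale = 1)
  f <- detect_null_clusters(mk(c(1.0, 0.95, 0.08)))
  expect_equal(f$clusters$null, c(FALSE, FALSE, TRUE))
  g <- detect_null_clusters(mk(c(1.0, 0.9)))
  expect_false(any(g$clusters$null))
  h <- detect_null_clusters(mk(0.05))   # single cluster: rule not applied
  expect_false(any(h$clusters$null))
})

test_that("the protocol routes assays to the step matching their geometry", {
  # well-separated three-cluster assay -> step 1
  simple <- simulate_panel(
    list(assay_design("easy")),
    list(population_design("diversity", 300, allele_freq = 0.4)),
    noise_model(seed = 21))
  r1 <- run_protocol(simple$panel, protocol_params("diversity"))
  expect_equal(r1$report$status, "accepted")
  expect_equal(r1$report$step, 1L)
  expect_equal(r1$report$n_clusters, 3L)

  # compressed pair -> merged in step 1, split in step 2
  comp <- simulate_panel(
    list(assay_design("tight", n_hyb_sites = 7)),
    list(population_design("diversity", 300, allele_freq = 0.5,
                           inbreeding = 1)),
    noise_model(seed = 22))
  r2 <- run_protocol(comp$panel, protocol_params("diversity"))
  expect_equal(r2$report$step, 2L)
  expect_equal(r2$report$n_clusters, 2L)

  # broad clusters, sparse at radius 0.07 but clustering at 0.09 -> step 3
  set.seed(2)
  n <- 12
  theta <- pmin(1, pmax(0, c(rnorm(n, 0.2, 0.05), rnorm(n, 0.8, 0.05))))
  r <- exp(rnorm(2 * n, 0, 0.1))
  broad <- panel_from(theta, r, "broad")
  r3 <- run_protocol(broad, protocol_params("diversity"))
  expect_equal(r3$report$step, 3L)
  expect_equal(r3$report$n_clusters, 2L)

  # every marker gets exactly one terminal status
  expect_equal(nrow(r1$report) + nrow(r2$report) + nrow(r3$report), 3L)
})

test_that("protocol call concordance is exact on a noiseless panel", {
  sim <- simulate_panel(
    list(assay_design("a"), assay_design("b", n_hyb_sites = 2)),
    list(population_design("diversity", 200, allele_freq = 0.5)),
    noise_model(theta_sd = 0, r_cv = 0, seed = 31))
  res <- run_protocol(sim$panel, protocol_params("diversity"))
  cc <- call_concordance(res, sim$truth)
  expect_equal(cc$concordance, 1)
  expect_equal(cc$nc_rate, 0)
})
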