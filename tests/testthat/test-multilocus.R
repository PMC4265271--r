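test_that("segregation detection applies the pair-frequency and size rules", {
  # near-1:1 doubled-haploid split
  rec <- detect_segregation(c(rep("C2", 52), rep("C3", 48)))
  expect_equal(c(rec$cluster_a, rec$cluster_b), c("C2", "C3"))
  expect_gt(rec$ratio_p, 0.05)
  # monomorphic population: nothing segregates
  expect_null(detect_segregation(rep("C1", 80)))
  # third cluster below min_points does not block the top pair
  rec2 <- detect_segregation(c(rep("C1", 60), rep("C2", 40), rep("C3", 5)))
  expect_equal(c(rec2$cluster_a, rec2$cluster_b), c("C1", "C2"))
  # third cluster at min_points pushes the pair below 90% combined: none
  expect_null(detect_segregation(c(rep("C1", 60), rep("C2", 40),
                                   rep("C3", 15))))
  # a qualifying pair must itself have min_points on both sides
  expect_null(detect_segregation(c(rep("C1", 90), rep("C2", 5))))
  # NC calls are excluded from the denominator
  rec3 <- detect_segregation(c(rep("C1", 30), rep("C2", 30), rep("NC", 40)))
  expect_false(is.null(rec3))
})

test_that("segregation rule matches brute-force enumeration on count tables", {
  enumerate_rule <- function(counts, min_points = 10, min_pair = 0.9) {
    counts <- sort(counts, decreasing = TRUE)
    if (length(counts) < 2) return(NULL)
    if (counts[1] < min_points || counts[2] < min_points) return(NULL)
    if ((counts[1] + counts[2]) / sum(counts) < min_pair) return(NULL)
    sort(names(counts)[1:2])
  }
  set.seed(41)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    counts <- setNames(sample(0:60, k, replace = TRUE), paste0("C", 1:k))
    counts <- counts[counts > 0]
    if (length(counts) < 2) next
    calls <- rep(names(counts), counts)
    rec <- detect_segregation(sample(calls))
    want <- enumerate_rule(counts)
    if (is.null(want)) expect_null(rec)
    else expect_equal(c(rec$cluster_a, rec$cluster_b), want)
  }
})

test_that("two crosses sharing one cluster resolve into two loci with a hub", {
  out <- multilocus_scenario(n_assays = 5, n_per_pop = 100,
                             noise = noise_model(seed = 51))
  res <- run_protocol(out$panel, protocol_params("mapping"))
  expect_true(all(res$report$status == "accepted"))
  part <- setNames(out$panel$samples$population,
                   out$panel$samples$sample_id)
  recs <- segregation_records(res$genotypes, res$model, part)
  map <- build_allelic_map(recs, res$model)
  exp_pairs <- attr(out, "expected")
  for (m in rownames(out$panel$theta)) {
    ed <- map$edges[map$edges$marker == m, ]
    expect_equal(nrow(ed), 2L)
    got1 <- ed[ed$populations == "cross1", ]
    expect_equal(sort(c(got1$cluster_a, got1$cluster_b)),
                 sort(exp_pairs$cross1))
    got2 <- ed[ed$populations == "cross2", ]
    expect_equal(sort(c(got2$cluster_a, got2$cluster_b)),
                 sort(exp_pairs$cross2))
    expect_equal(map$hubs$cluster[map$hubs$marker == m], exp_pairs$hub)
  }
  expect_equal(nrow(map$unresolved), 0L)
  expect_length(map$conflicts, 0L)
})

test_that("the allelic map is invariant to record processing order", {
  out <- multilocus_scenario(n_assays = 3, n_per_pop = 80,
                             noise = noise_model(seed = 52))
  res <- run_protocol(out$panel, protocol_params("mapping"))
  part <- setNames(out$panel$samples$population,
                   out$panel$samples$sample_id)
  recs <- segregation_records(res$genotypes, res$model, part)
  map_fwd <- build_allelic_map(recs, res$model)
  map_rev <- build_allelic_map(recs[rev(seq_len(nrow(recs))), ], res$model)
  expect_equal(map_fwd, map_rev, ignore_attr = TRUE)
})

test_that("conflicting records flag the marker and leave it unresolved", {
  model <- structure(list(markers = list(mX = list(
    clusters = data.frame(cluster = 1:3, center_theta = c(0.1, 0.5, 0.9),
                          center_r = 1, spread_theta = 0.02, spread_r = 0.02,
                          median_r = 1, n = 50, null = FALSE,
                          label = c("C1", "C2", "C3"),
                          genotype = NA_character_),
    r_scale = 1)), params = NULL), class = "cluster_model")
  recs <- data.frame(marker = "mX", population = c("p1", "p1"),
                     cluster_a = c("C1", "C2"), cluster_b = c("C3", "C3"),
                     n_a = 50, n_b = 50, ratio_p = 1)
  map <- build_allelic_map(recs, model)
  expect_equal(map$conflicts, "mX")
  expect_equal(sort(map$unresolved$cluster), c("C1", "C2", "C3"))
  expect_equal(nrow(map$edges), 0L)
})

test_that("a diversity-panel biallelic marker yields one locus and no hub", {
  sim <- simulate_panel(
    list(assay_design("bi")),
    list(population_design("DH", 100, label = "cross",
                           parents = list(founder("AA"), founder("BB")))),
    noise_model(seed = 53))
  res <- run_protocol(sim$panel, protocol_params("mapping"))
  part <- setNames(sim$panel$samples$population, sim$panel$samples$sample_id)
  recs <- segregation_records(res$genotypes, res$model, part)
  map <- build_allelic_map(recs, res$model)
  expect_equal(nrow(map$edges), 1L)
  expect_equal(nrow(map$hubs), 0L)
})
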