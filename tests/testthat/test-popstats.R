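# build a calls matrix from a list of per-marker call vectors
calls_matrix <- function(lst, samples = NULL) {
  m <- do.call(rbind, lst)
  rownames(m) <- names(lst)
  colnames(m) <- if (is.null(samples)) sprintf("s%02d", seq_len(ncol(m)))
                 else samples
  m
}

test_that("expected heterozygosity averages gene diversity over polymorphic markers", {
  # p in {0.1, 0.3, 0.5} -> 2p(1-p) in {0.18, 0.42, 0.5}; mean 0.366667
  gm <- calls_matrix(list(
    m1 = c(rep("BB", 1), rep("AA", 9)),             # p = 0.1
    m2 = c(rep("BB", 3), rep("AA", 7)),             # p = 0.3
    m3 = c(rep("BB", 5), rep("AA", 5))))            # p = 0.5
  part <- setNames(rep("pop", 10), colnames(gm))
  expect_equal(unname(mean_heterozygosity(gm, part)),
               mean(c(0.18, 0.42, 0.5)), tolerance = 1e-12)
  # all markers at p = 0.5 -> maximum gene diversity
  gm2 <- calls_matrix(list(m1 = rep(c("AA", "BB"), 5)))
  expect_equal(unname(mean_heterozygosity(gm2, part)), 0.5)
  # monomorphic population: undefined
  gm3 <- calls_matrix(list(m1 = rep("AA", 10)))
  expect_true(is.na(mean_heterozygosity(gm3, part)))
  # observed heterozygosity counts het calls directly
  gm4 <- calls_matrix(list(m1 = c(rep("AB", 4), rep("AA", 3), rep("BB", 3))))
  expect_equal(unname(mean_heterozygosity(gm4, part, "observed")), 0.4)
})

test_that("Weir-Cockerham F_ST has the fixation and null limits", {
  # populations fixed for alternative alleles, equal sizes -> exactly 1
  expect_equal(weir_cockerham_fst(c(10, 0, 0), c(0, 0, 10)), 1)
  # identical genotype counts -> no differentiation, estimator <= 0 + eps
  expect_lte(weir_cockerham_fst(c(5, 5, 5), c(5, 5, 5)), 1e-12)
  # symmetry
  set.seed(61)
  a <- matrix(sample(0:20, 30, replace = TRUE), ncol = 3)
  b <- matrix(sample(0:20, 30, replace = TRUE), ncol = 3)
  expect_equal(weir_cockerham_fst(a, b), weir_cockerham_fst(b, a))
  # zero total variance is undefined
  expect_true(is.na(weir_cockerham_fst(c(10, 0, 0), c(10, 0, 0))))
})

test_that("F_ST matches an independent transcription of the WC84 components", {
  # the printed two-population single-marker case: 18/2 vs 2/18 allele counts
  a <- c(AA = 1, AB = 0, BB = 9)   # p(B) = 18/20... counts: 2*9+0=18 of 20
  b <- c(AA = 9, AB = 0, BB = 1)
  got <- weir_cockerham_fst(a, b)
  want <- oracle_wc_theta(list(rbind(a, b)))
  expect_equal(got, want, tolerance = 1e-12)
  set.seed(62)
  for (i in 1:30) {
    L <- sample(1:6, 1)
    tabs <- lapply(seq_len(L), function(l)
      rbind(sample(0:30, 3, replace = TRUE) + c(1, 0, 0),
            sample(0:30, 3, replace = TRUE) + c(0, 0, 1)))
    ca <- do.call(rbind, lapply(tabs, function(t) t[1, ]))
    cb <- do.call(rbind, lapply(tabs, function(t) t[2, ]))
    expect_equal(weir_cockerham_fst(ca, cb), oracle_wc_theta(tabs),
                 tolerance = 1e-12)
  }
})

test_that("LD r-squared recovers the haplotype closed form and its limits", {
  # haplotype counts AB=40, Ab=10, aB=10, ab=40: D = 0.15, r^2 = 0.36
  g1 <- rep(c(2, 2, 0, 0), c(40, 10, 10, 40))
  g2 <- rep(c(2, 0, 2, 0), c(40, 10, 10, 40))
  r2 <- ld_r2(g1, g2)
  expect_equal(as.numeric(r2), 0.36, tolerance = 1e-12)
  expect_equal(attr(r2, "method"), "haplotype")
  # perfectly co-inherited markers
  expect_equal(as.numeric(ld_r2(rep(c(0, 2), 20), rep(c(0, 2), 20))), 1)
  # label-swap invariance at either marker
  expect_equal(as.numeric(ld_r2(2 - g1, g2)), 0.36, tolerance = 1e-12)
  expect_equal(as.numeric(ld_r2(g1, 2 - g2)), 0.36, tolerance = 1e-12)
  # unphased data falls back to genotype correlation
  h1 <- c(0, 1, 2, 1, 0, 2, 1, 0)
  h2 <- c(0, 1, 2, 1, 0, 2, 1, 0)
  rh <- ld_r2(h1, h2)
  expect_equal(attr(rh, "method"), "genotype_correlation")
  expect_equal(as.numeric(rh), 1)
  # independently shuffled markers sit near zero
  set.seed(63)
  x <- sample(rep(c(0, 2), 500)); y <- sample(rep(c(0, 2), 500))
  expect_lt(as.numeric(ld_r2(x, y)), 0.05)
  # monomorphic marker undefined
  expect_true(is.na(ld_r2(rep(2, 10), rep(c(0, 2), 5))))
})

test_that("shared polymorphism counts match exhaustive enumeration", {
  samples <- sprintf("s%02d", 1:12)
  part <- setNames(rep(c("A", "B", "C"), each = 4), samples)
  gm <- calls_matrix(list(
    m1 = c("AA", "AB", "AA", "AA",  "BB", "BB", "BB", "BB",  "AA", "AB", "BB", "AA"),
    m2 = c("AA", "AA", "AA", "AA",  "AA", "AB", "AA", "AA",  "BB", "BB", "BB", "BB"),
    m3 = c("AB", "AB", "AA", "BB",  "AA", "AA", "AA", "AA",  "AA", "AA", "AA", "AA"),
    m4 = c("AA", "AA", "AA", "AA",  "AA", "AA", "AA", "AA",  "AA", "AA", "AA", "AA"),
    m5 = c("AA", "BB", "AA", "BB",  "AA", "BB", "AA", "BB",  "AA", "BB", "AA", "BB")),
    samples)
  sh <- shared_polymorphic(gm, part)
  # brute force over the toy table
  poly <- sapply(c("A", "B", "C"), function(p) {
    apply(gm[, part == p], 1, function(cc) {
      d <- c(AA = 0, AB = 1, BB = 2)[cc]
      pr <- sum(d) / (2 * length(d)); pr > 0 && pr < 1
    })
  })
  for (i in 1:3) for (j in 1:3)
    expect_equal(sh[i, j], sum(poly[, i] & poly[, j]))
  # idempotence: diagonal equals each population's own polymorphic count
  expect_equal(unname(diag(sh)), unname(colSums(poly)))
  # markers polymorphic in one population only are in no shared pair
  expect_equal(sh["A", "B"], sum(poly[, "A"] & poly[, "B"]))
})

test_that("pairwise table combines shared counts and F_ST consistently", {
  samples <- sprintf("s%02d", 1:20)
  part <- setNames(rep(c("A", "B"), each = 10), samples)
  gm <- calls_matrix(list(
    m1 = c(rep("AA", 10), rep("BB", 10)),
    m2 = rep(c("AA", "BB"), 10)), samples)
  tab <- pairwise_stats(gm, part)
  expect_equal(tab["A", "B"], 1)                 # only m2 shared
  fst <- pairwise_fst(gm, part)
  expect_equal(tab["B", "A"], fst["A", "B"])
  expect_equal(fst["A", "B"], fst["B", "A"])
  expect_gt(fst["A", "B"], 0.4)                  # m1 fully differentiates
})

test_that("maf spectrum bins markers by minor allele frequency", {
  gm <- calls_matrix(list(
    m1 = c(rep("AA", 9), "BB"),       # maf 0.1
    m2 = c(rep("AA", 5), rep("BB", 5)),  # maf 0.5
    m3 = rep("AA", 10)))              # maf 0
  sp <- maf_spectrum(gm)
  expect_equal(sum(sp$count), 3)
  expect_equal(sp$count[sp$bin_high == 0.5], 1)
  expect_equal(sp$count[sp$bin_low == 0.05 & sp$bin_high == 0.1], 1)
})
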