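#' Describe one array assay and the gene copies its probe hybridizes to
#'
#' In a polyploid genome a single Infinium II probe may anneal to several
#' homoeologous or paralogous gene copies. Only one of them (the target site)
#' carries the segregating SNP; the others contribute a constitutive allele
#' signal, which compresses the angular separation between genotype clusters.
#' A site may additionally carry a failure haplotype (gene deletion or
#' divergence of the probe annealing site) that silences its contribution in
#' carriers, producing extra clusters or, for single-copy probes, null
#' (near-origin) signals.
#'
#' @param marker_id Character scalar naming the assay.
#' @param n_hyb_sites Number of gene copies the probe hybridizes to (>= 1).
#' @param target_site Index (1-based) of the copy carrying the segregating SNP.
#' @param fixed_alleles Character vector of length `n_hyb_sites` giving the
#'   constitutive allele ("A" or "B") contributed by each non-target site;
#'   the entry at `target_site` is ignored (use `NA`). Default: all "A".
#' @param site_failures Logical vector of length `n_hyb_sites`; `TRUE` marks a
#'   site silenced in carriers of the failure haplotype. Default: none.
#' @param failure_freq Frequency of the failure haplotype in a diversity
#'   population (carriers are treated as homozygous for it).
#' @param weights Positive per-site signal weights (default equal). Equal
#'   weights reproduce the canonical compressed-cluster geometry; unequal
#'   weights are accepted for robustness experiments.
#' @param pop_overrides Optional named list (by population label) overriding
#'   population-level genetics for this marker: elements `allele_freq`,
#'   `inbreeding`, `parents` (see [population_design()]). Each locus has its
#'   own allele frequency and founder alleles, so these are naturally
#'   per-marker quantities.
#' @return An object of class `assay_design`.
#' @seealso [expected_dosage()], [simulate_panel()]
#' @export
assay_design <- function(marker_id, n_hyb_sites = 1L, target_site = 1L,
                         fixed_alleles = NULL, site_failures = NULL,
                         failure_freq = 0, weights = NULL,
                         pop_overrides = NULL) {
  stopifnot(is.character(marker_id), length(marker_id) == 1L)
  n_hyb_sites <- as.integer(n_hyb_sites)
  target_site <- as.integer(target_site)
  if (n_hyb_sites < 1L) stop("n_hyb_sites must be >= 1")
  if (target_site < 1L || target_site > n_hyb_sites)
    stop("target_site must lie in 1..n_hyb_sites")
  if (is.null(fixed_alleles)) {
    fixed_alleles <- rep("A", n_hyb_sites)
    fixed_alleles[target_site] <- NA_character_
  }
  if (length(fixed_alleles) != n_hyb_sites)
    stop("fixed_alleles must have one entry per hybridizing site")
  bad <- which(!is.na(fixed_alleles) & !fixed_alleles %in% c("A", "B"))
  bad <- setdiff(bad, target_site)
  if (length(bad)) stop("fixed_alleles must be 'A' or 'B' at non-target sites")
  if (is.null(site_failures)) site_failures <- rep(FALSE, n_hyb_sites)
  stopifnot(is.logical(site_failures), length(site_failures) == n_hyb_sites)
  stopifnot(failure_freq >= 0, failure_freq <= 1)
  if (is.null(weights)) weights <- rep(1, n_hyb_sites)
  stopifnot(length(weights) == n_hyb_sites, all(weights > 0))
  structure(
    list(marker_id = marker_id, n_hyb_sites = n_hyb_sites,
         target_site = target_site, fixed_alleles = fixed_alleles,
         site_failures = site_failures, failure_freq = failure_freq,
         weights = weights, pop_overrides = pop_overrides),
    class = "assay_design")
}

#' Normalized polar angle of a two-channel dosage pair
#'
#' Theta is the angle of deviation from the pure A-channel signal on the
#' normalized polar scale used for array genotyping plots: 0 is a pure
#' A-allele signal, 1 a pure B-allele signal.
#'
#' @param x_dose,y_dose Non-negative allele doses on the A (x) and B (y)
#'   channel. Vectorized.
#' @return Theta in \[0, 1\]: `(2/pi) * atan2(y_dose, x_dose)`.
#' @examples
#' dosage_to_theta(2, 0)   # 0   : pure A signal
#' dosage_to_theta(0, 2)   # 1   : pure B signal
#' dosage_to_theta(1, 1)   # 0.5 : balanced heterozygote
#' @export
dosage_to_theta <- function(x_dose, y_dose) {
  if (any(x_dose < 0) || any(y_dose < 0))
    stop("doses must be non-negative")
  if (any(x_dose + y_dose == 0))
    stop("theta undefined: both channel doses are zero (null signal)")
  (2 / pi) * atan2(y_dose, x_dose)
}

#' Expected two-channel dosage for a genotype under an assay design
#'
#' Sums per-site allele contributions: every hybridizing site contributes two
#' allele doses (one per haplotype), split 1+1 between channels for a
#' heterozygous target site. Sites silenced by the failure haplotype
#' contribute nothing, so a failed single-copy assay yields the (0, 0) null
#' signal.
#'
#' @param design An [assay_design()].
#' @param genotype One of `"AA"`, `"AB"`, `"BB"` at the target site.
#' @param failure_carrier Logical: does this sample carry (homozygously) the
#'   failure haplotype silencing the flagged sites?
#' @return Named numeric vector `c(x_dose, y_dose)`.
#' @export
expected_dosage <- function(design, genotype, failure_carrier = FALSE) {
  stopifnot(inherits(design, "assay_design"))
  genotype <- match.arg(genotype, c("AA", "AB", "BB"))
  x <- 0; y <- 0
  for (s in seq_len(design$n_hyb_sites)) {
    if (failure_carrier && design$site_failures[s]) next
    w <- design$weights[s]
    if (s == design$target_site) {
      if (genotype == "AA") x <- x + 2 * w
      else if (genotype == "BB") y <- y + 2 * w
      else { x <- x + w; y <- y + w }
    } else if (design$fixed_alleles[s] == "A") {
      x <- x + 2 * w
    } else {
      y <- y + 2 * w
    }
  }
  c(x_dose = x, y_dose = y)
}

#' Founder genotype for a bi-parental population
#'
#' @param genotype `"AA"`, `"AB"` or `"BB"` at the target site.
#' @param failure Logical: does the founder carry the probe-failure haplotype?
#' @export
founder <- function(genotype = "AA", failure = FALSE) {
  genotype <- match.arg(genotype, c("AA", "AB", "BB"))
  list(genotype = genotype, failure = isTRUE(failure))
}

#' Describe a simulated population
#'
#' Three kinds are supported: `diversity` (unrelated accessions with
#' per-locus allele frequency and optional inbreeding), `DH` (doubled
#' haploids from a bi-parental cross, homozygous, segregating 1:1 with a small
#' residual heterozygosity), and `F4` (partially heterozygous bi-parental
#' progeny; expected residual heterozygosity 1/8 after three selfing
#' generations).
#'
#' @param kind `"diversity"`, `"DH"` or `"F4"`.
#' @param n_samples Number of samples.
#' @param label Population label used in sample metadata and sample ids.
#' @param allele_freq Frequency of the B allele at the target site
#'   (diversity kind; per-marker override possible via the design).
#' @param het_rate Residual heterozygosity: default 0.02 for DH, 0.125 for F4.
#' @param inbreeding Wright's inbreeding coefficient for the diversity kind
#'   (0 = Hardy-Weinberg, 1 = fully inbred accessions). Default 0.
#' @param parents List of two [founder()] genotypes (required for DH/F4).
#' @return An object of class `population_design`.
#' @export
population_design <- function(kind = c("diversity", "DH", "F4"), n_samples,
                              label = NULL, allele_freq = 0.5,
                              het_rate = NULL, inbreeding = 0,
                              parents = NULL) {
  kind <- match.arg(kind)
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 1L)
  if (is.null(label)) label <- kind
  if (is.null(het_rate)) het_rate <- switch(kind, DH = 0.02, F4 = 0.125, 0)
  stopifnot(allele_freq >= 0, allele_freq <= 1,
            het_rate >= 0, het_rate <= 1,
            inbreeding >= 0, inbreeding <= 1)
  if (kind %in% c("DH", "F4")) {
    if (is.null(parents) || length(parents) != 2L)
      stop("DH/F4 populations require a list of two founder() genotypes")
  }
  structure(
    list(kind = kind, n_samples = n_samples, label = label,
         allele_freq = allele_freq, het_rate = het_rate,
         inbreeding = inbreeding, parents = parents),
    class = "population_design")
}

#' Noise model for simulated intensities
#'
#' Angular noise is additive Gaussian truncated to \[0, 1\]; intensity noise
#' is multiplicative lognormal, which keeps both supports valid without
#' rejection sampling. Null (no-signal) points get a uniform theta and a low
#' background intensity: the angle of a no-signal point is pure noise, which
#' is what gives real null clusters their horizontal spread.
#'
#' @param theta_sd Standard deviation of the angular noise.
#' @param r_cv Coefficient of variation of the multiplicative intensity noise.
#' @param r_baseline Mean background intensity of null signals.
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @export
noise_model <- function(theta_sd = 0.02, r_cv = 0.1, r_baseline = 0.05,
                        seed = 1L) {
  stopifnot(theta_sd >= 0, r_cv >= 0, r_baseline > 0)
  structure(list(theta_sd = theta_sd, r_cv = r_cv, r_baseline = r_baseline,
                 seed = as.integer(seed)),
            class = "noise_model")
}

## genotype/carrier draws for one (marker, population); returns data.frame
draw_population <- function(design, pop) {
  n <- pop$n_samples
  ov <- design$pop_overrides[[pop$label]]
  p <- if (!is.null(ov$allele_freq)) ov$allele_freq else pop$allele_freq
  f_inb <- if (!is.null(ov$inbreeding)) ov$inbreeding else pop$inbreeding
  parents <- if (!is.null(ov$parents)) ov$parents else pop$parents
  any_fail <- any(design$site_failures)

  if (pop$kind == "diversity") {
    pr <- c(AA = (1 - p)^2 + f_inb * p * (1 - p),
            AB = 2 * p * (1 - p) * (1 - f_inb),
            BB = p^2 + f_inb * p * (1 - p))
    geno <- sample(c("AA", "AB", "BB"), n, replace = TRUE, prob = pr)
    carrier <- if (any_fail)
      stats::runif(n) < design$failure_freq else rep(FALSE, n)
  } else {
    g1 <- parents[[1]]$genotype; g2 <- parents[[2]]$genotype
    pick <- sample(1:2, n, replace = TRUE)
    geno <- c(g1, g2)[pick]
    if (g1 != g2) {
      het <- stats::runif(n) < pop$het_rate
      geno[het] <- "AB"
    }
    f1 <- parents[[1]]$failure; f2 <- parents[[2]]$failure
    if (any_fail && (f1 || f2)) {
      if (f1 == f2) {
        carrier <- rep(f1, n)
      } else {
        # failure segregates; carriers are homozygous for the failed haplotype
        p_carrier <- if (pop$kind == "DH") 0.5 else (1 - pop$het_rate) / 2
        carrier <- stats::runif(n) < p_carrier
      }
    } else carrier <- rep(FALSE, n)
  }
  data.frame(genotype = geno, carrier = carrier, stringsAsFactors = FALSE)
}

#' Simulate a two-channel intensity panel with ground truth
#'
#' For every (assay design, population, sample) triple the generator draws a
#' target-site genotype and failure-carrier state, sums per-site allele doses
#' into the two channels, converts to (theta, R) with `R` proportional to the
#' total hybridized dose, and applies the noise model. The returned truth
#' table records the generating configuration of every point, including the
#' expected cluster index: non-null dosage configurations ranked by (theta,
#' total dose), with the null configuration, when present, indexed last.
#'
#' @param designs List of [assay_design()] objects (one per marker).
#' @param pops List of [population_design()] objects.
#' @param noise A [noise_model()]; its seed makes the panel reproducible.
#' @return List with elements `panel` (an `intensity_panel`: `theta` and `r`
#'   marker-by-sample matrices plus a `samples` metadata data frame) and
#'   `truth` (long data frame: marker, sample, population, genotype, x_dose,
#'   y_dose, null, cluster).
#' @export
simulate_panel <- function(designs, pops, noise = noise_model()) {
  if (length(designs) == 0L) stop("at least one assay design is required")
  if (length(pops) == 0L) stop("at least one population is required")
  if (inherits(designs, "assay_design")) designs <- list(designs)
  if (inherits(pops, "population_design")) pops <- list(pops)
  markers <- vapply(designs, `[[`, character(1), "marker_id")
  if (anyDuplicated(markers)) stop("duplicate marker ids in designs")
  labels <- vapply(pops, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate population labels")

  sample_ids <- unlist(lapply(pops, function(p)
    paste0(p$label, "_", formatC(seq_len(p$n_samples),
                                 width = nchar(p$n_samples), flag = "0"))))
  sample_pop <- rep(labels, vapply(pops, `[[`, integer(1), "n_samples"))
  n_total <- length(sample_ids)

  set.seed(noise$seed)
  sdlog <- sqrt(log(1 + noise$r_cv^2))
  theta_m <- matrix(NA_real_, length(markers), n_total,
                    dimnames = list(markers, sample_ids))
  r_m <- theta_m
  truth <- vector("list", length(markers))

  for (mi in seq_along(designs)) {
    des <- designs[[mi]]
    geno <- character(n_total); carrier <- logical(n_total)
    off <- 0L
    for (pop in pops) {
      dr <- draw_population(des, pop)
      idx <- off + seq_len(pop$n_samples)
      geno[idx] <- dr$genotype; carrier[idx] <- dr$carrier
      off <- off + pop$n_samples
    }
    # dosages for the six (genotype, carrier) combinations
    key <- paste0(geno, ifelse(carrier, "+", "-"))
    combos <- unique(key)
    dose_tab <- vapply(combos, function(k) {
      g <- substr(k, 1, 2); fc <- substr(k, 3, 3) == "+"
      expected_dosage(des, g, fc)
    }, numeric(2))
    xd <- dose_tab["x_dose", match(key, combos)]
    yd <- dose_tab["y_dose", match(key, combos)]
    is_null <- (xd + yd) == 0

    th <- rep(NA_real_, n_total)
    if (any(!is_null))
      th[!is_null] <- dosage_to_theta(xd[!is_null], yd[!is_null])
    th_obs <- numeric(n_total)
    th_obs[!is_null] <- pmin(1, pmax(0, th[!is_null] +
      stats::rnorm(sum(!is_null), 0, noise$theta_sd)))
    if (any(is_null)) th_obs[is_null] <- stats::runif(sum(is_null))
    r_true <- ifelse(is_null, noise$r_baseline, (xd + yd) / 2)
    r_obs <- r_true * exp(stats::rnorm(n_total, 0, sdlog))

    theta_m[mi, ] <- th_obs
    r_m[mi, ] <- r_obs

    # expected cluster index: non-null configs by (theta, dose), null last
    cfg <- unique(data.frame(x = xd[!is_null], y = yd[!is_null]))
    if (nrow(cfg)) {
      cfg$theta <- dosage_to_theta(cfg$x, cfg$y)
      cfg <- cfg[order(cfg$theta, cfg$x + cfg$y), , drop = FALSE]
      cfg$rank <- seq_len(nrow(cfg))
    }
    cluster <- integer(n_total)
    if (any(!is_null))
      cluster[!is_null] <- cfg$rank[match(paste(xd[!is_null], yd[!is_null]),
                                          paste(cfg$x, cfg$y))]
    cluster[is_null] <- nrow(cfg) + 1L
    truth[[mi]] <- data.frame(
      marker = des$marker_id, sample = sample_ids, population = sample_pop,
      genotype = geno, x_dose = xd, y_dose = yd, null = is_null,
      cluster = cluster, stringsAsFactors = FALSE, row.names = NULL)
  }

  panel <- structure(
    list(theta = theta_m, r = r_m,
         samples = data.frame(sample_id = sample_ids,
                              population = sample_pop,
                              stringsAsFactors = FALSE)),
    class = "intensity_panel")
  list(panel = panel, truth = do.call(rbind, truth))
}

#' @export
print.intensity_panel <- function(x, ...) {
  cat("intensity_panel:", nrow(x$theta), "markers x", ncol(x$theta),
      "samples;", length(unique(x$samples$population)), "population(s)\n")
  invisible(x)
}

#' Subset an intensity panel by marker and/or sample
#'
#' @param panel An `intensity_panel`.
#' @param markers,samples Character vectors of ids to keep (default all).
#' @export
subset_panel <- function(panel, markers = NULL, samples = NULL) {
  stopifnot(inherits(panel, "intensity_panel"))
  if (is.null(markers)) markers <- rownames(panel$theta)
  if (is.null(samples)) samples <- colnames(panel$theta)
  structure(
    list(theta = panel$theta[markers, samples, drop = FALSE],
         r = panel$r[markers, samples, drop = FALSE],
         samples = panel$samples[match(samples, panel$samples$sample_id), ,
                                 drop = FALSE]),
    class = "intensity_panel")
}

## ---- study-condition design sets -------------------------------------------

#' Assay designs of the default benchmark panel
#'
#' A fixed mixture of 200 assay geometries spanning the cluster phenomena seen
#' on polyploid arrays: 40 single-copy biallelic assays (three clusters,
#' outcrossed-style frequencies), 50 single-copy assays in fully inbred
#' material (two clusters), 50 heavily compressed assays (probe hybridizing to
#' seven gene copies, angular separation ~0.105, merged by the first-step
#' clustering and recoverable only by the forced-two-cluster split), 20
#' four-cluster assays (three-copy probe whose fixed-A copy segregates for a
#' probe failure, giving four distinct angular positions), and 40 null-bearing assays (single-copy probe with a
#' deletion haplotype at frequency 0.3).
#'
#' @return List of [assay_design()] objects (length 200).
#' @export
benchmark_designs <- function() {
  designs <- list()
  p_cycle <- c(0.30, 0.35, 0.40, 0.45, 0.50)
  for (i in 1:40)
    designs[[length(designs) + 1L]] <- assay_design(
      sprintf("SIMPLE3_%03d", i),
      pop_overrides = list(diversity = list(
        allele_freq = p_cycle[(i - 1L) %% 5L + 1L], inbreeding = 0)))
  for (i in 1:50)
    designs[[length(designs) + 1L]] <- assay_design(
      sprintf("TWOCLUS_%03d", i),
      pop_overrides = list(diversity = list(allele_freq = 0.5,
                                            inbreeding = 1)))
  for (i in 1:50)
    designs[[length(designs) + 1L]] <- assay_design(
      sprintf("COMPRESS_%03d", i), n_hyb_sites = 7L, target_site = 1L,
      pop_overrides = list(diversity = list(allele_freq = 0.5,
                                            inbreeding = 1)))
  for (i in 1:20)
    designs[[length(designs) + 1L]] <- assay_design(
      sprintf("FOURCLUS_%03d", i), n_hyb_sites = 3L, target_site = 1L,
      fixed_alleles = c(NA, "A", "B"), site_failures = c(FALSE, TRUE, FALSE),
      failure_freq = 0.5,
      pop_overrides = list(diversity = list(allele_freq = 0.5,
                                            inbreeding = 1)))
  for (i in 1:40)
    designs[[length(designs) + 1L]] <- assay_design(
      sprintf("NULL_%03d", i), site_failures = TRUE, failure_freq = 0.3,
      pop_overrides = list(diversity = list(allele_freq = 0.5,
                                            inbreeding = 1)))
  designs
}

#' Simulate the default benchmark panel
#'
#' 1000 diversity-panel samples genotyped on the 200 [benchmark_designs()]
#' assays under the default noise model (theta_sd 0.02, r_cv 0.1).
#'
#' @param seed Integer seed passed to the noise model.
#' @return As [simulate_panel()]: list with `panel` and `truth`.
#' @export
benchmark_panel <- function(seed = 1L) {
  pops <- list(population_design("diversity", 1000L, label = "diversity"))
  simulate_panel(benchmark_designs(), pops, noise_model(seed = seed))
}

#' Simulate multi-cluster assays resolvable through bi-parental crosses
#'
#' Reproduces the canonical three-cluster situation of a probe hybridizing to
#' two genomes: the target SNP sits in genome A while a secondary SNP under
#' the probe in genome B abolishes that copy's signal on one haplotype. Two
#' doubled-haploid crosses are simulated: one fixed at the target site but
#' segregating for the genome-B probe failure (clusters C2/C3), the other
#' fixed for the failure but segregating at the target site (clusters C1/C3).
#' C3 is the cluster shared between the two crosses.
#'
#' @param n_assays Number of replicate assays with this geometry.
#' @param n_per_pop Samples per cross.
#' @param noise A [noise_model()].
#' @return As [simulate_panel()], plus attribute `expected` describing the
#'   true per-population segregating cluster pairs on the caller's ordinal
#'   label scale (C1 lowest theta .. C3, hub = the shared cluster).
#' @export
multilocus_scenario <- function(n_assays = 1L, n_per_pop = 100L,
                                noise = noise_model()) {
  designs <- lapply(seq_len(n_assays), function(i)
    assay_design(
      sprintf("MULTI_%03d", i), n_hyb_sites = 2L, target_site = 1L,
      fixed_alleles = c(NA, "A"), site_failures = c(FALSE, TRUE),
      pop_overrides = list(
        cross1 = list(parents = list(founder("BB", failure = FALSE),
                                     founder("BB", failure = TRUE))),
        cross2 = list(parents = list(founder("AA", failure = TRUE),
                                     founder("BB", failure = TRUE))))))
  pops <- list(
    population_design("DH", n_per_pop, label = "cross1",
                      parents = list(founder("BB"), founder("BB"))),
    population_design("DH", n_per_pop, label = "cross2",
                      parents = list(founder("AA"), founder("BB"))))
  out <- simulate_panel(designs, pops, noise)
  # configs: (2,0) theta 0 -> C1; (2,2) theta 0.5 -> C2; (0,2) theta 1 -> C3
  attr(out, "expected") <- list(cross1 = c("C2", "C3"),
                                cross2 = c("C1", "C3"),
                                hub = "C3")
  out
}
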