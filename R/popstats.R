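## sample -> population mapping in a canonical named-vector form
as_partition <- function(partition, samples) {
  if (is.data.frame(partition)) {
    stopifnot(all(c("sample_id", "population") %in% names(partition)))
    part <- stats::setNames(partition$population, partition$sample_id)
  } else {
    part <- partition
  }
  if (is.null(names(part))) stop("partition must be named by sample id")
  miss <- setdiff(samples, names(part))
  if (length(miss))
    stop("samples missing from partition: ", paste(utils::head(miss, 5),
                                                   collapse = ", "))
  part[samples]
}

#' B-allele dosage matrix from biallelic calls
#'
#' @param genotypes A `genotype_matrix` or a character calls matrix.
#' @return Numeric matrix: AA = 0, AB = 1, BB = 2, anything else `NA`.
#' @export
genotype_dosage <- function(genotypes) {
  calls <- if (inherits(genotypes, "genotype_matrix")) genotypes$calls
           else genotypes
  d <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  d[calls == "AA"] <- 0
  d[calls == "AB"] <- 1
  d[calls == "BB"] <- 2
  d
}

## per-population allele frequency p(B) and observed het per marker
pop_summaries <- function(dose, part) {
  pops <- sort(unique(part))
  lapply(stats::setNames(pops, pops), function(pop) {
    dd <- dose[, part == pop, drop = FALSE]
    n <- rowSums(!is.na(dd))
    p <- rowSums(dd, na.rm = TRUE) / (2 * n)
    h <- rowSums(dd == 1, na.rm = TRUE) / n
    list(n = n, p = p, h = h)
  })
}

#' Mean heterozygosity per population
#'
#' Averaged over the population's polymorphic markers. `"expected"` is gene
#' diversity 2p(1-p) from the population's own allele frequencies;
#' `"observed"` is the heterozygote call fraction. Populations with no
#' polymorphic marker are reported as `NA` (undefined).
#'
#' @param genotypes A `genotype_matrix` or calls matrix (biallelic calls).
#' @param partition Sample-to-population mapping (named vector or data frame
#'   with `sample_id`, `population`).
#' @param type `"expected"` or `"observed"`.
#' @return Named numeric vector, one entry per population.
#' @export
mean_heterozygosity <- function(genotypes, partition,
                                type = c("expected", "observed")) {
  type <- match.arg(type)
  dose <- genotype_dosage(genotypes)
  part <- as_partition(partition, colnames(dose))
  vapply(pop_summaries(dose, part), function(s) {
    poly <- which(s$n > 0 & s$p > 0 & s$p < 1)
    if (!length(poly)) return(NA_real_)
    if (type == "expected") mean(2 * s$p[poly] * (1 - s$p[poly]))
    else mean(s$h[poly])
  }, numeric(1))
}

## Weir & Cockerham (1984) two-population theta-hat variance components for
## one locus; n = individuals, p = allele frequency, h = observed het
## proportion. Returns c(a, b, c); theta = a / (a + b + c).
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir-Cockerham pairwise F_ST from genotype counts
#'
#' The unbiased theta-hat estimator of Weir & Cockerham (1984) for two
#' populations, combined over markers as a ratio of sums of the variance
#' components. The estimator can be slightly negative under no
#' differentiation; that is a property of the bias correction, not an error.
#'
#' @param counts_a,counts_b Integer matrices (markers x 3, columns AA/AB/BB)
#'   of genotype counts per population, or vectors of length 3 for a single
#'   marker.
#' @return Theta-hat (scalar); `NA` when the total variance is zero
#'   (undefined, e.g. both populations fixed for the same allele everywhere).
#' @export
weir_cockerham_fst <- function(counts_a, counts_b) {
  if (is.null(dim(counts_a))) counts_a <- matrix(counts_a, nrow = 1)
  if (is.null(dim(counts_b))) counts_b <- matrix(counts_b, nrow = 1)
  stopifnot(ncol(counts_a) == 3, ncol(counts_b) == 3,
            nrow(counts_a) == nrow(counts_b))
  num <- 0; den <- 0
  for (i in seq_len(nrow(counts_a))) {
    n1 <- sum(counts_a[i, ]); n2 <- sum(counts_b[i, ])
    if (n1 == 0 || n2 == 0) next
    p1 <- (2 * counts_a[i, 3] + counts_a[i, 2]) / (2 * n1)
    p2 <- (2 * counts_b[i, 3] + counts_b[i, 2]) / (2 * n2)
    h1 <- counts_a[i, 2] / n1
    h2 <- counts_b[i, 2] / n2
    comp <- wc_components(n1, p1, h1, n2, p2, h2)
    num <- num + comp["a"]
    den <- den + sum(comp)
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

## genotype count matrix (markers x AA/AB/BB) for one population's calls
genotype_counts <- function(calls) {
  cbind(AA = rowSums(calls == "AA", na.rm = TRUE),
        AB = rowSums(calls == "AB", na.rm = TRUE),
        BB = rowSums(calls == "BB", na.rm = TRUE))
}

#' Pairwise F_ST between all populations of a panel
#'
#' @param genotypes A `genotype_matrix` or calls matrix (biallelic calls).
#' @param partition Sample-to-population mapping.
#' @return Symmetric matrix of [weir_cockerham_fst()] estimates (diagonal
#'   `NA`).
#' @export
pairwise_fst <- function(genotypes, partition) {
  calls <- if (inherits(genotypes, "genotype_matrix")) genotypes$calls
           else genotypes
  part <- as_partition(partition, colnames(calls))
  pops <- sort(unique(part))
  counts <- lapply(stats::setNames(pops, pops), function(pop)
    genotype_counts(calls[, part == pop, drop = FALSE]))
  out <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i < j) {
      v <- weir_cockerham_fst(counts[[i]], counts[[j]])
      out[i, j] <- v; out[j, i] <- v
    }
  }
  out
}

#' Linkage disequilibrium r-squared between two markers
#'
#' On fully homozygous samples (inbred lines, doubled haploids) the phase is
#' trivial: haplotype frequencies are read off the homozygous calls and
#' r^2 = D^2 / (p_A p_a p_B p_b). When heterozygotes are present, the squared
#' Pearson correlation of allele dosages is used instead. The method used is
#' recorded in `attr(, "method")`.
#'
#' @param g1,g2 Dosage vectors (0/1/2, `NA` allowed) or character call
#'   vectors for the two markers, sample-aligned.
#' @return r^2 in \[0, 1\], or `NA` (with method `"undefined"`) when either
#'   marker is monomorphic among the complete cases.
#' @export
ld_r2 <- function(g1, g2) {
  if (is.character(g1)) g1 <- genotype_dosage(matrix(g1, nrow = 1))[1, ]
  if (is.character(g2)) g2 <- genotype_dosage(matrix(g2, nrow = 1))[1, ]
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (!length(g1)) return(structure(NA_real_, method = "undefined"))
  if (stats::var(g1) == 0 || stats::var(g2) == 0)
    return(structure(NA_real_, method = "undefined"))
  if (any(g1 == 1) || any(g2 == 1)) {
    out <- stats::cor(g1, g2)^2
    attr(out, "method") <- "genotype_correlation"
    return(out)
  }
  a1 <- g1 / 2; a2 <- g2 / 2          # haploid allele indicators
  pA <- mean(a1); pB <- mean(a2)
  D <- mean(a1 * a2) - pA * pB
  out <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  attr(out, "method") <- "haplotype"
  out
}

#' Markers polymorphic in both populations of each pair
#'
#' @param genotypes A `genotype_matrix` or calls matrix.
#' @param partition Sample-to-population mapping.
#' @param maf_min Per-population MAF floor for counting a marker as
#'   polymorphic (default 0: any minor allele observation counts).
#' @return Symmetric integer matrix of shared-polymorphism counts; the
#'   diagonal holds each population's own polymorphic count.
#' @export
shared_polymorphic <- function(genotypes, partition, maf_min = 0) {
  dose <- genotype_dosage(genotypes)
  part <- as_partition(partition, colnames(dose))
  sums <- pop_summaries(dose, part)
  poly <- lapply(sums, function(s)
    s$n > 0 & pmin(s$p, 1 - s$p) > maf_min)
  pops <- names(sums)
  out <- matrix(0L, length(pops), length(pops),
                dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops))
    out[i, j] <- sum(poly[[i]] & poly[[j]])
  out
}

#' Combined pairwise table: shared polymorphisms and F_ST
#'
#' Upper triangle: number of markers polymorphic in both populations. Lower
#' triangle: Weir-Cockerham pairwise F_ST. Diagonal: each population's
#' polymorphic marker count.
#'
#' @inheritParams shared_polymorphic
#' @return Numeric matrix.
#' @export
pairwise_stats <- function(genotypes, partition, maf_min = 0) {
  sh <- shared_polymorphic(genotypes, partition, maf_min)
  fst <- pairwise_fst(genotypes, partition)
  out <- matrix(NA_real_, nrow(sh), ncol(sh), dimnames = dimnames(sh))
  out[upper.tri(out)] <- sh[upper.tri(sh)]
  out[lower.tri(out)] <- fst[lower.tri(fst)]
  diag(out) <- diag(sh)
  out
}

#' MAF spectrum of a panel
#'
#' @param genotypes A `genotype_matrix` or calls matrix.
#' @param breaks Histogram breaks on \[0, 0.5\].
#' @return Data frame (`bin_low`, `bin_high`, `count`) over markers with at
#'   least one biallelic call.
#' @export
maf_spectrum <- function(genotypes, breaks = seq(0, 0.5, by = 0.05)) {
  calls <- if (inherits(genotypes, "genotype_matrix")) genotypes$calls
           else genotypes
  vals <- apply(calls, 1, function(cc) {
    cc <- cc[cc %in% c("AA", "AB", "BB")]
    if (!length(cc)) return(NA_real_)
    as.numeric(maf(cc))
  })
  vals <- vals[!is.na(vals)]
  bins <- cut(vals, breaks = breaks, include.lowest = TRUE, right = TRUE)
  data.frame(bin_low = utils::head(breaks, -1),
             bin_high = utils::tail(breaks, -1),
             count = as.integer(table(bins)))
}
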