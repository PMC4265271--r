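---
title: "Density-based genotype calling for polyploid SNP arrays"
author: "polyclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based genotype calling for polyploid SNP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyclust)
```

## The problem

An Infinium II array assay reads one SNP as two fluorescence channels, one
per allele. The standard summary is polar: the normalized angle
$\theta = \tfrac{2}{\pi}\arctan(y/x) \in [0,1]$ (0 = pure A-channel signal,
1 = pure B-channel signal) and the total intensity $R$. In a diploid, an
assay produces at most three clusters (AA, AB, BB) at predictable angles,
and model-based diploid callers exploit exactly that expectation.

Allopolyploids such as bread wheat break the expectation in three ways:

* **Cluster compression.** A probe that also hybridizes to homoeologous
  copies receives a constitutive signal from every non-target copy. With
  $s$ hybridizing sites and the non-target sites fixed for the A allele,
  the BB cluster sits at $\theta = \tfrac{2}{\pi}\arctan\!\big(\tfrac{1}{s-1}\big)$
  instead of 1, so genotype clusters crowd together as $s$ grows.
* **Extra clusters.** A secondary variant under the probe in another genome
  can abolish that copy's contribution on one haplotype, splitting each
  genotype cluster in two. Such assays show four or more clusters in
  diverse material even though each bi-parental cross segregates between
  just two of them.
* **Null alleles.** If a single-copy probe's site is deleted (or its
  annealing site diverged), carriers emit essentially no signal: a
  low-$R$ cluster whose angle is pure noise.

Because the number and position of clusters is unpredictable, the calling
strategy here is model-free: find whatever dense clusters exist, then
interpret them.

## Density-based clustering

Two classical algorithms are implemented from scratch on the
$(\theta, wR^{*})$ plane (see *The clustering metric* below):

* **DBSCAN** with the two standard knobs, neighborhood radius
  (`cluster_distance`) and minimum neighborhood size (`min_points`,
  counting the point itself). Core points with overlapping neighborhoods
  form clusters; non-core points within reach of a core point join as
  border points; the rest is noise. Border points reachable from several
  clusters go to the lowest-index core neighbor — DBSCAN leaves this open,
  and the fixed rule makes results reproducible across runs and platforms.
* **OPTICS**, which orders points by density connectivity and records each
  point's reachability distance. Cutting the resulting profile at a
  threshold $t$ recovers the DBSCAN($t$) partition of core points; the
  package's forced-$k$ extraction scans the distinct reachability values
  downward for the largest threshold whose cut yields exactly $k$ clusters
  of at least `min_points` members. If $k$ is unattainable the closest
  achievable count below $k$ is returned with a shortfall flag. The
  steepness-based extraction of the OPTICS literature is deliberately not
  used: forcing a cluster count only needs a threshold mechanism, and the
  threshold cut is the variant with the exact DBSCAN-equivalence property,
  which makes it independently checkable.

Ties in the OPTICS priority queue are broken by point index, and all
neighbor searches are exact all-pairs scans — panels have at most a few
thousand samples per marker, so spatial indexing would add code without
measurable benefit.

## The three-step protocol

`run_protocol()` applies the published three-step procedure per assay:

1. **DBSCAN** at radius 0.07, minimum 10 points, then filtering on cluster
   number, call rate and MAF.
2. Assays yielding a **single cluster** in step 1 — the compression
   signature — are re-clustered with **OPTICS + forced two-cluster
   extraction** (radius 0.07, minimum 10).
3. Assays still unsatisfactory (step-1 failures other than
   single-cluster, and step-2 failures) get **DBSCAN at radius 0.09**,
   which captures clusters too broad for the first pass.

After the accepted step, clusters are interpreted: ordinal labels C1..Cn by
ascending angle over non-null clusters, genotype labels AA/AB/BB only when
exactly three clusters exist and none is null-flagged, and the dedicated
label NULL for low-intensity clusters. Samples are then assigned with a
confidence score.

Defaults with no published value are configuration, logged per run:
call-rate minimum 0.90, acceptable cluster counts 2–6 for the DBSCAN steps
(step 2 requires exactly two). The MAF filter is 0.35 in mapping mode and
0.05 in diversity mode. In mapping mode the MAF criterion is evaluated per
population and passes if **any** cross reaches the threshold: 0.35 is an
expectation about a segregating cross (a DH population segregates 1:1, MAF
0.5), and pooling several crosses dilutes a marker segregating in only one
of them below any such threshold even though it is exactly the marker a
mapping panel wants. Ordinal labels skip null clusters because a null
cluster's angle is noise: ranking it among the dosage configurations would
shuffle the C-labels of otherwise identical assays.

### The confidence score

The published protocol names a confidence limit of 0.8 but not the score.
The score used here is a normalized Gaussian responsibility: for cluster
$k$ with per-axis spreads $s$ (floored at 0.01) and spread-standardized
distance $d_k$, $w_k = e^{-d_k^2/2}$ and
$\mathrm{conf} = \max_k w_k / \sum_k w_k$. It is bounded in $[0,1]$,
equals 1 at the center of an isolated cluster, and equals $1/2$ exactly
midway between two equal clusters — so the 0.8 limit has an interpretable
geometry. Whether the commercial software's score is numerically
comparable is unknown; only the limiting behavior is claimed. Calls
additionally require the best cluster to lie within 6 standardized spreads:
responsibilities are purely relative, and without an absolute cutoff a
point far from every cluster would still be "confidently" assigned to the
least-distant one. Within a cluster the cutoff is inert
($P(d > 6) \approx 10^{-8}$), but it is what makes a stored cluster model
return NC for samples from clusters that did not exist at training time.

### The clustering metric

Distances are Euclidean on $(\theta,\, w \cdot R^{*})$, where
$R^{*} = R / R_{95}$ is the marker's intensity scaled by its own 95th
percentile and $w$ defaults to 0.25. The intensity axis must participate —
null clusters separate only vertically — but genotype clusters separate in
angle while their intensity spread (coefficient of variation around 10%)
is an order of magnitude wider than their angular spread. At $w = 1$ that
intensity scatter dominates the published 0.07/0.09 radii and the forced
two-cluster split cuts along intensity noise rather than the angular
valley. At $w = 0.25$ angular structure dominates while a near-origin null
cluster ($\Delta R^{*} \approx 0.8$, i.e. $0.2$ after weighting) still
lies well beyond the 0.07 radius of any main cluster's lower tail. The
weight is a package decision, exposed as `r_weight`.

## Null-allele detection

A cluster is null-flagged when its median $R^{*}$ is below 0.25 times the
marker's largest cluster median (`detect_null_clusters()`). Members of
null clusters are reported with the call NULL and excluded from biallelic
genotype labels and downstream population statistics: a null allele is a
hemizygous/absent state, not a third nucleotide allele.

## Resolving multi-cluster assays

Assays with extra clusters are resolved through bi-parental crosses
(`detect_segregation()`, `build_allelic_map()`): within one cross such an
assay segregates between exactly two clusters, and each such pair is one
biallelic locus observation. Building a per-marker graph of clusters
(nodes) and segregating pairs (edges) identifies clusters shared between
crosses as hubs — the same cluster acting as one allele of two loci on
different genomes. The pair rule (combined frequency at least 90% of the
population's calls, each cluster at least `min_points`) is configuration;
the 1:1 chi-square test is annotation only, because segregation
legitimately distorts in restricted-recombination regions. A cross
segregating at two duplicated loci simultaneously would show four clusters
within one population; no such records are produced and those markers stay
unresolved.

## Population statistics

The statistics layer works on biallelic calls: per-population expected
heterozygosity $2p(1-p)$ averaged over polymorphic markers (observed
heterozygosity available as the alternative, since published
"mean heterozygosity" tables rarely say which was meant — both are
reported by the CLI), shared-polymorphism counts, the Weir–Cockerham
(1984) unbiased $\hat\theta$ for pairwise $F_{ST}$ combined over loci as a
ratio of sums of the $a, b, c$ variance components, and LD $r^2$ — from
haplotype counts ($D^2 / p_A p_a p_B p_b$) when all samples are homozygous
(phase is trivial in inbred material) and as squared genotype correlation
otherwise. EM haplotype-frequency estimation is out of scope. The test
suite checks $\hat\theta$ against an independent transcription of the
per-allele component equations in their general $r$-population form.

## The simulator

`simulate_panel()` generates panels from three ingredients:

* **Assay designs**: number of hybridizing sites, which site carries the
  target SNP, the constitutive allele of each non-target site, which sites
  a failure haplotype silences, and the failure-haplotype frequency.
  Per-site signal contributions are equal by default (a weight vector is
  accepted for robustness experiments) — the simplest model that
  reproduces every observed cluster pattern: compression, extra clusters
  and nulls are all dosage arithmetic.
* **Populations**: diversity panels (per-locus allele frequency, optional
  inbreeding coefficient), DH crosses (homozygous, 1:1, residual
  heterozygosity 0.02) and F4-style crosses (residual heterozygosity
  0.125, the selfing expectation). Founder genotypes, frequencies and
  inbreeding are population defaults that a design may override per
  marker, since each locus has its own frequency and founder alleles.
* **Noise**: additive Gaussian angular noise truncated to $[0,1]$ and
  multiplicative lognormal intensity noise — both supports stay valid
  without rejection sampling. Null points draw a uniform angle and a low
  background intensity (default 0.05 of a two-dose signal), reproducing
  the horizontal smear of real null clusters. Defaults
  (`theta_sd = 0.02`, `r_cv = 0.1`) are free parameters chosen to look
  like clean array data; no published noise magnitudes exist. $R$ is
  proportional to the total hybridized dose, so multi-copy assays are
  brighter — one real feature the 95th-percentile scaling then removes
  per marker.

Samples are treated as homozygous for a failure haplotype (carrier = both
haplotypes fail; carrier probability `failure_freq` in diversity material
under the inbred-accession assumption, 1/2 in a segregating DH cross,
$(1-\mathrm{het})/2$ in F4s). Heterozygous failure carriers — half-signal
hemizygotes — are not modeled; real intensity data would put such samples
between a main cluster and the null band.

What the simulator does **not** emulate: batch and plate effects, probe
thermodynamics, two-probe Infinium I chemistry, ascertainment bias, and
the irregular cluster shapes of real arrays. Passing tests on simulated
panels therefore demonstrate that the algorithms recover the geometry the
dosage model generates, not that real-array accuracy equals the measured
numbers.

## Benchmark scales and numerical choices

The default benchmark (`benchmark_panel()`) is 1000 diversity samples by
200 assays: 40 three-cluster, 50 two-cluster, 50 compressed
(seven hybridizing sites, angular separation
$\tfrac{2}{\pi}\arctan(1/6) \approx 0.105$ — merged by step 1, split by
the forced extraction in step 2), 20 four-cluster (a three-site probe
whose fixed-A copy segregates for failure, giving four distinct angles)
and 40 null-bearing assays (deletion haplotype at frequency 0.3). These
sizes keep a full run around a minute while every cluster class still
holds well over `min_points` samples. The multi-cluster resolution
scenario uses two DH crosses of 100 samples each, mirroring the shared-C3
geometry described above.

Other numerical choices: all stored model coordinates are rounded to six
decimals — the same precision as the on-disk cluster file — so a
write/read/apply round trip reproduces in-memory calls bit-exactly;
cluster spreads are floored at 0.01 before standardization; exact
responsibility ties yield NC; markers whose assay fails all three steps
are reported `failed` with every sample NC.

## Known limitations

* The forced-$k$ threshold cut can mis-split when the between-cluster
  valley is shallower than local density fluctuations; accuracy on the
  compressed benchmark geometry is about 98–99%, not 100%.
* Step-3 acceptance ("too broad for 0.07, dense at 0.09") occupies a
  narrow density window by construction; assays far outside it simply
  fail, as they should.
* Mapping-mode MAF filtering assumes population labels are supplied;
  without them the pooled MAF is used and markers segregating in a single
  cross may be filtered out.
* $F_{ST}$ and LD treat calls as codominant biallelic genotypes; markers
  with null-flagged clusters are excluded rather than modeled as
  hemizygous.
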