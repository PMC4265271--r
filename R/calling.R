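#' Parameters of the three-step calling protocol
#'
#' Defaults are the published settings of the polyploid calling protocol:
#' steps 1 and 2 use a neighborhood radius of 0.07, step 3 widens it to 0.09
#' to capture broad clusters, all steps require at least 10 points per
#' cluster, samples are assigned under a confidence limit of 0.8, and the
#' minor-allele-frequency filter is 0.35 for bi-parental mapping material
#' (expectation 0.5 in a segregating cross) or 0.05 for unrelated accessions.
#' The cluster-number ranges and the call-rate minimum are protocol
#' configuration with no published values; defaults are logged per marker.
#'
#' @param mode `"mapping"` (bi-parental populations; per-population MAF
#'   filter) or `"diversity"` (pooled MAF filter).
#' @param step1,step2,step3 [density_params()] per step.
#' @param confidence_limit Minimum assignment confidence for a call.
#' @param maf_min MAF filter threshold; default by mode (0.35 / 0.05).
#' @param call_rate_min Minimum fraction of non-NC samples per assay.
#' @param cluster_range_step1,cluster_range_step3 Acceptable cluster-count
#'   range (inclusive) for the DBSCAN steps; step 2 always requires exactly
#'   two clusters.
#' @param r_weight Weight of the scaled intensity axis in the clustering
#'   metric (theta is unweighted); see the package vignette for the choice.
#' @param spread_floor Lower bound on per-axis cluster spreads used in
#'   confidence scoring.
#' @param max_dist Maximum spread-standardized distance to the best cluster
#'   for a call; beyond it a sample is NC regardless of relative confidence,
#'   so points from clusters absent at training time are not force-called.
#' @param null_r_ratio Threshold of [detect_null_clusters()].
#' @export
protocol_params <- function(mode = c("diversity", "mapping"),
                            step1 = density_params(0.07, 10),
                            step2 = density_params(0.07, 10),
                            step3 = density_params(0.09, 10),
                            confidence_limit = 0.8,
                            maf_min = NULL,
                            call_rate_min = 0.90,
                            cluster_range_step1 = c(2L, 6L),
                            cluster_range_step3 = c(2L, 6L),
                            r_weight = 0.25,
                            spread_floor = 0.01,
                            max_dist = 6,
                            null_r_ratio = 0.25) {
  mode <- match.arg(mode)
  if (is.null(maf_min)) maf_min <- if (mode == "mapping") 0.35 else 0.05
  stopifnot(confidence_limit >= 0, confidence_limit <= 1,
            maf_min >= 0, maf_min <= 0.5,
            call_rate_min >= 0, call_rate_min <= 1,
            r_weight >= 0, spread_floor > 0, max_dist > 0,
            null_r_ratio > 0)
  structure(list(mode = mode, step1 = step1, step2 = step2, step3 = step3,
                 confidence_limit = confidence_limit, maf_min = maf_min,
                 call_rate_min = call_rate_min,
                 cluster_range_step1 = as.integer(cluster_range_step1),
                 cluster_range_step3 = as.integer(cluster_range_step3),
                 r_weight = r_weight, spread_floor = spread_floor,
                 max_dist = max_dist, null_r_ratio = null_r_ratio),
            class = "protocol_params")
}

## clustering coordinates for one marker: theta unchanged, R scaled by its
## 95th percentile so null clusters sit near 0 and main clusters near 1,
## then weighted
marker_points <- function(panel, marker, r_weight) {
  th <- panel$theta[marker, ]
  r <- panel$r[marker, ]
  ok <- is.finite(th) & is.finite(r)
  r_scale <- stats::quantile(r[ok], 0.95, names = FALSE, type = 7)
  if (!is.finite(r_scale) || r_scale <= 0) r_scale <- max(r[ok], 1e-9)
  # fixed decimal precision: the same scale a stored cluster file carries, so
  # applying a stored model reproduces in-memory calls exactly
  r_scale <- round(r_scale, 6)
  rs <- r / r_scale
  list(theta = th, r_scaled = rs, ok = ok,
       x = cbind(th[ok], r_weight * rs[ok]),
       samples = colnames(panel$theta), r_scale = r_scale)
}

## per-marker cluster summary from a labeling; coordinates rounded to the
## 6-decimal precision of the on-disk cluster file so an applied stored model
## reproduces in-memory calls exactly
marker_model <- function(theta, r_scaled, labels, r_scale) {
  ks <- sort(unique(labels[labels > 0L]))
  rows <- lapply(ks, function(k) {
    sel <- labels == k
    sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
    data.frame(cluster = k,
               center_theta = round(mean(theta[sel]), 6),
               center_r = round(mean(r_scaled[sel]), 6),
               spread_theta = round(sd0(theta[sel]), 6),
               spread_r = round(sd0(r_scaled[sel]), 6),
               median_r = round(stats::median(r_scaled[sel]), 6),
               n = sum(sel))
  })
  cl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), center_theta = numeric(0),
               center_r = numeric(0), spread_theta = numeric(0),
               spread_r = numeric(0), median_r = numeric(0), n = integer(0))
  cl$null <- logical(nrow(cl))
  cl$label <- rep(NA_character_, nrow(cl))
  cl$genotype <- rep(NA_character_, nrow(cl))
  list(clusters = cl, r_scale = round(r_scale, 6))
}

#' Flag low-intensity (null-allele) clusters
#'
#' A cluster whose median scaled intensity falls below `r_ratio` times the
#' largest cluster median of the same marker is flagged as a null cluster:
#' the signature of a deleted gene copy or a diverged probe annealing site.
#' Markers with fewer than two clusters are left untouched.
#'
#' @param model A `cluster_model` (or single marker model).
#' @param r_ratio Relative intensity threshold.
#' @return The model with `null` flags set.
#' @export
detect_null_clusters <- function(model, r_ratio = 0.25) {
  one <- function(mm) {
    if (nrow(mm$clusters) >= 2L) {
      top <- max(mm$clusters$median_r)
      mm$clusters$null <- mm$clusters$median_r < r_ratio * top
    }
    mm
  }
  if (inherits(model, "cluster_model")) {
    model$markers <- lapply(model$markers, one)
    model
  } else one(model)
}

#' Assign ordinal and genotype labels to fitted clusters
#'
#' Non-null clusters are sorted by ascending center theta (ties by center
#' intensity) and named C1..Cn; null clusters carry the label `NULL`. When a
#' marker has exactly three clusters and none is null-flagged, the biallelic
#' interpretation holds and the clusters are additionally labeled AA (lowest
#' theta), AB and BB.
#'
#' @param model A `cluster_model` (or single marker model).
#' @return The model with `label` and `genotype` columns filled.
#' @export
label_clusters <- function(model) {
  one <- function(mm) {
    cl <- mm$clusters
    nn <- which(!cl$null)
    ord <- nn[order(cl$center_theta[nn], cl$center_r[nn])]
    cl$label[ord] <- paste0("C", seq_along(ord))
    cl$label[cl$null] <- "NULL"
    cl$genotype <- NA_character_
    if (nrow(cl) == 3L && !any(cl$null))
      cl$genotype[ord] <- c("AA", "AB", "BB")
    mm$clusters <- cl
    mm
  }
  if (inherits(model, "cluster_model")) {
    model$markers <- lapply(model$markers, one)
    model
  } else one(model)
}

## call label of each cluster row: genotype if assigned, else ordinal/NULL
cluster_call_labels <- function(cl) {
  ifelse(!is.na(cl$genotype), cl$genotype, cl$label)
}

## confidence-scored assignment for one marker; returns call + confidence
assign_marker <- function(mm, theta, r_scaled, confidence_limit,
                          spread_floor = 0.01, max_dist = 6) {
  cl <- mm$clusters
  n <- length(theta)
  ok <- is.finite(theta) & is.finite(r_scaled)
  call <- rep("NC", n)
  conf <- rep(NA_real_, n)
  if (nrow(cl) == 0L || !any(ok))
    return(list(call = call, confidence = conf))
  st <- pmax(cl$spread_theta, spread_floor)
  sr <- pmax(cl$spread_r, spread_floor)
  d2 <- vapply(seq_len(nrow(cl)), function(j)
    ((theta[ok] - cl$center_theta[j]) / st[j])^2 +
      ((r_scaled[ok] - cl$center_r[j]) / sr[j])^2,
    numeric(sum(ok)))
  d2 <- matrix(d2, nrow = sum(ok))
  lw <- -d2 / 2
  m <- apply(lw, 1, max)
  cf <- 1 / rowSums(exp(lw - m))
  best <- max.col(lw, ties.method = "first")
  tied <- rowSums(lw == m) > 1L        # exact tie: no unique best cluster
  labs <- cluster_call_labels(cl)
  out <- labs[best]
  out[cf < confidence_limit | tied | sqrt(d2[cbind(seq_len(nrow(d2)), best)]) >
        max_dist] <- "NC"
  call[ok] <- out
  conf[ok] <- cf
  list(call = call, confidence = conf)
}

#' Assign samples of a panel to the clusters of a fitted model
#'
#' The confidence score of a sample is its normalized Gaussian
#' responsibility: for cluster k at spread-standardized distance d_k,
#' w_k = exp(-d_k^2 / 2) and confidence = max_k w_k / sum_k w_k. A sample is
#' called to the argmax cluster when its confidence reaches
#' `confidence_limit`, the best distance is within `max_dist` spreads, and
#' the maximum is unique; otherwise it is NC. A single-cluster model gives
#' every finite point confidence 1.
#'
#' @param model A `cluster_model` (e.g. from [run_protocol()] or
#'   [read_cluster_file()]).
#' @param panel An `intensity_panel`; markers absent from the model are
#'   skipped.
#' @param confidence_limit Minimum confidence for a call.
#' @param spread_floor,max_dist See [protocol_params()].
#' @return A `genotype_matrix`: list with character matrix `calls` and
#'   numeric matrix `confidence` (markers x samples).
#' @export
assign_samples <- function(model, panel, confidence_limit = 0.8,
                           spread_floor = 0.01, max_dist = 6) {
  stopifnot(inherits(model, "cluster_model"),
            inherits(panel, "intensity_panel"))
  markers <- intersect(names(model$markers), rownames(panel$theta))
  samples <- colnames(panel$theta)
  calls <- matrix("NC", length(markers), length(samples),
                  dimnames = list(markers, samples))
  confidence <- matrix(NA_real_, length(markers), length(samples),
                       dimnames = list(markers, samples))
  for (m in markers) {
    mm <- model$markers[[m]]
    rs <- panel$r[m, ] / mm$r_scale
    a <- assign_marker(mm, panel$theta[m, ], rs, confidence_limit,
                       spread_floor, max_dist)
    calls[m, ] <- a$call
    confidence[m, ] <- a$confidence
  }
  structure(list(calls = calls, confidence = confidence),
            class = "genotype_matrix")
}

#' Minor allele frequency of one assay's calls
#'
#' For biallelic calls (AA/AB/BB) the allele-frequency minimum over non-NC
#' calls, a heterozygote contributing one copy of each allele. For
#' multi-cluster assays (C1..Cn or NULL categories) the minimum cluster
#' frequency over non-NC calls is returned instead and the result carries
#' `attr(, "method") = "cluster_frequency"`.
#'
#' @param calls Character vector of calls for one marker.
#' @return MAF in \[0, 0.5\] (cluster-frequency MAF in \[0, 1/k\]).
#' @export
maf <- function(calls) {
  calls <- calls[!is.na(calls) & calls != "NC"]
  if (!length(calls)) stop("no non-NC calls: MAF undefined")
  if (all(calls %in% c("AA", "AB", "BB"))) {
    nb <- 2 * sum(calls == "BB") + sum(calls == "AB")
    p <- nb / (2 * length(calls))
    out <- min(p, 1 - p)
    attr(out, "method") <- "allele_frequency"
  } else {
    out <- min(table(calls)) / length(calls)
    attr(out, "method") <- "cluster_frequency"
  }
  out
}

#' Filter one assay on cluster number, call rate and MAF
#'
#' @param calls Character vector of per-sample calls for the marker.
#' @param n_clusters Number of clusters found.
#' @param cluster_range Length-2 inclusive range of acceptable counts.
#' @param call_rate_min,maf_min Thresholds.
#' @param populations Optional character vector (same length as `calls`) of
#'   population labels; when given, the MAF criterion passes if any
#'   population reaches `maf_min` (mapping mode, where the threshold is only
#'   meaningful within a segregating cross).
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed criteria among `"cluster_number"`, `"call_rate"`, `"maf"`), plus
#'   the measured `call_rate` and `maf`.
#' @export
filter_assay <- function(calls, n_clusters, cluster_range,
                         call_rate_min, maf_min, populations = NULL) {
  reasons <- character(0)
  if (n_clusters < cluster_range[1] || n_clusters > cluster_range[2])
    reasons <- c(reasons, "cluster_number")
  call_rate <- mean(calls != "NC")
  if (call_rate < call_rate_min) reasons <- c(reasons, "call_rate")
  maf_val <- if (all(calls == "NC")) {
    NA_real_
  } else if (is.null(populations)) {
    as.numeric(maf(calls))
  } else {
    max(vapply(split(calls, populations), function(cc) {
      if (all(cc == "NC")) NA_real_ else as.numeric(maf(cc))
    }, numeric(1)), na.rm = TRUE)
  }
  if (is.na(maf_val) || maf_val < maf_min) reasons <- c(reasons, "maf")
  list(pass = length(reasons) == 0L, reasons = reasons,
       call_rate = call_rate, maf = maf_val)
}

## fit + label + null-flag + assign + filter for one marker at one step
step_attempt <- function(pts, labeling, params, step, populations) {
  mm <- marker_model(pts$theta[pts$ok], pts$r_scaled[pts$ok],
                     labeling$labels, pts$r_scale)
  # place labeled clusters over all samples: labeling covers pts$ok subset
  mm <- detect_null_clusters(mm, params$null_r_ratio)
  mm <- label_clusters(mm)
  a <- assign_marker(mm, pts$theta, pts$r_scaled, params$confidence_limit,
                     params$spread_floor, params$max_dist)
  rng <- switch(step,
                `1` = params$cluster_range_step1,
                `2` = c(2L, 2L),
                `3` = params$cluster_range_step3)
  pops <- if (params$mode == "mapping") populations else NULL
  f <- filter_assay(a$call, nrow(mm$clusters), rng,
                    params$call_rate_min, params$maf_min, pops)
  list(model = mm, assign = a, filter = f,
       n_clusters = nrow(mm$clusters))
}

#' Run the three-step polyploid calling protocol on a panel
#'
#' Step 1 clusters every marker with DBSCAN at the narrow radius and filters
#' on cluster number, call rate and MAF. Markers yielding a single cluster —
#' the signature of compressed duplicate-locus clusters — are re-clustered in
#' step 2 with OPTICS and a forced two-cluster extraction. Markers failing
#' step 1 for any other reason, and step-2 failures, are re-clustered in
#' step 3 with DBSCAN at the wider radius to capture broad clusters. After
#' the accepted step, samples are assigned under the confidence limit;
#' markers failing all steps are reported as failed and their samples NC.
#'
#' @param panel An `intensity_panel`.
#' @param params A [protocol_params()]; its `mode` chooses the MAF regime.
#' @return A `protocol_result`: list with `model` (a `cluster_model` holding
#'   accepted markers), `genotypes` (a `genotype_matrix` over all markers),
#'   and `report` (per-marker data frame: accepted step or `failed`, cluster
#'   count, filter reasons, routing history).
#' @export
run_protocol <- function(panel, params = protocol_params()) {
  stopifnot(inherits(panel, "intensity_panel"),
            inherits(params, "protocol_params"))
  markers <- rownames(panel$theta)
  if (!length(markers)) stop("empty panel")
  samples <- colnames(panel$theta)
  populations <- panel$samples$population[match(samples,
                                                panel$samples$sample_id)]
  calls <- matrix("NC", length(markers), length(samples),
                  dimnames = list(markers, samples))
  confidence <- matrix(NA_real_, length(markers), length(samples),
                       dimnames = list(markers, samples))
  model_markers <- list()
  report <- vector("list", length(markers))

  for (mi in seq_along(markers)) {
    m <- markers[mi]
    pts <- marker_points(panel, m, params$r_weight)
    pops_ok <- populations[pts$ok]
    history <- character(0)
    accepted <- NULL
    step_no <- NA_integer_
    reasons <- character(0)
    n_cl <- 0L

    lab1 <- dbscan_cluster(pts$x, params$step1)
    if (lab1$n_clusters == 1L) {
      history <- c(history, "step1:single_cluster")
      prof <- optics_reachability(pts$x, params$step2)
      lab2 <- extract_k_clusters(prof, 2L)
      if (!lab2$shortfall) {
        att <- step_attempt(pts, lab2, params, 2L, pops_ok)
        if (att$filter$pass) {
          accepted <- att; step_no <- 2L
        } else {
          history <- c(history,
                       paste0("step2:", paste(att$filter$reasons,
                                              collapse = "+")))
        }
      } else {
        history <- c(history, "step2:forced_k_shortfall")
      }
    } else {
      att <- step_attempt(pts, lab1, params, 1L, pops_ok)
      if (att$filter$pass) {
        accepted <- att; step_no <- 1L
      } else {
        history <- c(history,
                     paste0("step1:", paste(att$filter$reasons,
                                            collapse = "+")))
      }
    }
    if (is.null(accepted)) {
      lab3 <- dbscan_cluster(pts$x, params$step3)
      att <- step_attempt(pts, lab3, params, 3L, pops_ok)
      if (att$filter$pass) {
        accepted <- att; step_no <- 3L
      } else {
        history <- c(history,
                     paste0("step3:", paste(att$filter$reasons,
                                            collapse = "+")))
        reasons <- att$filter$reasons
        n_cl <- att$n_clusters
      }
    }

    if (!is.null(accepted)) {
      model_markers[[m]] <- accepted$model
      calls[m, ] <- accepted$assign$call
      confidence[m, ] <- accepted$assign$confidence
      n_cl <- accepted$n_clusters
    }
    report[[mi]] <- data.frame(
      marker = m,
      status = if (is.null(accepted)) "failed" else "accepted",
      step = step_no, n_clusters = n_cl,
      reasons = paste(reasons, collapse = "+"),
      history = paste(history, collapse = ";"),
      stringsAsFactors = FALSE)
  }

  model <- structure(list(markers = model_markers, params = params),
                     class = "cluster_model")
  structure(
    list(model = model,
         genotypes = structure(list(calls = calls, confidence = confidence),
                               class = "genotype_matrix"),
         report = do.call(rbind, report)),
    class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  tab <- table(factor(ifelse(x$report$status == "failed", "failed",
                             paste0("step", x$report$step)),
                      levels = c("step1", "step2", "step3", "failed")))
  cat("protocol_result:", nrow(x$report), "markers;",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model:", length(x$markers), "markers\n")
  invisible(x)
}

#' Concordance of protocol calls with simulator ground truth
#'
#' For each accepted marker the expected call of a sample is derived from the
#' truth table: the truth genotype when the marker was genotype-labeled
#' (three clean clusters), `NULL` for null-signal samples, and otherwise the
#' ordinal label of the sample's dosage configuration (non-null
#' configurations ranked by theta, then total dose — the same convention the
#' model labeler uses). Concordance is computed over non-NC calls.
#'
#' @param result A [run_protocol()] result.
#' @param truth The truth data frame from [simulate_panel()].
#' @return List with `concordance` (fraction of non-NC calls matching),
#'   `nc_rate` (fraction NC over accepted markers), and the per-marker
#'   breakdown `per_marker`.
#' @export
call_concordance <- function(result, truth) {
  stopifnot(inherits(result, "protocol_result"))
  acc <- result$report$marker[result$report$status == "accepted"]
  per <- lapply(acc, function(m) {
    tr <- truth[truth$marker == m, ]
    mm <- result$model$markers[[m]]
    has_geno <- any(!is.na(mm$clusters$genotype))
    expected <- if (has_geno) {
      ifelse(tr$null, "NULL", tr$genotype)
    } else {
      cfg <- unique(tr[!tr$null, c("x_dose", "y_dose")])
      if (nrow(cfg)) {
        cfg$theta <- dosage_to_theta(cfg$x_dose, cfg$y_dose)
        cfg <- cfg[order(cfg$theta, cfg$x_dose + cfg$y_dose), ]
        cfg$lab <- paste0("C", seq_len(nrow(cfg)))
      }
      out <- rep("NULL", nrow(tr))
      hit <- !tr$null
      out[hit] <- cfg$lab[match(paste(tr$x_dose[hit], tr$y_dose[hit]),
                                paste(cfg$x_dose, cfg$y_dose))]
      out
    }
    got <- result$genotypes$calls[m, tr$sample]
    called <- got != "NC"
    data.frame(marker = m,
               n = nrow(tr),
               n_called = sum(called),
               n_match = sum(got[called] == expected[called]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(concordance = sum(per$n_match) / sum(per$n_called),
       nc_rate = 1 - sum(per$n_called) / sum(per$n),
       per_marker = per)
}
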