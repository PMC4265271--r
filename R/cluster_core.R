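#' Density parameters shared by DBSCAN and OPTICS
#'
#' The two user-set knobs of both algorithms: `cluster_distance` is the
#' neighborhood radius within which points count as density-connected, and
#' `min_points` is the minimum number of points (the point itself included)
#' a neighborhood must hold for its center to be a core point, which is also
#' the minimum size of a reported cluster.
#'
#' @param cluster_distance Neighborhood radius (> 0).
#' @param min_points Minimum neighborhood size (>= 1).
#' @export
density_params <- function(cluster_distance, min_points) {
  stopifnot(cluster_distance > 0, min_points >= 1)
  structure(list(cluster_distance = cluster_distance,
                 min_points = as.integer(min_points)),
            class = "density_params")
}

## all-pairs Euclidean neighborhoods; panels are at most a few thousand
## samples per marker so no spatial index is needed
neighborhoods <- function(x, eps) {
  d <- as.matrix(stats::dist(x))
  lapply(seq_len(nrow(x)), function(i) which(d[i, ] <= eps))
}

#' DBSCAN clustering
#'
#' Standard DBSCAN semantics: a core point has at least `min_points` points
#' (itself included) within `cluster_distance`; clusters are the connected
#' components of core points plus their border points; everything else is
#' noise (label 0). Border points reachable from several clusters are
#' assigned to the cluster of their lowest-index core neighbor, which makes
#' the labeling fully deterministic given the input order.
#'
#' @param points Numeric matrix (rows = points, 2 columns), finite values.
#' @param params A [density_params()].
#' @return A `cluster_labeling`: list with `labels` (integer vector, 0 =
#'   noise), `n_clusters`, `core` (logical vector), `shortfall = FALSE`.
#' @export
dbscan_cluster <- function(points, params) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) stop("empty point set")
  stopifnot(all(is.finite(points)))
  nb <- neighborhoods(points, params$cluster_distance)
  core <- lengths(nb) >= params$min_points
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    labels[i] <- cid
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]; head <- head + 1L
      nxt <- nb[[j]]
      nxt <- nxt[core[nxt] & labels[nxt] == 0L]
      labels[nxt] <- cid
      queue <- c(queue, nxt)
    }
  }
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  structure(list(labels = labels, n_clusters = cid, core = core,
                 shortfall = FALSE),
            class = "cluster_labeling")
}

#' OPTICS reachability analysis
#'
#' Computes the OPTICS visit ordering together with per-point reachability
#' and core distances, both bounded by `cluster_distance`. Ties in the
#' priority queue (equal reachability) are broken by point index, so the
#' profile is deterministic across runs and platforms. The first point of
#' each density-connected component has undefined reachability (`Inf`).
#'
#' @inheritParams dbscan_cluster
#' @return An `optics_profile`: list with `order` (visit order, point
#'   indices), `reachability` and `core_dist` (in visit order, `Inf` =
#'   undefined), `cluster_distance`, `min_points`, `n`.
#' @export
optics_reachability <- function(points, params) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) stop("empty point set")
  stopifnot(all(is.finite(points)))
  eps <- params$cluster_distance
  d <- as.matrix(stats::dist(points))
  core_dist <- apply(d, 1, function(v) {
    w <- sort(v[v <= eps])
    if (length(w) >= params$min_points) w[params$min_points] else Inf
  })
  reach <- rep(Inf, n)
  done <- logical(n)
  ord <- integer(n)
  reach_out <- numeric(n)
  for (step in seq_len(n)) {
    cand <- which(!done)
    i <- cand[order(reach[cand], cand)][1]
    done[i] <- TRUE
    ord[step] <- i
    reach_out[step] <- reach[i]
    if (is.finite(core_dist[i])) {
      nbi <- which(d[i, ] <= eps & !done)
      if (length(nbi))
        reach[nbi] <- pmin(reach[nbi], pmax(core_dist[i], d[i, nbi]))
    }
  }
  structure(list(order = ord, reachability = reach_out,
                 core_dist = core_dist[ord],
                 cluster_distance = eps, min_points = params$min_points,
                 n = n),
            class = "optics_profile")
}

#' Cut a reachability profile at a fixed threshold
#'
#' Walking the visit order, a point whose reachability exceeds `threshold`
#' starts a new cluster if its own core distance is within the threshold and
#' is noise otherwise; any other point joins the current cluster. Cutting at
#' `threshold = cluster_distance` reproduces the DBSCAN partition of core
#' points at that radius.
#'
#' @param profile An [optics_reachability()] profile.
#' @param threshold Distance threshold (<= the profile's `cluster_distance`).
#' @return A `cluster_labeling` in original point order.
#' @export
extract_at_threshold <- function(profile, threshold) {
  stopifnot(inherits(profile, "optics_profile"))
  lab_ord <- integer(profile$n)
  cid <- 0L; cur <- 0L
  for (k in seq_len(profile$n)) {
    if (profile$reachability[k] > threshold) {
      if (profile$core_dist[k] <= threshold) {
        cid <- cid + 1L; cur <- cid
        lab_ord[k] <- cur
      }
      # otherwise noise; the current cluster stays open for later points
      # whose reachability (set by an earlier core point) is within threshold
    } else {
      lab_ord[k] <- cur
    }
  }
  labels <- integer(profile$n)
  labels[profile$order] <- lab_ord
  structure(list(labels = labels, n_clusters = cid,
                 core = rep(NA, profile$n), shortfall = FALSE),
            class = "cluster_labeling")
}

#' Extract a requested number of clusters from a reachability profile
#'
#' Scans the distinct reachability/core-distance values (descending, bounded
#' by `cluster_distance`) for the largest threshold whose cut yields exactly
#' `k` clusters with at least `min_points` members each; members of
#' undersized clusters are relabeled noise. If no threshold achieves `k`, the
#' labeling with the closest achievable count below `k` is returned and the
#' shortfall is flagged. This is the forced-cluster-count mechanism used to
#' split compressed cluster pairs that a fixed-radius scan merges.
#'
#' @param profile An [optics_reachability()] profile.
#' @param k Requested number of clusters (>= 1).
#' @return A `cluster_labeling` with `shortfall = TRUE` when `k` was not
#'   achievable.
#' @export
extract_k_clusters <- function(profile, k) {
  stopifnot(inherits(profile, "optics_profile"), k >= 1)
  if (profile$n == 0L) stop("empty profile")
  eps <- profile$cluster_distance
  vals <- c(profile$reachability, profile$core_dist, eps)
  cand <- sort(unique(vals[is.finite(vals) & vals <= eps]), decreasing = TRUE)
  best <- NULL; best_cnt <- -1L
  for (t in cand) {
    lab <- extract_at_threshold(profile, t)
    keep <- prune_small(lab$labels, profile$min_points)
    cnt <- keep$n_clusters
    if (cnt == k)
      return(structure(list(labels = keep$labels, n_clusters = cnt,
                            core = rep(NA, profile$n), shortfall = FALSE,
                            threshold = t),
                       class = "cluster_labeling"))
    if (cnt < k && cnt > best_cnt) {
      best_cnt <- cnt
      best <- structure(list(labels = keep$labels, n_clusters = cnt,
                             core = rep(NA, profile$n), shortfall = TRUE,
                             threshold = t),
                        class = "cluster_labeling")
    }
  }
  if (is.null(best))
    best <- structure(list(labels = integer(profile$n), n_clusters = 0L,
                           core = rep(NA, profile$n), shortfall = TRUE,
                           threshold = NA_real_),
                      class = "cluster_labeling")
  best
}

## drop clusters below the minimum size and renumber 1..k in order of first
## appearance
prune_small <- function(labels, min_points) {
  if (!any(labels > 0L))
    return(list(labels = labels, n_clusters = 0L))
  tab <- table(labels[labels > 0L])
  valid <- as.integer(names(tab))[tab >= min_points]
  labels[!(labels %in% valid)] <- 0L
  old <- unique(labels[labels > 0L])   # order of first appearance
  labels <- match(labels, old, nomatch = 0L)
  list(labels = as.integer(labels), n_clusters = length(old))
}

#' Dump a reachability profile as a TSV for plotting
#'
#' @param profile An [optics_reachability()] profile.
#' @param path Output path.
#' @export
write_reachability <- function(profile, path) {
  df <- data.frame(position = seq_len(profile$n), point = profile$order,
                   reachability = fmt6(profile$reachability),
                   core_dist = fmt6(profile$core_dist))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
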