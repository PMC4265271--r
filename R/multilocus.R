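#' Detect the segregating cluster pair within one population
#'
#' In a bi-parental population an assay behaving as a single biallelic locus
#' splits its samples between exactly two clusters. The pair is accepted when
#' its combined frequency reaches `min_pair_freq` of the population's non-NC
#' calls and each member cluster holds at least `min_points` samples. A
#' chi-square test against the expected 1:1 doubled-haploid ratio is recorded
#' as annotation only (segregation can legitimately distort in
#' restricted-recombination regions), never as a filter.
#'
#' @param calls Character vector of one population's calls at one marker.
#' @param min_points Minimum samples per cluster of the pair.
#' @param min_pair_freq Minimum combined frequency of the pair among non-NC
#'   calls.
#' @return List (`cluster_a`, `cluster_b`, `n_a`, `n_b`, `ratio_p`) or `NULL`
#'   when no qualifying pair exists (monomorphic or diffuse assays).
#' @export
detect_segregation <- function(calls, min_points = 10L,
                               min_pair_freq = 0.9) {
  calls <- calls[!is.na(calls) & calls != "NC"]
  if (!length(calls)) return(NULL)
  tab <- sort(table(calls), decreasing = TRUE)
  if (length(tab) < 2L) return(NULL)
  top2 <- tab[1:2]
  if (any(top2 < min_points)) return(NULL)
  if (sum(top2) / length(calls) < min_pair_freq) return(NULL)
  p <- stats::chisq.test(as.vector(top2), p = c(0.5, 0.5))$p.value
  pair <- sort(names(top2))
  list(cluster_a = pair[1], cluster_b = pair[2],
       n_a = as.integer(tab[pair[1]]), n_b = as.integer(tab[pair[2]]),
       ratio_p = p)
}

#' Segregation records for all (marker, population) combinations
#'
#' Applies [detect_segregation()] across a genotype matrix. Calls are
#' translated to ordinal cluster labels (C1..Cn / NULL) through the cluster
#' model so that records from genotype-labeled and multi-cluster markers live
#' in one label space.
#'
#' @param genotypes A `genotype_matrix`.
#' @param model The `cluster_model` the calls came from.
#' @param partition Named character vector or data frame (`sample_id`,
#'   `population`) mapping samples to populations.
#' @param populations Populations to scan (default: all in the partition).
#' @inheritParams detect_segregation
#' @return Data frame with one row per detected record: marker, population,
#'   cluster_a, cluster_b, n_a, n_b, ratio_p.
#' @export
segregation_records <- function(genotypes, model, partition,
                                populations = NULL, min_points = 10L,
                                min_pair_freq = 0.9) {
  part <- as_partition(partition, colnames(genotypes$calls))
  if (is.null(populations)) populations <- sort(unique(part))
  rows <- list()
  for (m in rownames(genotypes$calls)) {
    mm <- model$markers[[m]]
    if (is.null(mm)) next
    # genotype call -> ordinal label translation for this marker
    map <- stats::setNames(mm$clusters$label, cluster_call_labels(mm$clusters))
    for (pop in populations) {
      cc <- genotypes$calls[m, part == pop]
      cc <- ifelse(cc %in% names(map), map[cc], cc)
      rec <- detect_segregation(cc, min_points, min_pair_freq)
      if (!is.null(rec))
        rows[[length(rows) + 1L]] <- data.frame(
          marker = m, population = pop, cluster_a = rec$cluster_a,
          cluster_b = rec$cluster_b, n_a = rec$n_a, n_b = rec$n_b,
          ratio_p = rec$ratio_p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(marker = character(0), population = character(0),
                      cluster_a = character(0), cluster_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      ratio_p = numeric(0)))
  do.call(rbind, rows)
}

#' Resolve multi-cluster assays into biallelic loci across populations
#'
#' Builds, per marker, a graph whose nodes are the marker's clusters and
#' whose edges are population-level segregating pairs: each edge is one
#' biallelic locus observation. A cluster incident to edges from different
#' populations (a hub) is a shared-allele state — the same cluster acting as
#' one allele of two distinct loci. Clusters with no incident edge are
#' reported unresolved. Conflicting records (same marker and population,
#' different pairs) flag the marker as conflicted and leave it unresolved.
#' The map is invariant to the order of the input records.
#'
#' @param records Data frame from [segregation_records()].
#' @param model The `cluster_model` (source of each marker's cluster set).
#' @return An `allelic_map`: list of data frames `edges` (marker, cluster_a,
#'   cluster_b, populations, n_populations), `hubs` (marker, cluster,
#'   degree), `unresolved` (marker, cluster) and the character vector
#'   `conflicts` of conflicted markers.
#' @export
build_allelic_map <- function(records, model) {
  stopifnot(inherits(model, "cluster_model"))
  records <- records[order(records$marker, records$population), , drop = FALSE]
  edges <- list(); hubs <- list(); unresolved <- list()
  conflicts <- character(0)
  for (m in sort(unique(c(records$marker, names(model$markers))))) {
    mm <- model$markers[[m]]
    if (is.null(mm)) next
    nodes <- sort(mm$clusters$label)
    rec <- records[records$marker == m, , drop = FALSE]
    conflict <- anyDuplicated(rec$population) > 0L
    if (conflict) {
      # same population reporting two different pairs is a contradiction
      dup <- unique(rec$population[duplicated(rec$population)])
      pairs <- unique(rec[rec$population %in% dup,
                          c("population", "cluster_a", "cluster_b")])
      conflict <- anyDuplicated(pairs$population) > 0L
    }
    if (conflict) {
      conflicts <- c(conflicts, m)
      unresolved[[length(unresolved) + 1L]] <-
        data.frame(marker = m, cluster = nodes, stringsAsFactors = FALSE)
      next
    }
    if (nrow(rec)) {
      key <- paste(rec$cluster_a, rec$cluster_b, sep = "|")
      agg <- lapply(sort(unique(key)), function(k) {
        sel <- key == k
        data.frame(marker = m,
                   cluster_a = rec$cluster_a[sel][1],
                   cluster_b = rec$cluster_b[sel][1],
                   populations = paste(sort(unique(rec$population[sel])),
                                       collapse = ","),
                   n_populations = length(unique(rec$population[sel])),
                   stringsAsFactors = FALSE)
      })
      agg <- do.call(rbind, agg)
      edges[[length(edges) + 1L]] <- agg
      deg <- table(c(agg$cluster_a, agg$cluster_b))
      hub <- names(deg)[deg >= 2L]
      if (length(hub))
        hubs[[length(hubs) + 1L]] <-
          data.frame(marker = m, cluster = sort(hub),
                     degree = as.integer(deg[sort(hub)]),
                     stringsAsFactors = FALSE)
      un <- setdiff(nodes, c(agg$cluster_a, agg$cluster_b))
      if (length(un))
        unresolved[[length(unresolved) + 1L]] <-
          data.frame(marker = m, cluster = un, stringsAsFactors = FALSE)
    } else {
      unresolved[[length(unresolved) + 1L]] <-
        data.frame(marker = m, cluster = nodes, stringsAsFactors = FALSE)
    }
  }
  empty_edges <- data.frame(marker = character(0), cluster_a = character(0),
                            cluster_b = character(0),
                            populations = character(0),
                            n_populations = integer(0))
  empty_nodes <- data.frame(marker = character(0), cluster = character(0))
  structure(
    list(edges = if (length(edges)) do.call(rbind, edges) else empty_edges,
         hubs = if (length(hubs)) do.call(rbind, hubs) else
           cbind(empty_nodes, degree = integer(0)),
         unresolved = if (length(unresolved)) do.call(rbind, unresolved)
           else empty_nodes,
         conflicts = conflicts),
    class = "allelic_map")
}

#' @export
print.allelic_map <- function(x, ...) {
  cat("allelic_map:", nrow(x$edges), "biallelic contrasts;",
      nrow(x$hubs), "shared-allele hubs;",
      nrow(x$unresolved), "unresolved clusters;",
      length(x$conflicts), "conflicted markers\n")
  invisible(x)
}

#' Write an allelic map as TSV files
#'
#' @param map An [build_allelic_map()] result.
#' @param path Path of the edges TSV; unresolved clusters go to
#'   `<path>.unresolved.tsv`.
#' @export
write_allelic_map <- function(map, path) {
  ed <- map$edges
  hubset <- paste(map$hubs$marker, map$hubs$cluster)
  ed$hub_a <- paste(ed$marker, ed$cluster_a) %in% hubset
  ed$hub_b <- paste(ed$marker, ed$cluster_b) %in% hubset
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(map$unresolved, paste0(path, ".unresolved.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
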