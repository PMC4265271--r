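fmt6 <- function(x) {
  out <- formatC(x, format = "f", digits = 6)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

CLUSTER_FILE_VERSION <- "polyclust_cluster_file_v1"

default_col_map <- list(
  marker = c("SNP Name", "SNP.Name", "SNP_Name", "marker", "marker_id"),
  sample = c("Sample ID", "Sample.ID", "Sample_ID", "sample", "sample_id"),
  theta = c("Theta", "theta"),
  r = c("R", "r"),
  x = c("X", "x"),
  y = c("Y", "y"))

find_col <- function(header, candidates) {
  hit <- which(header %in% candidates)
  if (length(hit)) hit[1] else NA_integer_
}

#' Read a final-report style intensity export
#'
#' Accepts the tab-delimited long format of array genotyping exports: an
#' optional bracketed header block terminated by a `[Data]` line, then one
#' row per (marker, sample) with either polar (`Theta`, `R`) or raw channel
#' (`X`, `Y`) intensities. Raw channels are converted by the fixed polar
#' transform `theta = (2/pi) atan2(Y, X)`, `R = X + Y` (theta is 1 at X = 0).
#' Markers and samples are identified by name, so column order is free.
#' Duplicate (marker, sample) rows, missing required columns, non-numeric or
#' out-of-range intensities are errors, never silent coercions; pairs absent
#' from the file stay `NA` (missing, never zero).
#'
#' @param path Input file.
#' @param col_map Optional named list overriding the accepted column names
#'   (elements `marker`, `sample`, `theta`, `r`, `x`, `y`).
#' @param sample_meta Optional data frame (`sample_id`, `population`) of
#'   panel metadata; default: all samples in one `"panel"` population.
#' @return An `intensity_panel`.
#' @export
read_final_report <- function(path, col_map = NULL, sample_meta = NULL) {
  cm <- default_col_map
  if (!is.null(col_map)) cm[names(col_map)] <- col_map
  lines <- readLines(path)
  start <- 1L
  dl <- grep("^\\[Data\\]", lines)
  if (length(dl)) start <- dl[1] + 1L
  if (start > length(lines)) stop("no data section in ", path)
  header <- strsplit(lines[start], "\t", fixed = TRUE)[[1]]
  ci <- lapply(cm, find_col, header = header)
  if (is.na(ci$marker)) stop("missing required column: marker (SNP Name)")
  if (is.na(ci$sample)) stop("missing required column: sample (Sample ID)")
  polar <- !is.na(ci$theta) && !is.na(ci$r)
  raw <- !is.na(ci$x) && !is.na(ci$y)
  if (!polar && !raw)
    stop("missing intensity columns: need (Theta, R) or (X, Y)")

  body <- lines[seq(start + 1L, length(lines))]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < length(header)))
    stop("malformed row at line ", start + which(nf < length(header))[1])
  get <- function(i) vapply(fields, `[[`, character(1), i)
  marker <- get(ci$marker)
  sample <- get(ci$sample)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric ", what, " at line ", start + bad[1])
    v
  }
  if (polar) {
    theta <- num(ci$theta, "Theta")
    r <- num(ci$r, "R")
    if (any(theta < 0 | theta > 1))
      stop("theta out of [0,1] at line ",
           start + which(theta < 0 | theta > 1)[1])
    if (any(r < 0))
      stop("negative R at line ", start + which(r < 0)[1])
  } else {
    x <- num(ci$x, "X")
    y <- num(ci$y, "Y")
    if (any(x < 0 | y < 0))
      stop("negative channel intensity at line ",
           start + which(x < 0 | y < 0)[1])
    if (any(x + y == 0))
      stop("zero total intensity (theta undefined) at line ",
           start + which(x + y == 0)[1])
    theta <- (2 / pi) * atan2(y, x)
    r <- x + y
  }
  key <- paste(marker, sample, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (marker, sample) row: ",
         sub("\r", " / ", key[duplicated(key)][1]))
  markers <- unique(marker)
  samples <- unique(sample)
  theta_m <- matrix(NA_real_, length(markers), length(samples),
                    dimnames = list(markers, samples))
  r_m <- theta_m
  idx <- cbind(match(marker, markers), match(sample, samples))
  theta_m[idx] <- theta
  r_m[idx] <- r
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample_id = samples, population = "panel",
                              stringsAsFactors = FALSE)
  structure(list(theta = theta_m, r = r_m,
                 samples = sample_meta[match(samples, sample_meta$sample_id),
                                       , drop = FALSE]),
            class = "intensity_panel")
}

#' Write an intensity panel in final-report long format
#'
#' Deterministic output: rows ordered by marker then sample
#' (lexicographically), intensities at fixed 6-decimal precision.
#'
#' @param panel An `intensity_panel`.
#' @param path Output file.
#' @export
write_final_report <- function(panel, path) {
  markers <- sort(rownames(panel$theta))
  samples <- sort(colnames(panel$theta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[Header]", "Content\tpolyclust simulated panel", "[Data]",
               "SNP Name\tSample ID\tTheta\tR"), con)
  for (m in markers) {
    ok <- is.finite(panel$theta[m, samples])
    writeLines(paste(m, samples[ok],
                     fmt6(panel$theta[m, samples[ok]]),
                     fmt6(panel$r[m, samples[ok]]), sep = "\t"), con)
  }
  invisible(path)
}

#' Write a simulator truth table as TSV
#'
#' @param truth Truth data frame from [simulate_panel()].
#' @param path Output file.
#' @export
write_truth_set <- function(truth, path) {
  truth <- truth[order(truth$marker, truth$sample), ]
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_set
#' @export
read_truth_set <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write genotype calls
#'
#' Three formats: `tsv_wide` (marker x sample call matrix), `tsv_long`
#' (marker, sample, call, confidence; the lossless round-trip format), and
#' `vcf` (VCF 4.2 sites-only coordinates with GT genotypes; AA -> 0/0,
#' AB -> 0/1, BB -> 1/1, NC -> ./.). Only genotype-labeled biallelic markers
#' are exported to VCF; multi-cluster and null-bearing markers are skipped
#' and their count reported in a message. Output ordering is deterministic
#' (markers then samples, lexicographic) with fixed 6-decimal confidences.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output file.
#' @param format `"tsv_wide"`, `"tsv_long"` or `"vcf"`.
#' @export
write_genotypes <- function(genotypes, path,
                            format = c("tsv_wide", "tsv_long", "vcf")) {
  format <- match.arg(format)
  calls <- genotypes$calls
  markers <- sort(rownames(calls))
  samples <- sort(colnames(calls))
  if (format == "tsv_wide") {
    df <- data.frame(marker = markers,
                     calls[markers, samples, drop = FALSE],
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "tsv_long") {
    long <- expand.grid(sample = samples, marker = markers,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    long <- long[, c("marker", "sample")]
    idx <- cbind(match(long$marker, rownames(calls)),
                 match(long$sample, colnames(calls)))
    long$call <- calls[idx]
    long$confidence <- fmt6(genotypes$confidence[idx])
    long$confidence[is.na(genotypes$confidence[idx])] <- "NA"
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    biallelic <- markers[apply(calls[markers, , drop = FALSE], 1, function(cc)
      all(cc %in% c("AA", "AB", "BB", "NC")))]
    skipped <- length(markers) - length(biallelic)
    if (skipped > 0)
      message(skipped,
              " non-biallelic (multi-cluster or null-bearing) marker(s)",
              " skipped in VCF export")
    gt_map <- c(AA = "0/0", AB = "0/1", BB = "1/1", NC = "./.")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=polyclust",
                 paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                        "Description=\"Genotype\">"),
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", samples),
                       collapse = "\t")), con)
    if (!length(biallelic))
      warning("no biallelic markers: VCF body is empty")
    for (i in seq_along(biallelic)) {
      m <- biallelic[i]
      writeLines(paste(c(".", i, m, "A", "B", ".", "PASS", ".", "GT",
                         unname(gt_map[calls[m, samples]])),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read genotype calls written by [write_genotypes()]
#'
#' @param path Input file.
#' @param format `"tsv_long"` (restores confidences) or `"tsv_wide"`.
#' @return A `genotype_matrix` (wide input: confidences `NA`).
#' @export
read_genotypes <- function(path, format = c("tsv_long", "tsv_wide")) {
  format <- match.arg(format)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (format == "tsv_long") {
    markers <- unique(df$marker)
    samples <- unique(df$sample)
    calls <- matrix("NC", length(markers), length(samples),
                    dimnames = list(markers, samples))
    confidence <- matrix(NA_real_, length(markers), length(samples),
                         dimnames = list(markers, samples))
    idx <- cbind(match(df$marker, markers), match(df$sample, samples))
    calls[idx] <- df$call
    confidence[idx] <- suppressWarnings(as.numeric(df$confidence))
  } else {
    markers <- df$marker
    calls <- as.matrix(df[, -1, drop = FALSE])
    rownames(calls) <- markers
    confidence <- matrix(NA_real_, nrow(calls), ncol(calls),
                         dimnames = dimnames(calls))
  }
  structure(list(calls = calls, confidence = confidence),
            class = "genotype_matrix")
}

#' Persist a fitted cluster model
#'
#' One row per cluster with centers, spreads, median intensity, member count,
#' labels and null flags at fixed 6-decimal precision — the precision the
#' model itself is stored at, so write/read round trips are bit-stable and a
#' re-applied stored model reproduces the original calls exactly. The file
#' starts with a version line; reading a different version is an explicit
#' error.
#'
#' @param model A `cluster_model`.
#' @param path Output file.
#' @export
write_cluster_file <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  rows <- lapply(sort(names(model$markers)), function(m) {
    cl <- model$markers[[m]]$clusters
    data.frame(marker = m, r_scale = fmt6(model$markers[[m]]$r_scale),
               cluster = cl$cluster, label = cl$label,
               genotype = ifelse(is.na(cl$genotype), ".", cl$genotype),
               center_theta = fmt6(cl$center_theta),
               center_r = fmt6(cl$center_r),
               spread_theta = fmt6(cl$spread_theta),
               spread_r = fmt6(cl$spread_r),
               median_r = fmt6(cl$median_r),
               n = cl$n, null = cl$null,
               stringsAsFactors = FALSE)
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", CLUSTER_FILE_VERSION), con)
  df <- do.call(rbind, rows)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_file
#' @export
read_cluster_file <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, paste0("#", CLUSTER_FILE_VERSION)))
    stop("cluster file version mismatch: expected ", CLUSTER_FILE_VERSION,
         ", found ", sub("^#", "", first))
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  markers <- lapply(split(df, df$marker), function(dd) {
    dd <- dd[order(dd$cluster), ]
    list(clusters = data.frame(
           cluster = dd$cluster,
           center_theta = dd$center_theta, center_r = dd$center_r,
           spread_theta = dd$spread_theta, spread_r = dd$spread_r,
           median_r = dd$median_r, n = dd$n, null = dd$null,
           label = dd$label,
           genotype = ifelse(dd$genotype == ".", NA_character_,
                             dd$genotype),
           stringsAsFactors = FALSE),
         r_scale = dd$r_scale[1])
  })
  structure(list(markers = markers, params = NULL),
            class = "cluster_model")
}

#' Genotype a panel with a stored cluster model
#'
#' The train-on-mapping-populations, apply-to-new-panel workflow: samples are
#' assigned to the stored clusters with [assign_samples()] without
#' re-clustering. Panel markers absent from the model are skipped; samples
#' sitting in clusters that did not exist at training time fall below the
#' distance cutoff and come back NC (their count is reported in a message).
#'
#' @param model A `cluster_model` (typically from [read_cluster_file()]).
#' @param panel An `intensity_panel`.
#' @param confidence_limit,spread_floor,max_dist See [assign_samples()].
#' @return A `genotype_matrix`.
#' @export
apply_cluster_file <- function(model, panel, confidence_limit = 0.8,
                               spread_floor = 0.01, max_dist = 6) {
  gm <- assign_samples(model, panel, confidence_limit, spread_floor,
                       max_dist)
  n_nc <- sum(gm$calls == "NC")
  message("applied stored model to ", nrow(gm$calls), " marker(s); ",
          n_nc, " NC call(s)")
  gm
}
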