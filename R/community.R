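#' Community read-count tables
#'
#' A `community_tbl` bundles one census of metabarcoding read counts with its
#' per-sample sequencing metadata. Counts are stored long (one row per
#' sample-by-OTU observation with `reads >= 1`); the `samples` tibble carries,
#' for every sample, the total filtered read count (`filtered_total`) and the
#' total after removing the synthetic spike-in reads (`nonspike_total`).
#' Spike reads are `filtered_total - nonspike_total`.
#'
#' @param counts Tibble with columns `sample_id`, `otu_id`, `reads`
#'   (positive integers).
#' @param samples Tibble with columns `sample_id`, `log_id`, `census`
#'   (one of `"pre"`, `"year1"`, `"year2"`), `filtered_total`,
#'   `nonspike_total`.
#' @return An object of class `community_tbl`.
#' @export
community_tbl <- function(counts, samples) {
  counts <- tibble::as_tibble(counts)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "otu_id", "reads") %in% names(counts)),
            all(c("sample_id", "log_id", "census", "filtered_total",
                  "nonspike_total") %in% names(samples)))
  counts <- counts[, c("sample_id", "otu_id", "reads")]
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample ids in sample table", call. = FALSE)
  }
  bad <- samples$sample_id[samples$nonspike_total > samples$filtered_total]
  if (length(bad)) {
    stop("nonspike_total exceeds filtered_total for sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(counts)) {
    if (any(counts$reads <= 0) || any(counts$reads != round(counts$reads))) {
      stop("read counts must be positive integers", call. = FALSE)
    }
    unknown <- setdiff(counts$sample_id, samples$sample_id)
    if (length(unknown)) {
      stop("counts reference unknown sample(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    sums <- dplyr::summarise(dplyr::group_by(counts, .data$sample_id),
                             total = sum(.data$reads), .groups = "drop")
    chk <- dplyr::left_join(samples, sums, by = "sample_id")
    chk$total[is.na(chk$total)] <- 0
    off <- chk$sample_id[chk$total != chk$nonspike_total]
    if (length(off)) {
      stop("nonspike_total does not equal the summed OTU reads for sample(s): ",
           paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
    }
  } else if (any(samples$nonspike_total != 0)) {
    stop("empty count table but nonzero nonspike_total", call. = FALSE)
  }
  structure(list(counts = counts, samples = samples), class = "community_tbl")
}

#' @export
print.community_tbl <- function(x, ...) {
  cat(sprintf(
    "<community_tbl> %d samples, %d OTUs, %d nonzero counts (censuses: %s)\n",
    nrow(x$samples), length(unique(x$counts$otu_id)), nrow(x$counts),
    paste(unique(x$samples$census), collapse = ", ")))
  invisible(x)
}

#' Number of samples in a community table
#' @param tbl A `community_tbl`.
#' @return Integer count of samples.
#' @export
n_samples <- function(tbl) nrow(tbl$samples)

#' Combine censuses into one community table
#' @param ... `community_tbl` objects with disjoint sample ids.
#' @return A single `community_tbl`.
#' @export
bind_censuses <- function(...) {
  tabs <- list(...)
  community_tbl(dplyr::bind_rows(lapply(tabs, `[[`, "counts")),
                dplyr::bind_rows(lapply(tabs, `[[`, "samples")))
}

#' Presence-absence matrix of a community table
#'
#' @param tbl A `community_tbl`.
#' @param min_reads Minimum reads for an OTU to count as present.
#' @return Integer 0/1 matrix, samples as rows (named by `sample_id`),
#'   OTUs as columns.
#' @export
presence_matrix <- function(tbl, min_reads = 1) {
  wide_matrix(tbl, presence = TRUE, min_reads = min_reads)
}

#' Read-count matrix of a community table
#' @param tbl A `community_tbl`.
#' @return Numeric matrix of reads, samples as rows, OTUs as columns.
#' @export
count_matrix <- function(tbl) wide_matrix(tbl, presence = FALSE)

wide_matrix <- function(tbl, presence, min_reads = 1) {
  samp <- tbl$samples$sample_id
  otus <- sort(unique(tbl$counts$otu_id))
  m <- matrix(0, nrow = length(samp), ncol = length(otus),
              dimnames = list(samp, otus))
  if (nrow(tbl$counts)) {
    cnt <- tbl$counts
    m[cbind(match(cnt$sample_id, samp), match(cnt$otu_id, otus))] <- cnt$reads
  }
  if (presence) m <- (m >= min_reads) * 1L
  m
}

#' Restrict a community table to a set of samples
#' @param tbl A `community_tbl`.
#' @param sample_ids Samples to keep.
#' @return A `community_tbl` with only those samples.
#' @export
subset_samples <- function(tbl, sample_ids) {
  community_tbl(
    dplyr::filter(tbl$counts, .data$sample_id %in% sample_ids),
    dplyr::filter(tbl$samples, .data$sample_id %in% sample_ids)
  )
}
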