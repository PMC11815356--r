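#' The ten candidate probit model configurations
#'
#' Model 1 is the environment-only model (log type, decay stage, sequencing
#' depth as fixed effects; site as a random effect). Models 2-10 add one block
#' of biotic predictors describing the resident fungal community, computed
#' either from the presence-absence community matrix (models 2-6) or from the
#' fourth-root relative read abundances (models 8-10); model 7 uses the
#' spike-calibrated DNA amount. Models 6 and 10 apply spike-and-slab variable
#' selection to their ten common-species columns.
#'
#' @param model_id Integer in 1..10.
#' @return A list of class `model_spec` with fields `model_id`, `name`,
#'   `data_type` (`"none"`, `"presence"` or `"rra"`), `biotic_block` and
#'   `variable_selection`.
#' @examples
#' model_spec(6)
#' model_catalog()
#' @export
model_spec <- function(model_id) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:10) stop("model_id must be in 1..10", call. = FALSE)
  cat_row <- model_catalog()[model_id, ]
  structure(as.list(cat_row), class = "model_spec")
}

#' @rdname model_spec
#' @export
model_catalog <- function() {
  tibble::tibble(
    model_id = 1:10,
    name = c("environment-only",
             "total species richness",
             "per-phylum species richness",
             "community composition (presence)",
             "ten most common species (presence)",
             "ten most common species (presence, variable selection)",
             "DNA amount",
             "community composition (RRA)",
             "ten most common species (RRA)",
             "ten most common species (RRA, variable selection)"),
    data_type = c("none", rep("presence", 5), "none", rep("rra", 3)),
    biotic_block = c("none", "total_richness", "per_phylum_richness",
                     "ordination", "top10", "top10_selected", "dna_amount",
                     "ordination", "top10", "top10_selected"),
    variable_selection = c(rep(FALSE, 5), TRUE, rep(FALSE, 3), TRUE)
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %d: %s (biotic block: %s%s)\n",
              x$model_id, x$name, x$biotic_block,
              if (x$variable_selection) ", variable selection" else ""))
  invisible(x)
}

#' Remove low-depth samples
#'
#' Drops every sample whose filtered read total falls strictly below
#' `min_reads` (default 10,000 reads), the standard depth cut-off for
#' metabarcoding sampling units.
#'
#' @param tbl A `community_tbl`.
#' @param min_reads Depth threshold; samples with `filtered_total < min_reads`
#'   are removed.
#' @return The filtered `community_tbl`, with the removed sample ids attached
#'   as attribute `"removed"` (also retrievable via [removed_samples()]).
#' @export
filter_samples <- function(tbl, min_reads = 10000) {
  keep <- tbl$samples$filtered_total >= min_reads
  removed <- tbl$samples$sample_id[!keep]
  out <- subset_samples(tbl, tbl$samples$sample_id[keep])
  attr(out, "removed") <- removed
  out
}

#' @rdname filter_samples
#' @export
removed_samples <- function(tbl) attr(tbl, "removed") %||% character(0)

#' Binary colonization response for one target species
#'
#' A target log scores 1 when the target species' OTU was detected (at least
#' `min_detect_reads` reads) in its sample one and/or two years after
#' inoculation, and 0 otherwise. Logs whose post-inoculation samples were all
#' removed by the depth filter are dropped from the sampling units.
#'
#' @param species Target species id.
#' @param design A `study_design`.
#' @param year1,year2 Post-inoculation `community_tbl` censuses (after
#'   [filter_samples()]).
#' @param target_otu The OTU id representing the target species; defaults to
#'   the id used by the simulator ([target_otu_id()]).
#' @param min_detect_reads Minimum reads accepted as a detection.
#' @return Tibble with one row per retained target log: `log_id`, `site_id`,
#'   `y` (0/1), and per-year detection columns `det_year1`, `det_year2`
#'   (`NA` when that year's sample was filtered out).
#' @export
build_response <- function(species, design, year1, year2,
                           target_otu = target_otu_id(species),
                           min_detect_reads = 1) {
  logs <- target_logs(design, species)
  det <- function(tbl, yr) {
    cnt <- dplyr::filter(tbl$counts, .data$otu_id == target_otu,
                         .data$reads >= min_detect_reads)
    samp <- dplyr::filter(tbl$samples, .data$log_id %in% logs$log_id,
                          .data$census == yr)
    tibble::tibble(log_id = samp$log_id,
                   det = as.integer(samp$sample_id %in% cnt$sample_id))
  }
  d1 <- det(year1, "year1")
  d2 <- det(year2, "year2")
  out <- dplyr::left_join(logs[, c("log_id", "site_id")],
                          dplyr::rename(d1, det_year1 = "det"), by = "log_id")
  out <- dplyr::left_join(out, dplyr::rename(d2, det_year2 = "det"),
                          by = "log_id")
  out <- dplyr::filter(out, !(is.na(.data$det_year1) & is.na(.data$det_year2)))
  out$y <- as.integer(pmax(out$det_year1, out$det_year2, na.rm = TRUE) > 0)
  dplyr::relocate(out, "log_id", "site_id", "y")
}

#' OTU id carried by the simulator for a target species
#' @param species Species id.
#' @return Character OTU id.
#' @export
target_otu_id <- function(species) paste0("OTU_target_", species)

#' Relative read abundances
#'
#' Divides each sample's OTU read counts by that sample's non-spike total, so
#' rows sum to one. Spike-in reads never enter the denominator.
#'
#' @param tbl A `community_tbl`.
#' @return Numeric matrix of relative read abundances (samples x OTUs).
#' @export
rra <- function(tbl) {
  zero <- tbl$samples$sample_id[tbl$samples$nonspike_total == 0]
  if (length(zero)) {
    stop("cannot compute relative read abundances: zero non-spike total for ",
         "sample(s): ", paste(utils::head(zero, 5), collapse = ", "),
         call. = FALSE)
  }
  m <- count_matrix(tbl)
  m / tbl$samples$nonspike_total[match(rownames(m), tbl$samples$sample_id)]
}

#' Fourth-root transform of relative read abundances
#'
#' Raising abundances to the power one-fourth compresses the heavy right tail
#' of read-abundance distributions and limits the leverage of dominant OTUs.
#'
#' @param x Numeric matrix or vector of abundances in `[0, 1]`.
#' @return `x^(1/4)`, same shape.
#' @export
transform_rra <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  x^0.25
}

#' Spike-calibrated DNA amount
#'
#' The number of spike reads is the filtered total minus the non-spike total;
#' the DNA amount proxy is the ratio of non-spike to spike reads, used in the
#' models on the natural-log scale.
#'
#' @param filtered_total,nonspike_total Per-sample read totals
#'   (`filtered_total >= nonspike_total >= 0`), vectorized.
#' @param pseudocount Added to both spike and non-spike reads before the
#'   ratio; the default 0 raises an error when a sample has no spike reads.
#' @return Tibble with columns `ratio` and `log_ratio`.
#' @export
dna_amount <- function(filtered_total, nonspike_total, pseudocount = 0) {
  if (any(nonspike_total > filtered_total) || any(nonspike_total < 0)) {
    stop("need filtered_total >= nonspike_total >= 0", call. = FALSE)
  }
  spike <- filtered_total - nonspike_total
  if (pseudocount == 0 && any(spike == 0)) {
    stop("sample(s) with zero spike reads; set a pseudocount to proceed",
         call. = FALSE)
  }
  ratio <- (nonspike_total + pseudocount) / (spike + pseudocount)
  tibble::tibble(ratio = ratio, log_ratio = log(ratio))
}

#' Sequencing-depth predictor
#'
#' Natural log of the mean filtered read total over the post-inoculation
#' years with a retained sample (average first, then log, by default).
#'
#' @param year1_total,year2_total Filtered totals (vectorized); `NA` for a
#'   year whose sample was removed.
#' @param log_first If `TRUE`, average the yearly log-totals instead.
#' @return Numeric vector.
#' @export
seq_depth_predictor <- function(year1_total, year2_total, log_first = FALSE) {
  if (any(is.na(year1_total) & is.na(year2_total))) {
    stop("at least one yearly total must be present per log", call. = FALSE)
  }
  if (log_first) {
    rowMeans(cbind(log(year1_total), log(year2_total)), na.rm = TRUE)
  } else {
    log(rowMeans(cbind(year1_total, year2_total), na.rm = TRUE))
  }
}

#' Resident richness, total and per phylum
#'
#' @param presence Presence-absence matrix (samples x OTUs) of the resident
#'   (pre-inoculation) census, e.g. from [presence_matrix()].
#' @param taxonomy Tibble with columns `otu_id`, `phylum`; OTUs absent from it
#'   (or with `NA` phylum) count toward the total only.
#' @return Tibble with columns `sample_id`, `richness_total`,
#'   `richness_ascomycota`, `richness_basidiomycota`.
#' @export
richness <- function(presence, taxonomy) {
  phy <- taxonomy$phylum[match(colnames(presence), taxonomy$otu_id)]
  tibble::tibble(
    sample_id = rownames(presence) %||% as.character(seq_len(nrow(presence))),
    richness_total = as.numeric(rowSums(presence)),
    richness_ascomycota =
      as.numeric(rowSums(presence[, which(!is.na(phy) & phy == "Ascomycota"),
                                  drop = FALSE])),
    richness_basidiomycota =
      as.numeric(rowSums(presence[, which(!is.na(phy) & phy == "Basidiomycota"),
                                  drop = FALSE]))
  )
}

#' The most common resident species across a set of logs
#'
#' Ranks OTUs by the number of logs occupied; ties are broken by the larger
#' total read count and then by OTU id, so the result is deterministic.
#'
#' @param presence Presence-absence matrix over the logs of interest.
#' @param k Number of OTUs to return (default 10).
#' @param counts Optional read-count matrix with the same dimnames, used for
#'   tie-breaking; ties go to the OTU with more reads.
#' @return Character vector of up to `k` OTU ids, most common first. If fewer
#'   than `k` OTUs occur at all, all occurring OTUs are returned with a
#'   warning.
#' @export
top_common_species <- function(presence, k = 10, counts = NULL) {
  occ <- colSums(presence)
  tot <- if (is.null(counts)) rep(0, ncol(presence)) else colSums(counts)
  ids <- colnames(presence)
  keep <- occ > 0
  ord <- order(-occ[keep], -tot[keep], ids[keep])
  ranked <- ids[keep][ord]
  if (length(ranked) < k) {
    warning(sprintf("only %d occurring OTUs available (k = %d)",
                    length(ranked), k))
    return(ranked)
  }
  ranked[seq_len(k)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
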