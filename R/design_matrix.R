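#' Assemble the probit design matrix for one species and one model
#'
#' Combines the binary colonization response with the abiotic predictors
#' (log-type contrasts against the broken reference level, decay stage,
#' sequencing depth) and, for models 2-10, the model's biotic block computed
#' from the pre-inoculation resident census. Continuous predictors are
#' standardized (mean 0, SD 1) over the retained rows; binary presence
#' columns stay 0/1.
#'
#' The retained rows are the species' target logs whose pre-inoculation
#' sample and at least one post-inoculation sample survived the depth filter,
#' so every model of the candidate set is fitted to the same sampling units.
#'
#' @param model A `model_spec` (or integer model id 1-10).
#' @param species Target species id.
#' @param design A `study_design`.
#' @param pre,year1,year2 Depth-filtered `community_tbl` censuses.
#' @param taxonomy Tibble (`otu_id`, `phylum`).
#' @param ordination_scores For models 4 and 8: tibble with columns `log_id`,
#'   `LV1`, `LV2` (see [scores_as_predictors()]).
#' @param top_k Number of common-species columns for models 5, 6, 9, 10.
#' @param min_detect_reads Detection threshold for the response.
#' @param standardize Standardize continuous predictors (default `TRUE`).
#' @param log_first Passed to [seq_depth_predictor()].
#' @return An object of class `design_matrix`: fields `X` (numeric matrix with
#'   an intercept column), `y` (0/1 response), `site` (site id per row),
#'   `log_id`, `groups` (per-column predictor-group label in
#'   `{intercept, environment, seq_depth, biotic}`), `select` (per-column flag
#'   marking spike-and-slab candidates), `model_id`, `species`, `scaling`.
#' @export
build_design_matrix <- function(model, species, design, pre, year1, year2,
                                taxonomy = NULL, ordination_scores = NULL,
                                top_k = 10, min_detect_reads = 1,
                                standardize = TRUE, log_first = FALSE) {
  if (is.numeric(model)) model <- model_spec(model)
  resp <- build_response(species, design, year1, year2,
                         min_detect_reads = min_detect_reads)

  # keep rows that also have a retained pre-census sample, for all models
  pre_samp <- dplyr::filter(pre$samples, .data$census == "pre")
  resp <- dplyr::filter(resp, .data$log_id %in% pre_samp$log_id)
  if (nrow(resp) == 0) stop("no retained sampling units for ", species,
                            call. = FALSE)
  logs <- dplyr::left_join(
    resp, tibble::as_tibble(design)[, c("log_id", "log_type", "decay_stage")],
    by = "log_id")

  lt <- cbind(felled_vs_broken = as.numeric(logs$log_type == "felled"),
              uprooted_vs_broken = as.numeric(logs$log_type == "uprooted"))

  depth_of <- function(tbl, yr) {
    s <- dplyr::filter(tbl$samples, .data$census == yr)
    s$filtered_total[match(logs$log_id, s$log_id)]
  }
  seq_depth <- seq_depth_predictor(depth_of(year1, "year1"),
                                   depth_of(year2, "year2"),
                                   log_first = log_first)

  X <- cbind(intercept = 1, lt, decay_stage = logs$decay_stage,
             seq_depth = seq_depth)
  groups <- c("intercept", "environment", "environment", "environment",
              "seq_depth")
  continuous <- c(FALSE, FALSE, FALSE, TRUE, TRUE)

  if (model$biotic_block != "none") {
    bio <- biotic_block(model, species, logs, pre, taxonomy,
                        ordination_scores, top_k)
    X <- cbind(X, bio$cols)
    groups <- c(groups, rep("biotic", ncol(bio$cols)))
    continuous <- c(continuous, bio$continuous)
  }

  scaling <- list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  names(scaling$center) <- names(scaling$scale) <- colnames(X)
  if (standardize) {
    for (j in which(continuous)) {
      mu <- mean(X[, j]); sdv <- stats::sd(X[, j])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      X[, j] <- (X[, j] - mu) / sdv
      scaling$center[j] <- mu; scaling$scale[j] <- sdv
    }
  }
  if (any(!is.finite(X))) stop("non-finite values in design matrix",
                               call. = FALSE)

  select <- if (model$variable_selection) groups == "biotic" else
    rep(FALSE, ncol(X))

  structure(list(X = X, y = logs$y, site = logs$site_id, log_id = logs$log_id,
                 groups = groups, select = select, model_id = model$model_id,
                 species = species, scaling = scaling),
            class = "design_matrix")
}

biotic_block <- function(model, species, logs, pre, taxonomy,
                         ordination_scores, top_k) {
  pre_sub <- subset_samples(
    pre, pre$samples$sample_id[pre$samples$census == "pre" &
                                 pre$samples$log_id %in% logs$log_id])
  samp_of_log <- pre_sub$samples$sample_id[match(logs$log_id,
                                                 pre_sub$samples$log_id)]
  P <- presence_matrix(pre_sub)[samp_of_log, , drop = FALSE]

  block <- model$biotic_block
  if (block %in% c("total_richness", "per_phylum_richness")) {
    if (is.null(taxonomy) && block == "per_phylum_richness") {
      stop("taxonomy required for per-phylum richness", call. = FALSE)
    }
    r <- richness(P, taxonomy %||%
                    tibble::tibble(otu_id = character(0), phylum = character(0)))
    cols <- if (block == "total_richness") {
      cbind(richness_total = r$richness_total)
    } else {
      cbind(richness_ascomycota = r$richness_ascomycota,
            richness_basidiomycota = r$richness_basidiomycota)
    }
    return(list(cols = cols, continuous = rep(TRUE, ncol(cols))))
  }
  if (block == "ordination") {
    if (is.null(ordination_scores)) {
      stop("ordination scores required for the community-composition models",
           call. = FALSE)
    }
    idx <- match(logs$log_id, ordination_scores$log_id)
    if (anyNA(idx)) stop("ordination scores missing for some logs",
                         call. = FALSE)
    cols <- cbind(LV1 = ordination_scores$LV1[idx],
                  LV2 = ordination_scores$LV2[idx])
    return(list(cols = cols, continuous = c(TRUE, TRUE)))
  }
  if (block == "dna_amount") {
    s <- pre_sub$samples[match(samp_of_log, pre_sub$samples$sample_id), ]
    da <- dna_amount(s$filtered_total, s$nonspike_total)
    return(list(cols = cbind(dna_amount = da$log_ratio), continuous = TRUE))
  }
  if (block %in% c("top10", "top10_selected")) {
    cnts <- count_matrix(pre_sub)[samp_of_log, , drop = FALSE]
    top <- top_common_species(P, k = top_k, counts = cnts)
    if (model$data_type == "presence") {
      cols <- P[, top, drop = FALSE]
      colnames(cols) <- paste0("occ_", top)
      return(list(cols = cols, continuous = rep(FALSE, ncol(cols))))
    }
    R <- transform_rra(rra(pre_sub))[samp_of_log, top, drop = FALSE]
    colnames(R) <- paste0("rra_", top)
    return(list(cols = R, continuous = rep(TRUE, ncol(R))))
  }
  stop("unknown biotic block: ", block, call. = FALSE)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "<design_matrix> model %d, %s: %d sampling units x %d predictors (%d successes)\n",
    x$model_id, x$species, nrow(x$X), ncol(x$X), sum(x$y)))
  invisible(x)
}

#' @export
as_tibble.design_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(log_id = x$log_id, site_id = x$site, y = x$y),
    tibble::as_tibble(x$X))
}

#' Write a design matrix as CSV with a group-label header line
#'
#' The first line is a comment (`# groups: ...`) giving each predictor
#' column's group label; the remainder is a regular CSV.
#'
#' @param dm A `design_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_matrix_csv <- function(dm, path) {
  hdr <- paste0("# groups: ",
                paste(colnames(dm$X), dm$groups, sep = "=", collapse = ","))
  writeLines(hdr, path)
  readr::write_csv(as_tibble.design_matrix(dm), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}
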