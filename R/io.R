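#' Write a community table to disk
#'
#' The OTU table is a TSV with OTUs as rows and samples as columns (the
#' dominant metabarcoding convention); per-sample metadata go to a sidecar
#' CSV (`sample_id`, `log_id`, `census`, `filtered_total`, `nonspike_total`).
#'
#' @param tbl A `community_tbl`.
#' @param otu_path,sidecar_path Output paths.
#' @return `otu_path`, invisibly.
#' @export
write_community_tsv <- function(tbl, otu_path, sidecar_path) {
  m <- t(count_matrix(tbl)) # OTUs x samples
  out <- dplyr::bind_cols(tibble::tibble(otu_id = rownames(m)),
                          tibble::as_tibble(m))
  readr::write_tsv(out, otu_path)
  readr::write_csv(tbl$samples, sidecar_path)
  invisible(otu_path)
}

#' Read a community table written by [write_community_tsv()]
#'
#' Validates the invariants on load: every count column must match a sample
#' in the sidecar, non-spike totals must equal the summed OTU reads and may
#' not exceed the filtered totals.
#'
#' @param otu_path,sidecar_path Input paths.
#' @return A `community_tbl`.
#' @export
read_community_tsv <- function(otu_path, sidecar_path) {
  wide <- readr::read_tsv(otu_path, show_col_types = FALSE)
  samples <- readr::read_csv(sidecar_path, show_col_types = FALSE,
                             col_types = readr::cols(
                               sample_id = "c", log_id = "c", census = "c",
                               filtered_total = "i", nonspike_total = "i"))
  long <- tidyr::pivot_longer(wide, cols = -"otu_id",
                              names_to = "sample_id", values_to = "reads")
  long <- dplyr::filter(long, .data$reads > 0)
  long$reads <- as.integer(long$reads)
  community_tbl(long[, c("sample_id", "otu_id", "reads")], samples)
}

#' Write / read a taxonomy table (TSV: otu_id, phylum)
#' @param taxonomy Tibble (`otu_id`, `phylum`).
#' @param path File path.
#' @return `path` (writer) or the taxonomy tibble (reader).
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path)
  invisible(path)
}

#' @rdname write_taxonomy_tsv
#' @export
read_taxonomy_tsv <- function(path) {
  tax <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(otu_id = "c", phylum = "c"))
  n_missing <- sum(is.na(tax$phylum))
  if (n_missing > 0) {
    warning(sprintf("%d OTUs lack a phylum assignment; they count toward %s",
                    n_missing, "total richness only"))
  }
  tax
}

#' Read a full on-disk dataset
#'
#' Loads the design CSV, the three census tables with their sidecars, and the
#' taxonomy, cross-checking sample-to-log references.
#'
#' @param dir Directory written by [write_dataset()] / [run_simulate()].
#' @return An `inoculation_data` list (without generator truth unless
#'   `truth.json` is present).
#' @export
read_dataset <- function(dir) {
  design <- read_design_csv(file.path(dir, "design.csv"))
  censuses <- lapply(stats::setNames(nm = c("pre", "year1", "year2")),
                     function(cn) {
    tbl <- read_community_tsv(file.path(dir, paste0("otu_", cn, ".tsv")),
                              file.path(dir, paste0("samples_", cn, ".csv")))
    unknown <- setdiff(tbl$samples$log_id, design$log_id)
    if (length(unknown)) {
      stop("sample sidecar references unknown log id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    tbl
  })
  taxonomy <- read_taxonomy_tsv(file.path(dir, "taxonomy.tsv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  structure(list(design = design, taxonomy = taxonomy, censuses = censuses,
                 detections = NULL, truth = truth),
            class = "inoculation_data")
}

#' Write a simulated dataset to disk
#'
#' @param data An `inoculation_data` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_design_csv(data$design, file.path(dir, "design.csv"))
  for (cn in names(data$censuses)) {
    write_community_tsv(data$censuses[[cn]],
                        file.path(dir, paste0("otu_", cn, ".tsv")),
                        file.path(dir, paste0("samples_", cn, ".csv")))
  }
  write_taxonomy_tsv(data$taxonomy, file.path(dir, "taxonomy.tsv"))
  if (!is.null(data$truth)) {
    jsonlite::write_json(
      list(true_beta = as.list(data$truth$true_beta),
           sigma_site = data$truth$sigma_site,
           true_model = data$truth$true_model,
           latent_success = data$truth$latent_success),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Run configuration for the simulate / analyze pipeline
#'
#' Validates keys up front so typos fail fast, and records every seed so any
#' stage can be re-run bit-identically.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param models Model ids to fit (subset of 1:10).
#' @param species Species ids to analyse (`NULL` = all).
#' @param min_reads Depth-filter threshold.
#' @param min_detect_reads Detection threshold for the response.
#' @param top_k Common-species block size.
#' @param mcmc Named list: `chains`, `warmup`, `samples`, `thin`.
#' @param params A [generator_params()] for simulation runs.
#' @param clamp_zero Clamp negative AUC differences at 0 in the report.
#' @param ... Must be empty; unknown keys raise a schema error.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("inocula_run"), seed = 1L,
                       models = 1:10, species = NULL,
                       min_reads = 10000, min_detect_reads = 1, top_k = 10,
                       mcmc = list(chains = 2, warmup = 500, samples = 500,
                                   thin = 1),
                       params = generator_params(seed = seed),
                       clamp_zero = FALSE, ...) {
  extras <- list(...)
  if (length(extras)) {
    stop("unknown config key(s): ", paste(names(extras), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(models %in% 1:10),
            all(c("chains", "warmup", "samples") %in% names(mcmc)))
  mcmc$thin <- mcmc$thin %||% 1
  structure(list(outdir = outdir, seed = seed, models = models,
                 species = species, min_reads = min_reads,
                 min_detect_reads = min_detect_reads, top_k = top_k,
                 mcmc = mcmc, params = params, clamp_zero = clamp_zero),
            class = "run_config")
}

#' Simulate a dataset and write it to disk
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config) {
  data <- simulate_dataset(config$params)
  write_dataset(data, config$outdir)
  invisible(config$outdir)
}

#' Analyse a dataset: filter, features, fits, LOO-CV, comparison
#'
#' Runs the full pipeline for every requested (species, model) pair:
#' depth filter, response construction, predictor assembly (with per-species
#' ordinations for the community-composition models), probit fits,
#' leave-one-out cross-validated AUC, variance partitioning and the
#' best-model comparison. Species whose response has a single class are
#' skipped with a message and the run continues.
#'
#' @param data An `inoculation_data` (from [simulate_dataset()] or
#'   [read_dataset()]).
#' @param config A [run_config()].
#' @return A list of class `colonization_analysis`: `auc_table` (tibble:
#'   species, model_id, auc, n), `comparison` (one row per species),
#'   `variance` (variance partitions of the environment-only fits),
#'   `skipped`, and `config`.
#' @export
run_analysis <- function(data, config = run_config()) {
  censuses <- lapply(data$censuses, filter_samples,
                     min_reads = config$min_reads)
  species <- config$species %||% attr(data$design, "species")
  auc_rows <- list(); var_rows <- list(); skipped <- character(0)

  for (sp in species) {
    resp <- build_response(sp, data$design, censuses$year1, censuses$year2,
                           min_detect_reads = config$min_detect_reads)
    if (length(unique(resp$y)) < 2) {
      message("skipping ", sp, ": single-class response, model unfittable")
      skipped <- c(skipped, sp)
      next
    }
    ords <- list()
    for (mid in config$models) {
      ms <- model_spec(mid)
      scores <- NULL
      if (ms$biotic_block == "ordination") {
        key <- ms$data_type
        if (is.null(ords[[key]])) {
          ords[[key]] <- fit_species_ordination(
            sp, data$design, censuses$pre, data_type = key,
            seed = config$seed + mid)
        }
        scores <- scores_as_predictors(ords[[key]],
                                       rownames(ords[[key]]$scores))
      }
      dm <- build_design_matrix(ms, sp, data$design, censuses$pre,
                                censuses$year1, censuses$year2,
                                taxonomy = data$taxonomy,
                                ordination_scores = scores,
                                top_k = config$top_k,
                                min_detect_reads = config$min_detect_reads)
      res <- loo_cv_auc(dm, chains = config$mcmc$chains,
                        warmup = config$mcmc$warmup,
                        samples = config$mcmc$samples,
                        thin = config$mcmc$thin,
                        seed = config$seed + 1000L * mid)
      auc_rows[[length(auc_rows) + 1L]] <- tidy.loo_auc(res)
      if (mid == 1) {
        fit <- fit_probit(dm, chains = config$mcmc$chains,
                          warmup = config$mcmc$warmup,
                          samples = config$mcmc$samples,
                          seed = config$seed)
        vp <- variance_partition(fit, dm)
        vp$species <- sp
        var_rows[[length(var_rows) + 1L]] <- vp
      }
    }
  }

  auc_table <- dplyr::bind_rows(auc_rows)
  comparison <- if (nrow(auc_table) && setequal(config$models, 1:10)) {
    dplyr::group_modify(dplyr::group_by(auc_table, .data$species),
                        ~ compare_models(.x, clamp_zero = config$clamp_zero))
  } else NULL
  structure(list(auc_table = auc_table,
                 comparison = if (!is.null(comparison))
                   dplyr::ungroup(comparison) else NULL,
                 variance = dplyr::bind_rows(var_rows),
                 skipped = skipped, config = config),
            class = "colonization_analysis")
}

#' @rdname run_analysis
#' @param config A [run_config()]; the dataset is read from
#'   `config$outdir`.
#' @return `run_analyze()` additionally writes `auc_table.csv`,
#'   `comparison.csv` and `analysis.json` under `config$outdir` and returns
#'   the `colonization_analysis` invisibly.
#' @export
run_analyze <- function(config) {
  data <- read_dataset(config$outdir)
  res <- run_analysis(data, config)
  readr::write_csv(res$auc_table, file.path(config$outdir, "auc_table.csv"))
  if (!is.null(res$comparison)) {
    readr::write_csv(res$comparison,
                     file.path(config$outdir, "comparison.csv"))
  }
  jsonlite::write_json(
    list(seed = config$seed, models = config$models,
         min_reads = config$min_reads, skipped = res$skipped),
    file.path(config$outdir, "analysis.json"), auto_unbox = TRUE)
  invisible(res)
}

#' @export
print.colonization_analysis <- function(x, ...) {
  cat(sprintf(
    "<colonization_analysis> %d species x %d models (LOO-CV AUC)\n",
    length(unique(x$auc_table$species)),
    length(unique(x$auc_table$model_id))))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Table-2-style report: models as rows, species as columns
#'
#' @param analysis A `colonization_analysis`.
#' @return Tibble with one row per model (named) and one column per species,
#'   plus a final `AUC difference` row when the comparison is available.
#' @export
report_table <- function(analysis) {
  wide <- tidyr::pivot_wider(analysis$auc_table[, c("species", "model_id",
                                                    "auc")],
                             names_from = "species", values_from = "auc")
  wide <- dplyr::arrange(wide, .data$model_id)
  wide$model <- model_catalog()$name[wide$model_id]
  wide <- dplyr::relocate(wide, "model_id", "model")
  if (!is.null(analysis$comparison)) {
    diff_row <- tibble::tibble(model_id = NA_integer_,
                               model = "AUC difference")
    for (sp in analysis$comparison$species) {
      diff_row[[sp]] <-
        analysis$comparison$auc_difference[analysis$comparison$species == sp]
    }
    wide <- dplyr::bind_rows(wide, diff_row)
  }
  wide
}
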