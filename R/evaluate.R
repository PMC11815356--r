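#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive's score exceeds the negative's, with ties credited 0.5.
#' Computed from midranks, so it is exact under ties and O(n log n).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1) of the same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)) # 0.75
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated AUC
#'
#' For every sampling unit, refits the probit model on the remaining units
#' (fresh seeded chains, same priors) and predicts the held-out unit with
#' [predict_success()]; the AUC is computed over the pooled held-out
#' predictions. Feature construction (ordination scores, common-species
#' identities, standardization constants) is frozen from the full data — the
#' refits touch only the regression stage.
#'
#' @param dm A `design_matrix` (features already built on the full data).
#' @param prior A [prior_spec()].
#' @param chains,warmup,samples,thin Per-fold sampler settings (kept modest
#'   by default: LOO multiplies fits by `n`).
#' @param seed Integer seed; fold `i` uses `seed + i`.
#' @return An object of class `loo_auc`: fields `species`, `model_id`,
#'   `auc`, `n` and `predictions` (tibble `log_id`, `y`, `pred`).
#' @export
loo_cv_auc <- function(dm, prior = prior_spec(), chains = 1,
                       warmup = 250, samples = 250, thin = 1, seed = 1L) {
  n <- nrow(dm$X)
  if (n < 2 || length(unique(dm$y)) < 2) {
    stop("LOO-CV needs n >= 2 with both outcome classes present",
         call. = FALSE)
  }
  preds <- numeric(n)
  for (i in seq_len(n)) {
    sub <- dm
    sub$X <- dm$X[-i, , drop = FALSE]
    sub$y <- dm$y[-i]
    sub$site <- dm$site[-i]
    fit <- fit_probit(sub, prior = prior, chains = chains, warmup = warmup,
                      samples = samples, thin = thin, seed = seed + i)
    preds[i] <- predict_success(fit, dm$X[i, , drop = FALSE], dm$site[i])
  }
  structure(list(species = dm$species, model_id = dm$model_id,
                 auc = auc(preds, dm$y), n = n,
                 predictions = tibble::tibble(log_id = dm$log_id, y = dm$y,
                                              pred = preds)),
            class = "loo_auc")
}

#' @export
print.loo_auc <- function(x, ...) {
  cat(sprintf("<loo_auc> %s, model %d: AUC %.3f (n = %d)\n",
              x$species %||% "?", x$model_id, x$auc, x$n))
  invisible(x)
}

#' @rdname loo_cv_auc
#' @param x A `loo_auc`.
#' @param ... Unused.
#' @export
tidy.loo_auc <- function(x, ...) {
  tibble::tibble(species = x$species %||% NA_character_,
                 model_id = x$model_id, auc = x$auc, n = x$n)
}

#' Variance partitioning over predictor groups and the site effect
#'
#' Per posterior draw, computes the across-unit variance of each predictor
#' group's contribution to the linear predictor (`sum_{k in g} x_ik beta_k`)
#' and takes the site random effect's share as its variance `sigma_site^2`;
#' shares are normalized to sum to one per draw and averaged over draws.
#' Group covariances are excluded by construction (shares come from the
#' per-group variances alone). The intercept column contributes no variance.
#'
#' @param fit A `probit_fit`, or a draws matrix of coefficients
#'   (draws x predictors).
#' @param dm The `design_matrix` the model was fitted to (needed when `fit`
#'   is a `probit_fit`).
#' @param X,groups,sigma2_draws Matrix interface: predictor matrix, per-column
#'   group labels, and per-draw site variances (0 to omit the site term).
#' @return Tibble of class `variance_partition` with columns `group` and
#'   `share`; shares are non-negative and sum to 1.
#' @export
variance_partition <- function(fit, dm = NULL, X = NULL, groups = NULL,
                               sigma2_draws = NULL) {
  if (inherits(fit, "probit_fit")) {
    beta <- fit$beta
    X <- dm$X; groups <- dm$groups
    sigma2_draws <- fit$sigma2
  } else {
    beta <- rbind(fit)
    if (is.null(sigma2_draws)) sigma2_draws <- rep(0, nrow(beta))
  }
  stopifnot(ncol(beta) == ncol(X), length(groups) == ncol(X))
  gset <- setdiff(unique(groups), "intercept")
  n_draw <- nrow(beta)
  shares <- matrix(0, n_draw, length(gset) + 1,
                   dimnames = list(NULL, c(gset, "site")))
  for (t in seq_len(n_draw)) {
    v <- vapply(gset, function(g) {
      cols <- which(groups == g)
      stats::var(as.vector(X[, cols, drop = FALSE] %*% beta[t, cols]))
    }, 0)
    v <- c(v, site = sigma2_draws[t])
    tot <- sum(v)
    if (tot > 0) shares[t, ] <- v / tot
  }
  if (all(rowSums(shares) == 0)) {
    stop("degenerate variance partition: zero total variance in every draw",
         call. = FALSE)
  }
  out <- tibble::tibble(group = colnames(shares),
                        share = unname(colMeans(shares)))
  out$share <- out$share / sum(out$share)
  class(out) <- c("variance_partition", class(out))
  out
}

#' Compare candidate models for one species
#'
#' Finds the best model by AUC (ties to the lower model id) and reports the
#' difference between the best resident-community model (ids 2-10) and the
#' environment-only model (id 1).
#'
#' @param auc_tbl Tibble with columns `model_id` and `auc` covering all ten
#'   models for one species (a `species` column is carried through if
#'   present).
#' @param clamp_zero If `TRUE`, negative differences are reported as 0 (the
#'   usual presentation in summary tables); the default reports the raw
#'   difference.
#' @return One-row tibble: `best_model_id`, `auc_env`, `auc_best_resident`,
#'   `auc_difference`.
#' @examples
#' compare_models(tibble::tibble(model_id = 1:10,
#'   auc = c(0.66, 0.81, 0.80, 0.73, 0.70, 0.61, 0.58, 0.64, 0.64, 0.60)))
#' @export
compare_models <- function(auc_tbl, clamp_zero = FALSE) {
  if (!all(1:10 %in% auc_tbl$model_id)) {
    stop("AUC values must cover all ten model ids", call. = FALSE)
  }
  auc_tbl <- dplyr::arrange(auc_tbl, .data$model_id)
  best <- auc_tbl$model_id[which.max(auc_tbl$auc)]
  env <- auc_tbl$auc[auc_tbl$model_id == 1]
  res <- max(auc_tbl$auc[auc_tbl$model_id != 1])
  diff <- res - env
  if (clamp_zero) diff <- max(0, diff)
  out <- tibble::tibble(best_model_id = best, auc_env = env,
                        auc_best_resident = res, auc_difference = diff)
  if ("species" %in% names(auc_tbl)) {
    out <- dplyr::bind_cols(tibble::tibble(species = auc_tbl$species[1]), out)
  }
  out
}

#' Target-species occurrence in logs where they were not inoculated
#'
#' @param design A `study_design`.
#' @param censuses Named list of `community_tbl` objects (e.g. `pre`,
#'   `year1`, `year2`), depth-filtered.
#' @param min_detect_reads Minimum reads counting as an occurrence.
#' @return Tibble with columns `species`, `census`, `n_background_logs`,
#'   `n_occupied`, `fraction`.
#' @export
background_prevalence <- function(design, censuses, min_detect_reads = 1) {
  species <- attr(design, "species")
  purrr::map_dfr(species, function(sp) {
    otu <- target_otu_id(sp)
    non_target <- setdiff(design$log_id, target_logs(design, sp)$log_id)
    purrr::map_dfr(names(censuses), function(cn) {
      tbl <- censuses[[cn]]
      samp <- dplyr::filter(tbl$samples, .data$log_id %in% non_target)
      hits <- dplyr::filter(tbl$counts, .data$otu_id == otu,
                            .data$reads >= min_detect_reads,
                            .data$sample_id %in% samp$sample_id)
      occ_logs <- unique(samp$log_id[samp$sample_id %in% hits$sample_id])
      tibble::tibble(species = sp, census = cn,
                     n_background_logs = length(unique(samp$log_id)),
                     n_occupied = length(occ_logs),
                     fraction = length(occ_logs) /
                       max(1, length(unique(samp$log_id))))
    })
  })
}

#' Per-species colonization prevalence and abundance by year
#'
#' The proportion of each species' retained target logs in which it was
#' detected one and two years after inoculation, with (when census tables
#' are supplied) the mean relative read abundance of the target OTU over
#' those logs.
#'
#' @param design A `study_design`.
#' @param year1,year2 Depth-filtered post-inoculation `community_tbl`
#'   censuses.
#' @param min_detect_reads Detection threshold.
#' @return Tibble of class `prevalence_report`: `species`, `year`,
#'   `n_logs`, `n_detected`, `prevalence`, `mean_rra`.
#' @export
prevalence_report <- function(design, year1, year2, min_detect_reads = 1) {
  species <- attr(design, "species")
  tabs <- list(year1 = year1, year2 = year2)
  out <- purrr::map_dfr(species, function(sp) {
    otu <- target_otu_id(sp)
    tl <- target_logs(design, sp)$log_id
    purrr::map_dfr(names(tabs), function(yr) {
      tbl <- tabs[[yr]]
      samp <- dplyr::filter(tbl$samples, .data$log_id %in% tl,
                            .data$census == yr)
      hits <- dplyr::filter(tbl$counts, .data$otu_id == otu,
                            .data$reads >= min_detect_reads,
                            .data$sample_id %in% samp$sample_id)
      rra_vals <- hits$reads /
        samp$nonspike_total[match(hits$sample_id, samp$sample_id)]
      tibble::tibble(
        species = sp, year = yr, n_logs = nrow(samp),
        n_detected = nrow(hits),
        prevalence = nrow(hits) / max(1, nrow(samp)),
        mean_rra = if (nrow(samp)) sum(rra_vals) / nrow(samp) else 0)
    })
  })
  class(out) <- c("prevalence_report", class(out))
  out
}
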