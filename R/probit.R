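#' Prior settings for the probit sampler
#'
#' Slab variances apply to standardized predictor columns, so effects are on
#' a comparable scale across predictors. The spike is an exact point mass at
#' zero. The site random-intercept variance carries an inverse-gamma prior.
#'
#' @param slab_variance_fixed Normal prior variance of always-included
#'   (abiotic) coefficients.
#' @param slab_variance_biotic Slab variance of biotic coefficients.
#' @param inclusion_prior_pi Prior inclusion probability of a selectable
#'   coefficient.
#' @param sigma_site_prior Named vector `c(shape, scale)` of the
#'   inverse-gamma prior on the site variance.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(slab_variance_fixed = 1,
                       slab_variance_biotic = 1,
                       inclusion_prior_pi = 0.5,
                       sigma_site_prior = c(shape = 1, scale = 1)) {
  stopifnot(slab_variance_fixed > 0, slab_variance_biotic > 0,
            inclusion_prior_pi > 0, inclusion_prior_pi < 1,
            all(sigma_site_prior > 0))
  structure(list(slab_variance_fixed = slab_variance_fixed,
                 slab_variance_biotic = slab_variance_biotic,
                 inclusion_prior_pi = inclusion_prior_pi,
                 sigma_site_prior = sigma_site_prior),
            class = "prior_spec")
}

#' Fit a Bayesian probit regression with a site random intercept
#'
#' Gibbs sampling with truncated-normal latent-variable augmentation:
#' conjugate normal updates for the coefficients and site effects, a
#' conjugate inverse-gamma update for the site variance, and — on columns
#' flagged for selection in the design matrix — spike-and-slab indicator
#' updates computed from the marginalized slab-vs-spike odds. Deterministic
#' given `seed`.
#'
#' @param dm A `design_matrix` from [build_design_matrix()] (or a bare list
#'   with fields `X`, `y`, `site`, `select`, `groups`).
#' @param prior A [prior_spec()].
#' @param chains Number of independent chains (seeded `seed`, `seed + 1`,
#'   ...).
#' @param warmup,samples,thin Iterations discarded, retained draws per chain,
#'   and thinning interval.
#' @param sigma_site_fixed If non-`NULL`, the site random-effect variance is
#'   fixed at this value instead of sampled (0 switches site effects off).
#' @param seed Integer seed.
#' @return An object of class `probit_fit` holding the pooled draws
#'   (`beta`, `gamma`, `a`, `sigma2`, plus a `chain` index) and metadata.
#' @export
fit_probit <- function(dm, prior = prior_spec(), chains = 2,
                       warmup = 1000, samples = 1000, thin = 1,
                       sigma_site_fixed = NULL, seed = 1L) {
  X <- dm$X
  if (any(!is.finite(X))) stop("non-finite design values", call. = FALSE)
  y <- as.integer(dm$y)
  site_levels <- sort(unique(dm$site))
  site <- match(dm$site, site_levels) - 1L
  select <- dm$select %||% rep(FALSE, ncol(X))
  groups <- dm$groups %||% rep("fixed", ncol(X))
  slab <- ifelse(groups == "biotic", prior$slab_variance_biotic,
                 prior$slab_variance_fixed)
  s2fix <- if (is.null(sigma_site_fixed)) -1 else sigma_site_fixed

  runs <- lapply(seq_len(chains), function(ch) {
    set.seed((seed + ch - 1L) %% .Machine$integer.max)
    .probit_gibbs_cpp(X, y, site, length(site_levels), slab,
                      as.integer(select), prior$inclusion_prior_pi,
                      prior$sigma_site_prior[["shape"]],
                      prior$sigma_site_prior[["scale"]],
                      s2fix, warmup, samples, thin)
  })
  bind <- function(f) do.call(rbind, lapply(runs, `[[`, f))
  beta <- bind("beta"); colnames(beta) <- colnames(X)
  gam <- bind("gamma"); colnames(gam) <- colnames(X)
  a <- bind("a"); colnames(a) <- site_levels
  structure(list(
    beta = beta, gamma = gam, a = a,
    sigma2 = unlist(lapply(runs, `[[`, "sigma2")),
    chain = rep(seq_len(chains), each = samples),
    columns = colnames(X), groups = groups, select = select,
    site_levels = site_levels, scaling = dm$scaling,
    model_id = dm$model_id, species = dm$species,
    n = nrow(X), chains = chains, warmup = warmup, samples = samples,
    thin = thin, seed = seed, prior = prior),
    class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf(
    "<probit_fit> %d obs, %d predictors, %d chains x %d draws (model %s, %s)\n",
    x$n, length(x$columns), x$chains, x$samples,
    x$model_id %||% "?", x$species %||% "?"))
  invisible(x)
}

#' Posterior predicted colonization probabilities
#'
#' Averages `pnorm(x'beta + a_site)` over the posterior draws. Rows must be
#' on the same (standardized) scale as the training design matrix. Sites not
#' represented in the fit receive the prior-mean site effect, zero.
#'
#' @param fit A `probit_fit`.
#' @param newX Numeric matrix with the fit's predictor columns.
#' @param site_ids Site id per row of `newX`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_success <- function(fit, newX, site_ids) {
  newX <- rbind(newX)
  if (is.null(colnames(newX)) || !identical(colnames(newX), fit$columns)) {
    if (!all(fit$columns %in% colnames(newX))) {
      stop("prediction rows must carry the fit's predictor columns",
           call. = FALSE)
    }
    newX <- newX[, fit$columns, drop = FALSE]
  }
  eta <- newX %*% t(fit$beta) # rows x draws
  sidx <- match(site_ids, fit$site_levels)
  aeff <- matrix(0, nrow(newX), nrow(fit$a))
  seen <- !is.na(sidx)
  if (any(seen)) aeff[seen, ] <- t(fit$a)[sidx[seen], , drop = FALSE]
  rowMeans(stats::pnorm(eta + aeff))
}

#' Posterior summaries per predictor
#'
#' @param fit A `probit_fit`.
#' @param support_level Posterior-support threshold; a coefficient is flagged
#'   `supported` when `max(Pr(beta > 0), Pr(beta < 0))` reaches it.
#' @param prob Credible-interval mass.
#' @return Tibble with one row per predictor: posterior `estimate` (mean),
#'   `sd`, `conf.low`/`conf.high` (equal-tail interval), `support`,
#'   `supported`, `inclusion_prob` (mean of the spike-and-slab indicator; 1
#'   for always-included columns), `group` and `rhat`.
#' @export
posterior_summary <- function(fit, support_level = 0.95, prob = 0.95) {
  rh <- apply_rhat(fit$beta, fit$chain)
  if (any(rh > 1.1, na.rm = TRUE)) {
    warning("some split-Rhat values exceed 1.1; chains may not have converged")
  }
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  sup <- apply(fit$beta, 2, function(b) max(mean(b > 0), mean(b < 0)))
  tibble::tibble(
    term = fit$columns,
    estimate = unname(colMeans(fit$beta)),
    sd = unname(apply(fit$beta, 2, stats::sd)),
    conf.low = unname(apply(fit$beta, 2, stats::quantile, qs[1])),
    conf.high = unname(apply(fit$beta, 2, stats::quantile, qs[2])),
    support = unname(sup),
    supported = unname(sup >= support_level),
    inclusion_prob = unname(colMeans(fit$gamma)),
    group = fit$groups,
    rhat = unname(rh))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname posterior_summary
#' @param x A `probit_fit`.
#' @param ... Passed to [posterior_summary()].
#' @export
tidy.probit_fit <- function(x, ...) posterior_summary(x, ...)

#' One-row fit overview
#'
#' @param x A `probit_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_predictors`, `chains`, `draws`,
#'   `sigma_site` (posterior mean SD of the site effect), `rhat_max` and
#'   `ess_min`.
#' @export
glance.probit_fit <- function(x, ...) {
  rh <- apply_rhat(x$beta, x$chain)
  ess <- apply(x$beta, 2, ess_basic)
  tibble::tibble(
    n = x$n, n_predictors = length(x$columns), chains = x$chains,
    draws = nrow(x$beta), sigma_site = mean(sqrt(x$sigma2)),
    rhat_max = suppressWarnings(max(rh, na.rm = TRUE)),
    ess_min = min(ess))
}

# split-Rhat per column of a draws matrix
apply_rhat <- function(draws, chain) {
  apply(draws, 2, function(v) split_rhat(v, chain))
}

split_rhat <- function(v, chain) {
  halves <- lapply(split(v, chain), function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  })
  segs <- unlist(halves, recursive = FALSE)
  m <- length(segs); n <- length(segs[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(segs, mean, 0); vars <- vapply(segs, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size from the lag-autocorrelation sum
ess_basic <- function(v) {
  n <- length(v)
  if (stats::sd(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}

#' Write posterior draws to CSV with a JSON metadata sidecar
#'
#' @param fit A `probit_fit`.
#' @param path Output CSV path (`<path>.json` gets the metadata).
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(fit, path) {
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(fit$beta), draw = dplyr::row_number(),
                    chain = fit$chain),
      cols = -c("draw", "chain"), names_to = "parameter"),
    tibble::tibble(draw = seq_along(fit$sigma2), chain = fit$chain,
                   parameter = "sigma2_site", value = fit$sigma2))
  readr::write_csv(long, path)
  meta <- list(seed = fit$seed, chains = fit$chains, warmup = fit$warmup,
               samples = fit$samples, thin = fit$thin,
               columns = fit$columns, groups = fit$groups,
               prior = unclass(fit$prior), scaling = fit$scaling)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
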