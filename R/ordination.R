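#' Model-based ordination with two latent variables
#'
#' Fits the low-rank latent-variable model `g(E[y_ij]) = alpha_j +
#' u_i' lambda_j` to a community matrix by Gibbs sampling: conjugate normal
#' updates for the row scores `u_i`, column loadings `lambda_j` and column
#' intercepts, an inverse-gamma update for the residual variance (Gaussian
#' family), and truncated-normal probit augmentation for presence-absence
#' data. The latent subspace is only identified up to rotation and
#' reflection, so each retained draw is aligned to a reference draw by
#' orthogonal Procrustes rotation before averaging; the chain is initialized
#' from the truncated SVD of the centred data. Returned scores are posterior
#' means on that common orientation, centred per dimension.
#'
#' For the Bernoulli family, columns (OTUs) occurring in fewer than
#' `min_prevalence` rows are dropped before fitting.
#'
#' @param Y Numeric matrix, rows = logs (rownames used as log ids), columns =
#'   OTUs. Presence-absence 0/1 for `family = "bernoulli_probit"`;
#'   fourth-root relative read abundances (or any Gaussian responses) for
#'   `family = "gaussian"`.
#' @param family `"bernoulli_probit"` or `"gaussian"`.
#' @param n_lv Number of latent dimensions (default 2).
#' @param warmup,samples Gibbs iterations discarded and retained.
#' @param min_prevalence Minimum occupied rows per column (binary family).
#' @param seed Integer seed.
#' @return An object of class `ordination_fit`: `scores` (rows x `n_lv`
#'   posterior-mean scores, centred), `loadings`, `alpha`, `family`,
#'   `ll_trace` (per-retained-draw log-likelihood), `dropped` (filtered
#'   columns) and sampler metadata.
#' @export
fit_ordination <- function(Y, family = c("bernoulli_probit", "gaussian"),
                           n_lv = 2, warmup = 500, samples = 500,
                           min_prevalence = 2, seed = 1L) {
  family <- match.arg(family)
  Y <- as.matrix(Y)
  dropped <- character(0)
  if (family == "bernoulli_probit") {
    if (!all(Y %in% c(0, 1))) {
      stop("bernoulli_probit family needs a 0/1 matrix", call. = FALSE)
    }
    occ <- colSums(Y)
    keep <- occ >= min_prevalence & occ <= nrow(Y) - 1
    dropped <- colnames(Y)[!keep] %||% which(!keep)
    Y <- Y[, keep, drop = FALSE]
  } else {
    keep <- apply(Y, 2, stats::sd) > 0
    dropped <- colnames(Y)[!keep] %||% which(!keep)
    Y <- Y[, keep, drop = FALSE]
  }
  n <- nrow(Y); p <- ncol(Y)
  if (p <= n_lv) {
    stop(sprintf(
      "degenerate community matrix: only %d informative columns left after
filtering (%d dropped: %s)", p, length(dropped),
      paste(utils::head(dropped, 5), collapse = ", ")), call. = FALSE)
  }
  if (n <= n_lv) stop("need more than n_lv rows", call. = FALSE)

  set.seed(seed %% .Machine$integer.max)
  binary <- family == "bernoulli_probit"
  # initialize from the truncated SVD of the centred data so the chain
  # starts near the dominant low-rank structure
  alpha <- if (binary) stats::qnorm(pmin(pmax(colMeans(Y), 0.02), 0.98)) else
    colMeans(Y)
  Y0 <- sweep(Y, 2, colMeans(Y))
  sv0 <- svd(Y0, nu = n_lv, nv = n_lv)
  U <- sv0$u * sqrt(n)
  L <- sv0$v %*% diag(sv0$d[seq_len(n_lv)] / sqrt(n), n_lv)
  sigma2 <- 1
  Z <- if (binary) matrix(0, n, p) else Y

  U_sum <- matrix(0, n, n_lv); L_sum <- matrix(0, p, n_lv)
  alpha_sum <- numeric(p)
  U_ref <- NULL
  ll_trace <- numeric(samples)

  for (it in seq_len(warmup + samples)) {
    M <- sweep(U %*% t(L), 2, alpha, "+")
    if (binary) {
      # truncated-normal augmentation
      pr_lo <- stats::pnorm(-M)
      u01 <- matrix(stats::runif(n * p), n, p)
      pq <- ifelse(Y == 1, pr_lo + u01 * (1 - pr_lo), u01 * pr_lo)
      pq <- pmin(pmax(pq, 1e-12), 1 - 1e-12)
      Z <- M + stats::qnorm(pq)
      sigma2 <- 1
    }
    R <- sweep(Z, 2, alpha, "-")

    # scores: shared posterior covariance across rows
    Su <- solve(diag(n_lv) + crossprod(L) / sigma2)
    Mu <- (R %*% L / sigma2) %*% Su
    U <- Mu + matrix(stats::rnorm(n * n_lv), n, n_lv) %*% chol(Su)

    # loadings row by row (shared posterior precision structure)
    precL <- diag(n_lv) + crossprod(U) / sigma2
    chL <- chol(precL)
    ML <- t(backsolve(chL, forwardsolve(t(chL), crossprod(U, R) / sigma2)))
    L <- ML + t(backsolve(chL, matrix(stats::rnorm(p * n_lv), n_lv, p)))

    # intercepts, prior N(0, 100)
    fitted_lv <- U %*% t(L)
    v_a <- 1 / (n / sigma2 + 0.01)
    alpha <- stats::rnorm(p, v_a * colSums(Z - fitted_lv) / sigma2, sqrt(v_a))

    if (!binary) {
      rss <- sum((Z - sweep(fitted_lv, 2, alpha, "+"))^2)
      sigma2 <- (1 + rss / 2) / stats::rgamma(1, 1 + n * p / 2)
    }

    if (it > warmup) {
      # align each draw to the first retained draw: the latent subspace is
      # only identified up to rotation/reflection, so average on a common
      # orientation (orthogonal Procrustes in the n_lv-dimensional space)
      if (is.null(U_ref)) U_ref <- U
      sv <- svd(crossprod(U, U_ref))
      Q <- sv$u %*% t(sv$v)
      Ud <- U %*% Q; Ld <- L %*% Q
      U_sum <- U_sum + Ud; L_sum <- L_sum + Ld; alpha_sum <- alpha_sum + alpha
      M2 <- sweep(U %*% t(L), 2, alpha, "+")
      ll_trace[it - warmup] <- if (binary) {
        sum(stats::pnorm(ifelse(Y == 1, M2, -M2), log.p = TRUE))
      } else {
        sum(stats::dnorm(Y, M2, sqrt(sigma2), log = TRUE))
      }
    }
  }

  scores <- U_sum / samples
  scores <- sweep(scores, 2, colMeans(scores))
  colnames(scores) <- paste0("LV", seq_len(n_lv))
  rownames(scores) <- rownames(Y)
  loadings <- L_sum / samples
  colnames(loadings) <- paste0("LV", seq_len(n_lv))
  rownames(loadings) <- colnames(Y)

  structure(list(scores = scores, loadings = loadings,
                 alpha = alpha_sum / samples, family = family, n_lv = n_lv,
                 warmup = warmup, samples = samples, seed = seed,
                 dropped = dropped, ll_trace = ll_trace,
                 converged = ll_stable(ll_trace)),
            class = "ordination_fit")
}

# stability check: mean log-likelihood of the two retained halves agree
# within two MC standard errors (no systematic drift)
ll_stable <- function(ll) {
  h <- length(ll) %/% 2
  a <- ll[seq_len(h)]; b <- ll[h + seq_len(h)]
  se <- sqrt(stats::var(a) / h + stats::var(b) / h)
  is.finite(se) && (se == 0 || abs(mean(b) - mean(a)) < 4 * se + 1e-8)
}

#' @export
print.ordination_fit <- function(x, ...) {
  cat(sprintf(
    "<ordination_fit> %s family, %d rows x %d columns, %d latent dims%s\n",
    x$family, nrow(x$scores), nrow(x$loadings), x$n_lv,
    if (x$converged) "" else " (log-likelihood drift detected)"))
  invisible(x)
}

#' Extract latent-variable scores as predictor columns
#'
#' @param fit An `ordination_fit`.
#' @param log_ids Row ids to extract, in the desired order.
#' @return Tibble with columns `log_id`, `LV1`, `LV2`, ... aligned to
#'   `log_ids`.
#' @export
scores_as_predictors <- function(fit, log_ids) {
  idx <- match(log_ids, rownames(fit$scores))
  if (anyNA(idx)) {
    stop("log id(s) not present in the ordination fit: ",
         paste(utils::head(log_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_cols(tibble::tibble(log_id = log_ids),
                   tibble::as_tibble(fit$scores[idx, , drop = FALSE]))
}

#' Ordination for one species' retained target logs
#'
#' Convenience wrapper: restricts the pre-inoculation census to the species'
#' target logs with retained samples, builds the presence-absence
#' (`data_type = "presence"`) or fourth-root RRA (`data_type = "rra"`)
#' matrix with rows named by log id, and fits the two-dimensional ordination.
#'
#' @param species Species id.
#' @param design A `study_design`.
#' @param pre Depth-filtered pre-inoculation `community_tbl`.
#' @param data_type `"presence"` or `"rra"`.
#' @param ... Passed to [fit_ordination()].
#' @return An `ordination_fit` with scores named by log id.
#' @export
fit_species_ordination <- function(species, design, pre,
                                   data_type = c("presence", "rra"), ...) {
  data_type <- match.arg(data_type)
  logs <- target_logs(design, species)
  samp <- dplyr::filter(pre$samples, .data$census == "pre",
                        .data$log_id %in% logs$log_id)
  sub <- subset_samples(pre, samp$sample_id)
  Y <- if (data_type == "presence") presence_matrix(sub) else
    transform_rra(rra(sub))
  rownames(Y) <- sub$samples$log_id[match(rownames(Y),
                                          sub$samples$sample_id)]
  fam <- if (data_type == "presence") "bernoulli_probit" else "gaussian"
  fit_ordination(Y, family = fam, ...)
}

#' Write ordination scores and loadings to CSV
#'
#' The file starts with a `#`-prefixed metadata line (family, dimensions,
#' seed, draws) followed by the scores block and the loadings block.
#'
#' @param fit An `ordination_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ordination_csv <- function(fit, path) {
  writeLines(sprintf("# family=%s n_lv=%d seed=%d samples=%d", fit$family,
                     fit$n_lv, fit$seed, fit$samples), path)
  sc <- dplyr::mutate(tibble::as_tibble(fit$scores, rownames = "id"),
                      what = "score")
  ld <- dplyr::mutate(tibble::as_tibble(fit$loadings, rownames = "id"),
                      what = "loading")
  readr::write_csv(dplyr::bind_rows(sc, ld), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}
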