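brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUC matches the exhaustive pair-count oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(c(0.1, 0.9), c(1, 1)), "both classes")

  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE) # plenty of ties
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("AUC is antisymmetric under score negation without ties", {
  set.seed(23)
  scores <- sample(seq_len(30)) / 31
  labels <- rep(c(0, 1), 15)
  expect_equal(auc(scores, labels) + auc(-scores, labels), 1)
})

test_that("variance partitioning reproduces hand-computable shares", {
  # one fixed group and no random effect: the whole share
  X <- cbind(x1 = rnorm(20))
  vp <- variance_partition(cbind(x1 = c(1, 2)), X = X, groups = "g1")
  expect_equal(vp$share[vp$group == "g1"], 1)
  expect_equal(sum(vp$share), 1, tolerance = 1e-9)

  # two orthogonal standardized columns, equal coefficients: 0.5 / 0.5
  x <- scale(c(-1.5, -0.5, 0.5, 1.5))
  Xo <- cbind(a = as.numeric(x), b = as.numeric(x) * c(1, -1, -1, 1))
  Xo <- apply(Xo, 2, function(v) v / sd(v))
  beta <- matrix(c(0.7, 0.7), 1, dimnames = list(NULL, c("a", "b")))
  vp2 <- variance_partition(beta, X = Xo, groups = c("ga", "gb"))
  expect_equal(vp2$share[vp2$group == "ga"], 0.5, tolerance = 1e-9)
  expect_equal(vp2$share[vp2$group == "gb"], 0.5, tolerance = 1e-9)

  # permutation equivariance in the group labels
  vp2r <- variance_partition(beta[, c("b", "a"), drop = FALSE],
                             X = Xo[, c("b", "a")], groups = c("gb", "ga"))
  expect_equal(dplyr::arrange(vp2, group), dplyr::arrange(vp2r, group))

  expect_error(variance_partition(matrix(0, 3, 2), X = Xo,
                                  groups = c("ga", "gb")),
               "degenerate")
})

test_that("shares recomputed from stored draws agree to numerical precision", {
  set.seed(31)
  X <- matrix(rnorm(40 * 4), 40,
              dimnames = list(NULL, c("u", "v", "w", "z")))
  groups <- c("env", "env", "depth", "biotic")
  beta <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, colnames(X)))
  s2 <- rexp(10)
  vp <- variance_partition(beta, X = X, groups = groups, sigma2_draws = s2)

  shares <- matrix(0, 10, 4)
  for (t in 1:10) {
    v <- c(var(X[, 1:2] %*% beta[t, 1:2]), var(X[, 3] * beta[t, 3]),
           var(X[, 4] * beta[t, 4]), s2[t])
    shares[t, ] <- v / sum(v)
  }
  oracle <- colMeans(shares)
  expect_equal(vp$share[match(c("env", "depth", "biotic", "site"), vp$group)],
               oracle / sum(oracle), tolerance = 1e-12)
})

test_that("variance partitioning of a fitted model sums to one", {
  dat <- small_dataset()
  cens <- filtered_censuses(dat)
  sp <- design_species(dat$design)[1]
  dm <- build_design_matrix(1, sp, dat$design, cens$pre, cens$year1,
                            cens$year2, taxonomy = dat$taxonomy)
  fit <- fit_probit(dm, chains = 1, warmup = 200, samples = 300, seed = 2)
  vp <- variance_partition(fit, dm)
  expect_equal(sum(vp$share), 1, tolerance = 1e-9)
  expect_true(all(vp$share >= 0))
  expect_setequal(vp$group, c("environment", "seq_depth", "site"))
})

test_that("model comparison reports the best-resident-vs-environment gap", {
  col_a <- c(0.66, 0.81, 0.80, 0.73, 0.70, 0.61, 0.58, 0.64, 0.64, 0.60)
  cmp_a <- compare_models(tibble::tibble(model_id = 1:10, auc = col_a))
  expect_equal(cmp_a$auc_difference, 0.15)
  expect_equal(cmp_a$best_model_id, 2)

  col_s <- c(0.73, 0.71, 0.72, 0.80, 0.88, 0.76, 0.70, 0.72, 0.96, 0.82)
  cmp_s <- compare_models(tibble::tibble(model_id = 1:10, auc = col_s))
  expect_equal(cmp_s$auc_difference, 0.23)
  expect_equal(cmp_s$best_model_id, 9)

  flat <- compare_models(tibble::tibble(model_id = 1:10, auc = rep(0.7, 10)))
  expect_equal(flat$auc_difference, 0)
  expect_equal(flat$best_model_id, 1)

  # environment ahead: raw difference is negative, clamped on request
  env_best <- tibble::tibble(model_id = 1:10, auc = c(0.9, rep(0.6, 9)))
  expect_lt(compare_models(env_best)$auc_difference, 0)
  expect_equal(compare_models(env_best, clamp_zero = TRUE)$auc_difference, 0)

  expect_error(compare_models(tibble::tibble(model_id = 1:9, auc = 0.5)),
               "all ten")
})

test_that("LOO-CV detects a strong log-type effect and not pure noise", {
  set.seed(47)
  aucs <- replicate(20, {
    lt <- sample(rep(c(1, 0), 20))
    X <- cbind(intercept = 1, felled = lt, z = rnorm(40))
    y <- rbinom(40, 1, pnorm(-1.25 + 2.5 * lt))
    if (length(unique(y)) < 2) return(NA)
    dm <- toy_dm(X, y)
    loo_cv_auc(dm, chains = 1, warmup = 150, samples = 150,
               seed = sample.int(1e6, 1))$auc
  })
  expect_gt(mean(aucs, na.rm = TRUE), 0.7)
})

test_that("LOO-CV plumbing: perfect held-out predictions give AUC 1", {
  y <- rep(c(0, 1), 10)
  expect_equal(auc(y, y), 1)
  res <- structure(list(species = "toy", model_id = 1, auc = auc(y, y),
                        n = 20,
                        predictions = tibble::tibble(log_id = paste0("l", 1:20),
                                                     y = y, pred = y)),
                   class = "loo_auc")
  expect_equal(tidy(res)$auc, 1)
  dm <- toy_dm(cbind(intercept = rep(1, 4)), rep(1, 4))
  expect_error(loo_cv_auc(dm), "both outcome classes")
})

test_that("background occurrence scans agree with a brute-force count", {
  dat <- small_dataset() # background_prob = 0
  bp <- background_prevalence(dat$design, filtered_censuses(dat))
  expect_true(all(bp$fraction == 0))

  dat_bg <- simulate_dataset(small_params(seed = 19, background_prob = 0.5),
                             small_design(seed = 19))
  cens <- filtered_censuses(dat_bg)
  bp2 <- background_prevalence(dat_bg$design, cens)
  expect_gt(max(bp2$fraction), 0)
  # brute-force scan oracle for one species / census
  sp <- design_species(dat_bg$design)[1]
  y1 <- cens$year1
  non_target <- setdiff(dat_bg$design$log_id,
                        target_logs(dat_bg$design, sp)$log_id)
  samp <- y1$samples[y1$samples$log_id %in% non_target, ]
  hit_logs <- unique(samp$log_id[samp$sample_id %in%
    y1$counts$sample_id[y1$counts$otu_id == target_otu_id(sp)]])
  row <- bp2[bp2$species == sp & bp2$census == "year1", ]
  expect_equal(row$n_occupied, length(hit_logs))
  expect_equal(row$fraction, length(hit_logs) / length(unique(samp$log_id)))
})

test_that("prevalence reports match hand counts on a toy fixture", {
  dat <- small_dataset()
  cens <- filtered_censuses(dat)
  rep1 <- prevalence_report(dat$design, cens$year1, cens$year2)
  expect_true(all(rep1$prevalence >= 0 & rep1$prevalence <= 1))
  # hand count for one species and year
  sp <- design_species(dat$design)[2]
  tl <- target_logs(dat$design, sp)$log_id
  y2 <- cens$year2
  samp <- y2$samples[y2$samples$log_id %in% tl, ]
  hits <- y2$counts[y2$counts$otu_id == target_otu_id(sp) &
                      y2$counts$sample_id %in% samp$sample_id, ]
  row <- rep1[rep1$species == sp & rep1$year == "year2", ]
  expect_equal(row$n_detected, nrow(hits))
  expect_equal(row$prevalence, nrow(hits) / nrow(samp))

  # degenerate detection regimes
  dat0 <- simulate_dataset(small_params(seed = 3, detection_prob_per_year = 0),
                           small_design(seed = 3))
  cens0 <- filtered_censuses(dat0)
  rep0 <- prevalence_report(dat0$design, cens0$year1, cens0$year2)
  expect_true(all(rep0$prevalence == 0))

  datA <- simulate_dataset(small_params(seed = 3,
                                        true_beta = c(intercept = 20)),
                           small_design(seed = 3))
  censA <- filtered_censuses(datA)
  repA <- prevalence_report(datA$design, censA$year1, censA$year2)
  expect_true(all(repA$prevalence == 1))
})
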