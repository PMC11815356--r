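# Shared fixtures, built in code and memoised per test run.

the_fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, the_fixture_cache)) {
    assign(key, force(expr), the_fixture_cache)
  }
  get(key, the_fixture_cache)
}

# A small two-site, three-species experiment: 50 logs, fast to simulate.
small_design <- function(seed = 7) {
  build_design(n_sites = 2, species_ids = c("spA", "spB", "spC"),
               targets_natural_per_site = 4, targets_felled_per_site = 3,
               controls_natural = 2, controls_felled = 2, seed = seed)
}

small_params <- function(seed = 7, ...) {
  defaults <- list(
    pool_size = 150,
    richness_mean_by_type = c(broken = 25, uprooted = 22, felled = 15),
    depth_mean = 20000,
    true_beta = c(intercept = 0, felled_vs_broken = 1),
    sigma_site = 0.2,
    seed = seed)
  do.call(generator_params, utils::modifyList(defaults, list(...)))
}

small_dataset <- function() {
  memo("small_dataset", simulate_dataset(small_params(), small_design()))
}

# the full-size layout simulated once (used by design/sample-count checks)
paper_scale_dataset <- function() {
  memo("paper_scale_dataset", {
    p <- generator_params(seed = 11, low_exact_k = 11)
    simulate_dataset(p)
  })
}

filtered_censuses <- function(data) {
  lapply(data$censuses, filter_samples)
}

# a bare design-matrix list for direct sampler tests
toy_dm <- function(X, y, site = rep("s1", length(y)),
                   select = rep(FALSE, ncol(X)),
                   groups = c("intercept", rep("environment", ncol(X) - 1))) {
  if (is.null(colnames(X))) {
    colnames(X) <- c("intercept", paste0("x", seq_len(ncol(X) - 1)))
  }
  list(X = X, y = y, site = site, select = select, groups = groups,
       log_id = paste0("log", seq_along(y)), model_id = 1L, species = "toy",
       scaling = NULL)
}
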