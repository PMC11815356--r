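test_that("simulated read tables satisfy the community invariants", {
  dat <- small_dataset()
  for (cn in names(dat$censuses)) {
    tbl <- dat$censuses[[cn]]
    sums <- tapply(tbl$counts$reads, tbl$counts$sample_id, sum)
    m <- match(names(sums), tbl$samples$sample_id)
    expect_equal(as.vector(sums), tbl$samples$nonspike_total[m])
    expect_true(all(tbl$samples$nonspike_total <= tbl$samples$filtered_total))
    expect_true(all(tbl$counts$reads >= 1))
  }
  expect_equal(sum(vapply(dat$censuses, n_samples, 0L)), 3 * nrow(dat$design))
})

test_that("realized mean richness tracks the design-weighted expectation", {
  # Monte-Carlo average over replicate pre-censuses of the full design
  means <- vapply(1:10, function(s) {
    d <- build_design(seed = s)
    res <- simulate_resident(d, generator_params(seed = s))
    mean(tabulate(factor(res$community$counts$sample_id,
                         levels = res$community$samples$sample_id)))
  }, 0)
  expected <- expected_mean_richness(c(broken = 59.4, uprooted = 56.6,
                                       felled = 44.8))
  expect_lt(abs(mean(means) - expected) / expected, 0.02)
})

test_that("degenerate generator settings produce the expected edge cases", {
  d <- small_design()
  p0 <- small_params(richness_mean_by_type = c(broken = 0, uprooted = 0,
                                               felled = 0))
  res <- simulate_resident(d, p0)
  expect_equal(nrow(res$community$counts), 0)
  expect_true(all(res$community$samples$nonspike_total == 0))

  p1 <- small_params(pool_size = 1,
                     richness_mean_by_type = c(broken = 1, uprooted = 1,
                                               felled = 1) * 0.9)
  res1 <- simulate_resident(d, p1)
  expect_true(all(res1$community$counts$otu_id == "OTU0001"))
  occupied <- subset_samples(
    res1$community,
    res1$community$samples$sample_id[res1$community$samples$nonspike_total > 0])
  r <- rra(occupied)[, "OTU0001"]
  expect_true(all(r == 1))
})

test_that("taxonomy mixes phyla at the configured fractions", {
  res <- simulate_resident(build_design(seed = 2), generator_params(seed = 2))
  tax <- dplyr::filter(res$taxonomy, !startsWith(otu_id, "OTU_target"))
  assigned <- tax$phylum[!is.na(tax$phylum)]
  expect_lt(abs(mean(assigned == "Ascomycota") - 0.570), 0.04)
  expect_lt(abs(mean(assigned == "Basidiomycota") - 0.379), 0.04)
})

test_that("colonization frequencies follow the probit process", {
  # null process: Phi(0) = 0.5
  d <- build_design(seed = 4)
  p <- generator_params(true_beta = c(intercept = 0), sigma_site = 0,
                        seed = 4)
  det <- simulate_colonization(d, NULL, p)
  expect_equal(nrow(det), 360)
  expect_lt(abs(mean(det$latent_success) - 0.5), 3 * sqrt(0.25 / 360))

  # an extreme intercept shuts success off entirely
  p_off <- generator_params(true_beta = c(intercept = -20), sigma_site = 0,
                            seed = 4)
  det_off <- simulate_colonization(d, NULL, p_off)
  expect_true(all(det_off$latent_success == 0))
  expect_true(all(det_off$det_year1 == 0))
})

test_that("a felled-log contrast of 1 yields success near pnorm(1)", {
  d <- build_design(n_sites = 1, species_ids = "spX",
                    targets_natural_per_site = 2500,
                    targets_felled_per_site = 2500,
                    controls_natural = 0, controls_felled = 0, seed = 8)
  p <- generator_params(true_beta = c(intercept = 0, felled_vs_broken = 1),
                        sigma_site = 0, seed = 8)
  det <- simulate_colonization(d, NULL, p)
  felled <- det$latent_success[d$log_type[match(det$log_id, d$log_id)] ==
                                 "felled"]
  expect_lt(abs(mean(felled) - pnorm(1)), 3 * sqrt(0.1335 / 2500))
})

test_that("detection thinning and read injection respect the detections", {
  d <- small_design()
  p <- small_params(detection_prob_per_year = 0)
  dat <- simulate_dataset(p, d)
  expect_true(all(dat$detections$det_year1 == 0))
  targets <- target_otu_id(design_species(d))
  for (yr in c("year1", "year2")) {
    expect_false(any(dat$censuses[[yr]]$counts$otu_id %in% targets))
  }

  dat2 <- small_dataset()
  hits <- dplyr::filter(dat2$detections, det_year1 == 1)
  y1 <- dat2$censuses$year1
  for (i in seq_len(nrow(hits))) {
    sid <- paste0(hits$log_id[i], "_year1")
    reads <- dplyr::filter(y1$counts, sample_id == sid,
                           otu_id == target_otu_id(hits$target_species[i]))
    expect_gte(sum(reads$reads), small_params()$min_target_reads)
  }
})

test_that("low-depth handling supports both rates and exact counts", {
  d <- small_design()
  p_none <- small_params(depth_low_frac = 0)
  dat <- simulate_dataset(p_none, d)
  all_samp <- dplyr::bind_rows(lapply(dat$censuses, `[[`, "samples"))
  expect_true(all(all_samp$filtered_total >= 10000))
  expect_equal(n_samples(filter_samples(dat$censuses$pre)),
               n_samples(dat$censuses$pre))

  dat11 <- paper_scale_dataset() # exact-count mode: 11 low of 1380
  all11 <- dplyr::bind_rows(lapply(dat11$censuses, `[[`, "samples"))
  expect_equal(nrow(all11), 1380)
  expect_equal(sum(all11$filtered_total < 10000), 11)
  kept <- sum(vapply(lapply(dat11$censuses, filter_samples), n_samples, 0L))
  expect_equal(kept, 1369)
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_dataset(small_params(seed = 31), small_design(seed = 31))
  b <- simulate_dataset(small_params(seed = 31), small_design(seed = 31))
  expect_identical(a$censuses$pre$counts, b$censuses$pre$counts)
  expect_identical(a$detections, b$detections)
  c2 <- simulate_dataset(small_params(seed = 32), small_design(seed = 31))
  expect_false(identical(a$censuses$pre$counts, c2$censuses$pre$counts))
})

test_that("unknown coefficient names in the true model are rejected", {
  d <- small_design()
  p <- small_params(true_beta = c(intercept = 0, not_a_predictor = 1))
  expect_error(simulate_colonization(d, NULL, p), "not buildable")
})
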