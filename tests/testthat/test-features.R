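make_tbl <- function(totals, census = "pre", reads = NULL) {
  n <- length(totals)
  ids <- paste0("s", seq_len(n))
  counts <- reads %||% tibble::tibble(
    sample_id = ids, otu_id = "OTU0001",
    reads = as.integer(pmax(1, totals %/% 2)))
  community_tbl(counts,
                tibble::tibble(sample_id = ids,
                               log_id = paste0("log", seq_len(n)),
                               census = census,
                               filtered_total = as.integer(totals),
                               nonspike_total =
                                 as.integer(tapply(counts$reads,
                                   factor(counts$sample_id, levels = ids),
                                   sum))))
}

test_that("the depth filter removes strictly sub-threshold samples", {
  tbl <- make_tbl(c(9999, 10000, 10001))
  out <- filter_samples(tbl)
  expect_equal(n_samples(out), 2)
  expect_equal(removed_samples(out), "s1")

  all_ok <- filter_samples(make_tbl(c(20000, 30000)))
  expect_equal(n_samples(all_ok), 2)
  expect_length(removed_samples(all_ok), 0)
})

test_that("relative read abundances sum to one and exclude spike reads", {
  counts <- tibble::tibble(sample_id = c("s1", "s1"),
                           otu_id = c("A", "B"), reads = c(30L, 10L))
  tbl <- community_tbl(counts,
                       tibble::tibble(sample_id = "s1", log_id = "log1",
                                      census = "pre",
                                      filtered_total = 100L,
                                      nonspike_total = 40L))
  r <- rra(tbl)
  expect_equal(unname(r[1, c("A", "B")]), c(0.75, 0.25))
  expect_equal(sum(r), 1, tolerance = 1e-12)

  dat <- small_dataset()
  R <- rra(dat$censuses$pre)
  nz <- rowSums(R) > 0
  expect_true(all(abs(rowSums(R)[nz] - 1) < 1e-12))

  zero <- community_tbl(tibble::tibble(sample_id = character(0),
                                       otu_id = character(0),
                                       reads = integer(0)),
                        tibble::tibble(sample_id = "s1", log_id = "l",
                                       census = "pre", filtered_total = 100L,
                                       nonspike_total = 0L))
  expect_error(rra(zero), "s1")
})

test_that("the fourth-root transform is a monotone map fixing 0 and 1", {
  expect_equal(transform_rra(c(0, 1)), c(0, 1))
  expect_equal(transform_rra(0.0016), 0.2)
  x <- sort(runif(50)); y <- transform_rra(x)
  expect_true(all(diff(y) >= 0))
  expect_equal(order(x), order(y))
  expect_error(transform_rra(-0.1), "non-negative")
})

test_that("DNA amount is the non-spike to spike read ratio", {
  expect_equal(dna_amount(2000, 1000)$ratio, 1)
  expect_equal(dna_amount(2000, 1000)$log_ratio, 0)
  expect_equal(dna_amount(3000, 2400)$ratio, 4)
  expect_error(dna_amount(1000, 1000), "zero spike")
  expect_equal(dna_amount(1000, 1000, pseudocount = 0.5)$ratio,
               1000.5 / 0.5)
  expect_equal(dna_amount(1000, 0)$ratio, 0)
  expect_error(dna_amount(100, 200), "filtered_total >= nonspike_total")
})

test_that("the depth predictor averages before taking the log", {
  expect_equal(seq_depth_predictor(10000, 10000), log(10000))
  expect_equal(seq_depth_predictor(0, 20000), log(10000))
  expect_equal(seq_depth_predictor(NA, 5000), log(5000))
  expect_error(seq_depth_predictor(NA, NA), "at least one")
  # log-first alternative
  expect_equal(seq_depth_predictor(100, 10000, log_first = TRUE),
               mean(log(c(100, 10000))))
})

test_that("richness decomposes into per-phylum counts plus unassigned", {
  P <- matrix(c(1, 1, 1, 1, 1, 1,
                0, 0, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("o", 1:6)))
  tax <- tibble::tibble(otu_id = paste0("o", 1:5),
                        phylum = c("Ascomycota", "Ascomycota", "Ascomycota",
                                   "Basidiomycota", "Basidiomycota"))
  r <- richness(P, tax)
  expect_equal(r$richness_total, c(6, 0))
  expect_equal(r$richness_ascomycota, c(3, 0))
  expect_equal(r$richness_basidiomycota, c(2, 0))
  expect_true(all(r$richness_total >=
                    r$richness_ascomycota + r$richness_basidiomycota))
})

test_that("common-species ranking matches an exhaustive sort oracle", {
  occ <- matrix(c(1, 1, 1, 1, 1,
                  1, 1, 1, 0, 0,
                  1, 0, 0, 0, 0), nrow = 5,
                dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(top_common_species(occ, k = 2), c("A", "B"))

  tie <- matrix(c(1, 1, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1), nrow = 4,
                dimnames = list(NULL, c("A", "B", "C")))
  cnt <- tie * rep(c(100, 50, 50), each = 4)
  expect_equal(top_common_species(tie, k = 1, counts = cnt), "A")
  # equal reads too: lexicographic id breaks the B/C tie
  expect_equal(top_common_species(tie, k = 3, counts = tie * 50),
               c("A", "B", "C"))

  set.seed(99)
  M <- matrix(rbinom(20 * 30, 1, 0.3), 20, 30,
              dimnames = list(NULL, sprintf("x%02d", 1:30)))
  cnts <- M * matrix(rpois(600, 40), 20, 30)
  # brute-force oracle: full sort by occupancy, then reads, then id
  ord <- order(-colSums(M), -colSums(cnts), colnames(M))
  expect_equal(top_common_species(M, k = 10, counts = cnts),
               colnames(M)[ord][1:10])

  few <- matrix(c(1, 0, 0, 0), 2, dimnames = list(NULL, c("A", "B")))
  expect_warning(res <- top_common_species(few, k = 5), "only")
  expect_equal(res, "A")
})

test_that("model catalogue encodes the ten configurations consistently", {
  cat10 <- model_catalog()
  expect_equal(nrow(cat10), 10)
  expect_equal(cat10$biotic_block[1], "none")
  expect_true(all(cat10$biotic_block[-c(1, 7)] != "none"))
  expect_equal(which(cat10$variable_selection), c(6, 10))
  expect_true(all(cat10$biotic_block[cat10$variable_selection] ==
                    "top10_selected"))
  expect_error(model_spec(11), "1..10")
})

test_that("response construction ORs the two post-inoculation years", {
  dat <- small_dataset()
  cens <- filtered_censuses(dat)
  for (sp in design_species(dat$design)) {
    resp <- build_response(sp, dat$design, cens$year1, cens$year2)
    truth <- dat$detections[dat$detections$target_species == sp, ]
    m <- match(resp$log_id, truth$log_id)
    expect_equal(resp$y,
                 as.integer(truth$det_year1[m] | truth$det_year2[m]))
    # symmetric in census order: relabel the two post censuses and swap
    relabel <- function(tbl, to) {
      tbl$samples$census <- to
      tbl
    }
    resp_swap <- build_response(sp, dat$design,
                                relabel(cens$year2, "year1"),
                                relabel(cens$year1, "year2"),
                                min_detect_reads = 1)
    expect_equal(resp$y[order(resp$log_id)],
                 resp_swap$y[order(resp_swap$log_id)])
  }
  expect_error(build_response("nope", dat$design, cens$year1, cens$year2),
               "unknown species")
})

test_that("logs lose sampling-unit status only when both years are filtered", {
  dat <- small_dataset()
  y1 <- dat$censuses$year1
  y2 <- dat$censuses$year2
  sp <- design_species(dat$design)[1]
  victim <- target_logs(dat$design, sp)$log_id[1]
  # force both yearly samples of one log below the depth threshold
  for (nm in c("y1", "y2")) {
    tbl <- get(nm)
    i <- tbl$samples$log_id == victim
    tbl$samples$filtered_total[i] <- 5000L
    assign(nm, tbl)
  }
  resp <- build_response(sp, dat$design, filter_samples(y1),
                         filter_samples(y2))
  expect_false(victim %in% resp$log_id)
  expect_equal(nrow(resp), nrow(target_logs(dat$design, sp)) - 1)
})

test_that("design matrices carry the model-specific predictor blocks", {
  dat <- small_dataset()
  cens <- filtered_censuses(dat)
  sp <- design_species(dat$design)[1]
  base_cols <- c("intercept", "felled_vs_broken", "uprooted_vs_broken",
                 "decay_stage", "seq_depth")

  dm1 <- build_design_matrix(1, sp, dat$design, cens$pre, cens$year1,
                             cens$year2, taxonomy = dat$taxonomy)
  expect_equal(colnames(dm1$X), base_cols)
  expect_equal(dm1$groups,
               c("intercept", rep("environment", 3), "seq_depth"))

  dm3 <- build_design_matrix(3, sp, dat$design, cens$pre, cens$year1,
                             cens$year2, taxonomy = dat$taxonomy)
  expect_equal(colnames(dm3$X),
               c(base_cols, "richness_ascomycota", "richness_basidiomycota"))

  dm9 <- build_design_matrix(9, sp, dat$design, cens$pre, cens$year1,
                             cens$year2, taxonomy = dat$taxonomy)
  expect_equal(ncol(dm9$X), 15)
  expect_true(all(startsWith(colnames(dm9$X)[6:15], "rra_")))

  # the environment-only columns are a prefix of every richer model
  for (mid in c(2, 3, 5, 6, 7, 9, 10)) {
    dm <- build_design_matrix(mid, sp, dat$design, cens$pre, cens$year1,
                              cens$year2, taxonomy = dat$taxonomy)
    expect_equal(colnames(dm$X)[1:5], base_cols)
    expect_equal(nrow(dm$X), nrow(dm1$X))
    expect_true(all(dm$X[, "felled_vs_broken"] %in% 0:1))
    if (mid %in% c(6, 10)) {
      expect_true(all(dm$select == (dm$groups == "biotic")))
      expect_gt(sum(dm$select), 0)
    } else {
      expect_false(any(dm$select))
    }
  }

  # continuous predictors are standardized over the rows
  expect_equal(mean(dm1$X[, "seq_depth"]), 0, tolerance = 1e-12)
  expect_equal(sd(dm1$X[, "seq_depth"]), 1, tolerance = 1e-12)

  expect_error(build_design_matrix(4, sp, dat$design, cens$pre, cens$year1,
                                   cens$year2, taxonomy = dat$taxonomy),
               "ordination scores required")
})
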