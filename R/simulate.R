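#' Parameters of the synthetic-data generator
#'
#' Collects every knob of the data-generating process: the regional OTU pool
#' and its lognormal abundance distribution, per-log-type expected resident
#' richness, sequencing-depth and spike-in settings, and the probit process
#' that produces colonization outcomes. Defaults emulate a five-site,
#' 460-log inoculation experiment: a pool of 2346 OTUs of which 57.0% /
#' 37.9% of the taxonomically assigned ones are Ascomycota / Basidiomycota,
#' mean resident richness 59.4 (broken), 56.6 (uprooted) and 44.8 (felled)
#' OTUs per log, and a small fraction (11/1380) of samples sequenced below
#' the 10,000-read depth threshold.
#'
#' @param pool_size Number of OTUs in the regional pool.
#' @param phylum_fracs Named fractions (`ascomycota`, `basidiomycota`,
#'   `other`) of the taxonomically assigned pool, summing to 1.
#' @param frac_assigned Fraction of pool OTUs with a phylum assignment.
#' @param richness_mean_by_type Named means (`broken`, `uprooted`, `felled`)
#'   of per-log resident OTU richness.
#' @param richness_dispersion Negative-binomial size parameter of the
#'   per-log richness draw (smaller = more overdispersed).
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of the
#'   pool's relative abundances.
#' @param depth_mean Median filtered read depth of a normal-depth sample.
#' @param depth_sdlog Lognormal spread of the filtered depth.
#' @param depth_low_frac Probability that a sample is a low-depth failure
#'   (filtered total drawn below 10,000 reads).
#' @param low_exact_k If set, [simulate_dataset()] places exactly this many
#'   low-depth samples among the full set instead of Bernoulli draws.
#' @param spike_frac Expected fraction of filtered reads that are spike-in.
#' @param true_model A `model_spec`: which predictor configuration drives the
#'   true colonization probabilities.
#' @param true_beta Named coefficient vector of the true probit linear
#'   predictor; names must be predictor columns buildable from the design and
#'   the resident census under `true_model` (e.g. `intercept`,
#'   `felled_vs_broken`, `uprooted_vs_broken`, `decay_stage`, biotic columns).
#' @param sigma_site SD of the site random intercept.
#' @param detection_prob_per_year Probability that a truly colonized log is
#'   detected in a given post-inoculation year; 1 collapses the observation
#'   layer so detections equal true colonization.
#' @param target_read_frac Expected fraction of a detected sample's non-spike
#'   reads belonging to the target OTU.
#' @param min_target_reads Minimum target-OTU reads injected for a detection.
#' @param background_prob Probability that a target species' OTU also occurs
#'   in a log where it was not inoculated (0 = targets only ever appear where
#'   inoculated).
#' @param seed Integer seed; every simulation function derives its random
#'   stream from it.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(pool_size = 2346,
                             phylum_fracs = c(ascomycota = 0.570,
                                              basidiomycota = 0.379,
                                              other = 0.051),
                             frac_assigned = 0.9,
                             richness_mean_by_type = c(broken = 59.4,
                                                       uprooted = 56.6,
                                                       felled = 44.8),
                             richness_dispersion = 3,
                             abundance_meanlog = 0,
                             abundance_sdlog = 1.5,
                             depth_mean = 50000,
                             depth_sdlog = 0.4,
                             depth_low_frac = 11 / 1380,
                             low_exact_k = NULL,
                             spike_frac = 0.03,
                             true_model = model_spec(1),
                             true_beta = c(intercept = -0.3,
                                           felled_vs_broken = 0.8),
                             sigma_site = 0.3,
                             detection_prob_per_year = 1,
                             target_read_frac = 0.05,
                             min_target_reads = 4,
                             background_prob = 0,
                             seed = 1L) {
  stopifnot(pool_size >= 1,
            abs(sum(phylum_fracs) - 1) < 1e-8,
            all(phylum_fracs >= 0), frac_assigned >= 0, frac_assigned <= 1,
            all(richness_mean_by_type >= 0),
            all(richness_mean_by_type < pool_size | richness_mean_by_type == 0),
            richness_dispersion > 0, abundance_sdlog > 0,
            depth_low_frac >= 0, depth_low_frac <= 1,
            spike_frac >= 0, spike_frac < 1,
            sigma_site >= 0,
            detection_prob_per_year >= 0, detection_prob_per_year <= 1)
  if (is.numeric(true_model)) true_model <- model_spec(true_model)
  structure(as.list(environment()), class = "generator_params")
}

# Regional OTU pool: ids, lognormal relative abundances, taxonomy.
# Deterministic given params$seed (its own RNG substream).
make_pool <- function(params) {
  stream <- local_rng(params$seed, 101L)
  on.exit(stream())
  n <- params$pool_size
  ids <- sprintf("OTU%04d", seq_len(n))
  abund <- stats::rlnorm(n, params$abundance_meanlog, params$abundance_sdlog)
  assigned <- stats::runif(n) < params$frac_assigned
  phy <- rep(NA_character_, n)
  phy[assigned] <- sample(c("Ascomycota", "Basidiomycota", "other"),
                          sum(assigned), replace = TRUE,
                          prob = params$phylum_fracs)
  list(ids = ids, abund = abund / sum(abund),
       taxonomy = tibble::tibble(otu_id = ids, phylum = phy))
}

# run code under a derived seed, then restore the caller's RNG state
local_rng <- function(seed, offset) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed((seed + offset) %% .Machine$integer.max)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }
}

draw_depths <- function(n, params, force_low = NULL) {
  low <- force_low %||% (stats::runif(n) < params$depth_low_frac)
  filtered <- integer(n)
  filtered[low] <- sample(1000:9999, sum(low), replace = TRUE)
  filtered[!low] <- pmax(
    10000L,
    as.integer(round(stats::rlnorm(sum(!low), log(params$depth_mean),
                                   params$depth_sdlog))))
  spike <- stats::rbinom(n, filtered, params$spike_frac)
  list(filtered = filtered, nonspike = filtered - spike)
}

# allocate `total` reads over `otus` (each gets >= 1) with prob ~ weights
allocate_reads <- function(otus, weights, total) {
  r <- length(otus)
  if (r == 0 || total == 0) {
    return(tibble::tibble(otu_id = character(0), reads = integer(0)))
  }
  if (total < r) {
    otus <- otus[seq_len(total)]
    return(tibble::tibble(otu_id = otus, reads = rep(1L, total)))
  }
  extra <- stats::rmultinom(1, total - r, prob = weights)[, 1]
  tibble::tibble(otu_id = otus, reads = as.integer(1L + extra))
}

simulate_census <- function(design, params, census, pool,
                            force_low = NULL, extra_otus = NULL) {
  n <- nrow(design)
  dep <- draw_depths(n, params, force_low)
  mu <- params$richness_mean_by_type[design$log_type]
  rich <- stats::rnbinom(n, size = params$richness_dispersion, mu = mu)
  rich[mu == 0] <- 0L
  over <- rich > params$pool_size
  if (any(over)) {
    warning(sprintf("%d richness draws truncated at the pool size", sum(over)))
    rich[over] <- params$pool_size
  }
  sample_ids <- paste0(design$log_id, "_", census)
  counts <- vector("list", n)
  nonspike <- integer(n)
  for (i in seq_len(n)) {
    present <- if (rich[i] > 0) {
      sample(params$pool_size, rich[i], prob = pool$abund)
    } else integer(0)
    otus <- pool$ids[present]
    w <- pool$abund[present]
    inj <- extra_otus[[design$log_id[i]]]
    if (!is.null(inj) && nrow(inj)) {
      # injected target reads claim part of the sample's non-spike total
      take <- min(sum(inj$reads), dep$nonspike[i])
      bg_total <- dep$nonspike[i] - take
      bg <- allocate_reads(otus, w, bg_total)
      tab <- dplyr::bind_rows(bg, inj[seq_len(nrow(inj)), , drop = FALSE])
      tab <- dplyr::summarise(dplyr::group_by(tab, .data$otu_id),
                              reads = sum(.data$reads), .groups = "drop")
      # cap at the available non-spike budget
      if (sum(tab$reads) > dep$nonspike[i]) {
        tab$reads[which.max(tab$reads)] <-
          tab$reads[which.max(tab$reads)] - (sum(tab$reads) - dep$nonspike[i])
        tab <- tab[tab$reads > 0, ]
      }
    } else {
      tab <- allocate_reads(otus, w, dep$nonspike[i])
    }
    nonspike[i] <- sum(tab$reads)
    if (nrow(tab)) tab$sample_id <- sample_ids[i]
    counts[[i]] <- tab
  }
  samples <- tibble::tibble(
    sample_id = sample_ids, log_id = design$log_id, census = census,
    filtered_total = dep$filtered, nonspike_total = nonspike)
  all_counts <- dplyr::bind_rows(counts)
  if (nrow(all_counts) == 0) {
    all_counts <- tibble::tibble(sample_id = character(0),
                                 otu_id = character(0), reads = integer(0))
  }
  community_tbl(all_counts, samples)
}

#' Simulate the pre-inoculation resident communities
#'
#' Draws, for every log, a negative-binomial OTU richness with the log-type
#' specific mean, samples that many OTUs from the regional pool with
#' probability proportional to their lognormal abundances, and allocates the
#' sample's non-spike reads multinomially over the present OTUs (each present
#' OTU receives at least one read, so realized richness equals the draw).
#'
#' @param design A `study_design`.
#' @param params A `generator_params`.
#' @param force_low Optional logical vector (one per log) forcing which
#'   samples are low-depth failures.
#' @return A list with elements `community` (a `community_tbl`, census
#'   `"pre"`) and `taxonomy` (tibble `otu_id`, `phylum`, covering the pool
#'   and the target-species OTUs).
#' @export
simulate_resident <- function(design, params, force_low = NULL) {
  pool <- make_pool(params)
  restore <- local_rng(params$seed, 202L)
  on.exit(restore())
  comm <- simulate_census(design, params, "pre", pool, force_low)
  tax <- dplyr::bind_rows(
    pool$taxonomy,
    tibble::tibble(otu_id = target_otu_id(attr(design, "species")),
                   phylum = "Basidiomycota"))
  list(community = comm, taxonomy = tax)
}

#' Simulate colonization outcomes from the true probit process
#'
#' For each target species, builds the true linear predictor from the design
#' and the resident census under `params$true_model`, adds a site random
#' intercept drawn with SD `params$sigma_site`, and draws latent colonization
#' success as Bernoulli(pnorm(eta)). Observed yearly detections are the
#' latent success thinned independently by `detection_prob_per_year`.
#'
#' @param design A `study_design`.
#' @param resident Output of [simulate_resident()] (or `NULL` for
#'   environment-only true models).
#' @param params A `generator_params`.
#' @return Tibble with one row per target log: `log_id`, `site_id`,
#'   `target_species`, `eta`, `latent_success`, `det_year1`, `det_year2`.
#' @export
simulate_colonization <- function(design, resident, params) {
  restore <- local_rng(params$seed, 303L)
  on.exit(restore())
  species <- attr(design, "species")
  sites <- attr(design, "sites")
  out <- vector("list", length(species))
  for (k in seq_along(species)) {
    sp <- species[k]
    logs <- target_logs(design, sp)
    X <- dgp_design_matrix(params$true_model, sp, logs, resident)
    unknown <- setdiff(names(params$true_beta), colnames(X))
    if (length(unknown)) {
      stop("true_beta names not buildable under the true model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    beta <- params$true_beta
    eta <- as.vector(X[, names(beta), drop = FALSE] %*% beta)
    a <- stats::rnorm(length(sites), 0, params$sigma_site)
    names(a) <- sites
    eta <- eta + a[logs$site_id]
    latent <- stats::rbinom(nrow(logs), 1, stats::pnorm(eta))
    d1 <- latent * stats::rbinom(nrow(logs), 1, params$detection_prob_per_year)
    d2 <- latent * stats::rbinom(nrow(logs), 1, params$detection_prob_per_year)
    out[[k]] <- tibble::tibble(
      log_id = logs$log_id, site_id = logs$site_id, target_species = sp,
      eta = eta, latent_success = latent, det_year1 = d1, det_year2 = d2)
  }
  dplyr::bind_rows(out)
}

# predictor columns of the data-generating process (no sequencing depth:
# depth is a post-census nuisance quantity, its true effect is zero)
dgp_design_matrix <- function(model, species, logs, resident) {
  X <- cbind(intercept = 1,
             felled_vs_broken = as.numeric(logs$log_type == "felled"),
             uprooted_vs_broken = as.numeric(logs$log_type == "uprooted"),
             decay_stage = std0(logs$decay_stage))
  if (is.numeric(model)) model <- model_spec(model)
  if (model$biotic_block %in% c("none", "ordination")) return(X)
  pre <- resident$community
  samp <- pre$samples$sample_id[match(logs$log_id, pre$samples$log_id)]
  P <- presence_matrix(pre)[samp, , drop = FALSE]
  if (model$biotic_block == "total_richness") {
    return(cbind(X, richness_total = std0(rowSums(P))))
  }
  if (model$biotic_block == "per_phylum_richness") {
    r <- richness(P, resident$taxonomy)
    return(cbind(X, richness_ascomycota = std0(r$richness_ascomycota),
                 richness_basidiomycota = std0(r$richness_basidiomycota)))
  }
  if (model$biotic_block == "dna_amount") {
    s <- pre$samples[match(samp, pre$samples$sample_id), ]
    da <- dna_amount(s$filtered_total, s$nonspike_total, pseudocount = 0.5)
    return(cbind(X, dna_amount = std0(da$log_ratio)))
  }
  # top10 blocks
  cnts <- count_matrix(pre)[samp, , drop = FALSE]
  top <- top_common_species(P, k = 10, counts = cnts)
  if (model$data_type == "presence") {
    B <- P[, top, drop = FALSE]; colnames(B) <- paste0("occ_", top)
  } else {
    B <- apply(transform_rra(rra(pre)[samp, top, drop = FALSE]), 2, std0)
    colnames(B) <- paste0("rra_", top)
  }
  cbind(X, B)
}

std0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Simulate the post-inoculation censuses
#'
#' Generates background communities (same machinery as the resident census)
#' for every log in year 1 and year 2, and injects the target species' OTU
#' reads into the samples of (log, year) pairs with a detection: a detected
#' sample carries at least `params$min_target_reads` reads of its target OTU,
#' with the expected share of non-spike reads set by
#' `params$target_read_frac`. With `params$background_prob > 0`, target OTUs
#' can additionally appear in logs where they were not inoculated.
#'
#' @param design A `study_design`.
#' @param detections Tibble from [simulate_colonization()].
#' @param params A `generator_params`.
#' @param force_low Optional list with logical vectors `year1`, `year2`
#'   forcing low-depth samples.
#' @return List of two `community_tbl` objects, `year1` and `year2`.
#' @export
simulate_post_census_reads <- function(design, detections, params,
                                       force_low = NULL) {
  restore <- local_rng(params$seed, 404L)
  on.exit(restore())
  pool <- make_pool(params)
  out <- list()
  for (yr in c("year1", "year2")) {
    det_col <- paste0("det_", yr)
    inject <- list()
    hit <- detections[detections[[det_col]] == 1, ]
    for (i in seq_len(nrow(hit))) {
      otu <- target_otu_id(hit$target_species[i])
      reads <- params$min_target_reads +
        stats::rnbinom(1, size = 2,
                       mu = params$target_read_frac * params$depth_mean)
      inject[[hit$log_id[i]]] <- tibble::tibble(otu_id = otu,
                                                reads = as.integer(reads))
    }
    if (params$background_prob > 0) {
      species <- attr(design, "species")
      for (sp in species) {
        non_target <- setdiff(design$log_id,
                              target_logs(design, sp)$log_id)
        bg <- non_target[stats::runif(length(non_target)) <
                           params$background_prob]
        for (lg in bg) {
          row <- tibble::tibble(otu_id = target_otu_id(sp),
                                reads = params$min_target_reads)
          inject[[lg]] <- dplyr::bind_rows(inject[[lg]], row)
        }
      }
    }
    out[[yr]] <- simulate_census(design, params, yr, pool,
                                 force_low = force_low[[yr]],
                                 extra_otus = inject)
  }
  out
}

#' Simulate a complete experiment
#'
#' Runs [build_design()] (unless a design is supplied), then
#' [simulate_resident()], [simulate_colonization()] and
#' [simulate_post_census_reads()], honouring `params$low_exact_k` by placing
#' exactly that many low-depth samples across all three censuses.
#'
#' @param params A `generator_params`.
#' @param design Optional pre-built `study_design`; by default the full
#'   five-site, 460-log layout with `params$seed`.
#' @return A list of class `inoculation_data` with elements `design`,
#'   `taxonomy`, `censuses` (list `pre`, `year1`, `year2` of
#'   `community_tbl`), `detections`, and `truth` (the generator's
#'   `true_beta`, `sigma_site`, `true_model` id and latent successes).
#' @export
simulate_dataset <- function(params = generator_params(), design = NULL) {
  if (is.null(design)) design <- build_design(seed = params$seed)
  n <- nrow(design)
  force <- list(pre = NULL, year1 = NULL, year2 = NULL)
  if (!is.null(params$low_exact_k)) {
    restore <- local_rng(params$seed, 505L)
    k <- params$low_exact_k
    stopifnot(k <= 3 * n)
    slots <- sample(3 * n, k)
    flag <- rep(FALSE, 3 * n)
    flag[slots] <- TRUE
    force <- list(pre = flag[1:n], year1 = flag[n + 1:n],
                  year2 = flag[2 * n + 1:n])
    restore()
  }
  resident <- simulate_resident(design, params, force_low = force$pre)
  detections <- simulate_colonization(design, resident, params)
  post <- simulate_post_census_reads(design, detections, params,
                                     force_low = force[c("year1", "year2")])
  structure(list(
    design = design, taxonomy = resident$taxonomy,
    censuses = list(pre = resident$community,
                    year1 = post$year1, year2 = post$year2),
    detections = detections,
    truth = list(true_beta = params$true_beta, sigma_site = params$sigma_site,
                 true_model = params$true_model$model_id,
                 latent_success = detections[, c("log_id", "target_species",
                                                 "latent_success")])),
    class = "inoculation_data")
}

#' @export
print.inoculation_data <- function(x, ...) {
  cat(sprintf(
    "<inoculation_data> %d logs, %d samples over 3 censuses, %d target species\n",
    nrow(x$design), sum(vapply(x$censuses, n_samples, 0L)),
    length(attr(x$design, "species"))))
  invisible(x)
}
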