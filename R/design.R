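#' Construct the site/log/species layout of an inoculation experiment
#'
#' Builds the full experimental design: per site, a set of felled (chainsaw-cut)
#' and natural (uprooted or broken) Norway-spruce logs, each either inoculated
#' with one of the target species (`role = "target"`) or mock-inoculated with
#' sterile dowels (`role = "control"`). Felled logs are always in decay stage 1;
#' natural logs are split between decay stages 1 and 2 and between the uprooted
#' and broken types according to the supplied fractions.
#'
#' With the defaults (9 species, 5 sites, 5 natural + 3 felled target logs per
#' species per site, 10 + 10 controls per site) the design has 460 logs:
#' 225 natural and 135 felled targets (40 per species) plus 100 controls,
#' i.e. 55 natural and 37 felled logs per site.
#'
#' @param n_sites Number of study sites.
#' @param species_ids Character vector of target species identifiers.
#' @param targets_natural_per_site Natural target logs per species per site.
#' @param targets_felled_per_site Felled target logs per species per site.
#' @param controls_natural,controls_felled Control logs per site by type.
#' @param frac_decay1_natural Fraction of natural logs in decay stage 1
#'   (the rest are stage 2).
#' @param frac_uprooted Fraction of natural logs that are uprooted
#'   (the rest are broken).
#' @param n_inoculation_points Inoculation points per log (metadata only).
#' @param exact_quota If `TRUE`, the uprooted/broken and decay-stage labels are
#'   assigned by rounded per-site quotas instead of independent Bernoulli draws;
#'   useful for exactly reproducible fixtures.
#' @param seed Integer seed controlling all randomized label assignments.
#'
#' @return A tibble of class `study_design` with one row per log and columns
#'   `log_id`, `site_id`, `log_type` (felled/uprooted/broken), `decay_stage`,
#'   `role` (target/control), `target_species` (`NA` for controls) and
#'   `n_inoculation_points`. The species and site id sets are attached as
#'   attributes `species` and `sites`.
#' @examples
#' d <- build_design(seed = 1)
#' nrow(d)            # 460
#' design_summary(d)
#' @export
build_design <- function(n_sites = 5,
                         species_ids = paste0("sp", 1:9),
                         targets_natural_per_site = 5,
                         targets_felled_per_site = 3,
                         controls_natural = 10,
                         controls_felled = 10,
                         frac_decay1_natural = 0.65,
                         frac_uprooted = 0.5,
                         n_inoculation_points = 10,
                         exact_quota = FALSE,
                         seed = 1L) {
  stopifnot(n_sites >= 1, length(species_ids) >= 1)
  counts <- c(targets_natural_per_site, targets_felled_per_site,
              controls_natural, controls_felled)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("design infeasible: log counts must be non-negative integers",
         call. = FALSE)
  }
  if (frac_decay1_natural < 0 || frac_decay1_natural > 1 ||
      frac_uprooted < 0 || frac_uprooted > 1) {
    stop("design infeasible: fractions must lie in [0, 1]", call. = FALSE)
  }

  n_sp <- length(species_ids)
  n_nat <- n_sp * targets_natural_per_site + controls_natural
  n_fel <- n_sp * targets_felled_per_site + controls_felled
  if (n_nat + n_fel == 0) {
    return(new_study_design(empty_design_tbl(), species_ids, character(0)))
  }

  set.seed(seed)
  sites <- sprintf("site%d", seq_len(n_sites))
  per_site <- purrr::map(sites, function(s) {
    build_site(s, species_ids,
               targets_natural_per_site, targets_felled_per_site,
               controls_natural, controls_felled,
               frac_decay1_natural, frac_uprooted,
               n_inoculation_points, exact_quota)
  })
  logs <- dplyr::bind_rows(per_site)
  logs$log_id <- sprintf("log%03d", seq_len(nrow(logs)))
  logs <- dplyr::relocate(logs, "log_id")
  new_study_design(logs, species_ids, sites)
}

build_site <- function(site_id, species_ids,
                       t_nat, t_fel, c_nat, c_fel,
                       frac_d1, frac_up, n_points, exact_quota) {
  n_sp <- length(species_ids)
  n_nat <- n_sp * t_nat + c_nat
  n_fel <- n_sp * t_fel + c_fel

  # roles: random interleaving of species targets and controls within each type
  role_nat <- sample(c(rep(species_ids, each = t_nat), rep(NA_character_, c_nat)))
  role_fel <- sample(c(rep(species_ids, each = t_fel), rep(NA_character_, c_fel)))

  if (exact_quota) {
    n_up <- round(frac_up * n_nat)
    type_nat <- sample(c(rep("uprooted", n_up), rep("broken", n_nat - n_up)))
    n_d1 <- round(frac_d1 * n_nat)
    decay_nat <- sample(c(rep(1, n_d1), rep(2, n_nat - n_d1)))
  } else {
    type_nat <- ifelse(stats::runif(n_nat) < frac_up, "uprooted", "broken")
    decay_nat <- ifelse(stats::runif(n_nat) < frac_d1, 1, 2)
  }

  tibble::tibble(
    site_id = site_id,
    log_type = c(type_nat, rep("felled", n_fel)),
    decay_stage = as.numeric(c(decay_nat, rep(1, n_fel))),
    role = ifelse(is.na(c(role_nat, role_fel)), "control", "target"),
    target_species = c(role_nat, role_fel),
    n_inoculation_points = n_points
  )
}

empty_design_tbl <- function() {
  tibble::tibble(
    log_id = character(0), site_id = character(0), log_type = character(0),
    decay_stage = numeric(0), role = character(0),
    target_species = character(0), n_inoculation_points = numeric(0)
  )
}

new_study_design <- function(tbl, species, sites) {
  validate_design_tbl(tbl)
  structure(tbl,
            species = species, sites = sites,
            class = c("study_design", class(tibble::tibble())))
}

validate_design_tbl <- function(tbl) {
  stopifnot(all(c("log_id", "site_id", "log_type", "decay_stage", "role",
                  "target_species") %in% names(tbl)))
  if (nrow(tbl) == 0) return(invisible(tbl))
  stopifnot(
    all(tbl$log_type %in% c("felled", "uprooted", "broken")),
    all(tbl$role %in% c("target", "control")),
    all(tbl$decay_stage >= 1 & tbl$decay_stage <= 5),
    all(tbl$decay_stage[tbl$log_type == "felled"] == 1),
    all(is.na(tbl$target_species[tbl$role == "control"])),
    all(!is.na(tbl$target_species[tbl$role == "target"]))
  )
  invisible(tbl)
}

#' Tabulate a study design
#'
#' Counts logs by site, log type, role and target species.
#'
#' @param design A `study_design` tibble from [build_design()].
#' @return A tibble with columns `site_id`, `log_type`, `role`,
#'   `target_species` and `n`; `n` sums to the total number of logs.
#' @export
design_summary <- function(design) {
  validate_design_tbl(design)
  if (nrow(design) == 0) {
    return(tibble::tibble(site_id = character(0), log_type = character(0),
                          role = character(0), target_species = character(0),
                          n = integer(0)))
  }
  dplyr::count(tibble::as_tibble(design),
               .data$site_id, .data$log_type, .data$role, .data$target_species)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d logs, %d sites, %d target species\n",
              nrow(x), length(attr(x, "sites")), length(attr(x, "species"))))
  NextMethod()
}

#' Species ids of a study design
#' @param design A `study_design`.
#' @return Character vector of target species ids.
#' @export
design_species <- function(design) attr(design, "species")

#' Target logs of one species
#' @param design A `study_design`.
#' @param species A single species id.
#' @return The design rows (tibble) for that species' target logs.
#' @export
target_logs <- function(design, species) {
  if (!species %in% attr(design, "species")) {
    stop("unknown species id: ", species, call. = FALSE)
  }
  dplyr::filter(tibble::as_tibble(design),
                .data$role == "target", .data$target_species == species)
}

#' Expected mean resident richness under a design
#'
#' Closed-form design-weighted expectation of per-log OTU richness: the mean of
#' the per-log-type richness means, weighted by the expected number of logs of
#' each type (felled counts are fixed; natural logs split uprooted/broken by
#' `frac_uprooted`, so the weights need not be integers).
#'
#' @param richness_means Named numeric vector with entries `broken`,
#'   `uprooted`, `felled`.
#' @param n_natural,n_felled Logs per site (or in total) by origin.
#' @param frac_uprooted Fraction of natural logs that are uprooted.
#' @return The expected richness (a single number).
#' @examples
#' expected_mean_richness(c(broken = 59.4, uprooted = 56.6, felled = 44.8))
#' @export
expected_mean_richness <- function(richness_means,
                                   n_natural = 55, n_felled = 37,
                                   frac_uprooted = 0.5) {
  stopifnot(all(c("broken", "uprooted", "felled") %in% names(richness_means)))
  w <- c(broken = n_natural * (1 - frac_uprooted),
         uprooted = n_natural * frac_uprooted,
         felled = n_felled)
  sum(w * richness_means[names(w)]) / sum(w)
}

#' Write log metadata to CSV
#'
#' @param design A `study_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  validate_design_tbl(design)
  readr::write_csv(tibble::as_tibble(design), path)
  invisible(path)
}

#' Read log metadata from CSV
#'
#' @param path CSV written by [write_design_csv()].
#' @return A `study_design` tibble.
#' @export
read_design_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           log_id = "c", site_id = "c", log_type = "c",
                           decay_stage = "d", role = "c", target_species = "c",
                           n_inoculation_points = "d"))
  attr(tbl, "spec") <- NULL
  attr(tbl, "problems") <- NULL
  sp <- sort(unique(tbl$target_species[!is.na(tbl$target_species)]))
  new_study_design(tbl, sp, sort(unique(tbl$site_id)))
}
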