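# Simulation configuration: construction, validation, YAML round trip, and
# canned scenario constructors.

SIM_SCHEMA_VERSION <- 1L

#' Default per-stratum parameters for the synthetic register
#'
#' One row per sex-by-education stratum with childlessness, timing-trait
#' distributions, mean parity among parous individuals, and the true selection
#' parameters for the active selection trait. The default values emulate a
#' twentieth-century Baltic register population: completed fertility around
#' 1.6--2.1 by stratum, women with primary education starting reproduction
#' earliest (~21 y) and women with tertiary education latest (~26 y), the
#' slowest reproductive pace among primary-educated women and the fastest
#' among primary-educated men, and directional selection for earlier first
#' birth that is strongest at the lowest education level.
#'
#' @return A `data.frame` with columns `sex, education, childless_prob,
#'   afb_mean, afb_sd, alb_mean, alb_sd, ibi_mean, ibi_sd, mean_parity,
#'   beta, gamma`.
#' @export
default_strata <- function() {
  data.frame(
    sex = rep(c("F", "M"), each = 5),
    education = rep(EDUCATION_LEVELS, 2),
    childless_prob = c(0.10, 0.12, 0.12, 0.14, 0.20,
                       0.22, 0.20, 0.18, 0.16, 0.25),
    afb_mean = c(21.0, 23.0, 23.5, 26.0, 23.0,
                 24.0, 25.0, 25.0, 27.0, 25.0),
    afb_sd   = c(3.5, 3.5, 3.5, 3.5, 3.5, 4.0, 4.0, 4.0, 4.0, 4.0),
    alb_mean = c(30, 30, 30, 31, 30, 32, 32, 32, 33, 32),
    alb_sd   = rep(4.0, 10),
    ibi_mean = c(2.6, 2.2, 2.2, 2.0, 2.2, 1.9, 2.0, 2.1, 2.3, 2.0),
    ibi_sd   = c(0.8, 0.7, 0.7, 0.6, 0.7, 0.6, 0.6, 0.6, 0.7, 0.6),
    mean_parity = c(2.38, 2.10, 2.15, 2.02, 2.00,
                    2.10, 2.16, 2.33, 2.36, 2.00),
    beta  = c(-0.30, -0.20, -0.20, -0.14, -0.20,
              -0.20, -0.18, -0.21, -0.18, -0.20),
    gamma = rep(0, 10),
    stringsAsFactors = FALSE
  )
}

#' Default cohort-block education composition
#'
#' Education shares drift across cohort blocks to emulate the secular
#' expansion of secondary, vocational, and tertiary education over the
#' 1925--1977 cohorts, with the share of unrecorded education shrinking in
#' later cohorts.
#'
#' @return A `data.frame` with columns `from, to, primary, secondary,
#'   vocational, tertiary, unknown`; shares sum to 1 within each block.
#' @export
default_education_mix <- function() {
  data.frame(
    from = c(1925L, 1940L, 1955L, 1967L),
    to   = c(1939L, 1954L, 1966L, 1977L),
    primary    = c(0.55, 0.38, 0.22, 0.14),
    secondary  = c(0.17, 0.25, 0.30, 0.32),
    vocational = c(0.13, 0.20, 0.28, 0.30),
    tertiary   = c(0.06, 0.11, 0.16, 0.21),
    unknown    = c(0.09, 0.06, 0.04, 0.03)
  )
}

#' Build and validate a synthetic-register configuration
#'
#' Full parameterization of [simulate_register()]: population size and seed,
#' cohort window, sex ratio, cohort-block education composition, per-stratum
#' childlessness, timing-trait distributions and parity, per-stratum true
#' selection parameters (`beta`, `gamma`, on the z scale) for one active
#' selection trait, education-dependent father under-registration
#' probabilities, and infant (pre-age-15) death probability.
#'
#' The offspring model for a parous individual with latent standardized trait
#' `z` is `W = min_parity + Poisson(max(0, lambda - min_parity))` with
#' `lambda = mean_parity * max(fitness_floor, 1 + beta*z + 0.5*gamma*(z^2-1))`,
#' so `E[W | z] = lambda(z)` exactly wherever `lambda >= min_parity` and the
#' configured gradients are the exact estimands of the Lande-Arnold regression
#' in that regime. `trait_z_max` optionally truncates the latent trait at
#' `+/- trait_z_max` pre-truncation standard deviations (the draw is rescaled
#' back to unit variance), which keeps the fitness function strictly positive
#' for steep gradients.
#'
#' @param n_individuals Number of individuals to generate.
#' @param seed Integer random seed (required).
#' @param birth_year_range Inclusive integer cohort window.
#' @param sex_ratio Probability that an individual is male.
#' @param education_mix Cohort-block education shares, see
#'   [default_education_mix()].
#' @param strata Per-stratum parameters, see [default_strata()].
#' @param selection_trait The trait the configured fitness function acts on:
#'   `"AFB"`, `"ALB"`, or `"IBI"`. One trait is active per dataset (a single
#'   offspring count cannot jointly satisfy independent fitness functions on
#'   three traits).
#' @param father_unlink_prob Named per-education probabilities that a
#'   father-child link is missing (default all 0).
#' @param infant_death_prob Probability of death before age 15 (such
#'   individuals get a recorded `age_at_death` and are removed by the default
#'   filters).
#' @param trait_z_max Truncation half-width of the latent trait in
#'   pre-truncation SD units; `Inf` (default) for an untruncated normal.
#' @param min_parity Minimum number of children of a parous individual (1 or
#'   2; 2 makes IBI defined for every parous individual).
#' @param fitness_floor Lower floor on the relative-fitness multiplier
#'   (guards the Poisson mean; activation is reported by the generator and
#'   should be negligible).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_individuals,
                       seed,
                       birth_year_range = c(1925L, 1977L),
                       sex_ratio = 0.51,
                       education_mix = default_education_mix(),
                       strata = default_strata(),
                       selection_trait = "AFB",
                       father_unlink_prob = c(primary = 0, secondary = 0,
                                              vocational = 0, tertiary = 0,
                                              unknown = 0),
                       infant_death_prob = 0.05,
                       trait_z_max = Inf,
                       min_parity = 1L,
                       fitness_floor = 0.01) {
  if (missing(n_individuals)) stop("sim_config: field 'n_individuals' is required")
  if (missing(seed)) stop("sim_config: field 'seed' is required")
  cfg <- list(
    schema_version = SIM_SCHEMA_VERSION,
    n_individuals = as.integer(n_individuals),
    seed = as.integer(seed),
    birth_year_range = as.integer(birth_year_range),
    sex_ratio = as.numeric(sex_ratio),
    education_mix = as.data.frame(education_mix),
    strata = as.data.frame(strata),
    selection_trait = match.arg(selection_trait, TRAIT_NAMES),
    father_unlink_prob = unlist(father_unlink_prob),
    infant_death_prob = as.numeric(infant_death_prob),
    trait_z_max = as.numeric(trait_z_max),
    min_parity = as.integer(min_parity),
    fitness_floor = as.numeric(fitness_floor)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Validate a simulation configuration
#'
#' Checks all probabilities lie in `[0, 1]`, SDs are positive, the education
#' mix blocks tile the cohort window with shares summing to 1, the strata
#' table covers every sex-by-education combination, and the selection
#' parameter guards `|beta| <= 0.4`, `|gamma| <= 0.6` hold (these keep the
#' fitness floor essentially inactive).
#'
#' @param cfg A configuration list.
#' @return `cfg`, invisibly; errors name the offending field.
#' @export
validate_sim_config <- function(cfg) {
  need <- c("n_individuals", "seed", "birth_year_range", "sex_ratio",
            "education_mix", "strata", "selection_trait",
            "father_unlink_prob", "infant_death_prob", "trait_z_max",
            "min_parity", "fitness_floor")
  for (f in need) {
    if (is.null(cfg[[f]]) || (f != "education_mix" && f != "strata" &&
                              anyNA(cfg[[f]]))) {
      stop("sim_config: field '", f, "' is required")
    }
  }
  if (cfg$n_individuals < 1L) stop("sim_config: n_individuals must be >= 1")
  if (length(cfg$birth_year_range) != 2L ||
      cfg$birth_year_range[1] > cfg$birth_year_range[2]) {
    stop("sim_config: birth_year_range must be c(from, to) with from <= to")
  }
  prob01 <- function(x, nm) {
    if (any(x < 0 | x > 1)) stop("sim_config: '", nm, "' must lie in [0, 1]")
  }
  prob01(cfg$sex_ratio, "sex_ratio")
  prob01(cfg$infant_death_prob, "infant_death_prob")
  prob01(cfg$father_unlink_prob, "father_unlink_prob")
  if (!all(EDUCATION_LEVELS %in% names(cfg$father_unlink_prob))) {
    stop("sim_config: father_unlink_prob must be named for every education level")
  }
  mix <- cfg$education_mix
  if (!all(c("from", "to", EDUCATION_LEVELS) %in% names(mix))) {
    stop("sim_config: education_mix must have columns from, to and every education level")
  }
  shares <- as.matrix(mix[EDUCATION_LEVELS])
  prob01(shares, "education_mix")
  if (any(abs(rowSums(shares) - 1) > 1e-8)) {
    stop("sim_config: education_mix shares must sum to 1 within each block")
  }
  yrs <- seq(cfg$birth_year_range[1], cfg$birth_year_range[2])
  cover <- vapply(yrs, function(y) sum(mix$from <= y & mix$to >= y), integer(1))
  if (any(cover != 1L)) {
    stop("sim_config: education_mix blocks must tile the cohort window exactly once")
  }
  st <- cfg$strata
  need_cols <- c("sex", "education", "childless_prob", "afb_mean", "afb_sd",
                 "alb_mean", "alb_sd", "ibi_mean", "ibi_sd", "mean_parity",
                 "beta", "gamma")
  if (!all(need_cols %in% names(st))) {
    stop("sim_config: strata is missing column(s): ",
         paste(setdiff(need_cols, names(st)), collapse = ", "))
  }
  combos <- paste(st$sex, st$education)
  # only combinations that can actually be drawn need parameters
  active_sex <- c(if (cfg$sex_ratio < 1) "F", if (cfg$sex_ratio > 0) "M")
  active_edu <- EDUCATION_LEVELS[colSums(shares) > 0]
  wanted <- as.vector(outer(active_sex, active_edu, paste))
  if (!all(wanted %in% combos)) {
    stop("sim_config: strata must cover every drawable sex-by-education combination; missing: ",
         paste(setdiff(wanted, combos), collapse = ", "))
  }
  if (anyDuplicated(combos)) stop("sim_config: duplicated strata rows")
  prob01(st$childless_prob, "childless_prob")
  if (any(c(st$afb_sd, st$alb_sd, st$ibi_sd) <= 0)) {
    stop("sim_config: trait SDs must be > 0")
  }
  if (any(st$mean_parity <= 0)) stop("sim_config: mean_parity must be > 0")
  if (any(abs(st$beta) > 0.4)) stop("sim_config: |beta| must be <= 0.4")
  if (any(abs(st$gamma) > 0.6)) stop("sim_config: |gamma| must be <= 0.6")
  if (!cfg$min_parity %in% c(1L, 2L)) stop("sim_config: min_parity must be 1 or 2")
  if (cfg$fitness_floor <= 0 || cfg$fitness_floor > 0.1) {
    stop("sim_config: fitness_floor must be in (0, 0.1]")
  }
  if (cfg$trait_z_max <= 0) stop("sim_config: trait_z_max must be > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: n = %d, seed = %d, cohorts %d-%d, selection on %s\n",
              x$n_individuals, x$seed, x$birth_year_range[1],
              x$birth_year_range[2], x$selection_trait))
  cat(sprintf("  %d strata; sex ratio (M) %.2f; infant death %.3f; min parity %d\n",
              nrow(x$strata), x$sex_ratio, x$infant_death_prob, x$min_parity))
  invisible(x)
}

#' Write a simulation configuration to a YAML file
#'
#' @param cfg A [sim_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  out <- unclass(cfg)
  out$education_mix <- as.list(out$education_mix)
  out$strata <- as.list(out$strata)
  out$father_unlink_prob <- as.list(out$father_unlink_prob)
  out$trait_z_max <- if (is.finite(out$trait_z_max)) out$trait_z_max else ".inf"
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read and validate a simulation configuration from YAML
#'
#' @param path Path to a YAML file written by [write_sim_config()] (or
#'   hand-authored with the same fields). A missing required field raises an
#'   error naming it.
#' @return A validated `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$schema_version) && raw$schema_version != SIM_SCHEMA_VERSION) {
    stop("unsupported config schema_version: ", raw$schema_version)
  }
  raw$schema_version <- NULL
  if (!is.null(raw$education_mix)) {
    raw$education_mix <- as.data.frame(raw$education_mix)
  }
  if (!is.null(raw$strata)) raw$strata <- as.data.frame(raw$strata)
  if (!is.null(raw$father_unlink_prob)) {
    raw$father_unlink_prob <- unlist(raw$father_unlink_prob)
  }
  if (!is.null(raw$trait_z_max) && identical(raw$trait_z_max, ".inf")) {
    raw$trait_z_max <- Inf
  }
  do.call(sim_config, raw)
}

#' Single-stratum parameter-recovery scenario
#'
#' A configuration whose configured gradient is the *exact* estimand of the
#' Lande-Arnold regression, used for parameter-recovery validation. The
#' scenario is a stylized natural-fertility regime: one sex and education
#' level, no childlessness or pre-15 mortality, mean parity 8 among parous
#' individuals, and a latent trait truncated at 1.8 pre-truncation SDs
#' (support about +/- 2.16 SD after rescaling to unit variance). Within that
#' support the fitness multiplier `1 + beta*z + 0.5*gamma*(z^2 - 1)` stays
#' well above `min_parity / mean_parity` for the parameter guards
#' `|beta| <= 0.4`, `|gamma| <= 0.6`, so the shifted-Poisson offspring model
#' has conditional mean exactly proportional to the multiplier and OLS is
#' unbiased for the configured `beta`/`gamma`. For `trait = "IBI"` the
#' scenario uses `min_parity = 2` so the interbirth interval is defined for
#' every parous individual and no selective exclusion occurs.
#'
#' @param trait Selection trait, `"AFB"`, `"ALB"`, or `"IBI"`.
#' @param beta_true,gamma_true Configured true gradients (z scale).
#' @param n,seed Population size and seed.
#' @param sex,education Stratum labels.
#' @return A `sim_config` object.
#' @export
sim_config_recovery <- function(trait = c("AFB", "ALB", "IBI"),
                                beta_true, gamma_true = 0,
                                n = 50000L, seed,
                                sex = "F", education = "primary") {
  trait <- match.arg(trait)
  tm <- switch(trait,
    AFB = list(afb_mean = 24, afb_sd = 3.5, alb_mean = 34, alb_sd = 3.5,
               ibi_mean = 1.5, ibi_sd = 0.4),
    ALB = list(afb_mean = 24, afb_sd = 3.5, alb_mean = 38, alb_sd = 3.5,
               ibi_mean = 1.2, ibi_sd = 0.3),
    IBI = list(afb_mean = 22, afb_sd = 3.0, alb_mean = 38, alb_sd = 3.5,
               ibi_mean = 3.0, ibi_sd = 1.2))
  strata <- data.frame(
    sex = sex, education = education, childless_prob = 0,
    afb_mean = tm$afb_mean, afb_sd = tm$afb_sd,
    alb_mean = tm$alb_mean, alb_sd = tm$alb_sd,
    ibi_mean = tm$ibi_mean, ibi_sd = tm$ibi_sd,
    mean_parity = 8, beta = beta_true, gamma = gamma_true,
    stringsAsFactors = FALSE
  )
  mix <- default_education_mix()[1, ]
  mix$from <- 1925L; mix$to <- 1977L
  mix[EDUCATION_LEVELS] <- 0
  mix[[education]] <- 1
  sim_config(
    n_individuals = n, seed = seed,
    sex_ratio = if (sex == "M") 1 else 0,
    education_mix = mix, strata = strata,
    selection_trait = trait,
    infant_death_prob = 0,
    trait_z_max = 1.8,
    min_parity = if (trait == "IBI") 2L else 1L
  )
}

#' Flat-fitness (null) scenario
#'
#' Single-stratum scenario with `beta = gamma = 0`: offspring number is
#' independent of the trait, so the true gradient is zero. Used for
#' confidence-interval calibration.
#'
#' @param n,seed Population size and seed.
#' @param trait Selection trait label (determines which trait is analysed).
#' @return A `sim_config` object.
#' @export
sim_config_null <- function(n = 2000L, seed, trait = "AFB") {
  cfg <- sim_config_recovery(trait = trait, beta_true = 0, gamma_true = 0,
                             n = n, seed = seed)
  cfg$strata$mean_parity <- 2.4
  cfg$strata$childless_prob <- 0.12
  cfg$trait_z_max <- Inf
  cfg$min_parity <- if (trait == "IBI") 2L else 1L
  validate_sim_config(cfg)
  cfg
}

#' Equal-fitness male population for under-registration experiments
#'
#' All-male population in which every education level shares the same
#' childlessness, timing-trait distribution, parity, and (flat) fitness
#' function, with education shares uniform over the four recorded levels.
#' Because the true fitness surface is identical across strata, any estimated
#' education contrast after father under-registration is pure registration
#' bias.
#'
#' @param n,seed Population size and seed.
#' @return A `sim_config` object.
#' @export
sim_config_equal_men <- function(n = 40000L, seed) {
  strata <- data.frame(
    sex = "M", education = setdiff(EDUCATION_LEVELS, "unknown"),
    childless_prob = 0.15,
    afb_mean = 25, afb_sd = 4, alb_mean = 32, alb_sd = 4,
    ibi_mean = 2.1, ibi_sd = 0.6, mean_parity = 2.3,
    beta = 0, gamma = 0, stringsAsFactors = FALSE
  )
  mix <- default_education_mix()[1, ]
  mix$from <- 1925L; mix$to <- 1977L
  mix[EDUCATION_LEVELS] <- c(0.25, 0.25, 0.25, 0.25, 0)
  sim_config(
    n_individuals = n, seed = seed, sex_ratio = 1,
    education_mix = mix, strata = strata,
    selection_trait = "AFB", infant_death_prob = 0
  )
}
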