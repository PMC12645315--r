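# Synthetic population-register generator with known ground truth.

# SD of a standard normal truncated symmetrically at +/- a.
truncnorm_sd <- function(a) {
  if (!is.finite(a)) return(1)
  mass <- 2 * stats::pnorm(a) - 1
  sqrt(1 - 2 * a * stats::dnorm(a) / mass)
}

#' Generate a synthetic population register
#'
#' Draws a register-style population with known ground truth. Per individual:
#' birth cohort (uniform over the window), sex, education (cohort-block
#' shares), survival to age 15, childlessness, then — for parous survivors — a
#' latent standardized trait `z`, an offspring count from the shifted-Poisson
#' fitness model described in [sim_config()], and first/last child birth years
#' constructed so that the derived AFB/ALB/IBI of [derive_timing()] round-trip
#' the configured trait distributions (`ALB = AFB + IBI_draw * n_children`, in
#' whole calendar years; ages at first birth are floored at 15).
#'
#' Randomness comes from a single seeded stream consumed as a fixed budget of
#' eight uniform draws per individual in individual-major order, so the same
#' config and seed reproduce the dataset exactly and enlarging
#' `n_individuals` does not perturb earlier individuals. If any
#' `father_unlink_prob` is positive, [apply_father_underregistration()] is
#' applied to the generated records (seeded from `seed + 1`).
#'
#' @param config A validated [sim_config()].
#' @param quiet Suppress the fitness-floor activation message.
#' @return A list with `records` (a register `data.frame`, see
#'   [read_register()]) and `truth` (the per-stratum parameters actually used,
#'   echoed with the seed, selection trait, and floor-activation rates).
#' @export
simulate_register <- function(config, quiet = FALSE) {
  validate_sim_config(config)
  n <- config$n_individuals
  set.seed(config$seed)
  U <- matrix(stats::runif(n * 8L), nrow = n, ncol = 8L, byrow = TRUE)

  yr0 <- config$birth_year_range[1]
  yr1 <- config$birth_year_range[2]
  birth_year <- yr0 + as.integer(floor(U[, 1] * (yr1 - yr0 + 1L)))
  birth_year[birth_year > yr1] <- yr1  # guard u == 1 edge

  sex <- ifelse(U[, 2] < config$sex_ratio, "M", "F")

  # education from cohort-block shares
  mix <- config$education_mix
  education <- character(n)
  for (b in seq_len(nrow(mix))) {
    inb <- birth_year >= mix$from[b] & birth_year <= mix$to[b]
    if (!any(inb)) next
    cp <- cumsum(as.numeric(mix[b, EDUCATION_LEVELS]))
    idx <- findInterval(U[inb, 3], cp[-length(cp)]) + 1L
    education[inb] <- EDUCATION_LEVELS[idx]
  }

  died <- U[, 4] < config$infant_death_prob
  age_at_death <- rep(NA_integer_, n)
  if (any(died)) {
    age_at_death[died] <- as.integer(floor(U[died, 4] /
                                             config$infant_death_prob * 15))
  }

  st <- config$strata
  si <- match(paste(sex, education), paste(st$sex, st$education))
  stopifnot(!anyNA(si))
  p_childless <- st$childless_prob[si]
  childless <- died | U[, 5] < p_childless

  # latent standardized trait (unit variance, optionally bounded support)
  zmax <- config$trait_z_max
  if (is.finite(zmax)) {
    lo <- stats::pnorm(-zmax)
    z <- stats::qnorm(lo + U[, 6] * (1 - 2 * lo)) / truncnorm_sd(zmax)
  } else {
    z <- stats::qnorm(U[, 6])
  }

  beta <- st$beta[si]
  gamma <- st$gamma[si]
  mult_raw <- 1 + beta * z + 0.5 * gamma * (z^2 - 1)
  mult <- pmax(config$fitness_floor, mult_raw)
  lambda <- st$mean_parity[si] * mult
  kmin <- config$min_parity
  lam_excess <- pmax(0, lambda - kmin)
  W <- kmin + stats::qpois(U[, 7], lam_excess)

  parous_idx <- !childless
  floor_rate <- mean(mult_raw[parous_idx] < config$fitness_floor)
  boundary_rate <- mean(lambda[parous_idx] < kmin)
  if (!quiet) {
    message(sprintf("simulate_register: fitness floor active for %.3f%% of parous draws; lambda below min_parity for %.3f%%",
                    100 * floor_rate, 100 * boundary_rate))
  }

  n_children <- ifelse(childless, 0L, W)

  o <- stats::qnorm(U[, 8])  # timing draw orthogonal to the selected trait
  trait <- config$selection_trait
  if (trait == "AFB") {
    afb <- st$afb_mean[si] + st$afb_sd[si] * z
    ibi_d <- pmax(0, st$ibi_mean[si] + st$ibi_sd[si] * o)
    afb_i <- pmax(15L, as.integer(round(afb)))
    gap <- ifelse(n_children >= 2L, as.integer(round(ibi_d * n_children)), 0L)
  } else if (trait == "ALB") {
    alb <- st$alb_mean[si] + st$alb_sd[si] * z
    ibi_d <- pmax(0, st$ibi_mean[si] + st$ibi_sd[si] * o)
    alb_i <- pmax(16L, as.integer(round(alb)))
    gap <- ifelse(n_children >= 2L, as.integer(round(ibi_d * n_children)), 0L)
    gap <- pmin(gap, alb_i - 15L)  # keep age at first birth >= 15
    afb_i <- alb_i - gap
  } else { # IBI
    ibi_d <- pmax(0, st$ibi_mean[si] + st$ibi_sd[si] * z)
    afb <- st$afb_mean[si] + st$afb_sd[si] * o
    afb_i <- pmax(15L, as.integer(round(afb)))
    gap <- ifelse(n_children >= 2L, as.integer(round(ibi_d * n_children)), 0L)
  }

  first_child_year <- ifelse(n_children >= 1L, birth_year + afb_i, NA_integer_)
  last_child_year <- ifelse(n_children >= 1L, first_child_year + gap, NA_integer_)

  records <- data.frame(
    person_id = sprintf("S%07d", seq_len(n)),
    sex = factor(sex, levels = SEX_LEVELS),
    birth_year = birth_year,
    education = factor(education, levels = EDUCATION_LEVELS),
    n_children = as.integer(n_children),
    first_child_year = as.integer(first_child_year),
    last_child_year = as.integer(last_child_year),
    age_at_death = age_at_death,
    stringsAsFactors = FALSE
  )

  if (any(config$father_unlink_prob > 0)) {
    records <- apply_father_underregistration(
      records, config$father_unlink_prob, seed = config$seed + 1L)
  }
  validate_register(records)

  truth <- st
  truth$selection_trait <- trait
  truth$seed <- config$seed
  truth$n_individuals <- n
  truth$min_parity <- kmin
  truth$trait_z_max <- zmax
  attr(truth, "floor_rate") <- floor_rate
  attr(truth, "boundary_rate") <- boundary_rate

  list(records = records, truth = truth)
}

#' Write the ground-truth sidecar of a simulated register
#'
#' @param truth The `truth` element returned by [simulate_register()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Remove father-child links to emulate paternity under-registration
#'
#' Register parity data are more complete for mothers than fathers: a
#' father-child link exists only when reported. This operation unlinks each
#' child of a male record independently with an education-specific probability
#' `q`, reduces `n_children` accordingly, and adjusts the first/last child
#' years to the surviving extremes; a man whose children are all unlinked
#' becomes childless. Female records are untouched. Interior child birth years
#' are not part of the register schema, so they are reconstructed as evenly
#' spaced between the recorded first and last years before unlinking (an
#' approximation documented here).
#'
#' @param reg A register `data.frame`.
#' @param unlink_prob Per-education unlink probabilities: a named vector (or a
#'   single number recycled over all levels), each in `[0, 1]`.
#' @param seed Integer seed for the per-child unlink draws.
#' @return The modified register `data.frame`.
#' @export
apply_father_underregistration <- function(reg, unlink_prob, seed) {
  validate_register(reg)
  if (length(unlink_prob) == 1L && is.null(names(unlink_prob))) {
    unlink_prob <- stats::setNames(rep(unlink_prob, length(EDUCATION_LEVELS)),
                                   EDUCATION_LEVELS)
  }
  if (any(unlink_prob < 0 | unlink_prob > 1)) {
    stop("apply_father_underregistration: unlink probabilities must lie in [0, 1]")
  }
  if (!all(EDUCATION_LEVELS %in% names(unlink_prob))) {
    stop("apply_father_underregistration: unlink_prob must be named for every education level")
  }
  men <- which(reg$sex == "M" & reg$n_children >= 1L)
  if (length(men) == 0L) return(reg)

  n_i <- reg$n_children[men]
  first_i <- reg$first_child_year[men]
  gap_i <- reg$last_child_year[men] - first_i

  # reconstruct child years as evenly spaced between the recorded extremes
  rows <- rep(seq_along(men), n_i)
  pos <- sequence(n_i)
  step <- gap_i[rows] / pmax(n_i[rows] - 1L, 1L)
  years <- first_i[rows] + as.integer(round((pos - 1L) * step))

  set.seed(as.integer(seed))
  u <- stats::runif(length(rows))
  q <- unlink_prob[as.character(reg$education[men])][rows]
  keep <- u >= q

  n_new <- as.integer(tapply(keep, factor(rows, levels = seq_along(men)), sum))
  kept_rows <- rows[keep]
  first_new <- rep(NA_integer_, length(men))
  last_new <- rep(NA_integer_, length(men))
  if (any(keep)) {
    mn <- tapply(years[keep], kept_rows, min)
    mx <- tapply(years[keep], kept_rows, max)
    at <- as.integer(names(mn))
    first_new[at] <- as.integer(mn)
    last_new[at] <- as.integer(mx)
  }

  reg$n_children[men] <- n_new
  reg$first_child_year[men] <- first_new
  reg$last_child_year[men] <- last_new
  validate_register(reg)
  reg
}
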