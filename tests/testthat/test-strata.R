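# Stratified gradients and education-attainment contrasts.

test_that("education gradient equals the group-mean difference oracle", {
  # two strata in one cohort; betas are plain mean-rLRS differences vs primary
  reg <- rbind(cohort_register(c(2L, 3L), education = "primary"),
               cohort_register(c(1L, 2L), education = "tertiary"))
  reg$person_id <- paste0("p", 1:4)
  wf <- relative_fitness(reg, quiet = TRUE)
  eg <- education_gradient(reg, min_n = 2)
  mean_diff <- mean(wf$rlrs[wf$education == "tertiary"]) -
    mean(wf$rlrs[wf$education == "primary"])
  expect_equal(eg$beta, mean_diff)
  expect_equal(eg$trait, "EDUCATION")
  expect_equal(eg$education, "tertiary")
})

test_that("identical mean rLRS across education levels gives zero contrasts", {
  reg <- do.call(rbind, lapply(c("primary", "secondary", "vocational",
                                 "tertiary"), function(e) {
    r <- cohort_register(c(1L, 3L), education = e)
    r$person_id <- paste0(e, 1:2)
    r
  }))
  eg <- education_gradient(reg, min_n = 2)
  expect_equal(eg$beta, rep(0, 3))
})

test_that("education gradient requires a primary reference group", {
  reg <- cohort_register(c(1L, 2L, 3L), education = "tertiary")
  expect_error(education_gradient(reg, min_n = 2), "primary")
})

test_that("configured education fitness gaps are recovered from a synthetic register", {
  cfg <- sim_config_equal_men(n = 30000, seed = 21)
  # impose a known fitness ordering through mean parity
  cfg$strata$mean_parity <- c(2.0, 2.2, 2.4, 2.6)
  cfg$strata$childless_prob <- 0.0
  validate_sim_config(cfg)
  sim <- simulate_register(cfg, quiet = TRUE)
  reg <- apply_filters(sim$records, quiet = TRUE)
  eg <- education_gradient(reg)
  # expected contrast: (mean_e - mean_primary) / overall cohort mean
  overall <- mean(cfg$strata$mean_parity)
  expected <- (cfg$strata$mean_parity[-1] - cfg$strata$mean_parity[1]) / overall
  got <- eg$beta[match(cfg$strata$education[-1], eg$education)]
  expect_lt(max(abs(got - expected)), 0.04)
})

test_that("strata below the minimum size are omitted with a warning", {
  big <- cohort_register(rep(c(1L, 2L, 3L), 20), education = "primary")
  big$person_id <- paste0("b", 1:60)
  big$first_child_year <- big$birth_year + rep(18:37, 3)
  big$last_child_year <- big$first_child_year +
    ifelse(big$n_children >= 2, 2L * big$n_children, 0L)
  small <- cohort_register(rep(2L, 10), education = "tertiary")
  small$person_id <- paste0("s", 1:10)
  small$first_child_year <- small$birth_year + 20:29
  small$last_child_year <- small$first_child_year + 4L
  reg <- rbind(big, small)
  expect_warning(tab <- gradient_by_stratum(reg, "AFB", models = "linear",
                                            min_n = 30),
                 "tertiary.*n = 10 < 30")
  expect_false("tertiary" %in% tab$education)
  expect_true("primary" %in% tab$education)
})

test_that("unknown education is excluded from strata but kept in cohort means", {
  known <- cohort_register(rep(c(1L, 2L), 20), education = "primary")
  known$person_id <- paste0("k", 1:40)
  known$first_child_year <- known$birth_year + rep(18:37, 2)
  known$last_child_year <- known$first_child_year +
    ifelse(known$n_children >= 2, 4L, 0L)
  unk <- cohort_register(rep(5L, 10), education = "unknown")
  unk$person_id <- paste0("u", 1:10)
  unk$first_child_year <- unk$birth_year + 20:29
  unk$last_child_year <- unk$first_child_year + 10L
  reg <- rbind(known, unk)
  tab <- gradient_by_stratum(reg, "AFB", models = "linear", min_n = 30)
  expect_false("unknown" %in% tab$education)
  # the unknown members still inflate the rLRS denominator:
  wf <- relative_fitness(reg, quiet = TRUE)
  expect_equal(unique(wf$n_children / wf$rlrs)[1],
               mean(reg$n_children))
})

test_that("strata sharing one fitness function give mutually consistent betas", {
  cfg <- sim_config_equal_men(n = 30000, seed = 5)
  cfg$strata$beta <- -0.2
  validate_sim_config(cfg)
  sim <- simulate_register(cfg, quiet = TRUE)
  reg <- apply_filters(sim$records, quiet = TRUE)
  tab <- gradient_by_stratum(reg, "AFB", models = "linear")
  betas <- tab$beta
  ses <- tab$se_beta
  # exchangeable strata: pairwise differences within ~4 joint SEs
  for (i in seq_along(betas)) for (j in seq_along(betas)) {
    expect_lt(abs(betas[i] - betas[j]), 4 * sqrt(ses[i]^2 + ses[j]^2) + 1e-12)
  }
})

test_that("per-cohort gradients scatter around the pooled estimate and allow gaps", {
  cfg <- sim_config_recovery("AFB", beta_true = -0.2, n = 20000, seed = 31)
  sim <- simulate_register(cfg, quiet = TRUE)
  reg <- apply_filters(sim$records, quiet = TRUE)
  pooled <- gradient_by_stratum(reg, "AFB", models = "linear")
  per <- gradient_by_cohort(reg, "AFB", models = "linear")
  expect_true(all(per$cohort_from == per$cohort_to))
  expect_false(is.unsorted(per$cohort_from))
  covered <- per$beta_ci_low <= pooled$beta & pooled$beta <= per$beta_ci_high
  expect_gt(mean(covered), 0.85)  # per-cohort CIs should usually cover the pooled truth

  # cohorts below the minimum size leave gaps rather than erroring
  tiny <- reg[reg$birth_year != 1950 | seq_len(nrow(reg)) %in%
                which(reg$birth_year == 1950)[1:10], ]
  per2 <- gradient_by_cohort(tiny, "AFB", models = "linear", min_n = 30)
  expect_false(1950 %in% per2$cohort_from)
})

test_that("cohorts present for one sex only are emitted only for that sex", {
  f <- cohort_register(rep(c(1L, 2L, 3L), 15), sex = "F", birth_year = 1950)
  f$person_id <- paste0("f", 1:45)
  f$first_child_year <- f$birth_year + rep(18:32, 3)
  f$last_child_year <- f$first_child_year +
    ifelse(f$n_children >= 2, 2L * f$n_children, 0L)
  per <- gradient_by_cohort(f, "AFB", models = "linear", by_education = FALSE)
  expect_equal(unique(per$sex), "F")
})

test_that("gradients are invariant to rescaling the raw trait", {
  cfg <- sim_config(n_individuals = 8000, seed = 17)
  sim <- simulate_register(cfg, quiet = TRUE)
  reg <- apply_filters(sim$records, quiet = TRUE)
  tab1 <- gradient_by_stratum(reg, "AFB", models = "linear")

  # rescale the trait: move every first child year to double the age offset
  reg2 <- reg
  parous <- reg2$n_children >= 1L
  gap <- reg2$last_child_year - reg2$first_child_year
  afb2 <- 2L * (reg2$first_child_year - reg2$birth_year)
  reg2$first_child_year[parous] <- reg2$birth_year[parous] + afb2[parous]
  reg2$last_child_year[parous] <- reg2$first_child_year[parous] + gap[parous]
  tab2 <- gradient_by_stratum(reg2, "AFB", models = "linear")
  expect_equal(tab1$beta, tab2$beta, tolerance = 1e-10)
  expect_equal(tab1$se_beta, tab2$se_beta, tolerance = 1e-10)
})

test_that("gradient tables serialize with the documented columns", {
  cfg <- sim_config(n_individuals = 6000, seed = 23)
  sim <- simulate_register(cfg, quiet = TRUE)
  reg <- apply_filters(sim$records, quiet = TRUE)
  tab <- suppressWarnings(gradient_by_stratum(reg, "AFB"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gradients(tab, path)
  back <- read.csv(path)
  expect_equal(names(back),
               c("trait", "sex", "education", "cohort_from", "cohort_to",
                 "model", "beta", "se_beta", "beta_ci_low", "beta_ci_high",
                 "gamma", "se_gamma", "gamma_ci_low", "gamma_ci_high", "n"))
  expect_true(all(is.na(back$gamma[back$model == "linear"])))
  expect_true(all(!is.na(back$gamma[back$model == "quadratic"])))
})
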