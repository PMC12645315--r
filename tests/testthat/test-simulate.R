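# The synthetic-register generator.

test_that("the same config and seed reproduce the register byte for byte", {
  cfg <- sim_config(n_individuals = 1000, seed = 7)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_register(simulate_register(cfg, quiet = TRUE)$records, p1)
  write_register(simulate_register(cfg, quiet = TRUE)$records, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("enlarging the population does not perturb earlier individuals", {
  cfg_small <- sim_config(n_individuals = 500, seed = 11)
  cfg_big <- sim_config(n_individuals = 1000, seed = 11)
  small <- simulate_register(cfg_small, quiet = TRUE)$records
  big <- simulate_register(cfg_big, quiet = TRUE)$records
  head_big <- big[seq_len(500), ]
  rownames(head_big) <- NULL
  expect_identical(small, head_big)
})

test_that("generated records always satisfy the register invariants", {
  for (s in 1:3) {
    cfg <- sim_config(n_individuals = 4000, seed = s)
    rec <- simulate_register(cfg, quiet = TRUE)$records
    expect_silent(validate_register(rec))
    parous <- rec$n_children >= 1L
    expect_true(all(rec$first_child_year[parous] > rec$birth_year[parous]))
    expect_true(all(rec$last_child_year[parous] >=
                      rec$first_child_year[parous]))
  }
})

test_that("empirical margins match the configured values", {
  cfg <- sim_config(n_individuals = 100000, seed = 42)
  sim <- simulate_register(cfg, quiet = TRUE)
  rec <- sim$records

  # education shares within each cohort block (3 MC SEs)
  mix <- cfg$education_mix
  for (b in seq_len(nrow(mix))) {
    inb <- rec$birth_year >= mix$from[b] & rec$birth_year <= mix$to[b]
    share <- table(rec$education[inb]) / sum(inb)
    for (e in names(share)) {
      p <- mix[[e]][b]
      se <- sqrt(p * (1 - p) / sum(inb))
      expect_lt(abs(share[[e]] - p), 3 * se + 1e-9)
    }
  }

  # per-stratum mean AFB and parous mean offspring (3 MC SEs)
  tt <- derive_timing(rec)
  st <- cfg$strata
  for (i in seq_len(nrow(st))) {
    idx <- rec$sex == st$sex[i] & rec$education == st$education[i] &
      rec$n_children >= 1L
    n <- sum(idx)
    expect_lt(abs(mean(tt$afb[idx]) - st$afb_mean[i]),
              3 * st$afb_sd[i] / sqrt(n) + 0.3)  # 0.3 covers rounding + age-15 floor
    w <- rec$n_children[idx]
    expect_lt(abs(mean(w) - st$mean_parity[i]),
              3 * sd(w) / sqrt(n) + 0.05)  # 0.05 covers the parity-floor clamp
  }

  # sex ratio and childlessness
  expect_lt(abs(mean(rec$sex == "M") - cfg$sex_ratio), 0.01)
  died <- !is.na(rec$age_at_death)
  expect_lt(abs(mean(died) - cfg$infant_death_prob), 0.005)
  expect_true(all(rec$age_at_death[died] < 15))
  expect_true(all(rec$n_children[died] == 0L))
})

test_that("a zero-gradient config yields a pooled gradient within 2 SE of zero", {
  cfg <- sim_config_null(n = 20000, seed = 77)
  sim <- simulate_register(cfg, quiet = TRUE)
  reg <- apply_filters(sim$records, quiet = TRUE)
  tab <- gradient_by_stratum(reg, "AFB", models = "linear")
  expect_lt(abs(tab$beta), 2 * tab$se_beta)
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(sim_config(n_individuals = 100), "seed")
  expect_error(sim_config(seed = 1), "n_individuals")
  expect_error(sim_config(100, 1, sex_ratio = 1.4), "\\[0, 1\\]")
  st <- default_strata(); st$beta[1] <- 0.9
  expect_error(sim_config(100, 1, strata = st), "beta")
  st <- default_strata(); st$afb_sd[2] <- 0
  expect_error(sim_config(100, 1, strata = st), "SDs")
  mix <- default_education_mix(); mix$primary[1] <- 0.9
  expect_error(sim_config(100, 1, education_mix = mix), "sum to 1")
  mix <- default_education_mix(); mix$to[1] <- 1935L
  expect_error(sim_config(100, 1, education_mix = mix), "tile")
})

test_that("configs round-trip through YAML", {
  cfg <- sim_config(n_individuals = 2500, seed = 13, trait_z_max = 1.8)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$strata, cfg$strata)
  expect_equal(back$education_mix, cfg$education_mix)
  expect_equal(back$trait_z_max, 1.8)
  expect_identical(simulate_register(back, quiet = TRUE)$records,
                   simulate_register(cfg, quiet = TRUE)$records)

  # infinite truncation survives serialization too
  cfg2 <- sim_config(n_individuals = 100, seed = 13)
  write_sim_config(cfg2, path)
  expect_equal(read_sim_config(path)$trait_z_max, Inf)
})

test_that("the truth sidecar echoes the parameters actually used", {
  cfg <- sim_config_recovery("ALB", beta_true = 0.38, n = 1000, seed = 3)
  sim <- simulate_register(cfg, quiet = TRUE)
  expect_equal(sim$truth$beta, 0.38)
  expect_equal(sim$truth$selection_trait, "ALB")
  expect_equal(sim$truth$seed, 3L)
  expect_equal(sim$truth$mean_parity, 8)
})

test_that("father under-registration thins male links as a per-child Bernoulli", {
  # q = 0 is the identity
  cfg <- sim_config_equal_men(n = 2000, seed = 9)
  rec <- simulate_register(cfg, quiet = TRUE)$records
  q0 <- setNames(rep(0, 5), c("primary", "secondary", "vocational",
                              "tertiary", "unknown"))
  expect_identical(apply_father_underregistration(rec, q0, seed = 1), rec)

  # q = 1 makes every man childless
  q1 <- setNames(rep(1, 5), names(q0))
  gone <- apply_father_underregistration(rec, q1, seed = 1)
  expect_true(all(gone$n_children[gone$sex == "M"] == 0L))
  expect_true(all(is.na(gone$first_child_year[gone$sex == "M"])))

  # q = 0.5 halves the expected linked count of 4-child fathers
  men4 <- make_register(paste0("m", 1:10000), "M", 1950,
                        n_children = 4L, first_child_year = 1975L,
                        last_child_year = 1981L)
  qh <- setNames(rep(0.5, 5), names(q0))
  thinned <- apply_father_underregistration(men4, qh, seed = 2)
  m <- mean(thinned$n_children)
  se <- sqrt(4 * 0.5 * 0.5 / 10000)
  expect_lt(abs(m - 2), 4 * se)
  # surviving extremes stay inside the original child-year span
  kept <- thinned$n_children >= 1L
  expect_true(all(thinned$first_child_year[kept] >= 1975L))
  expect_true(all(thinned$last_child_year[kept] <= 1981L))
  expect_silent(validate_register(thinned))

  # women untouched
  wom <- cohort_register(c(2L, 3L))
  expect_identical(apply_father_underregistration(wom, qh, seed = 1), wom)

  expect_error(apply_father_underregistration(rec, setNames(rep(1.2, 5),
                                                            names(q0)), 1),
               "\\[0, 1\\]")
})
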