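# Stratified selection-gradient drivers and the education-attainment gradient.

# Assemble one selgrad_table row from a fit (or from raw numbers for the
# education contrasts).
selgrad_row <- function(trait, sex, education, cohort_from, cohort_to, model,
                        beta, se_beta, ci_beta, gamma = NA_real_,
                        se_gamma = NA_real_, ci_gamma = c(NA_real_, NA_real_),
                        n) {
  data.frame(trait = trait, sex = sex, education = education,
             cohort_from = cohort_from, cohort_to = cohort_to, model = model,
             beta = beta, se_beta = se_beta,
             beta_ci_low = ci_beta[1], beta_ci_high = ci_beta[2],
             gamma = gamma, se_gamma = se_gamma,
             gamma_ci_low = ci_gamma[1], gamma_ci_high = ci_gamma[2],
             n = n, stringsAsFactors = FALSE)
}

selgrad_table <- function(rows, fits = list()) {
  out <- if (length(rows) == 0L) {
    selgrad_row(character(0), character(0), character(0), integer(0),
                integer(0), character(0), numeric(0), numeric(0),
                cbind(numeric(0), numeric(0)), numeric(0), numeric(0),
                cbind(numeric(0), numeric(0)), integer(0))[0, ]
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("selgrad_table", "data.frame")
  out
}

# Shared preparation: rLRS on the full filtered records, timing traits,
# cohort-standardized z. Returns only individuals for whom the trait and rlrs
# are defined.
prepare_selection_data <- function(reg, trait, scope = "cohort",
                                   rlrs_base = c("cohort", "parous"),
                                   quiet = TRUE) {
  rlrs_base <- match.arg(rlrs_base)
  means <- suppressWarnings(cohort_mean_fitness(reg, parous_only = rlrs_base == "parous"))
  wf <- relative_fitness(reg, means, quiet = quiet)
  wf <- derive_timing(wf)
  suppressWarnings(standardize_trait(wf, trait = trait, scope = scope))
}

#' Selection gradients per sex-by-education stratum
#'
#' Estimates linear and quadratic Lande-Arnold gradients for one timing trait
#' in each sex-by-education stratum, pooling all birth cohorts. Relative
#' fitness and the trait z-scores are computed on the *full* record set
#' (cohort means include childless and unknown-education individuals;
#' standardization pools education levels within sex-by-cohort by default),
#' and only the regressions are stratified. Individuals with unknown education
#' are excluded from the strata. Strata below `min_n` are omitted with a
#' warning, never pooled.
#'
#' @param reg A filtered register `data.frame` (see [apply_filters()]).
#' @param trait One of `"AFB"`, `"ALB"`, `"IBI"`.
#' @param models Character subset of `c("linear", "quadratic")`.
#' @param min_n Minimum stratum size (default 30).
#' @param robust,conf_level Passed to [selection_gradient()].
#' @param scope Standardization scope, `"cohort"` (default) or `"stratum"`.
#' @param rlrs_base Denominator of rLRS: the full sex-by-cohort mean
#'   (`"cohort"`, default) or the parous-only mean (`"parous"`).
#' @param include_pooled Also fit the education-pooled stratum per sex
#'   (labelled `education = "all"`).
#' @return A `data.frame` of class `selgrad_table` with one row per stratum
#'   and model, columns `trait, sex, education, cohort_from, cohort_to, model,
#'   beta, se_beta, beta_ci_low, beta_ci_high, gamma, se_gamma, gamma_ci_low,
#'   gamma_ci_high, n` (gamma columns `NA` for the linear model). The
#'   underlying `selgrad` fits are attached as `attr(, "fits")`.
#' @export
gradient_by_stratum <- function(reg, trait, models = c("linear", "quadratic"),
                                min_n = 30L, robust = FALSE, conf_level = 0.95,
                                scope = "cohort",
                                rlrs_base = c("cohort", "parous"),
                                include_pooled = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  dat <- prepare_selection_data(reg, trait, scope = scope,
                                rlrs_base = rlrs_base)
  groups <- expand.grid(sex = SEX_LEVELS,
                        education = setdiff(EDUCATION_LEVELS, "unknown"),
                        stringsAsFactors = FALSE)
  if (include_pooled) {
    groups <- rbind(groups, data.frame(sex = SEX_LEVELS, education = "all"))
  }
  rows <- list(); fits <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sel <- dat$sex == g$sex &
      (g$education == "all" |
         (!is.na(dat$education) & dat$education == g$education &
            dat$education != "unknown"))
    sub <- dat[sel, , drop = FALSE]
    if (nrow(sub) == 0L) next
    if (nrow(sub) < min_n) {
      warning(sprintf("gradient_by_stratum: stratum %s/%s has n = %d < %d; omitted",
                      g$sex, g$education, nrow(sub), min_n))
      next
    }
    for (m in models) {
      fit <- tryCatch(
        selection_gradient(sub$z, sub$rlrs, model = m, robust = robust,
                           min_n = min_n, conf_level = conf_level,
                           trait = trait,
                           stratum = list(sex = g$sex, education = g$education)),
        error = function(e) {
          warning(sprintf("gradient_by_stratum: stratum %s/%s (%s) failed: %s",
                          g$sex, g$education, m, conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- selgrad_row(
        trait, g$sex, g$education,
        min(sub$birth_year), max(sub$birth_year), m,
        fit$beta, fit$se_beta, fit$ci_beta,
        fit$gamma, fit$se_gamma, fit$ci_gamma, fit$n)
      fits[[paste(g$sex, g$education, m, sep = ".")]] <- fit
    }
  }
  selgrad_table(rows, fits)
}

#' Selection gradients per birth cohort
#'
#' As [gradient_by_stratum()] with `birth_year` added to the grouping: one
#' estimate per sex-by-education-by-cohort cell, ordered by cohort for
#' plotting. Cohort cells below `min_n` leave a gap in the series rather than
#' raising an error.
#'
#' @inheritParams gradient_by_stratum
#' @param by_education Stratify by education (default); when `FALSE` the
#'   education label is `"all"` and levels are pooled (unknown included).
#' @return A `selgrad_table` with `cohort_from == cohort_to == birth_year`.
#' @export
gradient_by_cohort <- function(reg, trait, models = "linear",
                               min_n = 30L, robust = FALSE, conf_level = 0.95,
                               scope = "cohort",
                               rlrs_base = c("cohort", "parous"),
                               by_education = TRUE) {
  models <- match.arg(models, c("linear", "quadratic"), several.ok = TRUE)
  dat <- prepare_selection_data(reg, trait, scope = scope,
                                rlrs_base = rlrs_base)
  if (by_education) {
    dat <- dat[!is.na(dat$education) & dat$education != "unknown", , drop = FALSE]
    key <- interaction(dat$sex, dat$education, dat$birth_year, drop = TRUE)
  } else {
    key <- interaction(dat$sex, dat$birth_year, drop = TRUE)
  }
  rows <- list(); fits <- list()
  for (k in levels(key)) {
    sub <- dat[key == k, , drop = FALSE]
    if (nrow(sub) < min_n) next  # gap in the series, not an error
    sex <- as.character(sub$sex[1])
    edu <- if (by_education) as.character(sub$education[1]) else "all"
    yr <- sub$birth_year[1]
    for (m in models) {
      fit <- tryCatch(
        selection_gradient(sub$z, sub$rlrs, model = m, robust = robust,
                           min_n = min_n, conf_level = conf_level,
                           trait = trait,
                           stratum = list(sex = sex, education = edu,
                                          birth_year = yr)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- selgrad_row(
        trait, sex, edu, yr, yr, m,
        fit$beta, fit$se_beta, fit$ci_beta,
        fit$gamma, fit$se_gamma, fit$ci_gamma, fit$n)
      fits[[paste(sex, edu, yr, m, sep = ".")]] <- fit
    }
  }
  out <- selgrad_table(rows, fits)
  out[order(out$sex, out$education, out$cohort_from, out$model), , drop = FALSE]
}

#' Selection gradients for educational attainment
#'
#' Linear selection gradients for education levels, each level contrasted
#' against primary education: per sex, rLRS is regressed on indicator
#' variables for secondary, vocational, and tertiary attainment (primary as
#' reference), so each beta is numerically the difference in mean rLRS between
#' that level and primary. Education is defined for everyone, so childless
#' individuals are included; individuals with unknown education are excluded
#' from the regression (they still enter the cohort means behind rLRS).
#'
#' @inheritParams gradient_by_stratum
#' @return A `selgrad_table` with `trait = "EDUCATION"` and one row per
#'   (sex, non-primary level).
#' @export
education_gradient <- function(reg, min_n = 30L, robust = FALSE,
                               conf_level = 0.95,
                               rlrs_base = c("cohort", "parous")) {
  rlrs_base <- match.arg(rlrs_base)
  means <- suppressWarnings(cohort_mean_fitness(reg, parous_only = rlrs_base == "parous"))
  dat <- relative_fitness(reg, means, quiet = TRUE)
  dat <- dat[dat$education != "unknown", , drop = FALSE]
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- list(); fits <- list()
  for (sx in SEX_LEVELS) {
    sub <- dat[dat$sex == sx, , drop = FALSE]
    if (nrow(sub) == 0L) next
    if (sum(sub$education == "primary") == 0L) {
      stop(sprintf("education_gradient: no primary-education reference group for sex %s", sx))
    }
    counts <- table(factor(sub$education,
                           levels = setdiff(EDUCATION_LEVELS, "unknown")))
    keep_levels <- names(counts)[counts >= min_n]
    if (!"primary" %in% keep_levels) {
      stop(sprintf("education_gradient: primary reference below min_n for sex %s", sx))
    }
    dropped <- setdiff(names(counts)[counts > 0], keep_levels)
    if (length(dropped) > 0L) {
      warning(sprintf("education_gradient: sex %s levels below min_n omitted: %s",
                      sx, paste(dropped, collapse = ", ")))
    }
    sub <- sub[sub$education %in% keep_levels, , drop = FALSE]
    sub$education <- factor(as.character(sub$education),
                            levels = c("primary", setdiff(keep_levels, "primary")))
    fit <- stats::lm(rlrs ~ education, data = sub)
    V <- if (robust) sandwich::vcovHC(fit, type = "HC3") else stats::vcov(fit)
    se_all <- sqrt(diag(V))
    for (lev in setdiff(levels(sub$education), "primary")) {
      term <- paste0("education", lev)
      b <- unname(stats::coef(fit)[term])
      se <- unname(se_all[term])
      rows[[length(rows) + 1L]] <- selgrad_row(
        "EDUCATION", sx, lev, min(sub$birth_year), max(sub$birth_year),
        "linear", b, se, b + c(-1, 1) * crit * se, n = nrow(sub))
    }
    fits[[sx]] <- fit
  }
  selgrad_table(rows, fits)
}

#' Write a gradient table to CSV
#'
#' Serializes a [gradient_by_stratum()]/[gradient_by_cohort()]/
#' [education_gradient()] table with floating-point values rounded to 12
#' significant digits so outputs are byte-stable across platforms. Gamma
#' columns are empty for linear-model rows.
#'
#' @param x A `selgrad_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gradients <- function(x, path) {
  stopifnot(inherits(x, "selgrad_table"))
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n" &
    !startsWith(names(out), "cohort")
  out[num] <- lapply(out[num], signif, digits = 12)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
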