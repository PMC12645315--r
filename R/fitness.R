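# Relative fitness and cohort standardization.

#' Cohort mean offspring counts
#'
#' Mean number of children per sex-by-birth-year cohort, computed over *all*
#' individuals of the cohort: childless individuals and individuals with
#' unknown education are included. These means are the denominators of
#' relative lifetime reproductive success.
#'
#' @param reg A filtered register `data.frame` (see [apply_filters()]).
#' @param parous_only Use only parous individuals in the denominator mean
#'   (sensitivity option; the default, `FALSE`, is the full-cohort mean).
#' @return A `data.frame` with columns `sex`, `birth_year`, `mean_children`,
#'   `n`, and logical `degenerate` flagging cohorts whose mean is zero
#'   (all members childless); such cohorts are dropped from downstream
#'   analyses with a warning.
#' @export
cohort_mean_fitness <- function(reg, parous_only = FALSE) {
  validate_register(reg)
  base <- if (parous_only) reg[reg$n_children >= 1L, , drop = FALSE] else reg
  if (nrow(base) == 0L) {
    return(data.frame(sex = factor(character(), levels = SEX_LEVELS),
                      birth_year = integer(), mean_children = numeric(),
                      n = integer(), degenerate = logical()))
  }
  agg <- stats::aggregate(n_children ~ sex + birth_year, data = base,
                          FUN = mean, drop = TRUE)
  cnt <- stats::aggregate(n_children ~ sex + birth_year, data = base,
                          FUN = length)
  out <- merge(agg, cnt, by = c("sex", "birth_year"),
               suffixes = c("", "_n"), sort = TRUE)
  names(out)[names(out) == "n_children"] <- "mean_children"
  names(out)[names(out) == "n_children_n"] <- "n"
  out$degenerate <- out$mean_children <= 0
  if (any(out$degenerate)) {
    warning(sprintf("%d cohort(s) have zero mean offspring count; rLRS is undefined there and those cohorts are dropped downstream",
                    sum(out$degenerate)))
  }
  out[order(out$sex, out$birth_year), , drop = FALSE]
}

#' Relative lifetime reproductive success (rLRS)
#'
#' Divides each individual's offspring count by the mean offspring count of
#' their own sex-by-birth-year cohort, so the mean rLRS within every retained
#' cohort is exactly 1 (to floating tolerance). Individuals in degenerate
#' (all-childless) cohorts are excluded with a message.
#'
#' @param reg A filtered register `data.frame`.
#' @param cohort_means Output of [cohort_mean_fitness()] over the same
#'   records; computed on the fly when omitted.
#' @param quiet Suppress the exclusion message.
#' @return `reg` with a numeric `rlrs` column appended, restricted to
#'   individuals in non-degenerate cohorts.
#' @export
relative_fitness <- function(reg, cohort_means = NULL, quiet = FALSE) {
  validate_register(reg)
  if (is.null(cohort_means)) {
    cohort_means <- suppressWarnings(cohort_mean_fitness(reg))
  }
  key <- paste(reg$sex, reg$birth_year)
  mkey <- paste(cohort_means$sex, cohort_means$birth_year)
  idx <- match(key, mkey)
  if (anyNA(idx)) {
    stop("cohort_means does not cover every (sex, birth_year) present in the records")
  }
  mean_w <- cohort_means$mean_children[idx]
  keep <- !cohort_means$degenerate[idx]
  if (!all(keep) && !quiet) {
    message(sprintf("relative_fitness: excluded %d individual(s) in %d degenerate cohort(s)",
                    sum(!keep), length(unique(key[!keep]))))
  }
  out <- reg[keep, , drop = FALSE]
  out$rlrs <- out$n_children / mean_w[keep]
  rownames(out) <- NULL
  out
}

#' Cohort-standardized trait values (z-scores)
#'
#' Standardizes a reproductive-timing trait to mean 0 and sample standard
#' deviation 1 (n-1 denominator) within each standardization group. The
#' default group is the sex-by-birth-year cohort with all education levels
#' pooled; `scope = "stratum"` standardizes within sex-by-education-by-cohort
#' groups instead (sensitivity option). Groups with fewer than two members or
#' zero variance are dropped with a warning. Individuals for whom the trait is
#' undefined (childless for AFB/ALB; parity < 2 for IBI) are dropped silently.
#'
#' @param reg A register `data.frame` carrying timing columns (see
#'   [derive_timing()]; they are derived on the fly when missing).
#' @param trait One of `"AFB"`, `"ALB"`, `"IBI"`.
#' @param scope `"cohort"` (default) or `"stratum"`.
#' @return `reg` rows for which the trait is defined and the group retained,
#'   with a numeric `z` column appended.
#' @export
standardize_trait <- function(reg, trait = c("AFB", "ALB", "IBI"),
                              scope = c("cohort", "stratum")) {
  trait <- match.arg(trait)
  scope <- match.arg(scope)
  if (!all(c("afb", "alb", "ibi") %in% names(reg))) reg <- derive_timing(reg)
  x <- reg[[trait_column(trait)]]
  keep <- !is.na(x)
  out <- reg[keep, , drop = FALSE]
  x <- x[keep]
  grp <- if (scope == "cohort") {
    paste(out$sex, out$birth_year)
  } else {
    paste(out$sex, out$education, out$birth_year)
  }
  n_g <- stats::ave(x, grp, FUN = length)
  mu_g <- stats::ave(x, grp, FUN = mean)
  sd_g <- stats::ave(x, grp, FUN = stats::sd)
  ok <- n_g >= 2 & !is.na(sd_g) & sd_g > 0
  if (any(!ok)) {
    warning(sprintf("standardize_trait: dropped %d group(s) with <2 members or zero variance (%d individual(s))",
                    length(unique(grp[!ok])), sum(!ok)))
  }
  out <- out[ok, , drop = FALSE]
  out$z <- (x[ok] - mu_g[ok]) / sd_g[ok]
  rownames(out) <- NULL
  out
}
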