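# Descriptive cohort-level trends: means with 95% CI per birth cohort.

SUMMARY_VARIABLES <- c("offspring", "AFB", "ALB", "IBI")

#' Cohort means with confidence intervals
#'
#' Per-birth-cohort averages of offspring number or a timing trait, by sex and
#' optionally education, with a 95% confidence interval. Eligibility follows
#' the variable: everyone for `offspring`, parous individuals for `AFB`/`ALB`,
#' and parity >= 2 for `IBI`. Groups with fewer than two eligible members are
#' omitted.
#'
#' @param reg A filtered register `data.frame`.
#' @param variable One of `"offspring"`, `"AFB"`, `"ALB"`, `"IBI"`.
#' @param by_education Also stratify by education (unknown kept as its own
#'   stratum); otherwise the education label is `"all"`.
#' @param ci `"normal"` for the normal-approximation interval
#'   `mean +/- 1.96 * SD/sqrt(n)` (default) or `"t"` for the t-based interval
#'   (preferable at small n).
#' @param conf_level Confidence level.
#' @return A `data.frame` with columns `variable, sex, education, birth_year,
#'   mean, ci_low, ci_high, n`, ordered by sex, education, cohort.
#' @export
cohort_summary <- function(reg, variable = c("offspring", "AFB", "ALB", "IBI"),
                           by_education = FALSE, ci = c("normal", "t"),
                           conf_level = 0.95) {
  variable <- match.arg(variable)
  ci <- match.arg(ci)
  if (variable != "offspring" && !all(c("afb", "alb", "ibi") %in% names(reg))) {
    reg <- derive_timing(reg)
  }
  x <- switch(variable,
              offspring = as.numeric(reg$n_children),
              reg[[trait_column(variable)]])
  keep <- !is.na(x)
  sub <- reg[keep, , drop = FALSE]
  x <- x[keep]
  edu <- if (by_education) as.character(sub$education) else rep("all", nrow(sub))
  key <- paste(sub$sex, edu, sub$birth_year, sep = "\r")
  n <- tapply(x, key, length)
  mu <- tapply(x, key, mean)
  sdv <- tapply(x, key, stats::sd)
  ok <- n >= 2
  parts <- do.call(rbind, strsplit(names(n)[ok], "\r", fixed = TRUE))
  n <- as.integer(n[ok]); mu <- as.numeric(mu[ok]); sdv <- as.numeric(sdv[ok])
  half <- if (ci == "normal") {
    stats::qnorm(1 - (1 - conf_level) / 2) * sdv / sqrt(n)
  } else {
    stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * sdv / sqrt(n)
  }
  out <- data.frame(variable = variable,
                    sex = parts[, 1], education = parts[, 2],
                    birth_year = as.integer(parts[, 3]),
                    mean = mu, ci_low = mu - half, ci_high = mu + half,
                    n = n, stringsAsFactors = FALSE)
  out <- out[order(out$sex, out$education, out$birth_year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohorts attaining extreme group means
#'
#' For each (sex, education) group in a [cohort_summary()] table, reports the
#' birth cohorts with the maximum and minimum mean. Ties are broken toward the
#' earlier cohort so the output is deterministic.
#'
#' @param summaries A [cohort_summary()] table (typically for
#'   `variable = "offspring"`).
#' @return A `data.frame` with columns `variable, sex, education, max_cohort,
#'   max_mean, min_cohort, min_mean, overall_mean`.
#' @export
extreme_cohorts <- function(summaries) {
  req <- c("variable", "sex", "education", "birth_year", "mean", "n")
  stopifnot(all(req %in% names(summaries)))
  key <- paste(summaries$variable, summaries$sex, summaries$education,
               sep = "\r")
  rows <- lapply(unique(key), function(k) {
    g <- summaries[key == k, , drop = FALSE]
    g <- g[order(g$birth_year), , drop = FALSE]  # earlier cohort wins ties
    imax <- which.max(g$mean)
    imin <- which.min(g$mean)
    data.frame(variable = g$variable[1], sex = g$sex[1],
               education = g$education[1],
               max_cohort = g$birth_year[imax], max_mean = g$mean[imax],
               min_cohort = g$birth_year[imin], min_mean = g$mean[imin],
               overall_mean = sum(g$mean * g$n) / sum(g$n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort-summary table to CSV
#'
#' @param x A [cohort_summary()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1)) & !names(x) %in% c("n", "birth_year")
  x[num] <- lapply(x[num], signif, digits = 12)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
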