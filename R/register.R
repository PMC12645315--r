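#' @keywords internal
"_PACKAGE"

# Register column dictionary. Empty CSV field = value absent.
REGISTER_COLUMNS <- c(
  "person_id", "sex", "birth_year", "education", "n_children",
  "first_child_year", "last_child_year", "age_at_death"
)

SEX_LEVELS <- c("F", "M")
EDUCATION_LEVELS <- c("primary", "secondary", "vocational", "tertiary", "unknown")
TRAIT_NAMES <- c("AFB", "ALB", "IBI")

#' Read a register-style CSV of individual reproductive histories
#'
#' One row per individual with columns
#' `person_id,sex,birth_year,education,n_children,first_child_year,last_child_year,age_at_death`.
#' Empty fields denote absent values and are returned as `NA`; sentinel numbers
#' are never used. Row order is preserved.
#'
#' @param path Path to a UTF-8, comma-delimited CSV file with the header above.
#' @return A `data.frame` with typed columns: character `person_id`, factor
#'   `sex` (levels `F`, `M`), integer `birth_year`, factor `education`
#'   (levels `primary`, `secondary`, `vocational`, `tertiary`, `unknown`),
#'   integer `n_children`, integer `first_child_year`, `last_child_year`,
#'   `age_at_death` (the last three `NA` when absent).
#' @details Records are validated on read: unknown sex or education tokens and
#'   violations of the parity/child-year invariants (a parous record must carry
#'   both child years, `last_child_year >= first_child_year`,
#'   `first_child_year > birth_year`, a single child implies equal first and
#'   last years) raise errors naming the offending row.
#' @seealso [write_register()], [apply_filters()], [derive_timing()]
#' @export
read_register <- function(path) {
  if (!file.exists(path)) stop("register file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  missing_cols <- setdiff(REGISTER_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("register header is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[REGISTER_COLUMNS]

  int_field <- function(x, field) {
    x <- trimws(x)
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad) > 0L) {
      stop(sprintf("row %d: field '%s' has non-integer value '%s'",
                   bad[1], field, x[bad[1]]))
    }
    out[!nzchar(x)] <- NA_integer_
    out
  }

  sex <- trimws(raw$sex)
  bad <- which(!sex %in% SEX_LEVELS)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: field 'sex' has unknown token '%s'", bad[1], sex[bad[1]]))
  }
  education <- trimws(raw$education)
  bad <- which(!education %in% EDUCATION_LEVELS)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: field 'education' has unknown token '%s'",
                 bad[1], education[bad[1]]))
  }

  reg <- data.frame(
    person_id = raw$person_id,
    sex = factor(sex, levels = SEX_LEVELS),
    birth_year = int_field(raw$birth_year, "birth_year"),
    education = factor(education, levels = EDUCATION_LEVELS),
    n_children = int_field(raw$n_children, "n_children"),
    first_child_year = int_field(raw$first_child_year, "first_child_year"),
    last_child_year = int_field(raw$last_child_year, "last_child_year"),
    age_at_death = int_field(raw$age_at_death, "age_at_death"),
    stringsAsFactors = FALSE
  )
  validate_register(reg)
  reg
}

#' Validate register records against the schema invariants
#'
#' Checks the record-level invariants: non-negative `n_children`, child years
#' present exactly for parous individuals, `last_child_year >= first_child_year`,
#' equal first/last years for single-child parents, and
#' `first_child_year > birth_year`.
#'
#' @param reg A register `data.frame` (see [read_register()]).
#' @return `reg`, invisibly. Errors name the first offending row.
#' @export
validate_register <- function(reg) {
  stopifnot(is.data.frame(reg))
  missing_cols <- setdiff(REGISTER_COLUMNS, names(reg))
  if (length(missing_cols) > 0L) {
    stop("register is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  fail <- function(idx, msg) {
    if (length(idx) > 0L) stop(sprintf("row %d: %s", idx[1], msg))
  }
  fail(which(is.na(reg$birth_year)), "birth_year is absent")
  fail(which(is.na(reg$n_children) | reg$n_children < 0L),
       "n_children must be a non-negative integer")
  parous <- reg$n_children >= 1L
  fail(which(parous & (is.na(reg$first_child_year) | is.na(reg$last_child_year))),
       "parous record lacks first/last child year")
  fail(which(!parous & (!is.na(reg$first_child_year) | !is.na(reg$last_child_year))),
       "childless record carries child years")
  both <- parous & !is.na(reg$first_child_year) & !is.na(reg$last_child_year)
  fail(which(both & reg$last_child_year < reg$first_child_year),
       "last_child_year precedes first_child_year")
  fail(which(both & reg$n_children == 1L &
               reg$last_child_year != reg$first_child_year),
       "single-child record has unequal first/last child years")
  fail(which(both & reg$first_child_year <= reg$birth_year),
       "first_child_year must fall after the parent's birth_year")
  fail(which(!is.na(reg$age_at_death) & reg$age_at_death < 0L),
       "age_at_death must be non-negative")
  invisible(reg)
}

#' Write register records to CSV
#'
#' Inverse of [read_register()]: absent values become empty fields, so a
#' write/read round trip reproduces all fields exactly.
#'
#' @param reg A register `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_register <- function(reg, path) {
  validate_register(reg)
  out <- reg[REGISTER_COLUMNS]
  out$sex <- as.character(out$sex)
  out$education <- as.character(out$education)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Filtering policy for register analyses
#'
#' The study window keeps birth cohorts 1925--1977 and individuals alive by
#' their 15th year of age. Death before 15 is encoded as a recorded
#' `age_at_death < min_survival_age`; an unrecorded age at death counts as
#' survival.
#'
#' @param min_birth_year,max_birth_year Inclusive birth-cohort window.
#' @param min_survival_age Minimum age (whole years, inclusive) an individual
#'   must have survived to; individuals with recorded `age_at_death` below it
#'   are removed.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_birth_year = 1925L, max_birth_year = 1977L,
                          min_survival_age = 15L) {
  min_birth_year <- as.integer(min_birth_year)
  max_birth_year <- as.integer(max_birth_year)
  min_survival_age <- as.integer(min_survival_age)
  if (min_birth_year > max_birth_year) {
    stop("min_birth_year must not exceed max_birth_year")
  }
  if (min_survival_age < 0L) stop("min_survival_age must be >= 0")
  structure(list(min_birth_year = min_birth_year,
                 max_birth_year = max_birth_year,
                 min_survival_age = min_survival_age),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat(sprintf("filter_policy: birth cohorts %d-%d, alive by age %d\n",
              x$min_birth_year, x$max_birth_year, x$min_survival_age))
  invisible(x)
}

#' Apply the cohort-window and survival filters
#'
#' Retains records with `min_birth_year <= birth_year <= max_birth_year` and
#' (`age_at_death` absent or `>= min_survival_age`). Idempotent. The number of
#' removals per rule is reported via `message()` unless `quiet = TRUE`.
#'
#' @param reg A register `data.frame`.
#' @param policy A [filter_policy()].
#' @param quiet Suppress the removal-count messages.
#' @return The filtered `data.frame` (possibly empty).
#' @export
apply_filters <- function(reg, policy = filter_policy(), quiet = FALSE) {
  validate_register(reg)
  stopifnot(inherits(policy, "filter_policy"))
  in_window <- reg$birth_year >= policy$min_birth_year &
    reg$birth_year <= policy$max_birth_year
  survived <- is.na(reg$age_at_death) |
    reg$age_at_death >= policy$min_survival_age
  if (!quiet) {
    message(sprintf("apply_filters: removed %d outside cohorts %d-%d, %d dead before age %d",
                    sum(!in_window), policy$min_birth_year, policy$max_birth_year,
                    sum(in_window & !survived), policy$min_survival_age))
  }
  out <- reg[in_window & survived, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive reproductive-timing traits
#'
#' Adds the timing traits to a register frame: age at first birth
#' `afb = first_child_year - birth_year`, age at last birth
#' `alb = last_child_year - birth_year` (whole years; the register carries
#' birth years only), and the average interbirth interval
#' `ibi = (alb - afb) / n_children`, defined only for individuals with at
#' least two children. Childless individuals get `NA` for all three;
#' single-child parents get `NA` for `ibi` (the formula presumes an interval
#' exists) and are excluded from IBI analyses.
#'
#' @param reg A register `data.frame`.
#' @return `reg` with numeric columns `afb`, `alb`, `ibi` appended.
#' @export
derive_timing <- function(reg) {
  validate_register(reg)
  afb <- as.numeric(reg$first_child_year - reg$birth_year)
  alb <- as.numeric(reg$last_child_year - reg$birth_year)
  ibi <- ifelse(reg$n_children >= 2L, (alb - afb) / reg$n_children, NA_real_)
  reg$afb <- afb
  reg$alb <- alb
  reg$ibi <- ibi
  reg
}

# Column holding a timing trait, given its conventional name.
trait_column <- function(trait) {
  trait <- match.arg(trait, TRAIT_NAMES)
  c(AFB = "afb", ALB = "alb", IBI = "ibi")[[trait]]
}
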