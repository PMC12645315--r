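# Small in-code fixtures shared across test files.

# Build a register data.frame from compact per-person arguments.
make_register <- function(person_id, sex, birth_year, education = "primary",
                          n_children = 0L, first_child_year = NA_integer_,
                          last_child_year = NA_integer_,
                          age_at_death = NA_integer_) {
  data.frame(
    person_id = as.character(person_id),
    sex = factor(sex, levels = c("F", "M")),
    birth_year = as.integer(birth_year),
    education = factor(education,
                       levels = c("primary", "secondary", "vocational",
                                  "tertiary", "unknown")),
    n_children = as.integer(n_children),
    first_child_year = as.integer(first_child_year),
    last_child_year = as.integer(last_child_year),
    age_at_death = as.integer(age_at_death),
    stringsAsFactors = FALSE
  )
}

# One-cohort register with given offspring counts (used for rLRS identities).
cohort_register <- function(counts, sex = "F", birth_year = 1950,
                            education = "primary", afb = 20, ibi = 2) {
  n <- length(counts)
  first <- ifelse(counts >= 1, birth_year + afb, NA_integer_)
  last <- ifelse(counts >= 1, first + ifelse(counts >= 2, ibi * counts, 0),
                 NA_integer_)
  make_register(paste0("p", seq_len(n)), rep(sex, n), rep(birth_year, n),
                rep(education, n), counts, first, last)
}

# Deterministic synthetic (rlrs, z) pairs with known OLS truth plus noise.
noisy_pairs <- function(n, a = 1, b = -0.2, c2 = 0, sd = 0.3, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  rlrs <- a + b * z + c2 * z^2 + rnorm(n, sd = sd)
  list(z = z, rlrs = rlrs)
}
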