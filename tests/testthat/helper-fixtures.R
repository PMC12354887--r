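# Small in-code fixtures shared across test files.

# A hand-written event table: two patients, mixed code systems.
tiny_events <- function() {
  data.frame(
    patient_id = c("A", "A", "A", "B", "B"),
    age_days = c(400L, 4000L, 410L, 800L, 805L),
    code = c("D1", "D1", "D2", "P1", "D1"),
    code_system = c("ICD10", "ICD10", "ICD9", "CPT4", "ICD10"),
    stringsAsFactors = FALSE
  )
}

tiny_map <- function() {
  data.frame(
    code = c("D1", "D2", "D3"),
    code_system = c("ICD10", "ICD9", "ICD10"),
    phecode = c("10.0", "10.0", "20.0"),
    disease_class = c("digestive", "digestive", "neoplasms"),
    stringsAsFactors = FALSE
  )
}

# Events with one code per (patient, year) pattern, years given explicitly.
events_from_years <- function(patient_id, years, codes) {
  data.frame(
    patient_id = patient_id,
    age_days = as.integer(ceiling(years * 365.25)),
    code = codes,
    code_system = "ICD10",
    stringsAsFactors = FALSE
  )
}

# Deterministic year-embedding fixture: n patients x y years, d dims.
toy_year_embeddings <- function(n_pat = 10L, n_yr = 4L, d = 5L, seed = 1L) {
  set.seed(seed)
  pid <- rep(sprintf("P%02d", seq_len(n_pat)), each = n_yr)
  yr <- rep(seq_len(n_yr) + 39L, times = n_pat)
  year_embeddings(matrix(rnorm(n_pat * n_yr * d), n_pat * n_yr, d), pid, yr)
}

# Finite-difference gradient of a scalar-valued forward function with
# respect to one parameter node.
numeric_grad <- function(fwd, par, eps = 1e-6) {
  g <- par$value * 0
  for (i in seq_along(par$value)) {
    par$value[i] <- par$value[i] + eps
    lp <- fwd()$value[1]
    par$value[i] <- par$value[i] - 2 * eps
    lm <- fwd()$value[1]
    par$value[i] <- par$value[i] + eps
    g[i] <- (lp - lm) / (2 * eps)
  }
  g
}

expect_grad_matches <- function(fwd, par, tol = 1e-6) {
  ad <- asNamespace("cohortvec")
  par$grad <- NULL
  loss <- fwd()
  ad$ad_backward(loss)
  expect_lt(max(abs(numeric_grad(fwd, par) - par$grad)), tol)
}
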