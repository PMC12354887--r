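# Synthetic longitudinal EHR cohorts with planted structure.
#
# Real coded-EHR cohorts of the kind this package targets are access
# restricted, so every downstream stage is exercised against simulated
# cohorts in which the quantities of interest -- latent comorbidity
# subtypes, onset ages, per-patient code signatures, subtype-differential
# mortality -- are planted and therefore known exactly.

#' Configuration for the synthetic EHR cohort generator
#'
#' Defines the study conditions for a simulated cohort: cohort size,
#' vocabulary sizes, number of latent comorbidity subtypes, follow-up and
#' code-density distributions, planted signal strengths and mortality
#' hazards.
#'
#' The generative model: each patient is observed from a uniform adult entry
#' age for `1 + Poisson(followup_years_mean - 1)` years (truncated at
#' `max_followup_years`). Background codes are drawn per year from a Zipf
#' (power-law) popularity distribution over the vocabulary, weighted by a
#' per-code Gaussian age profile, so code usage is both heavy-tailed and
#' age-structured. Each patient carries `n_signature_codes_per_patient`
#' personal signature codes placed in at least 90% of their years. Each
#' patient belongs to one latent subtype; an index-disease onset age is
#' drawn from the subtype's Normal onset distribution and patients whose
#' draw falls outside their observation window are non-cases with no
#' disease process. Cases receive a diagnosis code of `index_phecode` at
#' onset, accrue their subtype's comorbidity phecodes with probability
#' `emergent_code_prob` per phecode per year from `prodromal_years` before
#' onset onwards, and die with an exponential post-onset hazard
#' `mortality_hazard_per_subtype`, which truncates follow-up.
#'
#' @param n_patients Number of patients.
#' @param vocab_size_dx,vocab_size_px Number of distinct diagnosis and
#'   procedure codes in the synthetic vocabulary.
#' @param n_phecodes Number of phecodes the diagnosis vocabulary maps onto.
#' @param n_subtypes Number of latent comorbidity subtypes.
#' @param followup_years_mean Mean follow-up length in years.
#' @param max_followup_years Truncation point for follow-up length.
#' @param codes_per_year_mean Mean number of newly drawn background codes
#'   per year (Poisson).
#' @param bg_persist_prob Probability that a background code recurs in the
#'   following year, emulating multi-year episodes of care; this is what
#'   makes consecutive years of one patient more similar than distant
#'   years.
#' @param n_signature_codes_per_patient Personal signature codes per patient.
#' @param index_phecode Phecode id of the index disease.
#' @param subtype_onset_age_means Numeric vector, mean onset age (years) per
#'   subtype.
#' @param onset_age_sd Standard deviation of onset age (years).
#' @param subtype_comorbidity_sets List of character vectors of phecode ids,
#'   one per subtype; pairwise disjoint by construction of the default.
#' @param comorbidity_set_size Phecodes per subtype set when defaults are
#'   generated.
#' @param emergent_code_prob Probability per (phecode, year) that a case
#'   emits a code of a subtype comorbidity phecode in an at-risk year.
#' @param prodromal_years Years before clinical onset at which comorbidity
#'   accrual begins.
#' @param index_recur_prob Probability the index diagnosis code recurs in
#'   each post-onset year.
#' @param mortality_hazard_per_subtype Exponential death hazard (events/year
#'   from onset) per subtype.
#' @param entry_age_range Observation entry age, sampled uniformly (years).
#' @param zipf_exponent Exponent of the code-popularity power law.
#' @param demographic_levels Named list of category labels for gender, race,
#'   ethnicity and site.
#' @param seed Integer seed; identical configurations produce identical
#'   cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' head(cohort$events)
sim_config <- function(n_patients = 300L,
                       vocab_size_dx = 120L,
                       vocab_size_px = 30L,
                       n_phecodes = 40L,
                       n_subtypes = 3L,
                       followup_years_mean = 12,
                       max_followup_years = 25L,
                       codes_per_year_mean = 10,
                       bg_persist_prob = 0.5,
                       n_signature_codes_per_patient = 3L,
                       index_phecode = "1.0",
                       subtype_onset_age_means = NULL,
                       onset_age_sd = 4,
                       subtype_comorbidity_sets = NULL,
                       comorbidity_set_size = 5L,
                       emergent_code_prob = 0.9,
                       prodromal_years = 2L,
                       index_recur_prob = 0.7,
                       mortality_hazard_per_subtype = NULL,
                       entry_age_range = c(40, 50),
                       zipf_exponent = 1.1,
                       demographic_levels = list(
                         gender = c("F", "M"),
                         race = c("white", "black", "asian", "other"),
                         ethnicity = c("not_hispanic", "hispanic"),
                         site = c("site_A", "site_B", "site_C")
                       ),
                       seed = 1L) {
  if (n_patients < 0L) stop("n_patients must be non-negative")
  if (n_subtypes < 1L) stop("n_subtypes must be >= 1")
  if (n_patients > 0L && (vocab_size_dx < 1L || n_phecodes < 1L))
    stop("configuration error: empty diagnosis vocabulary")
  stopifnot(emergent_code_prob >= 0, emergent_code_prob <= 1,
            index_recur_prob >= 0, index_recur_prob <= 1)
  if (is.null(subtype_onset_age_means))
    subtype_onset_age_means <- 50 + 4 * (seq_len(n_subtypes) - 1)
  if (length(subtype_onset_age_means) != n_subtypes)
    stop("subtype_onset_age_means must have one entry per subtype")
  if (is.null(mortality_hazard_per_subtype))
    mortality_hazard_per_subtype <- 0.04 * 2^(seq_len(n_subtypes) - 1)
  if (length(mortality_hazard_per_subtype) != n_subtypes)
    stop("mortality_hazard_per_subtype must have one entry per subtype")
  phecode_ids <- sprintf("%.1f", seq_len(n_phecodes))
  if (is.null(subtype_comorbidity_sets)) {
    # disjoint ("separable") sets, skipping the index phecode
    pool <- setdiff(phecode_ids, index_phecode)
    need <- n_subtypes * comorbidity_set_size
    if (length(pool) < need)
      stop("n_phecodes too small for disjoint comorbidity sets")
    subtype_comorbidity_sets <- split(pool[seq_len(need)],
                                      rep(seq_len(n_subtypes),
                                          each = comorbidity_set_size))
  }
  if (length(subtype_comorbidity_sets) != n_subtypes)
    stop("subtype_comorbidity_sets must have one set per subtype")
  cfg <- list(
    n_patients = as.integer(n_patients),
    vocab_size_dx = as.integer(vocab_size_dx),
    vocab_size_px = as.integer(vocab_size_px),
    n_phecodes = as.integer(n_phecodes),
    n_subtypes = as.integer(n_subtypes),
    followup_years_mean = followup_years_mean,
    max_followup_years = as.integer(max_followup_years),
    codes_per_year_mean = codes_per_year_mean,
    bg_persist_prob = bg_persist_prob,
    n_signature_codes_per_patient = as.integer(n_signature_codes_per_patient),
    index_phecode = index_phecode,
    subtype_onset_age_means = subtype_onset_age_means,
    onset_age_sd = onset_age_sd,
    subtype_comorbidity_sets = lapply(subtype_comorbidity_sets, as.character),
    emergent_code_prob = emergent_code_prob,
    prodromal_years = as.integer(prodromal_years),
    index_recur_prob = index_recur_prob,
    mortality_hazard_per_subtype = mortality_hazard_per_subtype,
    entry_age_range = entry_age_range,
    zipf_exponent = zipf_exponent,
    demographic_levels = demographic_levels,
    phecode_ids = phecode_ids,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Synthetic code identifiers with ICD/CPT-like formatting.
sim_dx_codes <- function(n) {
  i <- seq_len(n)
  sprintf("%s%02d.%d", LETTERS[(i - 1L) %% 26L + 1L], (i - 1L) %/% 26L, i %% 10L)
}
sim_px_codes <- function(n) sprintf("%05d", 10000L + seq_len(n))

#' Build the synthetic code-to-phecode map
#'
#' Assigns each synthetic diagnosis code to exactly one phecode
#' (round-robin, so the map is surjective onto the phecode universe) and
#' each phecode to a disease class. Procedure codes map to no phecode and
#' are absent from the map. Construction is deterministic given the
#' configuration.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `code`, `code_system`, `phecode`,
#'   `disease_class`.
#' @export
generate_phecode_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  classes <- c("neoplasms", "circulatory system", "endocrine/metabolic",
               "digestive", "genitourinary", "infectious diseases",
               "musculoskeletal", "respiratory")
  dx <- sim_dx_codes(config$vocab_size_dx)
  i <- seq_along(dx)
  phe <- config$phecode_ids[(i - 1L) %% config$n_phecodes + 1L]
  pj <- match(phe, config$phecode_ids)
  data.frame(
    code = dx,
    code_system = ifelse(i %% 2L == 0L, "ICD9", "ICD10"),
    phecode = phe,
    disease_class = classes[(pj - 1L) %% length(classes) + 1L],
    stringsAsFactors = FALSE
  )
}

# dx codes carrying a given phecode, used when the simulator emits a
# phenotype.
codes_for_phecode <- function(map, phecode) map$code[map$phecode == phecode]

#' Generate a synthetic coded EHR cohort
#'
#' Draws a full cohort under the generative model described in
#' [sim_config()]: events, demographics, post-onset survival records and the
#' ground truth (subtype, onset, death, signature codes) for every patient.
#' Identical configurations (including the seed) reproduce the cohort
#' exactly.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_cohort` with elements `events` (patient_id,
#'   age_days, code, code_system; sorted), `demographics`, `survival`
#'   (patient_id, time_years from onset, event), `truth` (a `data.frame`
#'   with subtype, onset_age_years, death_age_years and a list-column of
#'   signature codes) and `phecode_map`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- generate_phecode_map(config)
  demo_cols <- config$demographic_levels
  if (config$n_patients == 0L) {
    empty_events <- data.frame(patient_id = character(), age_days = integer(),
                               code = character(), code_system = character(),
                               stringsAsFactors = FALSE)
    out <- list(
      events = empty_events,
      demographics = data.frame(patient_id = character(),
                                birth_decade = integer(),
                                gender = character(), race = character(),
                                ethnicity = character(), site = character(),
                                stringsAsFactors = FALSE),
      survival = data.frame(patient_id = character(), time_years = numeric(),
                            event = integer(), stringsAsFactors = FALSE),
      truth = data.frame(patient_id = character(), subtype = integer(),
                         onset_age_years = numeric(),
                         death_age_years = numeric(),
                         stringsAsFactors = FALSE),
      phecode_map = map, config = config
    )
    out$truth$signature_codes <- list()
    class(out) <- "sim_cohort"
    return(out)
  }
  set.seed(config$seed)

  dx <- sim_dx_codes(config$vocab_size_dx)
  px <- sim_px_codes(config$vocab_size_px)
  vocab <- c(dx, px)
  vocab_system <- c(map$code_system, rep("CPT4", length(px)))
  nv <- length(vocab)
  # heavy-tailed popularity in a random order, plus a Gaussian age profile
  pop <- (seq_len(nv))^(-config$zipf_exponent)
  pop <- sample(pop)
  age_center <- stats::runif(nv, 0, 90)
  age_sd <- stats::runif(nv, 10, 25)
  phe_codes <- lapply(config$phecode_ids, function(p) codes_for_phecode(map, p))
  names(phe_codes) <- config$phecode_ids
  index_codes <- phe_codes[[config$index_phecode]]
  if (length(index_codes) == 0L) stop("index_phecode not covered by the map")
  # codes representing planted disease processes (the index disease and the
  # subtype comorbidity sets) arise only from those processes, never as
  # background noise, so case/control and subtype ground truth is exact
  planted_phe <- unique(c(config$index_phecode,
                          unlist(config$subtype_comorbidity_sets)))
  planted_codes <- unlist(phe_codes[planted_phe])
  pop[vocab %in% planted_codes] <- 0

  ids <- sprintf("PT%05d", seq_len(config$n_patients))
  subtype <- sample.int(config$n_subtypes, config$n_patients, replace = TRUE) - 1L
  entry_age <- stats::runif(config$n_patients, config$entry_age_range[1],
                            config$entry_age_range[2])
  n_years <- pmin(1L + stats::rpois(config$n_patients,
                                    max(config$followup_years_mean - 1, 0)),
                  config$max_followup_years)
  onset_draw <- stats::rnorm(config$n_patients,
                             config$subtype_onset_age_means[subtype + 1L],
                             config$onset_age_sd)

  ev_pid <- vector("list", config$n_patients)
  ev_age <- vector("list", config$n_patients)
  ev_code <- vector("list", config$n_patients)
  onset_age <- rep(NA_real_, config$n_patients)
  death_age <- rep(NA_real_, config$n_patients)
  sig_list <- vector("list", config$n_patients)
  surv_time <- numeric(0); surv_id <- character(0); surv_event <- integer(0)

  for (i in seq_len(config$n_patients)) {
    start_year <- floor(entry_age[i])
    end_year <- start_year + n_years[i] - 1L
    # case if the onset draw lands strictly inside the observation window
    is_case <- onset_draw[i] >= start_year + 1 && onset_draw[i] <= end_year
    oy <- if (is_case) floor(onset_draw[i]) else NA_integer_
    if (is_case) {
      onset_age[i] <- oy
      h <- config$mortality_hazard_per_subtype[subtype[i] + 1L]
      dtime <- stats::rexp(1L, rate = h)
      if (oy + dtime <= end_year + 1) {
        death_age[i] <- oy + dtime
        end_year <- floor(death_age[i])          # no events after death
      }
      surv_id <- c(surv_id, ids[i])
      obs_end <- min(end_year + 1L, start_year + n_years[i])
      t_obs <- if (!is.na(death_age[i])) death_age[i] - oy else obs_end - oy
      surv_time <- c(surv_time, max(t_obs, 1 / 365.25))
      surv_event <- c(surv_event, as.integer(!is.na(death_age[i])))
    }
    years <- start_year:end_year
    ny <- length(years)
    sig <- sample(setdiff(vocab, planted_codes),
                  config$n_signature_codes_per_patient)
    sig_list[[i]] <- sig

    codes <- character(0); ages <- numeric(0)
    # each signature code is present in >= 90% of the patient's years
    for (s in sig) {
      yrs <- years[sample.int(ny, ceiling(0.9 * ny))]
      codes <- c(codes, rep(s, length(yrs)))
      ages <- c(ages, yrs + stats::runif(length(yrs)))
    }
    carried <- integer(0)
    for (y in years) {
      nbg <- stats::rpois(1L, config$codes_per_year_mean)
      bg <- integer(0)
      if (nbg > 0L) {
        w <- pop * stats::dnorm(y + 0.5, age_center, age_sd)
        bg <- sample.int(nv, nbg, replace = TRUE, prob = w)
      }
      # multi-year episodes: last year's background codes may recur
      bg <- c(bg, carried[stats::runif(length(carried)) <
                            config$bg_persist_prob])
      if (length(bg) > 0L) {
        codes <- c(codes, vocab[bg])
        ages <- c(ages, y + stats::runif(length(bg)))
      }
      carried <- unique(bg)
      if (is_case) {
        if (y >= oy) {
          if (y == oy || stats::runif(1) < config$index_recur_prob) {
            codes <- c(codes, sample(index_codes, 1L))
            ages <- c(ages, y + stats::runif(1))
          }
        }
        if (y >= oy - config$prodromal_years) {
          cset <- config$subtype_comorbidity_sets[[subtype[i] + 1L]]
          hit <- cset[stats::runif(length(cset)) < config$emergent_code_prob]
          for (p in hit) {
            codes <- c(codes, sample(phe_codes[[p]], 1L))
            ages <- c(ages, y + stats::runif(1))
          }
        }
      }
    }
    ev_pid[[i]] <- rep(ids[i], length(codes))
    ev_age[[i]] <- floor(ages * 365.25)
    ev_code[[i]] <- codes
  }

  events <- data.frame(
    patient_id = unlist(ev_pid),
    age_days = as.integer(unlist(ev_age)),
    code = unlist(ev_code),
    stringsAsFactors = FALSE
  )
  events$code_system <- vocab_system[match(events$code, vocab)]
  events <- events[order(events$patient_id, events$age_days, events$code), ]
  rownames(events) <- NULL

  demographics <- data.frame(
    patient_id = ids,
    birth_decade = 1920L + 10L * sample.int(6L, config$n_patients, replace = TRUE),
    gender = sample(demo_cols$gender, config$n_patients, replace = TRUE),
    race = sample(demo_cols$race, config$n_patients, replace = TRUE),
    ethnicity = sample(demo_cols$ethnicity, config$n_patients, replace = TRUE),
    site = sample(demo_cols$site, config$n_patients, replace = TRUE),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(patient_id = ids, subtype = subtype,
                      onset_age_years = onset_age,
                      death_age_years = death_age,
                      stringsAsFactors = FALSE)
  truth$signature_codes <- sig_list
  out <- list(
    events = events,
    demographics = demographics,
    survival = data.frame(patient_id = surv_id, time_years = surv_time,
                          event = surv_event, stringsAsFactors = FALSE),
    truth = truth,
    phecode_map = map,
    config = config
  )
  class(out) <- "sim_cohort"
  out
}

#' Generate a deterministic copy-task cohort
#'
#' A learnability oracle for the next-year objective: each patient carries a
#' fixed set of codes repeated identically in every follow-up year, so the
#' year i+1 sentence equals the year i sentence by construction and a
#' correctly wired model can drive next-year token accuracy towards 1. All
#' of a year's events share the same age stamp, so the deterministic
#' age-then-code sentence order is identical across a patient's years.
#'
#' @param n_patients Number of patients.
#' @param vocab_size Number of distinct codes.
#' @param n_years Follow-up years per patient.
#' @param codes_per_patient Codes in each patient's repeated set.
#' @param seed Integer seed.
#' @return An event table.
#' @export
generate_copy_cohort <- function(n_patients = 60L, vocab_size = 30L,
                                 n_years = 6L, codes_per_patient = 5L,
                                 seed = 1L) {
  set.seed(seed)
  codes <- sprintf("C%02d.%d", seq_len(vocab_size), seq_len(vocab_size) %% 10L)
  rows <- lapply(seq_len(n_patients), function(i) {
    own <- sample(codes, codes_per_patient)
    years <- 40L:(40L + n_years - 1L)
    data.frame(patient_id = sprintf("CP%04d", i),
               age_days = rep(as.integer(ceiling(years * 365.25)),
                              each = codes_per_patient),
               code = rep(own, times = n_years),
               code_system = "ICD10", stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev[order(ev$patient_id, ev$age_days, ev$code), , drop = FALSE]
}

#' Summarise follow-up and code density of an event table
#'
#' @param events An event table (patient_id, age_days, code, code_system).
#' @return A list of class `cohort_summary`: `followup` (patient_id,
#'   n_years = number of distinct age-years with events) and
#'   `codes_per_year` (patient_id, year_index, n_codes).
#' @export
summarize_cohort <- function(events) {
  if (nrow(events) == 0L) {
    out <- list(followup = data.frame(patient_id = character(),
                                      n_years = integer(),
                                      stringsAsFactors = FALSE),
                codes_per_year = data.frame(patient_id = character(),
                                            year_index = integer(),
                                            n_codes = integer(),
                                            stringsAsFactors = FALSE))
    class(out) <- "cohort_summary"
    return(out)
  }
  dt <- data.table::as.data.table(events)
  dt[, year_index := age_to_year(age_days)]
  cpy <- dt[, .(n_codes = .N), by = .(patient_id, year_index)]
  data.table::setorder(cpy, patient_id, year_index)
  fu <- cpy[, .(n_years = .N), by = patient_id]
  out <- list(followup = as.data.frame(fu), codes_per_year = as.data.frame(cpy))
  class(out) <- "cohort_summary"
  out
}
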