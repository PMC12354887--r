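test_that("zero patients give empty tables and truth", {
  co <- generate_cohort(sim_config(n_patients = 0L, seed = 1))
  expect_equal(nrow(co$events), 0L)
  expect_equal(nrow(co$demographics), 0L)
  expect_equal(nrow(co$survival), 0L)
  expect_equal(nrow(co$truth), 0L)
  expect_error(sim_config(n_patients = 10, vocab_size_dx = 0),
               "empty diagnosis vocabulary")
})

test_that("identical config and seed reproduce the cohort byte-for-byte", {
  cfg <- sim_config(n_patients = 40L, seed = 99L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$survival, b$survival)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(sim_config(n_patients = 40L, seed = 100L))
  expect_false(identical(a$events, c2$events))
})

test_that("signature codes recur in at least 80% of each patient's years", {
  co <- generate_cohort(sim_config(n_patients = 30L, seed = 5L))
  s <- summarize_cohort(co$events)
  yr <- age_to_year(co$events$age_days)
  for (i in seq_len(nrow(co$truth))) {
    pid <- co$truth$patient_id[i]
    ny <- s$followup$n_years[s$followup$patient_id == pid]
    for (sc in co$truth$signature_codes[[i]]) {
      n_with <- length(unique(yr[co$events$patient_id == pid &
                                   co$events$code == sc]))
      expect_gte(n_with / ny, 0.8)
    }
  }
})

test_that("post-onset years are enriched for the subtype's own comorbidity set", {
  cfg <- sim_config(n_patients = 200L, n_subtypes = 2L,
                    emergent_code_prob = 0.9, seed = 21L)
  co <- generate_cohort(cfg)
  map <- co$phecode_map
  sets <- cfg$subtype_comorbidity_sets
  ev <- co$events
  ev$phecode <- map$phecode[match(ev$code, map$code)]
  ev$year <- age_to_year(ev$age_days)
  for (st in 0:1) {
    tr <- co$truth[co$truth$subtype == st & !is.na(co$truth$onset_age_years), ]
    post <- merge(ev, tr[, c("patient_id", "onset_age_years")],
                  by = "patient_id")
    post <- post[post$year >= post$onset_age_years, ]
    own <- mean(post$phecode %in% sets[[st + 1L]], na.rm = TRUE)
    other <- mean(post$phecode %in% sets[[2L - st]], na.rm = TRUE)
    expect_gt(own, other)
  }
})

test_that("planted comorbidity signal rejects a chi-square test at 1e-6", {
  cfg <- sim_config(n_patients = 200L, n_subtypes = 2L,
                    emergent_code_prob = 0.9, seed = 33L)
  co <- generate_cohort(cfg)
  map <- co$phecode_map
  onset <- co$truth[!is.na(co$truth$onset_age_years), ]
  ev <- co$events[co$events$patient_id %in% onset$patient_id, ]
  ev$phecode <- map$phecode[match(ev$code, map$code)]
  own_set <- cfg$subtype_comorbidity_sets[[1L]]
  has_own <- vapply(onset$patient_id, function(p)
    any(ev$phecode[ev$patient_id == p] %in% own_set, na.rm = TRUE), TRUE)
  tst <- suppressWarnings(chisq.test(table(onset$subtype, has_own)))
  expect_lt(tst$p.value, 1e-6)
})

test_that("higher mortality hazard shortens post-onset survival", {
  cfg <- sim_config(n_patients = 500L, n_subtypes = 2L,
                    mortality_hazard_per_subtype = c(0.05, 0.30), seed = 8L)
  co <- generate_cohort(cfg)
  d <- merge(co$survival, co$truth[, c("patient_id", "subtype")],
             by = "patient_id")
  expect_gt(sum(d$event == 1L & d$subtype == 0L), 5)
  expect_gt(sum(d$event == 1L & d$subtype == 1L), 5)
  # censoring-aware two-group comparison
  sd <- survival::survdiff(survival::Surv(time_years, event) ~ subtype,
                           data = d)
  expect_lt(pchisq(sd$chisq, 1, lower.tail = FALSE), 1e-4)
  # the high-hazard subtype dies faster than expected under the null
  expect_gt(sd$obs[2] / sd$exp[2], sd$obs[1] / sd$exp[1])
  # death never precedes onset, and death truncates follow-up
  tr <- co$truth[!is.na(co$truth$death_age_years), ]
  expect_true(all(tr$death_age_years >= tr$onset_age_years))
})

test_that("the synthetic phecode map is a surjective function with classes", {
  cfg <- sim_config(n_patients = 5L, vocab_size_dx = 10L, n_phecodes = 5L,
                    comorbidity_set_size = 1L, seed = 1)
  map <- generate_phecode_map(cfg)
  expect_equal(nrow(map), 10L)
  expect_equal(anyDuplicated(map$code), 0L)
  expect_setequal(unique(map$phecode), sprintf("%.1f", 1:5))
  expect_true(all(nzchar(map$disease_class)))
  f <- tempfile(fileext = ".csv")
  write_phecode_map(map, f)
  expect_equal(read_phecode_map(f), map)
})

test_that("two codes on one phecode give the same phenotype call", {
  map <- tiny_map()   # D1 and D2 both map to 10.0
  ev1 <- events_from_years("X", 45, "D1")
  ev2 <- events_from_years("Y", 45, "D2")
  occ <- map_to_phecodes(rbind(ev1, ev2), map)
  expect_setequal(occ$phecode, "10.0")
  expect_equal(nrow(occ), 2L)
})

test_that("cohort summary counts follow-up years and codes per year", {
  ev <- events_from_years(rep("Z", 12), rep(c(41, 42, 43), each = 4),
                          sprintf("D%d", 1:12))
  s <- summarize_cohort(ev)
  expect_equal(s$followup$n_years, 3L)
  expect_equal(s$codes_per_year$n_codes, c(4L, 4L, 4L))
  expect_equal(sum(s$codes_per_year$n_codes), nrow(ev))
  empty <- summarize_cohort(ev[0, ])
  expect_equal(nrow(empty$followup), 0L)
  co <- generate_cohort(sim_config(n_patients = 25L, seed = 2))
  s2 <- summarize_cohort(co$events)
  expect_equal(sum(s2$codes_per_year$n_codes), nrow(co$events))
})

test_that("copy cohort repeats each patient's codes identically every year", {
  ev <- generate_copy_cohort(n_patients = 10L, n_years = 4L, seed = 2)
  v <- filter_vocabulary(ev, 0L)
  corpus <- build_year_sentences(ev, v, max_len = 16L)
  expect_equal(length(corpus$length), 40L)
  pairs <- make_nextyear_pairs(corpus)
  expect_equal(nrow(pairs), 30L)
  for (k in seq_len(nrow(pairs))) {
    expect_identical(corpus$tokens[pairs$input[k], ],
                     corpus$tokens[pairs$target[k], ])
  }
})
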