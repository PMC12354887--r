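blob_data <- function(n_per = 200L, centers, sd = 0.1, d = 2L, seed = 1L) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[k, ], n_per, d, byrow = TRUE)))
  rownames(x) <- sprintf("P%04d", seq_len(nrow(x)))
  x
}

test_that("BIC selects three components on three separated blobs", {
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5))
  x <- blob_data(200L, centers, sd = 0.1, seed = 3)
  cl <- fit_gmm_bic(x, k_range = 2:6, seed = 1)
  expect_equal(cl$K, 3L)
  # assignments partition the patients
  expect_equal(sort(unique(cl$assignments$cluster)), 0:2)
  expect_equal(nrow(cl$assignments), nrow(x))
  expect_equal(anyDuplicated(cl$assignments$patient_id), 0L)
  # chosen K minimises the reported (minimise-convention) BIC
  expect_equal(cl$bic$K[which.min(cl$bic$bic)], cl$K)
})

test_that("a single blob with k_range starting at 1 yields K = 1", {
  x <- blob_data(150L, rbind(c(0, 0)), sd = 0.5, seed = 5)
  cl <- fit_gmm_bic(x, k_range = 1:3, seed = 2)
  expect_equal(cl$K, 1L)
})

test_that("planted comorbidity enrichment is significant with positive log-OR", {
  set.seed(7)
  n <- 1000L
  pid <- sprintf("P%04d", seq_len(n))
  cluster <- rep(0:1, each = n / 2)
  assign <- data.frame(patient_id = pid, cluster = cluster,
                       stringsAsFactors = FALSE)
  # phecode 5.0: 60% in cluster 0, 5% elsewhere; 6.0 independent
  has5 <- ifelse(cluster == 0L, runif(n) < 0.6, runif(n) < 0.05)
  has6 <- runif(n) < 0.3
  on <- rbind(
    data.frame(patient_id = pid[has5], phecode = "5.0",
               onset_age_days = 18000L, onset_age_years = 49L),
    data.frame(patient_id = pid[has6], phecode = "6.0",
               onset_age_days = 18000L, onset_age_years = 49L))
  cov <- data.frame(patient_id = pid,
                    age_of_onset = round(runif(n, 45, 70)),
                    gender = sample(c("F", "M"), n, TRUE),
                    race = sample(c("a", "b", "c"), n, TRUE),
                    ethnicity = sample(c("x", "y"), n, TRUE),
                    site = sample(c("s1", "s2"), n, TRUE),
                    stringsAsFactors = FALSE)
  map <- data.frame(code = c("D5", "D6"), code_system = "ICD10",
                    phecode = c("5.0", "6.0"),
                    disease_class = c("digestive", "neoplasms"),
                    stringsAsFactors = FALSE)
  enr <- comorbidity_enrichment(assign, on, cov, map)
  hit <- enr[enr$cluster == 0L & enr$phecode == "5.0", ]
  expect_gt(hit$log_odds_ratio, 0)
  expect_lt(hit$p_adj, 2e-5)
  expect_true(hit$significant)
  # opposite cluster shows the mirrored (negative) effect
  expect_lt(enr$log_odds_ratio[enr$cluster == 1L & enr$phecode == "5.0"], 0)
  # the independent phenotype is not significant
  expect_false(any(enr$significant[enr$phecode == "6.0"]))
  # BH monotonicity
  expect_true(all(enr$p_adj >= enr$p - 1e-12))
  # bonferroni adjustment is at least as conservative
  enb <- comorbidity_enrichment(assign, on, cov, map, adjust = "bonferroni")
  expect_true(all(enb$p_adj >= enr$p_adj - 1e-12))
})

test_that("completely separated enrichment fits are flagged, not dropped", {
  set.seed(8)
  n <- 120L
  pid <- sprintf("P%03d", seq_len(n))
  cluster <- rep(0:1, each = n / 2)
  assign <- data.frame(patient_id = pid, cluster = cluster)
  on <- data.frame(patient_id = pid[cluster == 0L], phecode = "5.0",
                   onset_age_days = 18000L, onset_age_years = 49L)
  cov <- data.frame(patient_id = pid, age_of_onset = 50,
                    gender = sample(c("F", "M"), n, TRUE),
                    stringsAsFactors = FALSE)
  map <- data.frame(code = "D5", code_system = "ICD10", phecode = "5.0",
                    disease_class = "digestive", stringsAsFactors = FALSE)
  enr <- comorbidity_enrichment(assign, on, cov, map)
  expect_true(all(nzchar(enr$flag[enr$phecode == "5.0"])))
  expect_gt(enr$log_odds_ratio[enr$cluster == 0L], 0)
  expect_true(all(is.finite(enr$log_odds_ratio)))
})

test_that("Kaplan-Meier curves start at 1, decrease, and detect a hazard gap", {
  set.seed(9)
  n <- 250L
  cl <- rep(0:1, each = n)
  t0 <- ifelse(cl == 0L, rexp(2 * n, 0.05), rexp(2 * n, 0.15))
  cens <- rexp(2 * n, 0.05)
  surv <- data.frame(patient_id = sprintf("P%04d", seq_len(2 * n)),
                     time_years = pmin(t0, cens),
                     event = as.integer(t0 <= cens))
  assign <- data.frame(patient_id = surv$patient_id, cluster = cl)
  km <- km_logrank(assign, surv, horizon_years = 10)
  expect_lt(km$global$p, 0.01)
  for (g in unique(km$curves$cluster)) {
    s <- km$curves$surv[km$curves$cluster == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }
  expect_true(all(km$curves$time <= 10))
  expect_true(all(km$pairwise$p_adj >= km$pairwise$p - 1e-12))
  # a cluster with no survival record is excluded with a warning
  assign2 <- rbind(assign, data.frame(patient_id = "PX", cluster = 2L))
  expect_warning(km_logrank(assign2, surv), "excluded")
})

test_that("progression PCA separates planted post-onset trajectories", {
  set.seed(10)
  n_pat <- 40L
  onset_yr <- 45L
  pid <- sprintf("P%03d", seq_len(n_pat))
  cl <- rep(0:1, each = n_pat / 2)
  rows <- list(); meta_pid <- character(0); meta_yr <- integer(0)
  for (i in seq_len(n_pat)) {
    for (y in onset_yr:(onset_yr + 9L)) {
      v <- rnorm(6, sd = 0.3)
      v[1] <- v[1] + ifelse(cl[i] == 0L, 1, -1) * (y - onset_yr) * 0.3
      rows[[length(rows) + 1L]] <- v
      meta_pid <- c(meta_pid, pid[i]); meta_yr <- c(meta_yr, y)
    }
  }
  ye <- year_embeddings(do.call(rbind, rows), meta_pid, meta_yr)
  onsets <- data.frame(patient_id = pid, onset_age_years = onset_yr)
  assign <- data.frame(patient_id = pid, cluster = cl)
  cov <- data.frame(patient_id = pid, age_of_onset = onset_yr,
                    gender = sample(c("F", "M"), n_pat, TRUE),
                    stringsAsFactors = FALSE)
  pr <- progression_pca_anova(ye, onsets, assign, cov)
  expect_equal(pr$n_patients, n_pat)
  expect_true(all(diff(pr$var_explained) <= 1e-12))
  expect_lte(sum(pr$var_explained), 1 + 1e-12)
  p_cl <- pr$anova$p[pr$anova$term == "cluster" & pr$anova$pc == 1L]
  expect_lt(p_cl, 0.001)
  # too few eligible patients errors
  expect_error(progression_pca_anova(ye, onsets[1:2, ], assign, cov),
               "fewer than 3")
})

test_that("emerging phenotypes match manual enumeration on a toy cohort", {
  # 4 patients, clusters {0,0,1,1}; onset year 45 for all
  occ <- rbind(
    data.frame(patient_id = "A", phecode = "2.0", age_days = 17000L),  # y46
    data.frame(patient_id = "A", phecode = "3.0", age_days = 16000L),  # y43 pre
    data.frame(patient_id = "A", phecode = "3.0", age_days = 17200L),  # post too
    data.frame(patient_id = "B", phecode = "2.0", age_days = 16900L),  # y46
    data.frame(patient_id = "C", phecode = "4.0", age_days = 17000L),  # y46
    data.frame(patient_id = "D", phecode = "5.0", age_days = 15000L))  # y41 pre
  onsets <- data.frame(patient_id = c("A", "B", "C", "D"),
                       onset_age_years = 45L)
  assign <- data.frame(patient_id = c("A", "B", "C", "D"),
                       cluster = c(0L, 0L, 1L, 1L))
  em <- emerging_phenotypes(occ, onsets, assign)
  # cluster 0: 2.0 gained by both A and B -> 2/2; 3.0 existed before -> no gain
  expect_equal(em$frequency[em$cluster == 0L & em$phecode == "2.0"], 1)
  expect_false("3.0" %in% em$phecode[em$cluster == 0L])
  # cluster 1: 4.0 by C only -> 1/2; 5.0 pre-onset only -> no gain
  expect_equal(em$frequency[em$cluster == 1L & em$phecode == "4.0"], 0.5)
  expect_false("5.0" %in% em$phecode)
  # pre mode counts what existed before onset
  pre <- emerging_phenotypes(occ, onsets, assign, window = "pre")
  expect_setequal(pre$phecode, c("3.0", "5.0"))
  # no post-onset events anywhere gives an empty table
  none <- emerging_phenotypes(occ[occ$age_days < 16000L, ], onsets, assign)
  expect_equal(nrow(none), 0L)
})

test_that("top-n flagging is deterministic under frequency ties", {
  occ <- do.call(rbind, lapply(sprintf("%d.0", 2:8), function(p)
    data.frame(patient_id = "A", phecode = p, age_days = 17000L)))
  onsets <- data.frame(patient_id = "A", onset_age_years = 45L)
  assign <- data.frame(patient_id = "A", cluster = 0L)
  em <- emerging_phenotypes(occ, onsets, assign, top_n = 3L)
  expect_equal(em$phecode[em$top], sort(em$phecode)[1:3])  # phecode asc ties
})
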