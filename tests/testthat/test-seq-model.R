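# A tiny trained model shared by several blocks in this file.
tiny_model_env <- new.env()
tiny_model <- function() {
  if (is.null(tiny_model_env$m)) {
    ev <- generate_copy_cohort(n_patients = 12L, vocab_size = 15L,
                               n_years = 4L, codes_per_patient = 4L, seed = 3)
    v <- filter_vocabulary(ev, 0L)
    corpus <- build_year_sentences(ev, v, max_len = 16L)
    pairs <- make_nextyear_pairs(corpus)
    set.seed(1)
    E0 <- matrix(rnorm(v$size * 16, sd = 0.1), v$size, 16L)
    m <- train_transformer(corpus, pairs, E0,
                           transformer_desk_config(d = 16L, dff = 32L,
                                                   max_len = 16L, steps = 30L,
                                                   batch_size = 8L, seed = 2L))
    tiny_model_env$m <- m
    tiny_model_env$corpus <- corpus
    tiny_model_env$pairs <- pairs
  }
  tiny_model_env
}

test_that("year sentences bin codes by age-year with deterministic order", {
  ev <- events_from_years(rep("A", 5), c(3, 3, 5, 5, 5),
                          c("D2", "D1", "D3", "D1", "D2"))
  ev <- rbind(ev, events_from_years("B", 4, "D9"))   # unseen after filtering
  v <- filter_vocabulary(ev[ev$code != "D9", ], 0L)
  corpus <- build_year_sentences(ev, v, max_len = 10L)
  expect_equal(corpus$patient_id, c("A", "A"))       # B has no retained codes
  expect_equal(corpus$year_index, c(3L, 5L))
  expect_equal(corpus$length, c(2L, 3L))
  # padded to max_len with PAD beyond the true length
  expect_equal(ncol(corpus$tokens), 10L)
  expect_true(all(corpus$tokens[1, 3:10] == v$pad_id))
  expect_equal(sum(corpus$tokens[2, ] == v$pad_id), 7L)
})

test_that("next-year pairs require consecutive age-years", {
  ev <- events_from_years(rep("A", 3), c(3, 4, 5), c("D1", "D1", "D1"))
  ev <- rbind(ev, events_from_years(rep("B", 2), c(3, 5), c("D1", "D1")))
  ev <- rbind(ev, events_from_years("C", 7, "D1"))
  v <- filter_vocabulary(ev, 0L)
  corpus <- build_year_sentences(ev, v, max_len = 4L)
  pairs <- make_nextyear_pairs(corpus)
  pid <- corpus$patient_id[pairs$input]
  expect_equal(sum(pid == "A"), 2L)                  # (3->4), (4->5)
  expect_equal(sum(pid == "B"), 0L)                  # gap year breaks the pair
  expect_equal(sum(pid == "C"), 0L)                  # single year, no pair
  expect_true(all(corpus$year_index[pairs$target] ==
                    corpus$year_index[pairs$input] + 1L))
})

test_that("pair count equals the sum over consecutive-year runs", {
  co <- generate_cohort(sim_config(n_patients = 30L, seed = 12))
  v <- filter_vocabulary(co$events)
  corpus <- build_year_sentences(co$events, v, 32L)
  pairs <- make_nextyear_pairs(corpus)
  expected <- sum(vapply(split(corpus$year_index, corpus$patient_id),
                         function(y) sum(diff(sort(y)) == 1L), 1L))
  expect_equal(nrow(pairs), expected)
})

test_that("masking replaces ceil(fraction x length) non-PAD tokens", {
  set.seed(1)
  tokens <- c(4:13, rep(1L, 6))                      # 10 real + 6 PAD
  mk <- mask_tokens(tokens, 10L, 0.2)
  expect_equal(length(mk$masked), 2L)                # ceil(0.2 * 10)
  expect_true(all(mk$input[mk$masked] == 2L))
  expect_equal(mk$labels[mk$masked], tokens[mk$masked])
  expect_true(all(is.na(mk$labels[-mk$masked])))
  # ceiling boundary: a single real token is masked
  mk1 <- mask_tokens(c(5L, 1L, 1L), 1L, 0.2)
  expect_equal(length(mk1$masked), 1L)
  # PAD is never selected across many seeded draws
  for (i in 1:300) {
    mk <- mask_tokens(tokens, 10L, 0.33)
    expect_true(all(mk$masked <= 10L))
    expect_true(all(mk$input[11:16] == 1L))
  }
})

test_that("logits, pooling and reconstruction are permutation invariant", {
  env <- tiny_model()
  m <- env$m; corpus <- env$corpus
  i <- which(corpus$length == max(corpus$length))[1]
  li <- corpus$length[i]
  tok <- corpus$tokens[i, seq_len(li)]
  p1 <- pool_year_embedding(m, tok, li)
  set.seed(9)
  for (r in 1:5) {
    perm <- sample(li)
    p2 <- pool_year_embedding(m, tok[perm], li)
    expect_lt(max(abs(p1 - p2)), 1e-5)
  }
  # duplicating the full multiset leaves the pooled mean unchanged
  p3 <- pool_year_embedding(m, rep(tok, 2L), 2L * li)
  expect_lt(max(abs(p1 - p3)), 1e-8)
  # single-token sentence pools to that token's final representation
  p4 <- pool_year_embedding(m, tok[1], 1L)
  expect_equal(length(p4), m$config$d)
})

test_that("reconstruction output never contains reserved tokens", {
  env <- tiny_model()
  sets <- reconstruct_codes(env$m, env$corpus, 1:10)
  for (s in sets) expect_true(all(s > env$m$vocab$n_reserved))
})

test_that("sequence-recovery metrics follow set arithmetic", {
  m <- sequence_recovery_metrics(list(c(1, 2, 3)), list(c(1, 2, 4, 5)))
  expect_equal(m$per_event$precision, 2 / 3)
  expect_equal(m$per_event$recall, 1 / 2)
  m2 <- sequence_recovery_metrics(list(c(7, 8)), list(c(7, 8)))
  expect_equal(unlist(m2$per_event), c(precision = 1, recall = 1))
  m3 <- sequence_recovery_metrics(list(1:3), list(4:6))
  expect_equal(unlist(m3$per_event), c(precision = 0, recall = 0))
  # empty-truth events are skipped; length mismatch errors
  m4 <- sequence_recovery_metrics(list(1, 2), list(integer(0), 2))
  expect_equal(nrow(m4$per_event), 1L)
  expect_error(sequence_recovery_metrics(list(1), list(1, 2)), "length")
})

test_that("masked accuracy of an untrained model is near chance", {
  env <- tiny_model()
  corpus <- env$corpus
  set.seed(5)
  E0 <- matrix(rnorm(corpus$vocab$size * 16, sd = 0.1), corpus$vocab$size, 16L)
  m0 <- train_transformer(corpus, env$pairs, E0,
                          transformer_desk_config(d = 16L, dff = 32L,
                                                  max_len = 16L, steps = 1L,
                                                  batch_size = 4L, seed = 7L))
  acc <- masked_prediction_accuracy(m0, corpus, 0.2, seed = 3)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  expect_lt(acc, 0.5)                                 # far from memorised
})

test_that("the transformer memorises a tiny corpus (capacity check)", {
  ev <- generate_copy_cohort(n_patients = 8L, vocab_size = 12L, n_years = 4L,
                             codes_per_patient = 3L, seed = 6)
  v <- filter_vocabulary(ev, 0L)
  corpus <- build_year_sentences(ev, v, max_len = 8L)
  pairs <- make_nextyear_pairs(corpus)
  set.seed(2)
  E0 <- matrix(rnorm(v$size * 16, sd = 0.1), v$size, 16L)
  m <- train_transformer(corpus, pairs, E0,
                         transformer_desk_config(d = 16L, dff = 48L,
                                                 max_len = 8L, steps = 1000L,
                                                 batch_size = 8L, seed = 4L,
                                                 validation_fraction = 0))
  expect_gte(masked_prediction_accuracy(m, corpus, 0.2, seed = 8), 0.9)
  # and recovery of its own sentences is near-perfect
  sets <- reconstruct_codes(m, corpus, seq_along(corpus$length))
  truth <- lapply(seq_along(corpus$length), function(i)
    unique(corpus$tokens[i, seq_len(corpus$length[i])]))
  mm <- sequence_recovery_metrics(sets, truth)
  expect_gte(mean(mm$per_event$recall), 0.9)
})

test_that("training and validation losses are logged and finite", {
  env <- tiny_model()
  expect_equal(nrow(env$m$log), 30L)
  expect_true(all(is.finite(env$m$log$loss)))
  expect_true(all(env$m$log$lr > 0))
})
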