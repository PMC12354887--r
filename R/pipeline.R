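# One-command orchestration of the full desk-scale workflow:
# simulate -> vocabulary/VAE pre-training -> transformer pre-training ->
# pooled year vectors -> siamese fine-tuning -> mean patient vectors ->
# downstream analyses (classification, clustering, enrichment, survival,
# progression), with per-stage seeds, timings and output hashes collected
# in a manifest.

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

hash_table <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  utils::write.csv(x, f, row.names = FALSE)
  unname(tools::md5sum(f))
}

#' Pipeline configuration
#'
#' Desk-scale presets sized for a single CPU: every stage runs in minutes
#' on a cohort of a few hundred patients while preserving the production
#' architecture shapes (see the methods vignette for the reasoning behind
#' the problem sizes).
#'
#' @param seed Global seed; per-stage seeds are derived from it, so stages
#'   are independently reproducible.
#' @param sim A [sim_config()]; its `seed` is overwritten by the derived
#'   stage seed.
#' @param vae A [vae_config()].
#' @param transformer A [transformer_config()].
#' @param sbert An [sbert_config()].
#' @param n_pairs Number of siamese training pairs to sample.
#' @param finetune If `FALSE`, the siamese stage is skipped and downstream
#'   stages consume the pooled (pre-fine-tuning) embeddings; the manifest
#'   records the substitution.
#' @param k_range Candidate cluster numbers for the subtyping stage.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as CSV/TSV artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(n_patients = 400L),
                            vae = vae_desk_config(epochs = 15L),
                            transformer = transformer_desk_config(steps = 1200L,
                                                                  peak_lr = 2e-3,
                                                                  warmup_steps = 200L),
                            sbert = sbert_config(steps = 4000L,
                                                 embedding_dim = 32L),
                            n_pairs = 6000L,
                            finetune = TRUE,
                            k_range = 2:6,
                            out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), sim = sim, vae = vae,
              transformer = transformer, sbert = sbert,
              n_pairs = as.integer(n_pairs), finetune = isTRUE(finetune),
              k_range = k_range, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes simulate, pre-train (VAE), train (transformer), pool, fine-tune
#' (siamese), embed, and the downstream analyses in order, failing fast
#' with stage-attributed errors. Returns all artifacts plus a manifest of
#' per-stage seeds, durations and table hashes.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A list of class `pipeline_run` with elements `cohort`, `vocab`,
#'   `code_embedding`, `transformer`, `pooled`, `sbert`, `embedded`,
#'   `mean_vectors`, `onsets`, `metrics` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  metrics <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest[[name]] <<- list(seconds = tic() - t0)
    if (verbose) message("stage ", name, ": ",
                         round(manifest[[name]]$seconds, 1), "s")
    out
  }

  # -- simulate ---------------------------------------------------------------
  config$sim$seed <- derive_seed(config$seed, 1L)
  cohort <- stage("simulate", generate_cohort(config$sim))
  manifest$simulate$seed <- config$sim$seed
  manifest$simulate$events_hash <- hash_table(cohort$events)
  occ <- map_to_phecodes(cohort$events, cohort$phecode_map)
  onsets <- compute_onset_table(occ)

  # -- vocabulary + VAE -------------------------------------------------------
  config$vae$seed <- derive_seed(config$seed, 2L)
  vocab <- stage("vocabulary", filter_vocabulary(cohort$events, 5L))
  freq <- build_frequency_matrix(cohort$events, vocab)
  vae <- stage("pretrain_codes", train_code_vae(freq, config$vae))
  emb <- encode_codes(vae, freq)
  E0 <- embedding_table(vocab, emb)
  metrics$vae_final_loss <- utils::tail(vae$history$train_loss, 1L)

  # -- transformer ------------------------------------------------------------
  config$transformer$seed <- derive_seed(config$seed, 3L)
  corpus <- build_year_sentences(cohort$events, vocab,
                                 config$transformer$max_len)
  pairs <- make_nextyear_pairs(corpus)
  transformer <- stage("train_transformer",
                       train_transformer(corpus, pairs, E0,
                                         config$transformer))
  metrics$transformer_final_loss <- utils::tail(transformer$log$loss, 1L)
  metrics$masked_accuracy <- masked_prediction_accuracy(
    transformer, corpus, config$transformer$mask_fraction,
    seed = derive_seed(config$seed, 4L))

  # -- pooled year vectors ----------------------------------------------------
  pooled_mat <- stage("pool", pool_year_embeddings(transformer, corpus))
  pooled <- year_embeddings(pooled_mat, corpus$patient_id, corpus$year_index)

  # -- siamese fine-tuning ----------------------------------------------------
  sbert <- NULL
  if (config$finetune) {
    config$sbert$seed <- derive_seed(config$seed, 5L)
    train_pairs <- sample_pairs(pooled, config$n_pairs,
                                seed = derive_seed(config$seed, 6L))
    sbert <- stage("finetune", train_sbert(pooled, train_pairs, config$sbert))
    eval_pairs <- sample_pairs(pooled, config$n_pairs,
                               seed = derive_seed(config$seed, 7L))
    pt <- evaluate_pair_tasks(sbert, pooled, eval_pairs,
                              seed = derive_seed(config$seed, 8L))
    metrics$acc_same_patient <- unname(pt$same_patient["mean"])
    metrics$acc_next_event <- unname(pt$next_event["mean"])
    embedded <- embed_cohort(sbert, pooled)
  } else {
    manifest$finetune <- list(skipped = TRUE,
                              note = "downstream uses pooled embeddings")
    embedded <- pooled
  }
  mean_vec <- mean_patient_vector(embedded)

  # -- downstream -------------------------------------------------------------
  idx_phe <- config$sim$index_phecode
  bulk <- build_bulk_dataset(mean_vec, onsets, idx_phe)
  if (!is.null(bulk))
    metrics$bulk_auroc <- fit_eval_logistic(
      bulk, seed = derive_seed(config$seed, 9L))$auroc
  onset_ds <- build_onset_dataset(embedded, onsets, idx_phe,
                                  seed = derive_seed(config$seed, 10L))
  if (!is.null(onset_ds))
    metrics$onset_auroc <- fit_eval_logistic(
      onset_ds, seed = derive_seed(config$seed, 11L))$auroc

  cases <- onsets$patient_id[onsets$phecode == idx_phe]
  case_rows <- rownames(mean_vec$mean) %in% cases
  # directional (cosine) geometry: centre, then L2-normalise each patient
  # mean so the comorbidity mix (direction), not the post-onset fraction
  # (magnitude), drives the mixture fit
  Mcase <- mean_vec$mean[case_rows, , drop = FALSE]
  Mcase <- sweep(Mcase, 2L, colMeans(Mcase))
  Mcase <- Mcase / pmax(sqrt(rowSums(Mcase^2)), 1e-12)
  cl <- stage("cluster", fit_gmm_bic(Mcase, k_range = config$k_range,
                                     seed = derive_seed(config$seed, 12L)))
  metrics$chosen_K <- cl$K
  truth_sub <- cohort$truth$subtype[match(cl$assignments$patient_id,
                                          cohort$truth$patient_id)]
  metrics$subtype_ari <- mclust::adjustedRandIndex(cl$assignments$cluster,
                                                   truth_sub)
  covars <- data.frame(
    patient_id = cl$assignments$patient_id,
    age_of_onset = onsets$onset_age_years[match(
      paste(cl$assignments$patient_id, idx_phe),
      paste(onsets$patient_id, onsets$phecode))],
    cohort$demographics[match(cl$assignments$patient_id,
                              cohort$demographics$patient_id),
                        c("gender", "race", "ethnicity", "site")],
    stringsAsFactors = FALSE)
  enrich <- stage("enrich",
                  comorbidity_enrichment(cl$assignments, onsets, covars,
                                         cohort$phecode_map))
  metrics$n_enriched <- sum(enrich$significant)
  surv <- NULL
  if (nrow(cohort$survival) > 0L && length(unique(cl$assignments$cluster)) > 1L) {
    surv <- stage("survive", km_logrank(cl$assignments, cohort$survival))
    metrics$logrank_p <- surv$global$p
  }
  progression <- tryCatch(
    stage("progress", progression_pca_anova(
      embedded, onsets[onsets$phecode == idx_phe,
                       c("patient_id", "onset_age_years")],
      cl$assignments, covars)),
    error = function(e) {
      manifest$progress <<- list(skipped = TRUE, note = conditionMessage(e))
      NULL
    })
  if (!is.null(progression))
    metrics$progression_n <- progression$n_patients
  emerge <- stage("emerge", emerging_phenotypes(
    occ, stats::setNames(onsets[onsets$phecode == idx_phe,
                                c("patient_id", "onset_age_years")],
                         c("patient_id", "onset_age_years")),
    cl$assignments))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(cohort$events, file.path(config$out_dir, "events.csv"))
    write_phecode_map(cohort$phecode_map,
                      file.path(config$out_dir, "phecode_map.csv"))
    utils::write.csv(cohort$demographics,
                     file.path(config$out_dir, "demographics.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$survival,
                     file.path(config$out_dir, "survival.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cohort$truth, file.path(config$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    utils::write.csv(data.frame(patient_id = rownames(mean_vec$mean),
                                mean_vec$mean),
                     file.path(config$out_dir, "mean_vectors.csv"),
                     row.names = FALSE)
    utils::write.csv(cl$assignments,
                     file.path(config$out_dir, "clusters.csv"),
                     row.names = FALSE)
    utils::write.csv(enrich, file.path(config$out_dir, "enrichment.csv"),
                     row.names = FALSE)
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  out <- list(cohort = cohort, vocab = vocab, code_embedding = emb,
              transformer = transformer, pooled = pooled, sbert = sbert,
              embedded = embedded, mean_vectors = mean_vec, onsets = onsets,
              clusters = cl, enrichment = enrich, survival_comparison = surv,
              progression = progression, emerging = emerge,
              metrics = metrics, manifest = manifest,
              config = config)
  class(out) <- "pipeline_run"
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("cohortvec pipeline run\n")
  cat("  patients:", x$config$sim$n_patients,
      " sentences:", length(x$pooled$patient_id), "\n")
  for (m in names(x$metrics))
    cat(sprintf("  %-24s %s\n", m,
                format(x$metrics[[m]], digits = 4)))
  invisible(x)
}
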