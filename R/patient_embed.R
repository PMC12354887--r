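# Siamese fine-tuning of pooled year vectors. A shared feed-forward tower
# (pre-embedding layer -> 50-dimensional embedding layer) maps each pooled
# year vector to the final patient-year embedding. Two pair tasks drive the
# training: is_same_patient (contrastive distance loss) and is_next_event
# (binary head on the concatenated pair embeddings). Per-patient mean
# vectors (the arithmetic mean over year embeddings) are the patient-level
# representation for bulk tasks.

#' Container for per-year embeddings
#'
#' @param vectors Numeric matrix, one row per patient-year.
#' @param patient_id,year_index Metadata aligned with the rows.
#' @return An object of class `year_embeddings`.
#' @export
year_embeddings <- function(vectors, patient_id, year_index) {
  stopifnot(nrow(vectors) == length(patient_id),
            length(patient_id) == length(year_index))
  out <- list(vectors = vectors, patient_id = as.character(patient_id),
              year_index = as.integer(year_index))
  class(out) <- "year_embeddings"
  out
}

#' Sample labelled pairs of patient-years
#'
#' Balanced sampling over rows of a `year_embeddings` object: 50% of pairs
#' share a patient (half of those are ordered adjacent-year pairs, the
#' next-event positives) and 50% pair different patients. Labels are
#' assigned from the metadata, so an incidentally adjacent same-patient
#' draw is labelled `next_event = 1`; `next_event = 1` implies
#' `same_patient = 1` for every pair.
#'
#' @param ye A `year_embeddings` object (vectors are not used, only
#'   metadata).
#' @param n_pairs Number of pairs.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `a`, `b` (row indices),
#'   `same_patient`, `next_event`.
#' @export
sample_pairs <- function(ye, n_pairs, seed = 1L) {
  stopifnot(inherits(ye, "year_embeddings"))
  set.seed(seed)
  n <- length(ye$patient_id)
  if (length(unique(ye$patient_id)) < 2L)
    stop("need at least two patients to form different-patient pairs")
  rows_by_pat <- split(seq_len(n), ye$patient_id)
  multi <- rows_by_pat[vapply(rows_by_pat, length, 1L) >= 2L]
  if (length(multi) == 0L)
    stop("no patient has two embedded years; same-patient pairs impossible")
  # ordered adjacent pairs (candidate next-event positives)
  key <- paste(ye$patient_id, ye$year_index, sep = "\r")
  nxt <- match(paste(ye$patient_id, ye$year_index + 1L, sep = "\r"), key)
  adj_a <- which(!is.na(nxt)); adj_b <- nxt[adj_a]
  if (length(adj_a) == 0L)
    stop("no patient has two consecutive embedded years; ",
         "next-event positives impossible")
  n_same <- n_pairs %/% 2L
  n_adj <- n_same %/% 2L
  n_other <- n_same - n_adj
  n_diff <- n_pairs - n_same

  pick_adj <- sample.int(length(adj_a), n_adj, replace = TRUE)
  a1 <- adj_a[pick_adj]; b1 <- adj_b[pick_adj]
  # same-patient, random ordered pair of distinct years
  pats <- sample(names(multi), n_other, replace = TRUE)
  ab <- vapply(pats, function(p) sample(multi[[p]], 2L), integer(2))
  a2 <- ab[1L, ]; b2 <- ab[2L, ]
  # different patients
  a3 <- sample.int(n, n_diff, replace = TRUE)
  b3 <- vapply(a3, function(i) {
    repeat {
      j <- sample.int(n, 1L)
      if (ye$patient_id[j] != ye$patient_id[i]) return(j)
    }
  }, integer(1))
  a <- c(a1, a2, a3); b <- c(b1, b2, b3)
  same <- as.integer(ye$patient_id[a] == ye$patient_id[b])
  nxt_lab <- as.integer(same == 1L & ye$year_index[b] == ye$year_index[a] + 1L)
  data.frame(a = a, b = b, same_patient = same, next_event = nxt_lab)
}

#' Siamese fine-tuning configuration
#'
#' @param pre_width Width of the pre-embedding layer.
#' @param embedding_dim Final embedding dimension (default 50).
#' @param head_width Hidden width of the 2-layer next-event head.
#' @param learning_rate Adam learning rate (default 3e-4).
#' @param steps Training steps (default 5000).
#' @param batch_size Pairs per step.
#' @param margin Contrastive margin for negative (different-patient) pairs;
#'   `NULL` (default) calibrates it to the median different-patient input
#'   distance so the hinge is active at the scale of the data.
#' @param w_same Weight of the same-patient contrastive term.
#' @param w_next Weight of the next-event loss term.
#' @param seed Integer seed.
#' @return An `sbert_config` list.
#' @export
sbert_config <- function(pre_width = 128L, embedding_dim = 50L,
                         head_width = 64L, learning_rate = 3e-4,
                         steps = 5000L, batch_size = 64L, margin = NULL,
                         w_same = 1, w_next = 1, seed = 1L) {
  cfg <- list(pre_width = as.integer(pre_width),
              embedding_dim = as.integer(embedding_dim),
              head_width = as.integer(head_width),
              learning_rate = learning_rate, steps = as.integer(steps),
              batch_size = as.integer(batch_size), margin = margin,
              w_same = w_same, w_next = w_next, seed = as.integer(seed))
  class(cfg) <- "sbert_config"
  cfg
}

sbert_tower_values <- function(model, X) {
  Xs <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  h <- Xs %*% model$pre$W$value
  h <- pmax(sweep(h, 2L, as.numeric(model$pre$b$value), "+"), 0)
  out <- sweep(h %*% model$emb$W$value, 2L, as.numeric(model$emb$b$value), "+")
  if (model$residual) out <- out + Xs
  out
}

#' Train the siamese pair model
#'
#' The shared tower is applied to both members of each pair. The
#' same-patient task minimises squared embedding distance for positive
#' pairs and a squared hinge beyond `margin` for negatives; the next-event
#' task adds binary cross-entropy from a 2-layer feed-forward head on the
#' concatenated pair embeddings.
#'
#' Inputs are standardised (per-dimension z-score, stored in the model),
#' and when the input width equals `embedding_dim` the tower is residual
#' (`x + f(x)`), so fine-tuning perturbs the pre-trained embedding geometry
#' instead of replacing it with a fresh random projection.
#'
#' @param ye A `year_embeddings` object (pooled year vectors).
#' @param pairs Output of [sample_pairs()].
#' @param config An [sbert_config()].
#' @return An object of class `sbert_model` with the tower, head, config
#'   and per-step loss log.
#' @export
train_sbert <- function(ye, pairs, config = sbert_config()) {
  stopifnot(inherits(ye, "year_embeddings"), nrow(pairs) > 0L)
  set.seed(config$seed)
  X <- ye$vectors
  d_in <- ncol(X)
  center <- colMeans(X)
  scale <- pmax(apply(X, 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  model <- list(pre = ad_linear_new(d_in, config$pre_width),
                emb = ad_linear_new(config$pre_width, config$embedding_dim),
                h1 = ad_linear_new(2L * config$embedding_dim, config$head_width),
                h2 = ad_linear_new(config$head_width, 1L),
                config = config, d_in = d_in, center = center, scale = scale,
                residual = d_in == config$embedding_dim)
  class(model) <- "sbert_model"
  margin <- config$margin
  if (is.null(margin)) {
    neg <- pairs[pairs$same_patient == 0L, , drop = FALSE]
    neg <- neg[seq_len(min(nrow(neg), 500L)), , drop = FALSE]
    margin <- stats::median(sqrt(rowSums((Xs[neg$a, , drop = FALSE] -
                                            Xs[neg$b, , drop = FALSE])^2)))
    if (!is.finite(margin) || margin <= 0) margin <- 1
  }
  model$margin <- margin
  params <- ad_params(model[c("pre", "emb", "h1", "h2")])
  opt <- adam_new(params)
  tower <- function(xb) {
    out <- ad_linear(model$emb, ad_relu(ad_linear(model$pre, xb)))
    if (model$residual) out <- ad_add(out, xb)
    out
  }

  log <- numeric(config$steps)
  for (step in seq_len(config$steps)) {
    rows <- sample.int(nrow(pairs), min(config$batch_size, nrow(pairs)))
    pa <- pairs[rows, , drop = FALSE]
    ad_tape_reset()
    ea <- tower(ad_const(Xs[pa$a, , drop = FALSE]))
    eb <- tower(ad_const(Xs[pa$b, , drop = FALSE]))
    lc <- ad_contrastive(ea, eb, pa$same_patient == 1L, margin)
    logits <- ad_linear(model$h2,
                        ad_relu(ad_linear(model$h1, ad_concat_cols(ea, eb))))
    lb <- ad_bce(logits, matrix(pa$next_event, ncol = 1L))
    loss <- ad_add(ad_scale(lc, config$w_same), ad_scale(lb, config$w_next))
    if (!is.finite(loss$value[1]))
      stop("non-finite siamese loss at step ", step)
    ad_backward(loss)
    opt <- adam_step(opt, config$learning_rate)
    log[step] <- loss$value[1]
  }
  ad_tape_reset()
  model$log <- data.frame(step = seq_len(config$steps), loss = log)
  model
}

#' Embed pooled year vectors through the fine-tuned tower
#'
#' Deterministic inference pass; two calls on the same input give identical
#' output.
#'
#' @param model An `sbert_model`.
#' @param x A pooled vector (length d_in) or matrix of pooled vectors.
#' @return A matrix with `embedding_dim` columns.
#' @export
embed_year <- function(model, x) {
  stopifnot(inherits(model, "sbert_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$d_in) stop("input width does not match the tower")
  sbert_tower_values(model, x)
}

#' Embed a whole cohort of pooled year vectors
#'
#' @param model An `sbert_model`.
#' @param ye A `year_embeddings` object of pooled vectors.
#' @return A `year_embeddings` object of fine-tuned vectors.
#' @export
embed_cohort <- function(model, ye) {
  stopifnot(inherits(ye, "year_embeddings"))
  year_embeddings(embed_year(model, ye$vectors), ye$patient_id, ye$year_index)
}

#' Mean patient vectors
#'
#' The patient-level embedding: the exact arithmetic mean of a patient's
#' year vectors, invariant to year order.
#'
#' @param ye A `year_embeddings` object.
#' @return A list of class `patient_embedding`: `mean` (patients x d matrix
#'   with patient ids as rownames) and `n_years`.
#' @export
mean_patient_vector <- function(ye) {
  stopifnot(inherits(ye, "year_embeddings"))
  if (length(ye$patient_id) == 0L) stop("empty embedding series")
  sums <- rowsum(ye$vectors, ye$patient_id)
  n <- as.numeric(table(ye$patient_id)[rownames(sums)])
  out <- list(mean = sums / n, n_years = stats::setNames(n, rownames(sums)))
  class(out) <- "patient_embedding"
  out
}

# Distance-threshold classification accuracy for the same-patient task:
# threshold chosen on a calibration half, accuracy reported on the rest.
distance_threshold_accuracy <- function(dist, labels, calib_idx) {
  eval_idx <- setdiff(seq_along(dist), calib_idx)
  dc <- dist[calib_idx]; lc <- labels[calib_idx]
  ths <- sort(unique(dc))
  if (length(ths) > 200L) ths <- stats::quantile(dc, seq(0, 1, length.out = 200L))
  accs <- vapply(ths, function(th) mean((dc <= th) == (lc == 1L)), 0)
  th <- ths[which.max(accs)]
  mean((dist[eval_idx] <= th) == (labels[eval_idx] == 1L))
}

#' Evaluate the pair tasks
#'
#' Same-patient pairs are classified by thresholding the Euclidean distance
#' between fine-tuned embeddings (threshold calibrated on a held-in half of
#' each iteration's pairs); next-event pairs by the head's 0.5 cutoff. Each
#' task is scored on a class-balanced subset so chance performance is 0.5,
#' and accuracies are reported as mean and sd over `n_iter` resampling
#' iterations.
#'
#' @param model An `sbert_model` (or `NULL` to score raw input vectors by
#'   distance only; next-event is then skipped).
#' @param ye A `year_embeddings` object of pooled vectors.
#' @param pairs Labelled pairs from [sample_pairs()].
#' @param n_iter Evaluation iterations.
#' @param seed Integer seed.
#' @return A list with `same_patient` and `next_event` (each mean, sd) and
#'   the per-iteration accuracies.
#' @export
evaluate_pair_tasks <- function(model, ye, pairs, n_iter = 5L, seed = 1L) {
  set.seed(seed)
  if (length(unique(pairs$same_patient)) < 2L)
    stop("pair set contains a single same-patient class")
  E <- if (is.null(model)) ye$vectors else embed_year(model, ye$vectors)
  dist <- sqrt(rowSums((E[pairs$a, , drop = FALSE] -
                          E[pairs$b, , drop = FALSE])^2))
  head_prob <- NULL
  if (!is.null(model)) {
    ea <- E[pairs$a, , drop = FALSE]; eb <- E[pairs$b, , drop = FALSE]
    h <- pmax(sweep(cbind(ea, eb) %*% model$h1$W$value, 2L,
                    as.numeric(model$h1$b$value), "+"), 0)
    logit <- h %*% model$h2$W$value + model$h2$b$value[1L]
    head_prob <- 1 / (1 + exp(-logit[, 1L]))
  }
  acc_same <- numeric(n_iter); acc_next <- rep(NA_real_, n_iter)
  for (it in seq_len(n_iter)) {
    calib <- sample.int(nrow(pairs), nrow(pairs) %/% 2L)
    acc_same[it] <- distance_threshold_accuracy(dist, pairs$same_patient, calib)
    if (!is.null(head_prob)) {
      pos <- which(pairs$next_event == 1L)
      neg <- which(pairs$next_event == 0L)
      m <- min(length(pos), length(neg))
      if (m == 0L) stop("pair set contains a single next-event class")
      sel <- c(sample(pos, m), sample(neg, m))
      acc_next[it] <- mean((head_prob[sel] > 0.5) ==
                             (pairs$next_event[sel] == 1L))
    }
  }
  list(same_patient = c(mean = mean(acc_same), sd = stats::sd(acc_same)),
       next_event = c(mean = mean(acc_next), sd = stats::sd(acc_next)),
       iterations = data.frame(iter = seq_len(n_iter), same_patient = acc_same,
                               next_event = acc_next))
}
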