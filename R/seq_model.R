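# Year-sentence transformer. All of a patient's codes within one age-year
# form an unordered "sentence"; a standard encoder-decoder transformer
# *without positional encodings* is trained to predict the next year's
# sentence from the current year's, with 20% of input codes masked. Pooled
# (mean over non-PAD positions) final encoder states are the per-year
# patient representations consumed downstream.

#' Build year sentences from an event table
#'
#' Bins each patient's vocabulary-retained codes by age-year
#' (`floor(age_days / 365.25)`). One sentence is produced per
#' (patient, year) with at least one retained code; within a year, tokens
#' are ordered by age then code (a deterministic order that carries no
#' positional meaning for the model). Sentences longer than `max_len` keep
#' their earliest `max_len` tokens; the number truncated is reported via a
#' message.
#'
#' @param events Event table.
#' @param vocab An `ehr_vocab`.
#' @param max_len Maximum sentence length; shorter sentences are PAD-filled.
#' @return An object of class `sentence_corpus`: `patient_id`, `year_index`,
#'   `tokens` (n x max_len integer matrix, PAD-filled), `length` (true
#'   lengths), and the `vocab`.
#' @export
build_year_sentences <- function(events, vocab, max_len = 250L) {
  stopifnot(inherits(vocab, "ehr_vocab"), max_len >= 1L)
  validate_events(events)
  ids <- token_to_id(vocab, events$code)
  keep <- !is.na(ids)
  ev <- events[keep, , drop = FALSE]
  ids <- ids[keep]
  if (nrow(ev) == 0L) {
    out <- list(patient_id = character(), year_index = integer(),
                tokens = matrix(vocab$pad_id, 0L, max_len),
                length = integer(), max_len = as.integer(max_len),
                vocab = vocab)
    class(out) <- "sentence_corpus"
    return(out)
  }
  ord <- order(ev$patient_id, ev$age_days, ev$code)
  ev <- ev[ord, , drop = FALSE]
  ids <- ids[ord]
  yr <- age_to_year(ev$age_days)
  key <- paste(ev$patient_id, yr, sep = "\r")
  grp <- split(seq_along(ids), factor(key, levels = unique(key)))
  n <- length(grp)
  tokens <- matrix(vocab$pad_id, n, max_len)
  lens <- integer(n)
  pid <- character(n); yidx <- integer(n)
  truncated <- 0L
  for (g in seq_len(n)) {
    rows <- grp[[g]]
    pid[g] <- ev$patient_id[rows[1L]]
    yidx[g] <- yr[rows[1L]]
    if (length(rows) > max_len) {
      truncated <- truncated + 1L
      rows <- rows[seq_len(max_len)]
    }
    lens[g] <- length(rows)
    tokens[g, seq_along(rows)] <- ids[rows]
  }
  if (truncated > 0L)
    message(truncated, " sentence(s) truncated to max_len = ", max_len)
  out <- list(patient_id = pid, year_index = yidx, tokens = tokens,
              length = lens, max_len = as.integer(max_len), vocab = vocab)
  class(out) <- "sentence_corpus"
  out
}

#' Enumerate next-year sentence pairs
#'
#' A pair (i, j) is formed for every sentence i whose patient also has a
#' sentence j at `year_index + 1`; gap years and final years produce no
#' pair.
#'
#' @param corpus A `sentence_corpus`.
#' @return A `data.frame` with columns `input` and `target` (sentence row
#'   indices into the corpus).
#' @export
make_nextyear_pairs <- function(corpus) {
  stopifnot(inherits(corpus, "sentence_corpus"))
  n <- length(corpus$patient_id)
  if (n == 0L)
    return(data.frame(input = integer(), target = integer()))
  key <- paste(corpus$patient_id, corpus$year_index, sep = "\r")
  nxt <- match(paste(corpus$patient_id, corpus$year_index + 1L, sep = "\r"), key)
  ok <- which(!is.na(nxt))
  data.frame(input = ok, target = nxt[ok])
}

#' Mask tokens of a year sentence
#'
#' Replaces `ceil(fraction * true_length)` non-PAD positions, chosen
#' uniformly without replacement, with the MASK token. PAD positions are
#' never masked. Uses the current RNG state.
#'
#' @param tokens Padded integer token vector.
#' @param n_real True (non-PAD) length.
#' @param fraction Masking fraction in (0, 1).
#' @param mask_id MASK token id.
#' @return A list: `input` (masked tokens), `labels` (original token at
#'   masked positions, `NA` elsewhere), `masked` (positions).
#' @export
mask_tokens <- function(tokens, n_real, fraction, mask_id = 2L) {
  stopifnot(fraction > 0, fraction < 1)
  labels <- rep(NA_integer_, length(tokens))
  if (n_real == 0L)
    return(list(input = tokens, labels = labels, masked = integer()))
  n_mask <- ceiling(fraction * n_real)
  pos <- sample.int(n_real, n_mask)
  labels[pos] <- tokens[pos]
  tokens[pos] <- mask_id
  list(input = tokens, labels = labels, masked = sort(pos))
}

#' Transformer configuration
#'
#' The production preset follows the selected architecture: L = 6 layers,
#' H = 10 heads, feed-forward width 2048, model width d = 50, maximum
#' sentence length 250, 20% input masking, batch size 32, Adam with
#' beta1 = 0.9, beta2 = 0.98, epsilon = 1e-9, and a warmup /
#' inverse-square-root learning-rate schedule calibrated so the rate at
#' step 10,000 equals `lr_target` (0.002).
#'
#' @param n_layers,n_heads,dff,d Architecture; `d` divisible by `n_heads`.
#' @param max_len Maximum sentence length.
#' @param mask_fraction Input masking fraction.
#' @param batch_size Pairs per step.
#' @param steps Training steps.
#' @param beta1,beta2,eps Adam moments.
#' @param warmup_steps Linear warmup length.
#' @param lr_target,lr_target_step The schedule passes through `lr_target`
#'   at `lr_target_step` during inverse-square-root decay.
#' @param peak_lr Optional explicit peak rate; overrides the calibration.
#' @param validation_fraction Fraction of pairs held out for validation
#'   loss.
#' @param finetune_embeddings Whether the token-embedding table is updated
#'   during training.
#' @param seed Integer seed.
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(n_layers = 6L, n_heads = 10L, dff = 2048L,
                               d = 50L, max_len = 250L, mask_fraction = 0.2,
                               batch_size = 32L, steps = 20000L,
                               beta1 = 0.9, beta2 = 0.98, eps = 1e-9,
                               warmup_steps = 1000L, lr_target = 0.002,
                               lr_target_step = 10000L, peak_lr = NULL,
                               validation_fraction = 0.05,
                               finetune_embeddings = TRUE, seed = 1L) {
  stopifnot(d %% n_heads == 0L, mask_fraction > 0, mask_fraction < 1)
  if (is.null(peak_lr)) {
    # inverse-sqrt decay after warmup: lr(s) = peak * sqrt(warmup / s)
    peak_lr <- lr_target * sqrt(lr_target_step / warmup_steps)
  }
  cfg <- list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              dff = as.integer(dff), d = as.integer(d),
              max_len = as.integer(max_len), mask_fraction = mask_fraction,
              batch_size = as.integer(batch_size), steps = as.integer(steps),
              beta1 = beta1, beta2 = beta2, eps = eps,
              warmup_steps = as.integer(warmup_steps),
              peak_lr = peak_lr, validation_fraction = validation_fraction,
              finetune_embeddings = isTRUE(finetune_embeddings),
              seed = as.integer(seed))
  class(cfg) <- "transformer_config"
  cfg
}

#' Desk-scale transformer preset
#'
#' Small architecture (L = 2, H = 2, dff = 64, d = 32, max_len = 32) for
#' single-CPU runs and tests.
#' @param ... Overrides passed to [transformer_config()].
#' @export
transformer_desk_config <- function(...) {
  do.call(transformer_config, utils::modifyList(
    list(n_layers = 2L, n_heads = 2L, dff = 64L, d = 32L, max_len = 32L,
         batch_size = 16L, steps = 2000L, warmup_steps = 100L,
         peak_lr = 3e-3), list(...)))
}

transformer_lr <- function(cfg, step) {
  cfg$peak_lr * min(step / cfg$warmup_steps, sqrt(cfg$warmup_steps / step))
}

new_transformer_layers <- function(cfg, vocab_size) {
  d <- cfg$d
  mk_attn <- function() list(q = ad_linear_new(d, d), k = ad_linear_new(d, d),
                             v = ad_linear_new(d, d), o = ad_linear_new(d, d))
  mk_ffn <- function() list(l1 = ad_linear_new(d, cfg$dff),
                            l2 = ad_linear_new(cfg$dff, d))
  enc <- lapply(seq_len(cfg$n_layers), function(i) list(
    attn = mk_attn(), ln1 = ad_layernorm_new(d),
    ffn = mk_ffn(), ln2 = ad_layernorm_new(d)))
  dec <- lapply(seq_len(cfg$n_layers), function(i) list(
    self = mk_attn(), ln1 = ad_layernorm_new(d),
    cross = mk_attn(), ln2 = ad_layernorm_new(d),
    ffn = mk_ffn(), ln3 = ad_layernorm_new(d)))
  list(enc = enc, dec = dec, out = ad_linear_new(d, vocab_size))
}

attn_block <- function(blk, xq, xkv, n_heads, seg_q, seg_k, causal = FALSE) {
  q <- ad_linear(blk$q, xq)
  k <- ad_linear(blk$k, xkv)
  v <- ad_linear(blk$v, xkv)
  ad_linear(blk$o, ad_mha(q, k, v, n_heads, seg_q, seg_k, causal = causal))
}

ffn_block <- function(blk, x) ad_linear(blk$l2, ad_relu(ad_linear(blk$l1, x)))

encoder_forward <- function(model, tok_ids, seg) {
  x <- ad_embed(model$E, tok_ids)
  for (ly in model$layers$enc) {
    x <- ad_layernorm(ad_add(x, attn_block(ly$attn, x, x, model$config$n_heads,
                                           seg, seg)),
                      ly$ln1$gamma, ly$ln1$beta)
    x <- ad_layernorm(ad_add(x, ffn_block(ly$ffn, x)),
                      ly$ln2$gamma, ly$ln2$beta)
  }
  x
}

decoder_forward <- function(model, dec_ids, dec_seg, memory, mem_seg) {
  y <- ad_embed(model$E, dec_ids)
  for (ly in model$layers$dec) {
    y <- ad_layernorm(ad_add(y, attn_block(ly$self, y, y, model$config$n_heads,
                                           dec_seg, dec_seg, causal = TRUE)),
                      ly$ln1$gamma, ly$ln1$beta)
    y <- ad_layernorm(ad_add(y, attn_block(ly$cross, y, memory,
                                           model$config$n_heads,
                                           dec_seg, mem_seg)),
                      ly$ln2$gamma, ly$ln2$beta)
    y <- ad_layernorm(ad_add(y, ffn_block(ly$ffn, y)),
                      ly$ln3$gamma, ly$ln3$beta)
  }
  ad_linear(model$layers$out, y)
}

# Assemble ragged encoder/decoder inputs for a batch of (input, target)
# sentence pairs. Masking is applied to encoder tokens when mask_fraction
# is non-NULL.
batch_tensors <- function(corpus, input_idx, target_idx, mask_fraction,
                          vocab) {
  enc_tok <- integer(0); enc_seg <- integer(0)
  dec_tok <- integer(0); dec_seg <- integer(0); labels <- integer(0)
  for (b in seq_along(input_idx)) {
    i <- input_idx[b]
    li <- corpus$length[i]
    ti <- corpus$tokens[i, seq_len(li)]
    if (!is.null(mask_fraction)) {
      mk <- mask_tokens(ti, li, mask_fraction, vocab$mask_id)
      ti <- mk$input
    }
    enc_tok <- c(enc_tok, ti); enc_seg <- c(enc_seg, rep(b, li))
    j <- target_idx[b]
    lj <- corpus$length[j]
    tj <- corpus$tokens[j, seq_len(lj)]
    dec_tok <- c(dec_tok, vocab$bos_id, tj[-lj][seq_len(lj - 1L)])
    dec_seg <- c(dec_seg, rep(b, lj))
    labels <- c(labels, tj)
  }
  list(enc_tok = enc_tok, enc_seg = enc_seg, dec_tok = dec_tok,
       dec_seg = dec_seg, labels = labels)
}

#' Train the next-year transformer
#'
#' Encoder-decoder transformer with no positional encodings anywhere;
#' token embeddings are initialised from the code VAE (see
#' [embedding_table()]) and fine-tuned by default. Each step draws a batch
#' of (year i, year i+1) sentence pairs, masks `mask_fraction` of the input
#' tokens, and minimises token-level cross-entropy of the target-year
#' sentence under teacher forcing (PAD positions excluded by construction:
#' only true-length tokens enter the batch).
#'
#' @param corpus A `sentence_corpus`.
#' @param pairs Output of [make_nextyear_pairs()].
#' @param embeddings `vocab$size x d` initial token-embedding matrix.
#' @param config A [transformer_config()].
#' @param verbose Print progress every 200 steps.
#' @return An object of class `ehr_transformer`: parameters, config, vocab,
#'   and `log` (step, loss, lr, val_loss).
#' @export
train_transformer <- function(corpus, pairs, embeddings,
                              config = transformer_desk_config(),
                              verbose = FALSE) {
  stopifnot(inherits(corpus, "sentence_corpus"),
            inherits(config, "transformer_config"))
  if (nrow(pairs) == 0L) stop("no next-year pairs to train on")
  vocab <- corpus$vocab
  if (nrow(embeddings) != vocab$size || ncol(embeddings) != config$d)
    stop("embedding matrix does not match vocabulary size / model width")
  set.seed(config$seed)
  model <- list(E = ad_param(embeddings),
                layers = new_transformer_layers(config, vocab$size),
                config = config, vocab = vocab)
  class(model) <- "ehr_transformer"
  params <- ad_params(model$layers)
  if (config$finetune_embeddings) params <- c(params, list(model$E))
  opt <- adam_new(params, beta1 = config$beta1, beta2 = config$beta2,
                  eps = config$eps)

  n_val <- max(0L, floor(config$validation_fraction * nrow(pairs)))
  val <- if (n_val >= 1L) sample.int(nrow(pairs), n_val) else integer(0)
  train_rows <- setdiff(seq_len(nrow(pairs)), val)
  if (length(train_rows) == 0L) stop("no training pairs left after split")

  log <- vector("list", config$steps)
  pool <- sample(train_rows)
  pos <- 1L
  for (step in seq_len(config$steps)) {
    take <- min(config$batch_size, length(train_rows))
    if (pos + take - 1L > length(pool)) { pool <- sample(train_rows); pos <- 1L }
    rows <- pool[pos:(pos + take - 1L)]
    pos <- pos + take
    bt <- batch_tensors(corpus, pairs$input[rows], pairs$target[rows],
                        config$mask_fraction, vocab)
    ad_tape_reset()
    memory <- encoder_forward(model, bt$enc_tok, bt$enc_seg)
    logits <- decoder_forward(model, bt$dec_tok, bt$dec_seg, memory, bt$enc_seg)
    loss <- ad_softmax_xent(logits, bt$labels)
    if (!is.finite(loss$value[1]))
      stop("non-finite transformer loss at step ", step)
    ad_backward(loss)
    opt <- adam_step(opt, transformer_lr(config, step))
    vl <- NA_real_
    if (length(val) > 0L && (step %% 200L == 0L || step == config$steps)) {
      vrows <- val[seq_len(min(length(val), 64L))]
      vl <- transformer_eval_loss(model, corpus, pairs[vrows, , drop = FALSE])
    }
    log[[step]] <- data.frame(step = step, loss = loss$value[1],
                              lr = transformer_lr(config, step), val_loss = vl)
    if (verbose && step %% 200L == 0L)
      message("step ", step, " loss ", round(loss$value[1], 4))
  }
  ad_tape_reset()
  model$log <- do.call(rbind, log)
  model$val_rows <- val
  model
}

# Teacher-forced mean cross-entropy on a pair set (no masking).
transformer_eval_loss <- function(model, corpus, pairs) {
  bt <- batch_tensors(corpus, pairs$input, pairs$target, NULL, model$vocab)
  ad_tape_reset()
  memory <- encoder_forward(model, bt$enc_tok, bt$enc_seg)
  logits <- decoder_forward(model, bt$dec_tok, bt$dec_seg, memory, bt$enc_seg)
  out <- ad_softmax_xent(logits, bt$labels)$value[1]
  ad_tape_reset()
  out
}

#' Teacher-forced next-year token accuracy
#'
#' Fraction of target-year token positions (PAD excluded) whose argmax
#' prediction matches the true token, over a set of next-year pairs.
#'
#' @param model An `ehr_transformer`.
#' @param corpus The sentence corpus.
#' @param pairs Pair rows to evaluate.
#' @param batch_size Evaluation batch size.
#' @return Accuracy in [0, 1].
#' @export
nextyear_token_accuracy <- function(model, corpus, pairs, batch_size = 64L) {
  hits <- 0L; tot <- 0L
  chunks <- split(seq_len(nrow(pairs)), ceiling(seq_len(nrow(pairs)) / batch_size))
  for (ch in chunks) {
    bt <- batch_tensors(corpus, pairs$input[ch], pairs$target[ch], NULL,
                        model$vocab)
    ad_tape_reset()
    memory <- encoder_forward(model, bt$enc_tok, bt$enc_seg)
    logits <- decoder_forward(model, bt$dec_tok, bt$dec_seg, memory,
                              bt$enc_seg)$value
    ad_tape_reset()
    pred <- max.col(logits, ties.method = "first")
    hits <- hits + sum(pred == bt$labels)
    tot <- tot + length(bt$labels)
  }
  hits / tot
}

#' Reconstruct the code set of a sentence
#'
#' Feeds the unmasked sentence through the encoder, teacher-forces the
#' decoder on the same year, takes the argmax token at each true-length
#' position, drops reserved tokens and deduplicates.
#'
#' @param model An `ehr_transformer`.
#' @param corpus The sentence corpus.
#' @param idx Sentence row indices to reconstruct.
#' @return A list of integer code-id sets, one per sentence.
#' @export
reconstruct_codes <- function(model, corpus, idx) {
  out <- vector("list", length(idx))
  chunks <- split(seq_along(idx), ceiling(seq_along(idx) / 64L))
  for (ch in chunks) {
    ii <- idx[ch]
    bt <- batch_tensors(corpus, ii, ii, NULL, model$vocab)
    ad_tape_reset()
    memory <- encoder_forward(model, bt$enc_tok, bt$enc_seg)
    logits <- decoder_forward(model, bt$dec_tok, bt$dec_seg, memory,
                              bt$enc_seg)$value
    ad_tape_reset()
    pred <- max.col(logits, ties.method = "first")
    for (b in seq_along(ii)) {
      p <- pred[bt$dec_seg == b]
      p <- p[p > model$vocab$n_reserved]    # never PAD/MASK/BOS
      out[[ch[b]]] <- unique(p)
    }
  }
  out
}

#' Per-event sequence-recovery precision and recall
#'
#' @param predicted List of predicted code-id sets.
#' @param truth List of true code-id sets, aligned with `predicted`; events
#'   with empty truth are skipped.
#' @return A list: `per_event` data.frame (precision, recall) and `summary`
#'   (mean, sd, median, IQR for both metrics).
#' @export
sequence_recovery_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth collections differ in length")
  rows <- lapply(seq_along(truth), function(i) {
    tr <- unique(truth[[i]])
    if (length(tr) == 0L) return(NULL)
    pr <- unique(predicted[[i]])
    inter <- length(intersect(pr, tr))
    data.frame(precision = if (length(pr) == 0L) 0 else inter / length(pr),
               recall = inter / length(tr))
  })
  per_event <- do.call(rbind, rows)
  if (is.null(per_event))
    per_event <- data.frame(precision = numeric(), recall = numeric())
  summ <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        median = stats::median(x), IQR = stats::IQR(x))
  list(per_event = per_event,
       summary = rbind(precision = summ(per_event$precision),
                       recall = summ(per_event$recall)))
}

#' Masked-token prediction accuracy
#'
#' Masks `fraction` of each sentence's tokens, reconstructs the same year
#' (teacher-forced), and reports the fraction of masked positions whose
#' argmax prediction equals the hidden token.
#'
#' @param model An `ehr_transformer`.
#' @param corpus The sentence corpus.
#' @param fraction Masking fraction.
#' @param idx Sentence rows to evaluate (default: all).
#' @param seed Seed for the masking draw.
#' @return Accuracy in [0, 1].
#' @export
masked_prediction_accuracy <- function(model, corpus, fraction = 0.2,
                                       idx = seq_along(corpus$length),
                                       seed = 1L) {
  set.seed(seed)
  hits <- 0L; tot <- 0L
  chunks <- split(seq_along(idx), ceiling(seq_along(idx) / 64L))
  for (ch in chunks) {
    ii <- idx[ch]
    enc_tok <- integer(0); enc_seg <- integer(0)
    dec_tok <- integer(0); dec_seg <- integer(0)
    labels <- integer(0); mask_flag <- logical(0)
    for (b in seq_along(ii)) {
      i <- ii[b]
      li <- corpus$length[i]
      ti <- corpus$tokens[i, seq_len(li)]
      mk <- mask_tokens(ti, li, fraction, model$vocab$mask_id)
      enc_tok <- c(enc_tok, mk$input); enc_seg <- c(enc_seg, rep(b, li))
      dec_tok <- c(dec_tok, model$vocab$bos_id, ti[-li][seq_len(li - 1L)])
      dec_seg <- c(dec_seg, rep(b, li))
      labels <- c(labels, ti)
      flag <- rep(FALSE, li); flag[mk$masked] <- TRUE
      mask_flag <- c(mask_flag, flag)
    }
    ad_tape_reset()
    memory <- encoder_forward(model, enc_tok, enc_seg)
    logits <- decoder_forward(model, dec_tok, dec_seg, memory, enc_seg)$value
    ad_tape_reset()
    pred <- max.col(logits, ties.method = "first")
    hits <- hits + sum(pred[mask_flag] == labels[mask_flag])
    tot <- tot + sum(mask_flag)
  }
  if (tot == 0L) return(NA_real_)
  hits / tot
}

#' Pooled year embeddings
#'
#' The per-year patient representation: the mean over non-PAD positions of
#' the final encoder states of the (unmasked) sentence. Deterministic; with
#' no positional encodings it is invariant to within-year token order.
#'
#' @param model An `ehr_transformer`.
#' @param corpus The sentence corpus.
#' @param idx Sentence rows to embed (default: all).
#' @param batch_size Sentences per inference batch.
#' @return A numeric matrix `length(idx) x d`.
#' @export
pool_year_embeddings <- function(model, corpus, idx = seq_along(corpus$length),
                                 batch_size = 64L) {
  if (any(corpus$length[idx] == 0L)) stop("cannot pool an all-PAD sentence")
  d <- model$config$d
  out <- matrix(0, length(idx), d)
  chunks <- split(seq_along(idx), ceiling(seq_along(idx) / batch_size))
  for (ch in chunks) {
    ii <- idx[ch]
    enc_tok <- integer(0); enc_seg <- integer(0)
    for (b in seq_along(ii)) {
      li <- corpus$length[ii[b]]
      enc_tok <- c(enc_tok, corpus$tokens[ii[b], seq_len(li)])
      enc_seg <- c(enc_seg, rep(b, li))
    }
    ad_tape_reset()
    mem <- encoder_forward(model, enc_tok, enc_seg)$value
    ad_tape_reset()
    pooled <- rowsum(mem, enc_seg) / as.numeric(table(enc_seg))
    out[ch, ] <- pooled
  }
  out
}

#' Pool one sentence given as a token vector
#'
#' Convenience wrapper for a single padded sentence.
#' @param model An `ehr_transformer`.
#' @param tokens Padded integer token vector.
#' @param n_real True length (> 0).
#' @return A numeric vector of length d.
#' @export
pool_year_embedding <- function(model, tokens, n_real) {
  if (n_real == 0L) stop("cannot pool an all-PAD sentence")
  tok <- tokens[seq_len(n_real)]
  ad_tape_reset()
  mem <- encoder_forward(model, tok, rep(1L, n_real))$value
  ad_tape_reset()
  colMeans(mem)
}
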