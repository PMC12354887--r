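# Vocabulary embedding: each retained code's age-frequency profile
# (occurrences per age-week, pooled over patients) is compressed to a
# low-dimensional latent vector by a variational autoencoder whose loss
# combines reconstruction error, a cosine-structure term that preserves
# pairwise linear correlation between codes, and a KL term.

#' Build the model vocabulary from an event table
#'
#' Retains codes whose total occurrence count is strictly greater than
#' `min_occurrences`. Three special tokens are reserved ahead of the code
#' tokens: PAD (padding), MASK (input masking) and BOS (decoder
#' start-of-sentence); none of these can occur in event data.
#'
#' @param events Event table.
#' @param min_occurrences Strict occurrence threshold; a code must appear
#'   more than this many times to be kept.
#' @return An object of class `ehr_vocab`: `tokens` (retained codes, ordered
#'   by decreasing count then token), `counts`, reserved ids `pad_id`,
#'   `mask_id`, `bos_id`, and `size` (total token count incl. reserved).
#' @export
filter_vocabulary <- function(events, min_occurrences = 5L) {
  validate_events(events)
  if (nrow(events) == 0L) stop("empty event table")
  tab <- table(events$code)
  keep <- tab[tab > min_occurrences]
  if (length(keep) == 0L)
    stop("no code appears more than ", min_occurrences,
         " times; lower the threshold")
  ord <- order(-as.integer(keep), names(keep))
  vocab <- list(
    tokens = names(keep)[ord],
    counts = as.integer(keep)[ord],
    pad_id = 1L, mask_id = 2L, bos_id = 3L,
    n_reserved = 3L,
    size = 3L + length(keep)
  )
  class(vocab) <- "ehr_vocab"
  vocab
}

#' Map code tokens to vocabulary indices
#' @param vocab An `ehr_vocab`.
#' @param codes Character vector; codes outside the vocabulary give `NA`.
#' @return Integer ids.
#' @export
token_to_id <- function(vocab, codes) {
  m <- match(codes, vocab$tokens)
  ifelse(is.na(m), NA_integer_, m + vocab$n_reserved)
}

#' Map vocabulary indices back to code tokens
#' @param vocab An `ehr_vocab`.
#' @param ids Integer ids; reserved ids return `NA`.
#' @export
id_to_token <- function(vocab, ids) {
  out <- rep(NA_character_, length(ids))
  real <- !is.na(ids) & ids > vocab$n_reserved
  out[real] <- vocab$tokens[ids[real] - vocab$n_reserved]
  out
}

#' Build the code-by-age-week onset-frequency matrix
#'
#' Counts occurrences of each vocabulary code at each patient-age week
#' (`floor(age_days / 7)`), pooled over patients. Events at ages beyond the
#' last week bin are clipped into it with a warning.
#'
#' @param events Event table.
#' @param vocab An `ehr_vocab`.
#' @param n_weeks Number of week bins (default 4320 = 90 years).
#' @return An integer matrix `|V| x n_weeks` with code tokens as rownames;
#'   the sum of all entries equals the number of retained events.
#' @export
build_frequency_matrix <- function(events, vocab, n_weeks = 4320L) {
  stopifnot(inherits(vocab, "ehr_vocab"), n_weeks >= 1L)
  keep <- events$code %in% vocab$tokens
  ev <- events[keep, , drop = FALSE]
  mat <- matrix(0L, nrow = length(vocab$tokens), ncol = n_weeks,
                dimnames = list(vocab$tokens, NULL))
  if (nrow(ev) == 0L) return(mat)
  over <- sum(ev$age_days >= n_weeks * 7L)
  if (over > 0L)
    warning(over, " event(s) beyond week ", n_weeks,
            " clipped to the last bin")
  wk <- age_to_week(ev$age_days, n_weeks)
  ri <- match(ev$code, vocab$tokens)
  tab <- table(factor(ri, levels = seq_along(vocab$tokens)),
               factor(wk, levels = 0:(n_weeks - 1L)))
  mat[] <- as.integer(tab)
  mat
}

#' VAE configuration
#'
#' @param latent_dim Latent embedding dimension (production default 50).
#' @param hidden Encoder hidden-layer widths (mirrored in the decoder); the
#'   production default `c(1024, 256)` gives a three-layer encoder
#'   (input -> 1024 -> 256 -> latent).
#' @param learning_rate Adam learning rate. The production preset is 1e-7;
#'   [vae_desk_config()] uses 1e-3, which is appropriate for toy matrices.
#' @param batch_size,epochs Training schedule.
#' @param w_recon,w_cos,w_kl Loss weights for the reconstruction, cosine
#'   structure and KL terms.
#' @param validation_fraction Fraction of codes held out to track
#'   validation loss.
#' @param seed Integer seed.
#' @return A `vae_config` list.
#' @export
vae_config <- function(latent_dim = 50L, hidden = c(1024L, 256L),
                       learning_rate = 1e-7, batch_size = 64L,
                       epochs = 100L, w_recon = 1, w_cos = 1, w_kl = 0.1,
                       validation_fraction = 0.05, seed = 1L) {
  stopifnot(latent_dim >= 1L, all(hidden >= 1L),
            w_recon >= 0, w_cos >= 0, w_kl >= 0)
  cfg <- list(latent_dim = as.integer(latent_dim), hidden = as.integer(hidden),
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), w_recon = w_recon, w_cos = w_cos,
              w_kl = w_kl, validation_fraction = validation_fraction,
              seed = as.integer(seed))
  class(cfg) <- "vae_config"
  cfg
}

#' Desk-scale VAE preset
#'
#' Small widths and a practical learning rate for toy matrices and tests.
#' @param ... Overrides passed to [vae_config()].
#' @export
vae_desk_config <- function(...) {
  do.call(vae_config, utils::modifyList(
    list(latent_dim = 32L, hidden = c(128L, 64L), learning_rate = 1e-3,
         batch_size = 32L, epochs = 30L), list(...)))
}

vae_forward_mu <- function(model, X) {
  h <- X
  for (ly in model$enc) h <- pmax(h %*% ly$W$value +
                                    matrix(ly$b$value, nrow(h), length(ly$b$value), byrow = TRUE), 0)
  list(mu = h %*% model$mu$W$value +
         matrix(model$mu$b$value, nrow(h), model$config$latent_dim, byrow = TRUE),
       logvar = h %*% model$lv$W$value +
         matrix(model$lv$b$value, nrow(h), model$config$latent_dim, byrow = TRUE))
}

#' Train the code variational autoencoder
#'
#' Each code's frequency row is scaled to unit L2 norm; the model is trained
#' to minimise `w_recon * MSE(reconstruction, row) + w_cos *` (squared
#' difference between the batch's input-space and latent-mean cosine
#' similarity matrices) `+ w_kl * KL(q || N(0, I))`, using the
#' reparameterisation trick and Adam.
#'
#' @param freq_matrix Output of [build_frequency_matrix()].
#' @param config A [vae_config()].
#' @return An object of class `code_vae` with the trained layers, the
#'   config, and `history` (per-epoch train/validation losses and loss
#'   components).
#' @export
train_code_vae <- function(freq_matrix, config = vae_config()) {
  stopifnot(inherits(config, "vae_config"), nrow(freq_matrix) >= 2L)
  set.seed(config$seed)
  X <- freq_matrix / pmax(sqrt(rowSums(freq_matrix^2)), 1e-12)
  n <- nrow(X); Tdim <- ncol(X); d <- config$latent_dim
  widths <- c(Tdim, config$hidden)
  enc <- lapply(seq_len(length(widths) - 1L),
                function(i) ad_linear_new(widths[i], widths[i + 1L]))
  mu_head <- ad_linear_new(widths[length(widths)], d)
  lv_head <- ad_linear_new(widths[length(widths)], d)
  dwidths <- c(d, rev(config$hidden), Tdim)
  dec <- lapply(seq_len(length(dwidths) - 1L),
                function(i) ad_linear_new(dwidths[i], dwidths[i + 1L]))
  model <- list(enc = enc, mu = mu_head, lv = lv_head, dec = dec,
                config = config, tokens = rownames(freq_matrix))
  params <- ad_params(list(enc, mu_head, lv_head, dec))
  opt <- adam_new(params)

  n_val <- max(if (n >= 20L) ceiling(config$validation_fraction * n) else 0L, 0L)
  val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  fwd_loss <- function(rows, sample_z = TRUE) {
    xb <- X[rows, , drop = FALSE]
    x <- ad_const(xb)
    h <- x
    for (ly in enc) h <- ad_relu(ad_linear(ly, h))
    mu <- ad_linear(mu_head, h)
    lv <- ad_linear(lv_head, h)
    z <- if (sample_z) {
      eps <- matrix(stats::rnorm(length(rows) * d), length(rows), d)
      ad_add(mu, ad_mul(ad_exp(ad_scale(lv, 0.5)), ad_const(eps)))
    } else mu
    hdec <- z
    for (i in seq_along(dec)) {
      hdec <- ad_linear(dec[[i]], hdec)
      if (i < length(dec)) hdec <- ad_relu(hdec)
    }
    recon <- ad_mse(hdec, ad_const(xb))
    Cin <- xb %*% t(xb)   # rows are unit-norm, so this is the cosine matrix
    cosl <- ad_cosine_match(mu, ad_const(Cin))
    kl <- ad_kl_gauss(mu, lv)
    total <- ad_add(ad_scale(recon, config$w_recon),
                    ad_add(ad_scale(cosl, config$w_cos),
                           ad_scale(kl, config$w_kl)))
    list(total = total, recon = recon$value[1], cos = cosl$value[1],
         kl = kl$value[1])
  }

  history <- data.frame()
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(tr_idx)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0; ep_recon <- 0; ep_cos <- 0; ep_kl <- 0
    for (b in batches) {
      if (length(b) < 2L) next
      ad_tape_reset()
      fl <- fwd_loss(b)
      ad_backward(fl$total)
      opt <- adam_step(opt, config$learning_rate)
      ep_loss <- ep_loss + fl$total$value[1] * length(b)
      ep_recon <- ep_recon + fl$recon * length(b)
      ep_cos <- ep_cos + fl$cos * length(b)
      ep_kl <- ep_kl + fl$kl * length(b)
    }
    val_loss <- NA_real_
    if (length(val_idx) >= 2L) {
      ad_tape_reset()
      val_loss <- fwd_loss(val_idx, sample_z = FALSE)$total$value[1]
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / length(perm),
      recon = ep_recon / length(perm), cosine = ep_cos / length(perm),
      kl = ep_kl / length(perm), val_loss = val_loss))
  }
  ad_tape_reset()
  model$history <- history
  class(model) <- "code_vae"
  model
}

#' Encode codes to their latent embeddings
#'
#' Deterministic inference: returns the latent means (no sampling), one row
#' per code, in the row order of the input matrix.
#'
#' @param model A trained `code_vae`.
#' @param freq_matrix The frequency matrix to encode (same width as used in
#'   training).
#' @return A list of class `code_embedding`: `mean` (codes x latent_dim) and
#'   `logvar`, both with code rownames.
#' @export
encode_codes <- function(model, freq_matrix) {
  stopifnot(inherits(model, "code_vae"))
  if (ncol(freq_matrix) != nrow(model$enc[[1]]$W$value))
    stop("frequency matrix width does not match the trained model")
  X <- freq_matrix / pmax(sqrt(rowSums(freq_matrix^2)), 1e-12)
  out <- vae_forward_mu(model, X)
  rownames(out$mu) <- rownames(freq_matrix)
  rownames(out$logvar) <- rownames(freq_matrix)
  res <- list(mean = out$mu, logvar = out$logvar)
  class(res) <- "code_embedding"
  res
}

#' Assemble the transformer token-embedding matrix
#'
#' Rows follow vocabulary id order: PAD, MASK and BOS receive fixed
#' zero/small embeddings (they have no frequency profile), followed by the
#' VAE latent means of the code tokens.
#'
#' @param vocab An `ehr_vocab`.
#' @param code_embedding Output of [encode_codes()] covering the vocabulary
#'   tokens.
#' @return A numeric matrix `vocab$size x latent_dim`.
#' @export
embedding_table <- function(vocab, code_embedding) {
  d <- ncol(code_embedding$mean)
  E <- matrix(0, vocab$size, d)
  m <- match(vocab$tokens, rownames(code_embedding$mean))
  if (anyNA(m)) stop("code embedding does not cover the vocabulary")
  E[vocab$n_reserved + seq_along(vocab$tokens), ] <- code_embedding$mean[m, ]
  E
}
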