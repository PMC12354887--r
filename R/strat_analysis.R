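# Stratification within a phenotype: Gaussian-mixture clustering of mean
# patient vectors with BIC model selection, covariate-adjusted comorbidity
# enrichment per cluster, Kaplan-Meier survival contrasts over a 10-year
# horizon, and post-onset progression analysis (PCA + ANOVA, emerging
# phenotypes).

#' Gaussian-mixture clustering with BIC model selection
#'
#' Fits Gaussian mixtures over the candidate component numbers by restarted
#' EM: for every (covariance structure, K) pair, EM is run from `n_init`
#' k-means initialisations plus mclust's hierarchical initialisation, the
#' highest-likelihood fit is kept, and the (structure, K) pair minimising
#' BIC (`-2 log L + k log n`) is returned with hard assignments by maximum
#' posterior. Covariance structures range from full to spherical and BIC
#' arbitrates, so high-dimensional fits fall back gracefully when a full
#' covariance is not estimable.
#'
#' @param x Numeric matrix of mean patient vectors (rownames = patient
#'   ids).
#' @param k_range Candidate numbers of clusters (default 2..8).
#' @param model_names mclust covariance structures to consider.
#' @param n_init Number of k-means restarts per (structure, K).
#' @param seed Integer seed.
#' @return A list of class `cluster_model`: `K` (chosen), `model_name`,
#'   `bic` (data.frame of the best BIC per K, minimize convention),
#'   `z` (posterior membership matrix of the chosen model), and
#'   `assignments` (data.frame patient_id, cluster with 0-based labels).
#' @export
fit_gmm_bic <- function(x, k_range = 2:8, model_names = c("VVV", "VVI", "EII"),
                        n_init = 10L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  set.seed(seed)
  n <- nrow(x); d <- ncol(x)
  k_range <- sort(unique(as.integer(k_range)))
  hcini <- tryCatch(mclust::hc(x, modelName = "VVV", use = "SVD"),
                    error = function(e) NULL)
  best <- NULL
  bic_rows <- list()
  for (K in k_range) {
    best_k <- NULL
    for (mod in model_names) {
      if (K == 1L) {
        fit <- tryCatch(mclust::mvn(mod, x), error = function(e) NULL)
        if (is.null(fit) || is.na(fit$loglik)) next
        val <- mclust::bic(mod, fit$loglik, n, d, 1L)
        cand <- list(loglik = fit$loglik, z = matrix(1, n, 1L), bic = val)
      } else {
        inits <- lapply(seq_len(n_init), function(r)
          tryCatch(mclust::unmap(stats::kmeans(x, K, nstart = 1L)$cluster,
                                 groups = seq_len(K)),
                   error = function(e) NULL))
        if (!is.null(hcini))
          inits <- c(inits, list(tryCatch(
            mclust::unmap(mclust::hclass(hcini, K), groups = seq_len(K)),
            error = function(e) NULL)))
        inits <- Filter(Negate(is.null), inits)
        cand <- NULL
        for (z0 in inits) {
          fit <- tryCatch(suppressWarnings(mclust::me(x, mod, z0)),
                          error = function(e) NULL)
          if (is.null(fit) || is.null(fit$loglik) || is.na(fit$loglik)) next
          if (is.null(cand) || fit$loglik > cand$loglik)
            cand <- list(loglik = fit$loglik, z = fit$z)
        }
        if (is.null(cand)) next
        cand$bic <- mclust::bic(mod, cand$loglik, n, d, K)
        if (is.na(cand$bic)) next
      }
      if (is.null(best_k) || cand$bic > best_k$bic) {
        best_k <- cand; best_k$model <- mod; best_k$K <- K
      }
    }
    if (is.null(best_k)) next
    bic_rows[[length(bic_rows) + 1L]] <-
      data.frame(K = K, model = best_k$model, bic = -best_k$bic)
    if (is.null(best) || best_k$bic > best$bic) best <- best_k
  }
  if (is.null(best)) stop("no Gaussian mixture could be fitted")
  pid <- rownames(x)
  if (is.null(pid)) pid <- as.character(seq_len(nrow(x)))
  cls <- max.col(best$z, ties.method = "first")
  # relabel clusters by size for determinism
  sz <- sort(table(cls), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sz) - 1L, names(sz))
  out <- list(K = best$K, model_name = best$model,
              bic = do.call(rbind, bic_rows), z = best$z,
              loglik = best$loglik,
              assignments = data.frame(
                patient_id = pid,
                cluster = unname(relab[as.character(cls)]),
                stringsAsFactors = FALSE),
              seed = seed)
  class(out) <- "cluster_model"
  out
}

# Penalised logistic fallback for separated fits: IRLS with an L2 penalty;
# Wald tests from the penalised information matrix.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 50L) {
  X <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    H <- t(X) %*% (X * w) + diag(lambda, ncol(X))
    g <- t(X) %*% (y - p) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- as.numeric(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- pmax(p * (1 - p), 1e-10)
  H <- t(X) %*% (X * w) + diag(lambda, ncol(X))
  se <- sqrt(diag(solve(H)))
  list(coef = stats::setNames(as.numeric(beta), colnames(X)),
       se = stats::setNames(se, colnames(X)))
}

#' Covariate-adjusted comorbidity enrichment per cluster
#'
#' For every (cluster, phecode) pair with the phecode observed in at least
#' `min_count` clustered patients, fits a logistic regression of phenotype
#' presence on a one-vs-rest cluster indicator plus age of onset, gender,
#' ethnicity, race and site. The cluster coefficient is reported as a log
#' odds ratio with its Wald p-value; p-values are adjusted across all
#' tests (Benjamini-Hochberg by default) and flagged significant below
#' `alpha` (default 2e-5). Fits that do not converge or that separate
#' completely are refitted with a small ridge and flagged rather than
#' dropped.
#'
#' @param assignments `data.frame(patient_id, cluster)` from
#'   [fit_gmm_bic()].
#' @param onsets Onset table (phenotype presence = any onset row).
#' @param covariates `data.frame` with `patient_id`, `age_of_onset` and
#'   categorical covariates; missing levels become `"unknown"`.
#' @param map Phecode map (for disease classes).
#' @param min_count Minimum phenotype carriers among clustered patients.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param alpha Significance level on the adjusted p-value.
#' @return A `data.frame`: cluster, phecode, disease_class, log_odds_ratio,
#'   p, p_adj, significant, flag, n_tests.
#' @export
comorbidity_enrichment <- function(assignments, onsets, covariates, map,
                                   min_count = 5L, adjust = c("BH", "bonferroni"),
                                   alpha = 2e-5) {
  adjust <- match.arg(adjust)
  pid <- assignments$patient_id
  cov <- covariates[match(pid, covariates$patient_id), , drop = FALSE]
  cov$patient_id <- NULL
  for (j in seq_along(cov)) {
    if (is.character(cov[[j]]) || is.factor(cov[[j]])) {
      v <- as.character(cov[[j]])
      v[is.na(v)] <- "unknown"
      # largest category as the reference level
      lv <- names(sort(table(v), decreasing = TRUE))
      cov[[j]] <- factor(v, levels = lv)
    } else {
      v <- cov[[j]]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      cov[[j]] <- v
    }
  }
  # drop covariates with a single level (no information)
  keep <- vapply(cov, function(v) length(unique(v)) > 1L, TRUE)
  cov <- cov[, keep, drop = FALSE]
  counts <- table(onsets$phecode[onsets$patient_id %in% pid])
  phe <- names(counts[counts >= min_count])
  clusters <- sort(unique(assignments$cluster))
  rows <- list()
  for (p in phe) {
    y <- as.integer(pid %in% onsets$patient_id[onsets$phecode == p])
    if (length(unique(y)) < 2L) next
    for (cl in clusters) {
      df <- cov
      df$in_cluster <- as.integer(assignments$cluster == cl)
      df$y <- y
      saw_sep <- FALSE; saw_ncv <- FALSE
      fit <- withCallingHandlers(
        stats::glm(y ~ ., data = df, family = stats::binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
            saw_sep <<- TRUE
          else if (grepl("did not converge", conditionMessage(w)))
            saw_ncv <<- TRUE
          invokeRestart("muffleWarning")
        })
      flag <- if (saw_sep) "separation" else if (saw_ncv) "nonconverged" else ""
      if (flag != "") {
        mm <- stats::model.matrix(y ~ ., data = df)[, -1, drop = FALSE]
        rf <- ridge_logistic(mm, y)
        beta <- rf$coef[["in_cluster"]]
        se <- rf$se[["in_cluster"]]
      } else {
        sm <- summary(fit)$coefficients
        if (!"in_cluster" %in% rownames(sm)) next
        beta <- sm["in_cluster", "Estimate"]
        se <- sm["in_cluster", "Std. Error"]
      }
      pval <- 2 * stats::pnorm(-abs(beta / se))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, phecode = p,
        disease_class = map$disease_class[match(p, map$phecode)],
        log_odds_ratio = beta, p = pval, flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(cluster = integer(), phecode = character(),
                      disease_class = character(), log_odds_ratio = numeric(),
                      p = numeric(), p_adj = numeric(), significant = logical(),
                      flag = character(), n_tests = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p,
                               method = if (adjust == "BH") "BH" else "bonferroni")
  out$significant <- out$p_adj < alpha
  out$n_tests <- nrow(out)
  out[order(out$cluster, out$phecode), , drop = FALSE]
}

#' Kaplan-Meier survival contrasts between clusters
#'
#' Estimates per-cluster Kaplan-Meier curves administratively censored at
#' the horizon, the global log-rank test across clusters, and all pairwise
#' log-rank tests with BH adjustment.
#'
#' @param assignments `data.frame(patient_id, cluster)`.
#' @param survival_tab `data.frame(patient_id, time_years, event)` with
#'   time measured from index onset.
#' @param horizon_years Follow-up horizon (default 10).
#' @return A list of class `survival_comparison`: `curves` (cluster, time,
#'   surv, n_risk), `global` (chisq, df, p), `pairwise` (cluster_a,
#'   cluster_b, chisq, p, p_adj), `n_per_cluster`.
#' @export
km_logrank <- function(assignments, survival_tab, horizon_years = 10) {
  d <- merge(survival_tab, assignments, by = "patient_id")
  if (nrow(d) == 0L) stop("no survival records match the cluster assignments")
  drop_cl <- setdiff(unique(assignments$cluster), unique(d$cluster))
  if (length(drop_cl) > 0L)
    warning("cluster(s) without survival records excluded: ",
            paste(drop_cl, collapse = ", "))
  over <- d$time_years > horizon_years
  d$event[over] <- 0L
  d$time_years[over] <- horizon_years
  if (length(unique(d$cluster)) < 2L)
    stop("need at least two clusters with survival records")
  d$cluster <- factor(d$cluster)
  sf <- survival::survfit(survival::Surv(time_years, event) ~ cluster, data = d)
  st <- summary(sf)
  curves <- data.frame(cluster = sub("^cluster=", "", as.character(st$strata)),
                       time = st$time, surv = st$surv, n_risk = st$n.risk,
                       stringsAsFactors = FALSE)
  gd <- survival::survdiff(survival::Surv(time_years, event) ~ cluster,
                           data = d)
  global <- data.frame(chisq = gd$chisq, df = length(gd$n) - 1L,
                       p = stats::pchisq(gd$chisq, length(gd$n) - 1L,
                                         lower.tail = FALSE))
  cls <- levels(d$cluster)
  pw <- list()
  if (length(cls) >= 2L) {
    for (i in seq_len(length(cls) - 1L)) for (j in (i + 1L):length(cls)) {
      sub <- d[d$cluster %in% cls[c(i, j)], , drop = FALSE]
      if (sum(sub$event) == 0L) next
      pd <- survival::survdiff(survival::Surv(time_years, event) ~ cluster,
                               data = sub)
      pw[[length(pw) + 1L]] <- data.frame(
        cluster_a = cls[i], cluster_b = cls[j], chisq = pd$chisq,
        p = stats::pchisq(pd$chisq, 1L, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  pairwise <- if (length(pw) > 0L) do.call(rbind, pw) else
    data.frame(cluster_a = character(), cluster_b = character(),
               chisq = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (nrow(pairwise) > 0L) pairwise$p_adj <- stats::p.adjust(pairwise$p, "BH")
  out <- list(curves = curves, global = global, pairwise = pairwise,
              n_per_cluster = table(d$cluster), horizon_years = horizon_years)
  class(out) <- "survival_comparison"
  out
}

#' Post-onset progression analysis (PCA + ANOVA)
#'
#' Restricts to patients with an embedded year for every year of the
#' post-onset window (onset year through onset + window - 1), averages
#' each patient's window vectors, performs PCA on the averages, and runs a
#' per-PC analysis of variance on age of onset, the categorical
#' demographics and the cluster label (additive linear model, type-II
#' tests).
#'
#' @param ye A `year_embeddings` object.
#' @param index_onsets `data.frame(patient_id, onset_age_years)` for the
#'   index phenotype.
#' @param assignments `data.frame(patient_id, cluster)`.
#' @param covariates `data.frame` with `patient_id`, `age_of_onset` and
#'   categorical demographics.
#' @param window_years Progression window length (default 10).
#' @param n_pc Number of PCs retained (default 3).
#' @return A list of class `progression_result`: `scores`, `loadings`,
#'   `var_explained`, `anova` (pc, term, df, F, p), `n_patients`.
#' @export
progression_pca_anova <- function(ye, index_onsets, assignments, covariates,
                                  window_years = 10L, n_pc = 3L) {
  key <- paste(ye$patient_id, ye$year_index, sep = "\r")
  eligible <- vapply(seq_len(nrow(index_onsets)), function(i) {
    yrs <- index_onsets$onset_age_years[i] + 0:(window_years - 1L)
    all(paste(index_onsets$patient_id[i], yrs, sep = "\r") %in% key)
  }, TRUE)
  pats <- index_onsets$patient_id[eligible]
  if (length(pats) < 3L)
    stop("fewer than 3 patients have full ", window_years,
         "-year post-onset coverage")
  avg <- t(vapply(seq_along(pats), function(i) {
    yrs <- index_onsets$onset_age_years[eligible][i] + 0:(window_years - 1L)
    rows <- match(paste(pats[i], yrs, sep = "\r"), key)
    colMeans(ye$vectors[rows, , drop = FALSE])
  }, numeric(ncol(ye$vectors))))
  rownames(avg) <- pats
  pc <- stats::prcomp(avg, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  cov <- covariates[match(pats, covariates$patient_id), , drop = FALSE]
  cov$patient_id <- NULL
  cov$cluster <- factor(assignments$cluster[match(pats,
                                                  assignments$patient_id)])
  keep <- vapply(cov, function(v) length(unique(v)) > 1L, TRUE)
  cov <- cov[, keep, drop = FALSE]
  an_rows <- list()
  for (k in seq_len(n_pc)) {
    df <- cov
    df$pc <- pc$x[, k]
    fit <- stats::lm(pc ~ ., data = df)
    at <- car::Anova(fit, type = 2)
    terms <- rownames(at)
    terms <- terms[terms != "Residuals"]
    for (tm in terms) {
      an_rows[[length(an_rows) + 1L]] <- data.frame(
        pc = k, term = tm, df = at[tm, "Df"], F = at[tm, "F value"],
        p = at[tm, "Pr(>F)"], stringsAsFactors = FALSE)
    }
  }
  out <- list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
              loadings = pc$rotation[, seq_len(n_pc), drop = FALSE],
              var_explained = ve[seq_len(n_pc)],
              anova = do.call(rbind, an_rows),
              n_patients = length(pats))
  class(out) <- "progression_result"
  out
}

#' Emerging (or pre-existing) phenotype frequencies per cluster
#'
#' In `"post"` mode a phecode counts as an emerging phenotype for a patient
#' when its first occurrence falls strictly after the patient's index
#' onset year -- phecodes also seen at or before onset are not gains. In
#' `"pre"` mode the table counts phecodes present strictly before onset.
#' Counts are normalised by cluster size, and the top `top_n` phecodes per
#' cluster are flagged (ties broken by frequency desc, then phecode asc).
#'
#' @param occurrences Phecode occurrences from [map_to_phecodes()].
#' @param index_onsets `data.frame(patient_id, onset_age_years)`.
#' @param assignments `data.frame(patient_id, cluster)`.
#' @param top_n Top flag count per cluster (default 15).
#' @param window `"post"` (default) or `"pre"`.
#' @return A `data.frame`: cluster, phecode, n_patients, frequency, top.
#' @export
emerging_phenotypes <- function(occurrences, index_onsets, assignments,
                                top_n = 15L, window = c("post", "pre")) {
  window <- match.arg(window)
  d <- merge(occurrences, index_onsets, by = "patient_id")
  d <- merge(d, assignments, by = "patient_id")
  if (nrow(d) == 0L)
    return(data.frame(cluster = integer(), phecode = character(),
                      n_patients = integer(), frequency = numeric(),
                      top = logical(), stringsAsFactors = FALSE))
  d$year <- age_to_year(d$age_days)
  dt <- data.table::as.data.table(d)
  rng <- dt[, .(first_year = min(year), last_pre = min(year)),
            by = .(patient_id, phecode, cluster, onset_age_years)]
  if (window == "post") {
    hit <- rng[first_year > onset_age_years]
  } else {
    hit <- rng[first_year < onset_age_years]
  }
  csize <- table(assignments$cluster)
  if (nrow(hit) == 0L)
    return(data.frame(cluster = integer(), phecode = character(),
                      n_patients = integer(), frequency = numeric(),
                      top = logical(), stringsAsFactors = FALSE))
  cnt <- hit[, .(n_patients = data.table::uniqueN(patient_id)),
             by = .(cluster, phecode)]
  cnt[, frequency := n_patients / as.numeric(csize[as.character(cluster)])]
  out <- as.data.frame(cnt)
  out <- out[order(out$cluster, -out$frequency, out$phecode), , drop = FALSE]
  out$top <- stats::ave(seq_len(nrow(out)), out$cluster,
                        FUN = seq_along) <= top_n
  rownames(out) <- NULL
  out
}
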