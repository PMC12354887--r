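# Phenome-wide classification tasks on embedding features: disease-state
# classification (pre- vs post-onset patient-years), disease-onset
# prediction (the embedding one year before onset vs never-affected
# patients), and bulk phenotyping (mean patient vectors vs ever-present
# phenotype labels). All three use plain logistic regression on the
# embedding coordinates with an 80/20 patient-grouped split, scored by
# AUROC and AUPRC.

task_dataset <- function(x, y, patient_id, phecode) {
  out <- list(x = x, y = as.integer(y), patient_id = as.character(patient_id),
              phecode = phecode)
  class(out) <- "task_dataset"
  out
}

onsets_for <- function(onsets, phecode) {
  onsets[onsets$phecode == phecode, , drop = FALSE]
}

#' Disease-state dataset for one phenotype
#'
#' Positives are case patient-years at or after the onset year; negatives
#' are the same cases' patient-years before onset.
#'
#' @param ye A `year_embeddings` object.
#' @param onsets Onset table from [compute_onset_table()].
#' @param phecode Phenotype to build.
#' @param min_cases Minimum number of case patients contributing both a
#'   pre-onset and a post-onset year.
#' @return A `task_dataset`, or `NULL` (with a message) if ineligible.
#' @export
build_state_dataset <- function(ye, onsets, phecode, min_cases = 20L) {
  on <- onsets_for(onsets, phecode)
  m <- match(ye$patient_id, on$patient_id)
  case <- !is.na(m)
  if (!any(case)) {
    message("phecode ", phecode, " skipped: no cases with embedded years")
    return(NULL)
  }
  oy <- on$onset_age_years[m[case]]
  label <- as.integer(ye$year_index[case] >= oy)
  pid <- ye$patient_id[case]
  both <- intersect(unique(pid[label == 1L]), unique(pid[label == 0L]))
  if (length(both) < min_cases) {
    message("phecode ", phecode, " skipped: only ", length(both),
            " case(s) with both pre- and post-onset years (min ", min_cases, ")")
    return(NULL)
  }
  task_dataset(ye$vectors[case, , drop = FALSE], label, pid, phecode)
}

#' Disease-onset prediction dataset for one phenotype
#'
#' Positives are each case's embedding at year `onset - 1`. Negatives are
#' drawn from patients who never acquire the phenotype, matched to the
#' positives' year-index frequencies (`negatives = "never"`, the default),
#' or from the cases' own years strictly before `onset - 1`
#' (`negatives = "preonset"`).
#'
#' @inheritParams build_state_dataset
#' @param negatives Negative-class definition.
#' @param seed Seed for negative sampling.
#' @return A `task_dataset`, or `NULL` if no case has an observed lead
#'   year.
#' @export
build_onset_dataset <- function(ye, onsets, phecode, min_cases = 20L,
                                negatives = c("never", "preonset"),
                                seed = 1L) {
  negatives <- match.arg(negatives)
  set.seed(seed)
  on <- onsets_for(onsets, phecode)
  key <- paste(ye$patient_id, ye$year_index, sep = "\r")
  lead <- match(paste(on$patient_id, on$onset_age_years - 1L, sep = "\r"), key)
  pos_rows <- lead[!is.na(lead)]
  if (length(pos_rows) < min_cases) {
    message("phecode ", phecode, " skipped: only ", length(pos_rows),
            " case(s) with an observed lead year (min ", min_cases, ")")
    return(NULL)
  }
  if (negatives == "never") {
    affected <- unique(on$patient_id)
    cand <- which(!(ye$patient_id %in% affected))
    if (length(cand) == 0L) {
      message("phecode ", phecode, " skipped: no never-affected patients")
      return(NULL)
    }
    # frequency-match the positives' year indices
    neg_rows <- vapply(ye$year_index[pos_rows], function(y) {
      at <- cand[ye$year_index[cand] == y]
      if (length(at) == 0L) {
        gap <- abs(ye$year_index[cand] - y)
        at <- cand[gap == min(gap)]
      }
      at[sample.int(length(at), 1L)]
    }, integer(1))
  } else {
    m <- match(ye$patient_id, on$patient_id)
    case <- !is.na(m)
    neg_rows <- which(case & ye$year_index < on$onset_age_years[m] - 1L)
    if (length(neg_rows) == 0L) {
      message("phecode ", phecode, " skipped: no pre-lead case years")
      return(NULL)
    }
  }
  rows <- c(pos_rows, neg_rows)
  task_dataset(ye$vectors[rows, , drop = FALSE],
               rep(c(1L, 0L), c(length(pos_rows), length(neg_rows))),
               ye$patient_id[rows], phecode)
}

#' Bulk-phenotyping dataset for one phenotype
#'
#' One row per patient (the Eq.-1 mean vector); the label is whether the
#' phenotype is ever present for that patient.
#'
#' @param pe A `patient_embedding` from [mean_patient_vector()].
#' @param onsets Onset table.
#' @param phecode Phenotype to build.
#' @return A `task_dataset`, or `NULL` if labels are single-class.
#' @export
build_bulk_dataset <- function(pe, onsets, phecode) {
  stopifnot(inherits(pe, "patient_embedding"))
  pid <- rownames(pe$mean)
  lab <- as.integer(pid %in% onsets$patient_id[onsets$phecode == phecode])
  if (length(unique(lab)) < 2L) {
    message("phecode ", phecode, " skipped: single-class labels")
    return(NULL)
  }
  task_dataset(pe$mean, lab, pid, phecode)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise average precision: the mean over positive instances of the
#' precision at each positive's rank, with ties broken by rank order.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @return AUPRC in [0, 1].
#' @export
average_precision <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1L]) / sum(lab)
}

#' Fit and evaluate a logistic classifier on a task dataset
#'
#' Plain (unpenalised) logistic regression on the embedding coordinates.
#' The 80/20 split is stratified by class and grouped by patient, so no
#' patient contributes rows to both sides. If a split lands a single class
#' in either side it is reshuffled once, then an error is raised.
#'
#' @param dataset A `task_dataset`.
#' @param train_fraction Fraction of patients used for training.
#' @param seed Split seed.
#' @return A one-row `data.frame` (`task_result`): phecode, AUROC, AUPRC,
#'   n_pos, n_neg, pos_neg_ratio, seed.
#' @export
fit_eval_logistic <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "task_dataset"))
  set.seed(seed)
  split_once <- function() {
    # stratify at the patient level by the patient's majority label
    pat <- unique(dataset$patient_id)
    plab <- vapply(split(dataset$y, dataset$patient_id)[pat],
                   function(v) as.integer(mean(v) >= 0.5), 1L)
    tr <- character(0)
    for (cl in unique(plab)) {
      p <- pat[plab == cl]
      tr <- c(tr, sample(p, max(1L, round(train_fraction * length(p)))))
    }
    dataset$patient_id %in% tr
  }
  in_train <- split_once()
  ok <- function(idx) length(unique(dataset$y[idx])) == 2L &&
    length(unique(dataset$y[!idx])) == 2L
  if (!ok(in_train)) in_train <- split_once()
  if (!ok(in_train))
    stop("degenerate split: a side of the 80/20 split is single-class")
  df <- as.data.frame(dataset$x)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$y <- dataset$y
  fit <- suppressWarnings(stats::glm(y ~ ., data = df[in_train, , drop = FALSE],
                                     family = stats::binomial()))
  score <- suppressWarnings(
    stats::predict(fit, newdata = df[!in_train, , drop = FALSE],
                   type = "response"))
  ytest <- dataset$y[!in_train]
  auroc <- as.numeric(pROC::auc(pROC::roc(ytest, score, quiet = TRUE,
                                          direction = "<")))
  auprc <- average_precision(score, ytest)
  n_pos <- sum(dataset$y == 1L); n_neg <- sum(dataset$y == 0L)
  out <- data.frame(phecode = dataset$phecode, auroc = auroc, auprc = auprc,
                    n_pos = n_pos, n_neg = n_neg,
                    pos_neg_ratio = n_pos / n_neg, seed = seed,
                    stringsAsFactors = FALSE)
  class(out) <- c("task_result", class(out))
  out
}

#' Run a classification task phenome-wide
#'
#' Builds the requested dataset for every phecode in the map, fits and
#' evaluates the classifier for each eligible phenotype, and summarises
#' AUROC/AUPRC medians by disease class. Skips are reported via messages
#' and returned.
#'
#' @param ye A `year_embeddings` object (state/onset tasks).
#' @param pe A `patient_embedding` (bulk task).
#' @param onsets Onset table.
#' @param map Phecode map with `phecode` and `disease_class` columns.
#' @param task One of `"state"`, `"onset"`, `"bulk"`.
#' @param min_cases Eligibility floor passed to the dataset builders.
#' @param train_fraction,seed Passed to [fit_eval_logistic()].
#' @return A list: `results` (one row per eligible phecode, sorted by
#'   phecode, with disease classes), `by_class` (median AUROC/AUPRC per
#'   disease class), `skipped` (phecodes with no dataset).
#' @export
run_phenome <- function(ye = NULL, pe = NULL, onsets, map,
                        task = c("state", "onset", "bulk"),
                        min_cases = 20L, train_fraction = 0.8, seed = 1L) {
  task <- match.arg(task)
  phe <- sort(unique(map$phecode))
  cls <- map$disease_class[match(phe, map$phecode)]
  res <- list(); skipped <- character(0)
  for (i in seq_along(phe)) {
    ds <- switch(task,
      state = build_state_dataset(ye, onsets, phe[i], min_cases),
      onset = build_onset_dataset(ye, onsets, phe[i], min_cases, seed = seed),
      bulk = build_bulk_dataset(pe, onsets, phe[i]))
    if (is.null(ds)) { skipped <- c(skipped, phe[i]); next }
    r <- fit_eval_logistic(ds, train_fraction, seed)
    r$disease_class <- cls[i]
    res[[length(res) + 1L]] <- r
  }
  results <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(phecode = character(), auroc = numeric(), auprc = numeric(),
               n_pos = integer(), n_neg = integer(),
               pos_neg_ratio = numeric(), seed = integer(),
               disease_class = character(), stringsAsFactors = FALSE)
  results <- results[order(results$phecode), , drop = FALSE]
  rownames(results) <- NULL
  by_class <- if (nrow(results) > 0L) {
    agg <- stats::aggregate(cbind(auroc, auprc) ~ disease_class,
                            data = results, FUN = stats::median)
    names(agg)[2:3] <- c("median_auroc", "median_auprc")
    agg
  } else data.frame(disease_class = character(), median_auroc = numeric(),
                    median_auprc = numeric(), stringsAsFactors = FALSE)
  list(results = results, by_class = by_class, skipped = skipped)
}
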