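# Evaluation: ranking metrics for imbalanced binary cohorts, stratified
# cross-validated model comparison, and the data-ablation study.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive outranks a uniformly chosen negative, ties counted one half
#' (midranks).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise (non-interpolated) average precision, preferred under heavy
#' class imbalance because it ignores true negatives. Tied scores are
#' handled as a block: precision is evaluated once at the end of each tied
#' group, so a constant scorer scores exactly the prevalence.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("AUPRC undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  npred <- grp_end
  dtp <- diff(c(0, tp))
  sum(dtp / n1 * (tp / npred))
}

stratified_folds <- function(labels, k, seed = 1) {
  if (k > min(table(labels))) stop("k exceeds the minority class count")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- sample(which(labels == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

subset_cohort <- function(cohort, idx) {
  new_event_cohort(cohort$sequences[idx], cohort$vocab, cohort$config)
}

#' Cross-validated evaluation of one model variant
#'
#' Stratified k-fold cross-validation preserving the case:control ratio:
#' each fold serves once as the held-out test set while the model is
#' refitted on the remainder. Reports mean and standard deviation of AUROC
#' and AUPRC across folds, plus the trainable parameter count.
#'
#' @param cohort an `event_cohort`.
#' @param variant model variant string (see [model_variants()]).
#' @param k number of folds (default 5).
#' @param seed seed controlling fold assignment and model fits.
#' @param ... further arguments to [sigfit()].
#' @return A one-row data frame of class `eval_report`.
#' @export
cross_validate <- function(cohort, variant = "LS2+LL", k = 5, seed = 1, ...) {
  labels <- cohort_labels(cohort)
  fold <- stratified_folds(labels, k, seed)
  rocs <- prcs <- numeric(k)
  npar <- NA_integer_
  for (f in seq_len(k)) {
    fitc <- subset_cohort(cohort, which(fold != f))
    test <- subset_cohort(cohort, which(fold == f))
    m <- sigfit(fitc, variant = variant, seed = seed + f, ...)
    s <- predict(m, test)
    yl <- cohort_labels(test)
    rocs[f] <- auroc(s, yl)
    prcs[f] <- auprc(s, yl)
    npar <- m$n_params
  }
  out <- data.frame(model = variant,
                    auroc_mean = mean(rocs), auroc_sd = stats::sd(rocs),
                    auprc_mean = mean(prcs), auprc_sd = stats::sd(prcs),
                    n_params = npar, stringsAsFactors = FALSE)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Compare several model variants by cross-validation
#'
#' @param cohort an `event_cohort`.
#' @param variants character vector of variant strings.
#' @param k,seed,... passed to [cross_validate()].
#' @return An `eval_report` data frame, one row per variant.
#' @export
compare_models <- function(cohort, variants = c("LS2+LL", "GRU", "BOW"),
                           k = 5, seed = 1, ...) {
  rows <- lapply(variants, function(v) cross_validate(cohort, v, k = k, seed = seed, ...))
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Data ablation study
#'
#' Holds out a fixed stratified test set once, then for each training
#' fraction and seed subsamples the remaining patients (stratified),
#' refits each variant on the subsample, and evaluates on the unchanged
#' test set, producing metric-versus-fraction curves.
#'
#' @param cohort an `event_cohort`.
#' @param variants character vector of variant strings.
#' @param fractions training fractions in (0, 1].
#' @param seeds integer vector of replicate seeds.
#' @param test_fraction fraction held out once as the fixed test set.
#' @param ... further arguments to [sigfit()].
#' @return A data frame of class `eval_report` with one row per
#'   variant x fraction x seed.
#' @export
ablation_study <- function(cohort, variants = c("LS2+LL", "GRU"),
                           fractions = c(0.05, 0.1, 0.2, 0.4, 0.7, 1.0),
                           seeds = 1:3, test_fraction = 0.2, ...) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  labels <- cohort_labels(cohort)
  set.seed(seeds[1])
  ord <- sample(length(labels))
  test <- ord[stratified_split(labels[ord], test_fraction)]
  pool <- setdiff(seq_along(labels), test)
  test_cohort <- subset_cohort(cohort, test)
  ytest <- labels[test]
  rows <- list()
  for (fr in fractions) for (sd in seeds) {
    set.seed(sd * 1000 + round(fr * 100))
    po <- sample(pool)
    sub <- po[stratified_split(labels[po], fr)]
    if (fr == 1) sub <- pool
    yl <- labels[sub]
    if (length(unique(yl)) < 2) {
      warning(sprintf("fraction %.2f too small to contain both classes; skipped", fr))
      next
    }
    for (v in variants) {
      m <- sigfit(subset_cohort(cohort, sub), variant = v, seed = sd, ...)
      s <- predict(m, test_cohort)
      rows[[length(rows) + 1]] <-
        data.frame(model = v, fraction = fr, seed = sd,
                   auroc = auroc(s, ytest), auprc = auprc(s, ytest),
                   n_train = length(sub), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  df <- as.data.frame(x)
  if (all(c("auroc_mean", "auprc_mean") %in% names(df))) {
    cat(sprintf("%-14s %-17s %-17s %10s\n", "Model", "AUROC", "AUPRC", "# Params"))
    for (i in seq_len(nrow(df))) {
      cat(sprintf("%-14s %.3f ± %.3f     %.3f ± %.3f     %10s\n",
                  df$model[i], df$auroc_mean[i], df$auroc_sd[i],
                  df$auprc_mean[i], df$auprc_sd[i],
                  if (df$model[i] == "BOW") "-" else format(df$n_params[i])))
    }
  } else {
    print(df)
  }
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report an `eval_report`.
#' @param path output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return The paths, invisibly.
#' @export
write_eval_report <- function(report, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(report), js, dataframe = "rows", digits = NA)
  invisible(c(csv, js))
}
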