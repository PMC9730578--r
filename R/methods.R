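# S3 methods for fitted sigfit models.

#' @export
print.sigfit <- function(x, ...) {
  cat(sprintf("<sigfit %s: %d parameters>\n", x$variant, x$n_params))
  if (!is.null(x$feature_width))
    cat(sprintf("  pooled feature width: %d\n", x$feature_width))
  if (nrow(x$history) > 0 && !is.na(x$history$val_auroc[nrow(x$history)])) {
    cat(sprintf("  epochs run: %d (best validation AUROC %.3f at epoch %d)\n",
                nrow(x$history), max(x$history$val_auroc, na.rm = TRUE),
                if (!is.null(x$best_epoch)) x$best_epoch else NA_integer_))
  }
  invisible(x)
}

#' @export
summary.sigfit <- function(object, ...) {
  out <- list(variant = object$variant, kind = object$spec$kind,
              n_params = object$n_params,
              feature_width = object$feature_width,
              vocab_size = nrow(object$vocab),
              history = object$history,
              train_auroc = if (length(unique(object$labels)) > 1)
                auroc(object$fitted, object$labels) else NA_real_,
              train_auprc = if (any(object$labels == 1))
                auprc(object$fitted, object$labels) else NA_real_)
  class(out) <- "summary.sigfit"
  out
}

#' @export
print.summary.sigfit <- function(x, ...) {
  cat(sprintf("Sequence classifier %s (%s)\n", x$variant, x$kind))
  cat(sprintf("  vocabulary: %d tokens; trainable parameters: %d\n",
              x$vocab_size, x$n_params))
  if (!is.null(x$feature_width))
    cat(sprintf("  pooled feature width: %d\n", x$feature_width))
  cat(sprintf("  training-set AUROC %.3f, AUPRC %.3f\n",
              x$train_auroc, x$train_auprc))
  if (nrow(x$history) > 1)
    cat(sprintf("  final training loss %.4f after %d epochs\n",
                x$history$train_loss[nrow(x$history)], nrow(x$history)))
  invisible(x)
}

#' @export
coef.sigfit <- function(object, ...) {
  object$params
}

#' Predict disease scores for event sequences
#'
#' @param object a fitted `sigfit` model.
#' @param newdata an `event_cohort`; defaults to refitting scores on the
#'   training cohort's stored fitted values.
#' @param type `"response"` for probabilities in \[0, 1\].
#' @param ... unused.
#' @return Numeric vector of scores, one per patient.
#' @export
predict.sigfit <- function(object, newdata = NULL, type = "response", ...) {
  if (is.null(newdata)) return(object$fitted)
  stopifnot(inherits(newdata, "event_cohort"))
  if (object$spec$kind == "bow_lr") {
    X <- bow_counts(newdata, object$vocab)
    return(as.numeric(stats::plogis(cbind(1, X) %*% object$params$beta)))
  }
  samples <- prep_samples(newdata, object$vocab)
  vapply(samples, function(s)
    model_sample_score(s, object$params, object$spec, object$hp), 0)
}

#' @export
residuals.sigfit <- function(object, type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  y <- object$labels
  p <- pmin(pmax(object$fitted, 1e-12), 1 - 1e-12)
  switch(type,
         response = y - p,
         pearson = (y - p) / sqrt(p * (1 - p)),
         deviance = sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p))))
}

#' @export
plot.sigfit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = if (any(!is.na(h$val_auroc))) c(1, 2) else c(1, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
       ylab = "training loss", main = x$variant, ...)
  if (any(!is.na(h$val_auroc)))
    plot(h$epoch, h$val_auroc, type = "b", xlab = "epoch",
         ylab = "validation AUROC", main = x$variant, ...)
  invisible(x)
}

#' Simulate labels from a fitted classifier
#'
#' Draws Bernoulli outcomes from the fitted (or newly predicted) scores.
#'
#' @param object a fitted `sigfit`.
#' @param nsim number of simulated label vectors.
#' @param seed optional seed.
#' @param newdata optional `event_cohort` to score first.
#' @param ... unused.
#' @return A data frame with `nsim` columns of 0/1 labels.
#' @export
simulate.sigfit <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
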