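# Sequence classifiers: the neural-signature model
#   score = sigmoid( fc( sig_or_logsig( augment( embed(one-hot path) ) ) ) )
# trained end-to-end (the signature acts as a non-parametric pooling layer),
# plus a gated-recurrent baseline and a bag-of-words logistic regression.
# All gradients are hand-written reverse mode; optimisation is Adam on
# mini-batch binary cross-entropy.

#' Model variant identifiers
#'
#' Canonical variant strings accepted by [sigfit()]: `"S2"` (signature,
#' depth 2), `"LS2"` (log-signature), `"LS2+LL"` (+ lead-lag),
#' `"LS2+LL+ATI"` (+ time index), `"LS2+LL+ATD"` (+ scaled time delta),
#' `"LS3+LL+ATD"` (depth 3), `"BOW"` (one-hot bag-of-words logistic
#' regression), `"GRU"`, `"GRU+ATD"`.
#'
#' @return Character vector of variant names.
#' @export
model_variants <- function() {
  c("S2", "LS2", "LS2+LL", "LS2+LL+ATI", "LS2+LL+ATD", "LS3+LL+ATD",
    "BOW", "GRU", "GRU+ATD")
}

parse_variant <- function(variant) {
  v <- toupper(gsub("\\s", "", variant))
  if (v %in% c("BOW", "BOW-OH-LR", "BOWOHLR"))
    return(list(kind = "bow_lr", label = "BOW"))
  if (v %in% c("GRU", "GRU+ATD"))
    return(list(kind = "gru", time = if (grepl("ATD", v)) "delta" else "none", label = v))
  m <- regmatches(v, regexec("^(L?)S([23])((\\+[A-Z]+)*)$", v))[[1]]
  if (length(m) == 0) stop("unknown model variant: ", variant,
                           " (see model_variants())")
  logsig <- m[2] == "L"
  depth <- as.integer(m[3])
  flags <- strsplit(sub("^\\+", "", m[4]), "\\+")[[1]]
  time <- if ("ATI" %in% flags) "index" else if ("ATD" %in% flags) "delta" else "none"
  list(kind = "neural_signature", depth = depth, logsig = logsig,
       lead_lag = "LL" %in% flags, time = time, label = v)
}

# cached lower-triangular ones matrix (cumulative sums as one BLAS call)
ones_lower <- function(m) {
  key <- sprintf("L%d", m)
  if (is.null(.sig_cache[[key]])) {
    L <- matrix(0, m, m); L[lower.tri(L, diag = TRUE)] <- 1
    .sig_cache[[key]] <- L
  }
  .sig_cache[[key]]
}

# ---- neural-signature forward / backward for one sample ----
# tok: 1-based token indices; dt: days to prediction date per event.
# Returns feature vector + cache for the reverse pass.
ns_pool <- function(tok, dt, A, spec, hp) {
  m <- length(tok)
  emb <- t(A[, tok, drop = FALSE])                       # m x a
  P <- if (hp$stream == "cumulative" && m > 1) ones_lower(m) %*% emb else emb
  if (spec$time == "index") P <- cbind(P, seq_len(m) - 1)
  else if (spec$time == "delta")
    P <- cbind(P, add_time_delta(dt, hp$t_scale, hp$t_max))
  D0 <- ncol(P)
  if (spec$lead_lag)
    P <- if (m >= 2) lead_lag(P) else cbind(P, P)        # 1-point path: (x1, x1)
  P <- add_basepoint(P)
  q <- nrow(P)
  delta <- P[-1, , drop = FALSE] - P[-q, , drop = FALSE]
  sf <- sig_features(delta, spec$depth, spec$logsig)
  list(feat = sf$feat,
       cache = list(sig = sf$cache, m = m, D0 = D0, tok = tok, spec = spec, hp = hp))
}

ns_pool_vjp <- function(dfeat, cache, a) {
  spec <- cache$spec; hp <- cache$hp
  m <- cache$m; D0 <- cache$D0
  dDelta <- sig_features_vjp(dfeat, cache$sig)
  q <- nrow(dDelta) + 1
  dP <- matrix(0, q, ncol(dDelta))
  dP[-1, ] <- dDelta
  dP[-q, ] <- dP[-q, ] - dDelta
  dP <- dP[-1, , drop = FALSE]                           # basepoint: drop origin row
  if (spec$lead_lag) {
    if (m >= 2) {
      k <- seq_len(2 * m - 1)
      lead <- rowsum(dP[, seq_len(D0), drop = FALSE], ceiling((k + 1) / 2))
      lag <- rowsum(dP[, D0 + seq_len(D0), drop = FALSE], ceiling(k / 2))
      dP <- lead + lag
    } else {
      dP <- dP[, seq_len(D0), drop = FALSE] + dP[, D0 + seq_len(D0), drop = FALSE]
    }
  }
  if (spec$time != "none") dP <- dP[, seq_len(ncol(dP) - 1), drop = FALSE]
  demb <- if (hp$stream == "cumulative" && m > 1) crossprod(ones_lower(m), dP) else dP
  # accumulate into embedding columns by token
  sums <- rowsum(demb, cache$tok)
  list(cols = as.integer(rownames(sums)), dcols = t(sums))
}

# fully connected head: optional single hidden layer (ReLU), sigmoid output
fc_forward <- function(feat, params, drop_mask = NULL) {
  if (!is.null(params$W1)) {
    h <- pmax(params$W1 %*% feat + params$b1, 0)
    if (!is.null(drop_mask)) h <- h * drop_mask
    logit <- sum(params$w2 * h) + params$b2
    list(logit = as.numeric(logit), h = h, feat = feat)
  } else {
    list(logit = as.numeric(sum(params$w2 * feat) + params$b2), h = NULL, feat = feat)
  }
}

fc_backward <- function(dlogit, fwd, params, drop_mask = NULL) {
  if (!is.null(params$W1)) {
    dh <- dlogit * params$w2
    if (!is.null(drop_mask)) dh <- dh * drop_mask
    dh <- dh * (fwd$h > 0)
    list(dW1 = dh %*% t(fwd$feat), db1 = as.numeric(dh),
         dw2 = dlogit * as.numeric(fwd$h), db2 = dlogit,
         dfeat = as.numeric(crossprod(params$W1, dh)))
  } else {
    list(dw2 = dlogit * as.numeric(fwd$feat), db2 = dlogit,
         dfeat = dlogit * params$w2)
  }
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_ns_params <- function(V, a, Fw, hidden) {
  params <- list(A = matrix(stats::rnorm(a * V, 0, 1 / sqrt(a)), a, V))
  if (!is.null(hidden) && hidden > 0) {
    params$W1 <- glorot(hidden, Fw)
    params$b1 <- numeric(hidden)
    params$w2 <- numeric(hidden)                         # zero-init final layer:
    params$b2 <- 0                                       # untrained score is exactly 0.5
  } else {
    params$w2 <- numeric(Fw)
    params$b2 <- 0
  }
  params
}

init_gru_params <- function(V, a, h, time_delta) {
  din <- a + as.integer(time_delta)
  p <- list(A = matrix(stats::rnorm(a * V, 0, 1 / sqrt(a)), a, V),
            Wz = glorot(h, din), Wr = glorot(h, din), Wh = glorot(h, din),
            Uz = glorot(h, h), Ur = glorot(h, h), Uh = glorot(h, h),
            bz = numeric(h), br = numeric(h), bh = numeric(h),
            w2 = numeric(h), b2 = 0)
  p
}

gru_forward <- function(tok, dt, params, spec, hp, keep = FALSE) {
  a <- nrow(params$A); h <- length(params$bz)
  m <- length(tok)
  X <- params$A[, tok, drop = FALSE]                     # a x m
  if (spec$time == "delta")
    X <- rbind(X, add_time_delta(dt, hp$t_scale, hp$t_max))
  hs <- matrix(0, h, m + 1)
  zs <- rs <- hh <- if (keep) matrix(0, h, m) else NULL
  hprev <- numeric(h)
  for (t in seq_len(m)) {
    x <- X[, t]
    z <- stats::plogis(params$Wz %*% x + params$Uz %*% hprev + params$bz)
    r <- stats::plogis(params$Wr %*% x + params$Ur %*% hprev + params$br)
    hht <- tanh(params$Wh %*% x + params$Uh %*% (r * hprev) + params$bh)
    hprev <- (1 - z) * hprev + z * hht
    hs[, t + 1] <- hprev
    if (keep) { zs[, t] <- z; rs[, t] <- r; hh[, t] <- hht }
  }
  logit <- sum(params$w2 * hprev) + params$b2
  list(logit = as.numeric(logit), X = X, hs = hs, zs = zs, rs = rs, hh = hh, m = m)
}

gru_backward <- function(dlogit, fwd, params, tok) {
  a <- nrow(params$A); h <- length(params$bz); m <- fwd$m
  g <- list(Wz = 0 * params$Wz, Wr = 0 * params$Wr, Wh = 0 * params$Wh,
            Uz = 0 * params$Uz, Ur = 0 * params$Ur, Uh = 0 * params$Uh,
            bz = numeric(h), br = numeric(h), bh = numeric(h),
            w2 = dlogit * fwd$hs[, m + 1], b2 = dlogit)
  dX <- matrix(0, nrow(fwd$X), m)
  dh <- dlogit * params$w2
  for (t in rev(seq_len(m))) {
    x <- fwd$X[, t]; hprev <- fwd$hs[, t]
    z <- fwd$zs[, t]; r <- fwd$rs[, t]; hht <- fwd$hh[, t]
    dz <- dh * (hht - hprev)
    dhh <- dh * z
    dhprev <- dh * (1 - z)
    daz <- dz * z * (1 - z)
    dah <- dhh * (1 - hht^2)
    drh <- as.numeric(crossprod(params$Uh, dah))         # cotangent of r * hprev
    dr <- drh * hprev
    dhprev <- dhprev + drh * r
    dar <- dr * r * (1 - r)
    dhprev <- dhprev + as.numeric(crossprod(params$Uz, daz)) +
      as.numeric(crossprod(params$Ur, dar))
    g$Wz <- g$Wz + daz %*% t(x); g$Uz <- g$Uz + daz %*% t(hprev); g$bz <- g$bz + daz
    g$Wr <- g$Wr + dar %*% t(x); g$Ur <- g$Ur + dar %*% t(hprev); g$br <- g$br + dar
    g$Wh <- g$Wh + dah %*% t(x); g$Uh <- g$Uh + dah %*% t(r * hprev); g$bh <- g$bh + dah
    dX[, t] <- crossprod(params$Wz, daz) + crossprod(params$Wr, dar) +
      crossprod(params$Wh, dah)
    dh <- dhprev
  }
  sums <- rowsum(t(dX[seq_len(a), , drop = FALSE]), tok)
  g$A_cols <- as.integer(rownames(sums))
  g$A_dcols <- t(sums)
  g
}

# ---- Adam ----
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# per-sample data extracted once per fit
prep_samples <- function(cohort, vocab) {
  lapply(cohort$sequences, function(s) {
    idx <- match(s$tokens, vocab$token)
    if (anyNA(idx))
      stop("cohort contains token(s) absent from the vocabulary: ",
           paste(unique(s$tokens[is.na(idx)]), collapse = ", "))
    list(tok = idx, dt = as.numeric(s$index_date - s$times), y = s$label)
  })
}

stratified_split <- function(labels, fraction) {
  held <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
    k <- round(length(ix) * fraction)
    if (k > 0) ix[seq_len(k)] else integer(0)
  }), use.names = FALSE)
  sort(held)
}

#' Fit a sequence classifier on an event cohort
#'
#' The single entry point for all model variants: the neural-signature
#' classifier `sigmoid(fc(Sig^N(augment(embed(path)))))` trained end-to-end
#' with gradients flowing through the signature pooling layer, a GRU
#' baseline over the embedded event sequence (optionally with a scaled
#' time-delta input channel), or a bag-of-words logistic regression.
#' Signature variants always use a basepoint (so single-event sequences are
#' signaturable) and embed tokens through a trainable projection before the
#' signature.
#'
#' @param cohort an `event_cohort` (see [generate_cohort()] / [read_events()]).
#' @param variant model variant string, see [model_variants()].
#' @param vocab token vocabulary; defaults to the cohort's own.
#' @param embedding_dim dimension of the learnt token projection.
#' @param hidden width of the fully connected hidden layer (`0` for a linear
#'   head).
#' @param gru_hidden GRU hidden state size.
#' @param dropout dropout rate on the hidden layer during training.
#' @param learning_rate,batch_size,epochs Adam settings and epoch cap.
#' @param patience early-stopping patience on validation AUROC (epochs).
#' @param val_fraction fraction of patients held out (stratified) for the
#'   validation curve and early stopping.
#' @param t_scale,t_max time-delta scaling parameters (days channel).
#' @param stream path stream for signature variants: `"cumulative"` running
#'   counts (increments are the one-hot events; default) or `"onehot"` raw
#'   one-hot rows.
#' @param seed integer seed; fits are deterministic given the seed.
#' @param verbose print per-epoch loss at INFO level?
#' @return An object of class `sigfit` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals` and `simulate` methods.
#' @export
sigfit <- function(cohort, variant = "LS2+LL", vocab = NULL,
                   embedding_dim = 30, hidden = 64, gru_hidden = 32,
                   dropout = 0.1, learning_rate = 1e-3, batch_size = 64,
                   epochs = 50, patience = 5, val_fraction = 0.15,
                   t_scale = 0.25, t_max = 2,
                   stream = c("cumulative", "onehot"),
                   seed = 1, verbose = FALSE) {
  stopifnot(inherits(cohort, "event_cohort"))
  stream <- match.arg(stream)
  spec <- parse_variant(variant)
  if (is.null(vocab)) vocab <- cohort$vocab
  if (is.null(vocab)) vocab <- token_vocabulary(cohort)
  V <- nrow(vocab)
  labels <- cohort_labels(cohort)
  if (length(unique(labels)) < 2) stop("cohort must contain both classes")
  hp <- list(embedding_dim = embedding_dim, hidden = hidden,
             gru_hidden = gru_hidden, dropout = dropout,
             learning_rate = learning_rate, batch_size = batch_size,
             epochs = epochs, patience = patience, val_fraction = val_fraction,
             t_scale = t_scale, t_max = t_max, stream = stream, seed = seed)
  obj <- list(variant = spec$label, spec = spec, vocab = vocab, hp = hp,
              call = match.call())
  class(obj) <- "sigfit"

  if (spec$kind == "bow_lr") {
    X <- bow_counts(cohort, vocab)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), labels,
                                           family = stats::binomial()))
    obj$params <- list(beta = fit$coefficients)
    obj$params$beta[is.na(obj$params$beta)] <- 0
    obj$n_params <- V + 1L
    obj$fitted <- as.numeric(stats::plogis(cbind(1, X) %*% obj$params$beta))
    obj$labels <- labels
    obj$history <- data.frame(epoch = 1L, train_loss = bce(obj$fitted, labels),
                              val_auroc = NA_real_)
    return(obj)
  }

  set.seed(seed)
  samples <- prep_samples(cohort, vocab)
  n <- length(samples)
  ord <- sample(n)
  val <- ord[stratified_split(labels[ord], val_fraction)]
  train <- setdiff(seq_len(n), val)
  a <- embedding_dim

  if (spec$kind == "neural_signature") {
    aug_spec <- augmentation_spec(time = spec$time, t_scale = t_scale,
                                  t_max = t_max, basepoint = TRUE,
                                  lead_lag = spec$lead_lag, proj_dim = a)
    D <- augmented_dim(aug_spec, V)
    Fw <- sig_feature_width(D, spec$depth, spec$logsig)
    params <- init_ns_params(V, a, Fw, hidden)
    obj$aug_spec <- aug_spec
    obj$feature_width <- Fw
  } else {
    params <- init_gru_params(V, a, gru_hidden, spec$time == "delta")
    obj$feature_width <- gru_hidden
  }

  opt <- adam_init(params)
  history <- data.frame()
  best <- list(params = params, val = -Inf, epoch = 0L)
  for (epoch in seq_len(epochs)) {
    idx <- sample(train)
    losses <- numeric(0)
    for (start in seq(1, length(idx), by = batch_size)) {
      batch <- idx[start:min(start + batch_size - 1, length(idx))]
      grads <- NULL
      bl <- 0
      for (i in batch) {
        s <- samples[[i]]
        gi <- model_sample_grad(s, params, spec, hp, train = TRUE)
        bl <- bl + gi$loss
        grads <- if (is.null(grads)) gi$grads else acc_grads(grads, gi$grads)
      }
      grads <- scale_grads(grads, 1 / length(batch))
      st <- adam_step(params, grads, opt, learning_rate)
      params <- st$params; opt <- st$state
      losses <- c(losses, bl / length(batch))
    }
    vs <- vapply(val, function(i)
      model_sample_score(samples[[i]], params, spec, hp), 0)
    va <- if (length(unique(labels[val])) > 1) auroc(vs, labels[val]) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_auroc = va))
    if (verbose)
      message(sprintf("[sigfit %s] epoch %d loss %.4f val AUROC %.3f",
                      spec$label, epoch, mean(losses), va))
    if (!is.na(va) && va > best$val + 1e-6) {
      best <- list(params = params, val = va, epoch = epoch)
    } else if (epoch - best$epoch >= patience && best$epoch > 0) break
    if (!is.finite(mean(losses)))
      stop("non-finite training loss at epoch ", epoch)
  }
  obj$params <- if (best$epoch > 0) best$params else params
  obj$best_epoch <- best$epoch
  obj$history <- history
  obj$labels <- labels
  obj$fitted <- vapply(samples, function(s)
    model_sample_score(s, obj$params, spec, hp), 0)
  obj$n_params <- count_params(obj)
  obj
}

bow_counts <- function(cohort, vocab) {
  n <- length(cohort$sequences)
  X <- matrix(0, n, nrow(vocab))
  for (i in seq_len(n)) {
    idx <- match(cohort$sequences[[i]]$tokens, vocab$token)
    if (anyNA(idx)) stop("unknown token in cohort")
    tab <- tabulate(idx, nbins = nrow(vocab))
    X[i, ] <- tab
  }
  X
}

bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

acc_grads <- function(a, b) {
  for (nm in names(b)) {
    if (nm %in% c("A_cols", "A_dcols")) next
    a[[nm]] <- a[[nm]] + b[[nm]]
  }
  if (!is.null(b$A_cols)) a$A[, b$A_cols] <- a$A[, b$A_cols] + b$A_dcols
  a
}

scale_grads <- function(g, s) {
  for (nm in names(g)) g[[nm]] <- g[[nm]] * s
  g
}

# loss + parameter gradients for one sample
model_sample_grad <- function(s, params, spec, hp, train = TRUE) {
  if (spec$kind == "neural_signature") {
    pool <- ns_pool(s$tok, s$dt, params$A, spec, hp)
    drop_mask <- if (train && hp$dropout > 0 && !is.null(params$W1))
      (stats::runif(length(params$b1)) >= hp$dropout) / (1 - hp$dropout) else NULL
    fwd <- fc_forward(pool$feat, params, drop_mask)
    p <- stats::plogis(fwd$logit)
    dlogit <- p - s$y
    fb <- fc_backward(dlogit, fwd, params, drop_mask)
    emb <- ns_pool_vjp(fb$dfeat, pool$cache, nrow(params$A))
    grads <- list(A = params$A * 0)
    grads$A[, emb$cols] <- emb$dcols
    grads[setdiff(names(fb), "dfeat")] <- fb[setdiff(names(fb), "dfeat")]
    names(grads) <- sub("^d", "", names(grads))
    list(loss = bce(p, s$y), grads = grads)
  } else {
    fwd <- gru_forward(s$tok, s$dt, params, spec, hp, keep = TRUE)
    p <- stats::plogis(fwd$logit)
    g <- gru_backward(p - s$y, fwd, params, s$tok)
    g$A <- params$A * 0
    g$A[, g$A_cols] <- g$A_dcols
    g$A_cols <- NULL; g$A_dcols <- NULL
    list(loss = bce(p, s$y), grads = g)
  }
}

model_sample_score <- function(s, params, spec, hp) {
  if (spec$kind == "neural_signature") {
    pool <- ns_pool(s$tok, s$dt, params$A, spec, hp)
    stats::plogis(fc_forward(pool$feat, params)$logit)
  } else {
    stats::plogis(gru_forward(s$tok, s$dt, params, spec, hp)$logit)
  }
}

#' Count trainable parameters of a fitted model
#'
#' Total number of trainable scalars: embedding plus classifier weights for
#' neural-signature models, all gate matrices for the GRU, vocabulary + 1
#' for the bag-of-words logistic regression.
#'
#' @param model a `sigfit` object.
#' @return Integer count.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "sigfit"))
  if (model$spec$kind == "bow_lr") return(length(model$params$beta))
  sum(vapply(model$params, length, 0L))
}
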