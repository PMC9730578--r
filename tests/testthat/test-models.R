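# Classifier variants: composition, differentiability, training behaviour.

fast_fit <- function(cohort, variant, ...) {
  sigfit(cohort, variant, embedding_dim = 4, hidden = 8, gru_hidden = 8,
         epochs = 3, val_fraction = 0.2, ...)
}

test_that("variant strings parse to the documented specifications", {
  s <- sigehr:::parse_variant("LS2+LL+ATD")
  expect_equal(s[c("kind", "depth", "logsig", "lead_lag", "time")],
               list(kind = "neural_signature", depth = 2L, logsig = TRUE,
                    lead_lag = TRUE, time = "delta"))
  expect_equal(sigehr:::parse_variant("S2")$logsig, FALSE)
  expect_equal(sigehr:::parse_variant("LS3+LL+ATD")$depth, 3L)
  expect_equal(sigehr:::parse_variant("GRU+ATD")$time, "delta")
  expect_equal(sigehr:::parse_variant("BoW-OH-LR")$kind, "bow_lr")
  expect_error(sigehr:::parse_variant("LS4"), "unknown model variant")
})

test_that("pooled feature widths follow the term-count formulas for every variant", {
  co <- make_test_cohort(n = 60, V = 12, seed = 1)
  a <- 4
  widths <- list("S2" = num_sig_terms(a, 2) - 1,
                 "LS2" = num_logsig_terms(a, 2),
                 "LS2+LL" = num_logsig_terms(2 * a, 2),
                 "LS2+LL+ATI" = num_logsig_terms(2 * (a + 1), 2),
                 "LS2+LL+ATD" = num_logsig_terms(2 * (a + 1), 2),
                 "LS3+LL+ATD" = num_logsig_terms(2 * (a + 1), 3))
  for (v in names(widths)) {
    m <- sigfit(co, v, embedding_dim = a, hidden = 4, epochs = 1)
    expect_equal(m$feature_width, as.integer(widths[[v]]), info = v)
    expect_equal(dim(m$params$W1), c(4L, as.integer(widths[[v]])), info = v)
  }
})

test_that("an untrained model with zero-initialised final layer scores exactly 0.5", {
  co <- make_test_cohort(n = 40, V = 10, seed = 2)
  m <- sigfit(co, "LS2+LL", embedding_dim = 4, hidden = 8, epochs = 1)
  params <- sigehr:::init_ns_params(10, 4, m$feature_width, 8)
  samples <- sigehr:::prep_samples(co, co$vocab)
  scores <- vapply(samples, function(s)
    sigehr:::model_sample_score(s, params, m$spec, m$hp), 0)
  expect_equal(scores, rep(0.5, length(scores)))
})

test_that("scores are invariant to timestamp re-spacing unless time augmentation is on", {
  toks <- c("A", "B", "C", "B")
  co <- manual_cohort(list(list(times = c(100, 300, 500, 700), tokens = toks, label = 1),
                           list(times = c(100, 110, 3000, 3500), tokens = toks, label = 0)))
  hp <- list(stream = "cumulative", t_scale = 0.25, t_max = 2, dropout = 0)
  set.seed(3)
  params <- sigehr:::init_ns_params(3, 3, num_logsig_terms(6, 2), 5)
  params$w2 <- rnorm(5)
  samples <- sigehr:::prep_samples(co, co$vocab)
  sc <- function(spec) vapply(samples, function(s)
    sigehr:::model_sample_score(s, params, spec, hp), 0)
  plain <- sc(sigehr:::parse_variant("LS2+LL"))
  expect_equal(plain[1], plain[2])
  paramsT <- sigehr:::init_ns_params(3, 3, num_logsig_terms(8, 2), 5)
  set.seed(3); paramsT$w2 <- rnorm(5)
  scT <- vapply(samples, function(s)
    sigehr:::model_sample_score(s, paramsT, sigehr:::parse_variant("LS2+LL+ATD"),
                                hp), 0)
  expect_false(scT[1] == scT[2])
})

test_that("loss gradients match central finite differences on tiny models", {
  co <- make_test_cohort(n = 10, V = 8, seed = 4)
  samples <- sigehr:::prep_samples(co, co$vocab)
  hp <- list(stream = "cumulative", t_scale = 0.25, t_max = 2, dropout = 0)
  eps <- 1e-5
  for (v in c("LS2+LL", "LS3+LL+ATD", "GRU+ATD")) {
    spec <- sigehr:::parse_variant(v)
    set.seed(5)
    if (spec$kind == "gru") {
      params <- sigehr:::init_gru_params(8, 3, 4, TRUE)
    } else {
      D <- sigehr:::augmented_dim(augmentation_spec(time = spec$time,
                                                    lead_lag = spec$lead_lag,
                                                    basepoint = TRUE, proj_dim = 3), 8)
      params <- sigehr:::init_ns_params(8, 3, sigehr:::sig_feature_width(D, spec$depth, spec$logsig), 4)
      params$W1 <- params$W1 * 0.5
    }
    params$w2 <- rnorm(length(params$w2)) * 0.5
    s <- samples[[3]]
    g <- sigehr:::model_sample_grad(s, params, spec, hp, train = FALSE)
    loss_at <- function(px) sigehr:::model_sample_grad(s, px, spec, hp,
                                                       train = FALSE)$loss
    worst <- 0
    a_emb <- nrow(params$A)
    for (nm in names(params)) {
      probe <- seq_len(min(6, length(params[[nm]])))
      if (nm == "A") probe <- (s$tok[1] - 1) * a_emb + seq_len(a_emb)  # a used column
      for (ii in probe) {
        pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
        pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
        fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        an <- g$grads[[nm]][ii]
        if (abs(fd) > 1e-8) worst <- max(worst, abs(fd - an) / max(abs(fd), 1e-4))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("training reduces the loss and beats chance on a separable cohort", {
  co <- generate_cohort(cohort_config(n_patients = 300, vocab_size = 15, seed = 6,
                                      signal_type = "frequency"))
  m <- sigfit(co, "LS2+LL", embedding_dim = 4, hidden = 8, epochs = 30,
              batch_size = 32, learning_rate = 3e-3, patience = 30,
              val_fraction = 0.2, seed = 1)
  h <- m$history
  expect_lt(mean(tail(h$train_loss, 2)), mean(head(h$train_loss, 2)))
  labs <- sigehr:::cohort_labels(co)
  expect_gt(auroc(m$fitted, labs), 0.8)
})

test_that("bag-of-words scoring is order-blind and handles empty feature rows", {
  co <- manual_cohort(list(
    list(times = c(1, 2, 3), tokens = c("A", "B", "C"), label = 1),
    list(times = c(1, 2, 3), tokens = c("C", "B", "A"), label = 0),
    list(times = c(1, 2), tokens = c("A", "A"), label = 1),
    list(times = c(1, 2), tokens = c("B", "C"), label = 0)))
  m <- sigfit(co, "BOW")
  s <- predict(m, co)
  expect_equal(s[1], s[2])  # permutations of the same events score identically
  # a patient with only out-of-model signal: all-zero count row scores the intercept
  vocab2 <- rbind(co$vocab, data.frame(token = "Z", index = 4))
  m2 <- m; m2$vocab <- vocab2
  m2$params$beta <- c(m$params$beta, 0)
  lone <- manual_cohort(list(list(times = 1, tokens = "Z", label = 0)))
  expect_equal(predict(m2, lone), as.numeric(plogis(m$params$beta[1])))
})

test_that("the GRU scores single events and is order-sensitive", {
  co <- manual_cohort(list(
    list(times = 5, tokens = "A", label = 1),
    list(times = c(1, 2, 3), tokens = c("A", "B", "C"), label = 0),
    list(times = c(1, 2, 3), tokens = c("C", "B", "A"), label = 1)))
  hp <- list(stream = "cumulative", t_scale = 0.25, t_max = 2, dropout = 0)
  set.seed(7)
  params <- sigehr:::init_gru_params(3, 3, 4, FALSE)
  params$w2 <- rnorm(4)
  spec <- sigehr:::parse_variant("GRU")
  samples <- sigehr:::prep_samples(co, co$vocab)
  sc <- vapply(samples, function(s)
    sigehr:::model_sample_score(s, params, spec, hp), 0)
  expect_true(all(is.finite(sc)) && all(sc > 0 & sc < 1))
  expect_false(sc[2] == sc[3])  # permuted events change the score
})

test_that("fits are deterministic given the seed", {
  co <- make_test_cohort(n = 80, V = 10, seed = 8)
  m1 <- fast_fit(co, "LS2+LL", seed = 11)
  m2 <- fast_fit(co, "LS2+LL", seed = 11)
  expect_identical(m1$fitted, m2$fitted)
  expect_identical(m1$history, m2$history)
  g1 <- fast_fit(co, "GRU", seed = 11)
  g2 <- fast_fit(co, "GRU", seed = 11)
  expect_identical(g1$fitted, g2$fitted)
})

test_that("parameter counts equal the hand-computed architecture sums", {
  co <- make_test_cohort(n = 60, V = 50, seed = 9)
  m <- sigfit(co, "LS2+LL", embedding_dim = 8, hidden = 16, epochs = 1)
  Fw <- num_logsig_terms(16, 2)          # post-augmentation dimension 2*8
  expect_equal(m$feature_width, Fw)
  expect_equal(count_params(m), 50 * 8 + 16 * Fw + 16 + 16 + 1)
  b <- sigfit(co, "BOW")
  expect_equal(count_params(b), 51)
  g <- sigfit(co, "GRU", embedding_dim = 8, gru_hidden = 4, epochs = 1)
  expect_equal(count_params(g), 50 * 8 + 3 * (4 * 8 + 4 * 4 + 4) + 4 + 1)
})

test_that("sigfit S3 methods behave like a classical model object", {
  co <- make_test_cohort(n = 80, V = 10, seed = 10)
  m <- fast_fit(co, "LS2+LL", seed = 1)
  expect_output(print(m), "LS2\\+LL")
  expect_output(print(summary(m)), "AUROC")
  expect_named(coef(m), c("A", "W1", "b1", "w2", "b2"))
  expect_equal(predict(m), m$fitted)
  expect_length(predict(m, co), 80)
  r <- residuals(m)
  expect_equal(sign(r), sign(m$labels - m$fitted))
  sims <- simulate(m, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(80L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  f <- file.path(tempdir(), "plot.pdf")
  grDevices::pdf(f); plot(m); grDevices::dev.off()
  expect_true(file.exists(f))
})
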