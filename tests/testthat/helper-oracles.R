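# Independent oracles used across the suite.

# Numerical quadrature oracle: evaluates each signature coefficient of a
# piecewise-linear path by cumulative numerical evaluation of the recursion
#   Sig^{w}(t) = int_0^t Sig^{w[1:k-1]}(s) df_{w[k]}(s)
# on a fine grid of subdivided segments, with the trapezoid rule applied in
# Riemann-Stieltjes form (increments of f, so segment boundaries are exact).
# Independent of the Chen-product implementation. The level-k integrand is a
# degree-(k-1) polynomial per segment, so the rule is exact up to level 2
# and O(h^2) at level 3.
quad_signature <- function(path, depth, subdiv = 6000) {
  path <- as.matrix(path)
  n <- nrow(path); d <- ncol(path)
  f <- path[1, , drop = FALSE]
  for (i in seq_len(n - 1)) {
    s <- seq(0, 1, length.out = subdiv + 1)[-1]
    f <- rbind(f, outer(1 - s, path[i, ]) + outer(s, path[i + 1, ]))
  }
  m <- nrow(f)
  df <- f[-1, , drop = FALSE] - f[-m, , drop = FALSE]
  words <- list(list(w = integer(0), vals = rep(1, m)))
  out <- list()
  for (k in seq_len(depth)) {
    new_words <- list()
    for (prev in words) for (i in seq_len(d)) {
      w <- c(prev$w, i)
      mid <- 0.5 * (prev$vals[-m] + prev$vals[-1])
      vals <- c(0, cumsum(mid * df[, i]))
      new_words[[length(new_words) + 1]] <- list(w = w, vals = vals)
      out[[paste(w, collapse = "")]] <- vals[m]
    }
    words <- new_words
  }
  out
}

# Flatten the oracle output into the package's lexicographic level order.
quad_signature_flat <- function(path, depth, subdiv = 6000) {
  oc <- quad_signature(path, depth, subdiv)
  d <- ncol(as.matrix(path))
  keys <- unlist(lapply(seq_len(depth), function(k)
    apply(expand_words_oracle(d, k), 1, paste, collapse = "")))
  unlist(oc[keys], use.names = FALSE)
}

expand_words_oracle <- function(d, k) {
  g <- do.call(expand.grid, rev(replicate(k, seq_len(d), simplify = FALSE)))
  as.matrix(g[, rev(seq_len(k)), drop = FALSE])
}

# Brute-force AUROC by pair counting (ties half).
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force average precision by explicit threshold sweep: confusion
# counts at every distinct score threshold, step integral of precision
# over recall.
brute_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  prev_rec <- 0; ap <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n1
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Brute-force Lyndon words: filter all words by the rotation criterion.
brute_lyndon_count <- function(d, N) {
  total <- 0
  for (k in seq_len(N)) {
    words <- expand_words_oracle(d, k)
    for (r in seq_len(nrow(words))) {
      w <- words[r, ]
      key <- paste(sprintf("%02d", w), collapse = "")
      ok <- TRUE
      if (k > 1) for (s in 2:k) {
        rot <- paste(sprintf("%02d", w[c(s:k, 1:(s - 1))]), collapse = "")
        if (rot <= key) { ok <- FALSE; break }
      }
      if (ok) total <- total + 1
    }
  }
  total
}

# Small synthetic cohort wrapper with common test defaults.
make_test_cohort <- function(n = 300, V = 20, seed = 1, ...) {
  generate_cohort(cohort_config(n_patients = n, vocab_size = V, seed = seed, ...))
}

# Manual event cohort from a per-patient list of (times, tokens, label).
manual_cohort <- function(patients, index_date = 4000) {
  seqs <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    sigehr:::new_event_sequence(sprintf("M%03d", i), p$times, p$tokens,
                                p$label, index_date)
  })
  sigehr:::new_event_cohort(seqs, token_vocabulary(
    unlist(lapply(patients, `[[`, "tokens"))))
}
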