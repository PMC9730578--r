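# Truncated tensor algebra over R^d and exact signatures of piecewise-linear
# paths. A level-k coefficient at multi-index (i1,...,ik) is stored in a flat
# vector of length d^k at position 1 + sum_j (i_j - 1) * d^(k-j), i.e.
# lexicographic order with i1 most significant. This ordering is fixed so that
# serialised feature vectors are reproducible.

# kron_vec(a, b): tensor product of flat level vectors, first factor most
# significant. as.vector(outer(b, a)) puts a_p * b_q at (p-1)*length(b) + q.
kron_vec <- function(a, b) as.vector(outer(b, a))

#' Construct a truncated tensor
#'
#' A graded coefficient container for signature and log-signature values:
#' one flat coefficient vector per level `k = 0, ..., depth`, level `k`
#' holding `dim^k` entries in lexicographic multi-index order (first index
#' most significant). Level 0 is the scalar unit of the algebra.
#'
#' @param dim channel dimension `d >= 1`.
#' @param depth truncation depth `N >= 1`.
#' @param levels optional list of `depth + 1` numeric vectors (level 0 first).
#'   Defaults to the identity tensor (level 0 equal to 1, all else 0).
#' @return An object of class `truncated_tensor`.
#' @export
truncated_tensor <- function(dim, depth, levels = NULL) {
  stopifnot(dim >= 1, depth >= 1)
  if (is.null(levels)) {
    levels <- lapply(0:depth, function(k) numeric(dim^k))
    levels[[1]] <- 1
  }
  if (length(levels) != depth + 1)
    stop("`levels` must have depth + 1 entries (level 0 first)")
  for (k in 0:depth) {
    if (length(levels[[k + 1]]) != dim^k)
      stop(sprintf("level %d must have %d coefficients, got %d",
                   k, dim^k, length(levels[[k + 1]])))
  }
  structure(list(dim = as.integer(dim), depth = as.integer(depth),
                 levels = lapply(levels, as.numeric)),
            class = "truncated_tensor")
}

tt_identity <- function(dim, depth) truncated_tensor(dim, depth)

tt_zero <- function(dim, depth) {
  lv <- lapply(0:depth, function(k) numeric(dim^k))
  truncated_tensor(dim, depth, lv)
}

#' @export
print.truncated_tensor <- function(x, ...) {
  cat(sprintf("<truncated_tensor d=%d N=%d (%d coefficients)>\n",
              x$dim, x$depth, sum(lengths(x$levels))))
  cat("  level 0:", format(x$levels[[1]]), "\n")
  for (k in seq_len(x$depth)) {
    v <- x$levels[[k + 1]]
    show <- utils::head(v, 8)
    cat(sprintf("  level %d: %s%s\n", k, paste(signif(show, 6), collapse = " "),
                if (length(v) > 8) " ..." else ""))
  }
  invisible(x)
}

#' Signature of a single linear segment
#'
#' For a linear segment from `start` to `end` the level-k signature
#' coefficient at multi-index (i1,...,ik) is the scaled increment product
#' `prod_j (end[i_j] - start[i_j]) / k!`.
#'
#' @param start,end numeric vectors of equal length (the segment endpoints).
#' @param depth truncation depth `N >= 1`.
#' @return A `truncated_tensor` of dimension `length(start)` and the given depth.
#' @export
segment_signature <- function(start, end, depth) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end))
    stop("start and end must have the same dimension")
  if (!all(is.finite(start)) || !all(is.finite(end)))
    stop("segment endpoints must be finite")
  if (depth < 1) stop("depth must be >= 1")
  d <- length(start)
  delta <- end - start
  lv <- vector("list", depth + 1)
  lv[[1]] <- 1
  ek <- 1
  for (k in seq_len(depth)) {
    ek <- kron_vec(ek, delta) / k   # delta^{(x)k} / k!
    lv[[k + 1]] <- ek
  }
  truncated_tensor(d, depth, lv)
}

#' Truncated tensor product (Chen product)
#'
#' Graded product of two truncated tensors: the level-k coefficient of the
#' product is `sum_{j=0..k} A_j (x) B_{k-j}`, with terms above the truncation
#' depth discarded. With `A` and `B` the signatures of two consecutive path
#' pieces this is Chen's identity: the product is the signature of the
#' concatenated path.
#'
#' @param A,B `truncated_tensor`s of equal dimension.
#' @param depth output truncation depth; defaults to the smaller input depth.
#' @return A `truncated_tensor`.
#' @export
tensor_product_truncated <- function(A, B, depth = min(A$depth, B$depth)) {
  if (A$dim != B$dim) stop("tensor dimensions differ")
  if (A$depth < depth || B$depth < depth) stop("input depth below requested depth")
  d <- A$dim
  lv <- vector("list", depth + 1)
  for (k in 0:depth) {
    acc <- numeric(d^k)
    for (j in 0:k) {
      a <- A$levels[[j + 1]]; b <- B$levels[[k - j + 1]]
      acc <- acc + if (j == 0 || j == k) as.numeric(a) * as.numeric(b) else kron_vec(a, b)
    }
    lv[[k + 1]] <- acc
  }
  truncated_tensor(d, depth, lv)
}

#' Signature of a piecewise-linear path
#'
#' Computes the truncated signature as the left-to-right Chen product of the
#' signatures of consecutive linear segments; linear in the number of points.
#' Level-1 coefficients equal the total increment of the path.
#'
#' @param path an `n x d` numeric matrix of points, `n >= 2`.
#' @param depth truncation depth `N >= 1`.
#' @return A `truncated_tensor`.
#' @export
path_signature <- function(path, depth) {
  path <- as.matrix(path)
  if (!all(is.finite(path))) stop("path coordinates must be finite")
  n <- nrow(path)
  if (n < 2)
    stop("path must have at least 2 points; apply add_basepoint() first")
  S <- segment_signature(path[1, ], path[2, ], depth)
  if (n > 2) for (t in 2:(n - 1)) {
    S <- tensor_product_truncated(S, segment_signature(path[t, ], path[t + 1, ], depth))
  }
  S
}

#' Tensor logarithm
#'
#' Formal logarithm on the truncated algebra: with `B = A - 1`,
#' `log(A) = sum_{m>=1} (-1)^(m+1) B^m / m` truncated at the tensor depth.
#' Requires the level-0 coefficient of `A` to equal 1 (as for any signature);
#' the result has level 0 equal to 0.
#'
#' @param A a `truncated_tensor` with unit level-0 coefficient.
#' @return A `truncated_tensor`.
#' @export
tensor_log <- function(A) {
  if (abs(A$levels[[1]] - 1) > 1e-9)
    stop("tensor_log requires level-0 coefficient equal to 1")
  N <- A$depth
  B <- A
  B$levels[[1]] <- 0
  P <- B
  L <- B
  if (N >= 2) for (m in 2:N) {
    P <- tensor_product_truncated(P, B, N)
    sgn <- if (m %% 2 == 0) -1 else 1
    for (k in 0:N) L$levels[[k + 1]] <- L$levels[[k + 1]] + sgn / m * P$levels[[k + 1]]
  }
  L
}

#' Tensor exponential
#'
#' Graded truncated exponential series, the inverse of [tensor_log()] on the
#' truncated algebra. Requires level 0 of the input to equal 0; the result
#' has level 0 equal to 1.
#'
#' @param A a `truncated_tensor` with zero level-0 coefficient.
#' @return A `truncated_tensor`.
#' @export
tensor_exp <- function(A) {
  if (abs(A$levels[[1]]) > 1e-9)
    stop("tensor_exp requires level-0 coefficient equal to 0")
  N <- A$depth
  E <- tt_identity(A$dim, N)
  P <- A
  fact <- 1
  for (k in 0:N) E$levels[[k + 1]] <- E$levels[[k + 1]] + P$levels[[k + 1]]
  if (N >= 2) for (m in 2:N) {
    P <- tensor_product_truncated(P, A, N)
    fact <- fact * m
    for (k in 0:N) E$levels[[k + 1]] <- E$levels[[k + 1]] + P$levels[[k + 1]] / fact
  }
  E
}

#' Flatten a truncated tensor to a vector
#'
#' Concatenates levels in increasing order, each level in lexicographic
#' multi-index order (first index most significant).
#'
#' @param T a `truncated_tensor`.
#' @param include_level0 keep the constant level-0 scalar? Default `FALSE`
#'   (the scalar is 1 for every signature and carries no information).
#' @return A numeric vector.
#' @export
flatten_tensor <- function(T, include_level0 = FALSE) {
  from <- if (include_level0) 1 else 2
  unlist(T$levels[from:(T$depth + 1)], use.names = FALSE)
}

#' Rebuild a truncated tensor from its flattened form
#'
#' @param v numeric vector produced by [flatten_tensor()].
#' @param dim,depth tensor dimension and depth.
#' @param include_level0 whether `v` contains the level-0 scalar; if `FALSE`
#'   the level-0 coefficient is set to 1.
#' @return A `truncated_tensor`.
#' @export
unflatten_tensor <- function(v, dim, depth, include_level0 = FALSE) {
  lens <- dim^(0:depth)
  if (!include_level0) {
    expected <- sum(lens[-1])
    if (length(v) != expected) stop("flat vector has wrong length")
    v <- c(1, v)
  } else if (length(v) != sum(lens)) stop("flat vector has wrong length")
  lv <- vector("list", depth + 1)
  pos <- 0
  for (k in 0:depth) {
    lv[[k + 1]] <- v[pos + seq_len(lens[k + 1])]
    pos <- pos + lens[k + 1]
  }
  truncated_tensor(dim, depth, lv)
}

#' Number of truncated signature terms
#'
#' The geometric series `sum_{k=0..N} d^k` (including the constant level-0
#' term), i.e. `(d^(N+1) - 1) / (d - 1)` for `d > 1`.
#'
#' @param d path dimension, `d >= 1`.
#' @param N truncation depth, `N >= 0`.
#' @return Integer count.
#' @export
num_sig_terms <- function(d, N) {
  stopifnot(d >= 1, N >= 0)
  sum(d^(0:N))
}

# Moebius function by trial-division factorisation; arguments are small.
mobius_mu <- function(n) {
  if (n == 1) return(1)
  k <- 0
  m <- n
  p <- 2
  while (p * p <= m) {
    if (m %% p == 0) {
      m <- m %/% p
      k <- k + 1
      if (m %% p == 0) return(0)
    } else p <- p + 1
  }
  if (m > 1) k <- k + 1
  if (k %% 2 == 0) 1 else -1
}

#' Number of log-signature terms (Witt's formula)
#'
#' Dimension of the free Lie algebra over `d` letters graded up to degree `N`:
#' `sum_{k=1..N} W(d,k)` with the necklace-counting Witt numbers
#' `W(d,k) = (1/k) sum_{m | k} mu(m) d^(k/m)`. Equals the number of Lyndon
#' words over `d` letters of length at most `N`.
#'
#' @param d alphabet size, `d >= 1`.
#' @param N maximum word length, `N >= 1`.
#' @return Integer count.
#' @export
num_logsig_terms <- function(d, N) {
  stopifnot(d >= 1, N >= 1)
  total <- 0
  for (k in 1:N) {
    divs <- which(k %% seq_len(k) == 0)
    total <- total + sum(vapply(divs, function(m) mobius_mu(m) * d^(k %/% m), 0)) / k
  }
  as.integer(round(total))
}

#' Lyndon words up to a given length
#'
#' Generates all Lyndon words (aperiodic words strictly smaller than all of
#' their rotations) over the alphabet `1..d` of length at most `N`, by
#' Duval's algorithm, returned sorted by length then lexicographically.
#'
#' @param d alphabet size.
#' @param N maximum word length.
#' @return A list of integer vectors.
#' @export
lyndon_words <- function(d, N) {
  out <- list()
  w <- c(1L)
  repeat {
    if (length(w) <= N) out[[length(out) + 1]] <- w
    # Duval: extend periodically to length N, then increment the last
    # incrementable letter.
    w <- w[((seq_len(N) - 1L) %% length(w)) + 1L]
    while (length(w) > 0 && w[length(w)] == d) w <- w[-length(w)]
    if (length(w) == 0) break
    w[length(w)] <- w[length(w)] + 1L
  }
  ord <- order(lengths(out), vapply(out, function(x) paste(sprintf("%03d", x), collapse = ""), ""))
  out[ord]
}

# Flat (within-level) index of a multi-index word over 1..d.
word_flat_index <- function(w, d) {
  idx <- 0
  for (i in w) idx <- idx * d + (i - 1)
  idx + 1
}

# Right standard factorisation bracketing of a Lyndon word, expanded in the
# level-|w| tensor coordinates: rho(letter) = e_letter; rho(uv) =
# rho(u) (x) rho(v) - rho(v) (x) rho(u), v the lexicographically smallest
# (equivalently longest Lyndon) proper suffix.
lyndon_expansion <- function(w, d) {
  k <- length(w)
  if (k == 1) {
    e <- numeric(d); e[w] <- 1
    return(e)
  }
  sufs <- lapply(2:k, function(i) w[i:k])
  keys <- vapply(sufs, function(x) paste(sprintf("%03d", x), collapse = ""), "")
  v <- sufs[[order(keys)[1]]]
  u <- w[seq_len(k - length(v))]
  eu <- lyndon_expansion(u, d)
  ev <- lyndon_expansion(v, d)
  kron_vec(eu, ev) - kron_vec(ev, eu)
}

# Cache of Lyndon projection data per (d, N): for each level k a list with
# words, their flat indices, and the unit lower-triangular matrix M with
# M[r, c] = coefficient of Lyndon word r in the expansion of bracketed
# Lyndon word c (rows/cols in lex order). Solving M c = tlog[idx] recovers
# the Lyndon-basis coordinates by forward substitution.
.sig_cache <- new.env(parent = emptyenv())

lyndon_projection_data <- function(d, N) {
  key <- sprintf("lyndon_%d_%d", d, N)
  if (!is.null(.sig_cache[[key]])) return(.sig_cache[[key]])
  words <- lyndon_words(d, N)
  out <- vector("list", N)
  for (k in seq_len(N)) {
    wk <- words[lengths(words) == k]
    idx <- vapply(wk, word_flat_index, 0, d = d)
    W <- length(wk)
    M <- matrix(0, W, W)
    for (c in seq_len(W)) {
      exp_c <- lyndon_expansion(wk[[c]], d)
      M[, c] <- exp_c[idx]
    }
    out[[k]] <- list(words = wk, idx = idx, M = M)
  }
  .sig_cache[[key]] <- out
  out
}

#' Log-signature of a piecewise-linear path
#'
#' The tensor logarithm of the truncated signature, expressed either in full
#' tensor coordinates (`basis = "tensor"`, verbose, mainly for testing) or on
#' the Lyndon-word basis of the free Lie algebra (`basis = "lyndon"`, the
#' compact default, with exactly [num_logsig_terms()] coefficients). Lyndon
#' coordinates are recovered by a triangular solve in lexicographic Lyndon
#' order.
#'
#' @param path an `n x d` numeric matrix, `n >= 2`.
#' @param depth truncation depth `N >= 1`.
#' @param basis `"lyndon"` (default) or `"tensor"`.
#' @return An object of class `log_signature` with fields `dim`, `depth`,
#'   `basis`, `coeffs` and `basis_labels`.
#' @export
log_signature <- function(path, depth, basis = c("lyndon", "tensor")) {
  basis <- match.arg(basis)
  S <- path_signature(path, depth)
  L <- tensor_log(S)
  d <- S$dim
  if (basis == "tensor") {
    coeffs <- flatten_tensor(L, include_level0 = FALSE)
    labels <- unlist(lapply(seq_len(depth), function(k) {
      apply(as.matrix(expand_words(d, k)), 1, paste, collapse = "")
    }))
  } else {
    proj <- lyndon_projection_data(d, depth)
    coeffs <- numeric(0)
    labels <- character(0)
    for (k in seq_len(depth)) {
      pk <- proj[[k]]
      ck <- forwardsolve(pk$M, L$levels[[k + 1]][pk$idx])
      coeffs <- c(coeffs, ck)
      labels <- c(labels, vapply(pk$words, paste, "", collapse = ""))
    }
  }
  structure(list(dim = d, depth = depth, basis = basis,
                 coeffs = as.numeric(coeffs), basis_labels = labels),
            class = "log_signature")
}

# All words of length k over 1..d in lexicographic order, as a matrix.
expand_words <- function(d, k) {
  g <- do.call(expand.grid, rev(replicate(k, seq_len(d), simplify = FALSE)))
  as.matrix(g[, rev(seq_len(k)), drop = FALSE])
}

#' @export
print.log_signature <- function(x, ...) {
  cat(sprintf("<log_signature d=%d N=%d basis=%s (%d terms)>\n",
              x$dim, x$depth, x$basis, length(x$coeffs)))
  show <- utils::head(seq_along(x$coeffs), 10)
  cat(paste(sprintf("  [%s] %.6g", x$basis_labels[show], x$coeffs[show]),
            collapse = "\n"), "\n")
  if (length(x$coeffs) > 10) cat("  ...\n")
  invisible(x)
}
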