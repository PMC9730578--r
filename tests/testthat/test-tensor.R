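# Truncated tensor algebra and signature computation.

test_that("segment signatures are scaled increment products", {
  s <- segment_signature(c(0, 0), c(1, 2), 2)
  expect_equal(s$levels[[1]], 1)
  expect_equal(s$levels[[2]], c(1, 2))
  # level-2 flat order (1,1),(1,2),(2,1),(2,2)
  expect_equal(s$levels[[3]], c(0.5, 1, 1, 2))

  z <- segment_signature(c(1, 3), c(1, 3), 4)
  expect_equal(z$levels[[1]], 1)
  for (k in 1:4) expect_equal(z$levels[[k + 1]], numeric(2^k))

  a <- 1.7
  s1 <- segment_signature(0, a, 3)
  expect_equal(unlist(s1$levels), c(1, a, a^2 / 2, a^3 / 6))
})

test_that("segment signature validates inputs", {
  expect_error(segment_signature(c(0, NA), c(1, 1), 2), "finite")
  expect_error(segment_signature(0, Inf, 2), "finite")
  expect_error(segment_signature(c(0, 0), c(1, 1), 0), "depth")
  expect_error(segment_signature(c(0, 0), 1, 2), "dimension")
})

test_that("Chen product reproduces concatenated paths", {
  A <- segment_signature(c(0, 0), c(1, 0), 2)
  B <- segment_signature(c(1, 0), c(1, 1), 2)
  C <- tensor_product_truncated(A, B)
  expect_equal(C$levels[[2]], c(1, 1))
  expect_equal(C$levels[[3]], c(0.5, 1, 0, 0.5))

  # identity of the algebra
  id <- truncated_tensor(2, 2)
  expect_equal(tensor_product_truncated(id, B)$levels, B$levels)
  expect_equal(tensor_product_truncated(B, id)$levels, B$levels)

  # collinear doubling: S (x) S equals the signature of the doubled segment
  S <- segment_signature(c(0.3, -1), c(1.1, 0.5), 3)
  SS <- tensor_product_truncated(S, S)
  doubled <- segment_signature(c(0.3, -1), c(1.9, 2), 3)
  expect_equal(unlist(SS$levels), unlist(doubled$levels), tolerance = 1e-12)

  expect_error(tensor_product_truncated(S, segment_signature(0, 1, 3)), "dimension")
})

test_that("path signature: single segment, L-path, and the increment property", {
  p2 <- rbind(c(0.2, 1), c(1.5, -0.3))
  expect_equal(unlist(path_signature(p2, 3)$levels),
               unlist(segment_signature(p2[1, ], p2[2, ], 3)$levels))

  L <- path_signature(rbind(c(0, 0), c(1, 0), c(1, 1)), 2)
  expect_equal(L$levels[[2]], c(1, 1))
  expect_equal(L$levels[[3]], c(0.5, 1, 0, 0.5))

  set.seed(1)
  for (rep in 1:5) {
    p <- matrix(rnorm(12), 4, 3)
    S <- path_signature(p, 2)
    expect_equal(S$levels[[2]], p[4, ] - p[1, ])  # exact increments
  }

  expect_error(path_signature(matrix(1:2, 1, 2), 2), "basepoint")
})

test_that("signature is invariant to collinear refinement and translation", {
  set.seed(2)
  p <- matrix(rnorm(8), 4, 2)
  # insert midpoints of every segment
  refined <- p[1, , drop = FALSE]
  for (i in 1:3) refined <- rbind(refined, (p[i, ] + p[i + 1, ]) / 2, p[i + 1, ])
  expect_equal(unlist(path_signature(p, 3)$levels),
               unlist(path_signature(refined, 3)$levels), tolerance = 1e-12)
  shifted <- sweep(p, 2, c(5, -3), "+")
  expect_equal(unlist(path_signature(p, 3)$levels),
               unlist(path_signature(shifted, 3)$levels), tolerance = 1e-12)
})

test_that("Chen splitting at interior points matches the whole-path signature", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(4:6, 1); d <- sample(2:3, 1)
    p <- matrix(rnorm(n * d), n, d)
    cut <- sample(2:(n - 1), 1)
    S <- path_signature(p, 3)
    AB <- tensor_product_truncated(path_signature(p[1:cut, , drop = FALSE], 3),
                                   path_signature(p[cut:n, , drop = FALSE], 3))
    expect_lt(max(abs(unlist(S$levels) - unlist(AB$levels))), 1e-10)
  }
})

test_that("tensor exp and log are mutually inverse on the truncated algebra", {
  expect_equal(unlist(tensor_log(truncated_tensor(2, 3))$levels), numeric(15))
  z <- sigehr:::tt_zero(2, 3); z$levels[[1]] <- 0
  expect_equal(unlist(tensor_exp(z)$levels), unlist(truncated_tensor(2, 3)$levels))

  # scalar exponential along the 1-d diagonal
  a <- 0.8
  A1 <- truncated_tensor(1, 4, list(0, a, 0, 0, 0))
  expect_equal(unlist(tensor_exp(A1)$levels), c(1, a, a^2 / 2, a^3 / 6, a^4 / 24))

  set.seed(4)
  for (rep in 1:5) {
    p <- matrix(rnorm(10), 5, 2)
    S <- path_signature(p, 3)
    expect_lt(max(abs(unlist(tensor_exp(tensor_log(S))$levels) - unlist(S$levels))), 1e-10)
    L <- tensor_log(S)
    expect_lt(max(abs(unlist(tensor_log(tensor_exp(L))$levels) - unlist(L$levels))), 1e-10)
    expect_equal(L$levels[[1]], 0)
  }

  # single linear segment: log is the pure level-1 increment
  S1 <- segment_signature(c(0, 1), c(2, -1), 3)
  L1 <- tensor_log(S1)
  expect_equal(L1$levels[[2]], c(2, -2))
  expect_lt(max(abs(L1$levels[[3]])), 1e-12)
  expect_lt(max(abs(L1$levels[[4]])), 1e-12)

  bad <- truncated_tensor(2, 2); bad$levels[[1]] <- 2
  expect_error(tensor_log(bad), "level-0")
  expect_error(tensor_exp(truncated_tensor(2, 2)), "level-0")
})

test_that("term counts follow the geometric series and Witt's formula", {
  expect_identical(num_sig_terms(2, 2), 7)
  expect_identical(num_sig_terms(1, 5), 6)
  expect_identical(num_sig_terms(10, 3), 1111)
  expect_identical(num_logsig_terms(2, 2), 3L)
  expect_identical(num_logsig_terms(2, 3), 5L)
  expect_identical(num_logsig_terms(1, 4), 1L)
  for (d in 1:5) for (N in 1:5) {
    expect_identical(num_logsig_terms(d, N), length(lyndon_words(d, N)))
    expect_identical(num_logsig_terms(d, N), as.integer(brute_lyndon_count(d, N)))
  }
})

test_that("log-signature in the Lyndon basis matches the tensor logarithm", {
  p <- rbind(c(0, 0), c(1, 0), c(1, 1))
  ls <- log_signature(p, 2)
  expect_length(ls$coeffs, 3)
  expect_equal(ls$basis_labels, c("1", "2", "12"))
  # depth-2 coefficient is the Levy area
  expect_equal(ls$coeffs[3], 0.5)
  S <- path_signature(p, 2)
  expect_equal(ls$coeffs[3], 0.5 * (S$levels[[3]][2] - S$levels[[3]][3]))

  # a 2-point path is a pure level-1 exponential
  ls2 <- log_signature(rbind(c(0, 0, 0), c(1, 2, 3)), 3)
  expect_lt(max(abs(ls2$coeffs[-(1:3)])), 1e-12)
  expect_length(log_signature(rbind(c(0, 0, 0), c(1, 2, 3)), 2)$coeffs, 6)

  # Lyndon coefficients reconstruct the full tensor logarithm
  set.seed(5)
  for (rep in 1:3) {
    d <- sample(2:3, 1)
    p <- matrix(rnorm(4 * d), 4, d)
    ly <- log_signature(p, 3, basis = "lyndon")
    tl <- log_signature(p, 3, basis = "tensor")
    pd <- sigehr:::lyndon_projection_data(d, 3)
    rec <- numeric(0)
    off <- 0
    for (k in 1:3) {
      W <- length(pd[[k]]$idx)
      lvl <- numeric(d^k)
      for (ci in seq_len(W))
        lvl <- lvl + ly$coeffs[off + ci] * sigehr:::lyndon_expansion(pd[[k]]$words[[ci]], d)
      rec <- c(rec, lvl)
      off <- off + W
    }
    expect_lt(max(abs(rec - tl$coeffs)), 1e-10)
  }
  expect_error(log_signature(p, 2, basis = "hall"), "arg")
})

test_that("flatten and unflatten round-trip in fixed lexicographic order", {
  set.seed(6)
  p <- matrix(rnorm(8), 4, 2)
  S <- path_signature(p, 2)
  v <- flatten_tensor(S)
  expect_length(v, 6)
  expect_equal(v[1:2], S$levels[[2]])
  back <- unflatten_tensor(v, 2, 2)
  expect_equal(back$levels, S$levels)
  v0 <- flatten_tensor(S, include_level0 = TRUE)
  expect_length(v0, num_sig_terms(2, 2))
  expect_equal(unflatten_tensor(v0, 2, 2, include_level0 = TRUE)$levels, S$levels)
  expect_equal(flatten_tensor(truncated_tensor(2, 2)), numeric(6))
  expect_error(unflatten_tensor(v[-1], 2, 2), "length")
})

test_that("signature coefficients agree with the quadrature oracle", {
  set.seed(7)
  for (rep in 1:4) {
    d <- sample(2:3, 1); n <- sample(3:6, 1); N <- sample(2:3, 1)
    p <- matrix(rnorm(n * d), n, d)
    expect_lt(max(abs(quad_signature_flat(p, N, subdiv = 3000) -
                        flatten_tensor(path_signature(p, N)))), 2e-6)
  }
})
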