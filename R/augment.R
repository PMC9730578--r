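# Path augmentations applied before the signature. A path is a plain n x d
# numeric matrix of points. Fixed application order in apply_chain():
# learnt projection -> time channel (index or delta) -> lead-lag -> basepoint.

#' Declare an augmentation chain
#'
#' Declarative description of the augmentations applied to an event path
#' before the signature. Time-index and time-delta channels are mutually
#' exclusive. Applied in the fixed order: learnt projection, time channel,
#' lead-lag, basepoint (the basepoint must anchor the final path).
#'
#' @param time one of `"none"`, `"index"` (event position 0..n-1) or
#'   `"delta"` (scaled days-to-prediction channel).
#' @param t_scale,t_max parameters of the time-delta scaling
#'   `min(t_scale * log(dT), t_max)`, with `dT` in days; both positive.
#' @param basepoint prepend a zero origin point?
#' @param lead_lag add a one-step lagged copy of the path as extra channels?
#' @param proj_dim output dimension of the learnt projection, or `NULL` for
#'   no projection.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(time = c("none", "index", "delta"),
                              t_scale = 0.25, t_max = 2,
                              basepoint = FALSE, lead_lag = FALSE,
                              proj_dim = NULL) {
  time <- match.arg(time)
  if (t_scale <= 0 || t_max <= 0) stop("t_scale and t_max must be positive")
  if (!is.null(proj_dim) && proj_dim < 1) stop("proj_dim must be a positive integer")
  structure(list(time = time, t_scale = t_scale, t_max = t_max,
                 basepoint = isTRUE(basepoint), lead_lag = isTRUE(lead_lag),
                 proj_dim = if (is.null(proj_dim)) NULL else as.integer(proj_dim)),
            class = "augmentation_spec")
}

#' @export
print.augmentation_spec <- function(x, ...) {
  parts <- c(if (!is.null(x$proj_dim)) sprintf("proj(%d)", x$proj_dim),
             if (x$time == "index") "time-index",
             if (x$time == "delta") sprintf("time-delta(scale=%g, max=%g)", x$t_scale, x$t_max),
             if (x$lead_lag) "lead-lag",
             if (x$basepoint) "basepoint")
  cat("<augmentation_spec:", if (length(parts)) paste(parts, collapse = " -> ") else "identity", ">\n")
  invisible(x)
}

#' Append an event-index time channel
#'
#' Concatenates one extra dimension holding the position of each event in
#' the sequence (0, 1, ..., n-1), which removes the signature's
#' reparameterisation invariance even when no timestamps are available.
#'
#' @param path an `n x d` numeric matrix, `n >= 1`.
#' @return An `n x (d+1)` matrix; the index is the last column.
#' @export
add_time_index <- function(path) {
  path <- as.matrix(path)
  cbind(path, seq_len(nrow(path)) - 1)
}

#' Scaled time-delta channel
#'
#' Maps each event's distance to the prediction date, `dT` in days, through
#' the capped logarithmic scaling `min(t_scale * log(dT), t_max)`. Events on
#' the prediction date itself cannot occur under a pre-index buffer, but a
#' `dT` of zero is floored at one day so the logarithm stays defined.
#'
#' @param delta_days non-negative numeric vector of days from event to
#'   prediction date.
#' @param t_scale,t_max positive scaling parameters.
#' @return Numeric vector of channel values, to be appended as the last path
#'   coordinate.
#' @export
add_time_delta <- function(delta_days, t_scale = 0.25, t_max = 2) {
  if (any(!is.finite(delta_days))) stop("time deltas must be finite")
  if (any(delta_days < 0)) stop("negative time delta: event after prediction date")
  pmin(t_scale * log(pmax(delta_days, 1)), t_max)
}

#' Prepend a basepoint
#'
#' Introduces a zero origin point at the start of the path. This removes the
#' signature's translation invariance and guarantees at least two points, so
#' single-event sequences become signaturable.
#'
#' @param path an `n x d` numeric matrix, `n >= 1`.
#' @return An `(n+1) x d` matrix whose first row is zero.
#' @export
add_basepoint <- function(path) {
  path <- as.matrix(path)
  rbind(numeric(ncol(path)), path)
}

#' Lead-lag augmentation
#'
#' Pairs the path with a one-step lagged copy of itself: the output point
#' sequence is `(x1,x1), (x2,x1), (x2,x2), ..., (xn,xn)` (2n-1 points, 2d
#' channels; lead block first). Signature terms of the lead-lag path capture
#' the quadratic variation and co-variation of the original channels.
#'
#' @param path an `n x d` numeric matrix, `n >= 2`.
#' @return A `(2n-1) x 2d` matrix.
#' @export
lead_lag <- function(path) {
  path <- as.matrix(path)
  n <- nrow(path)
  if (n < 2) stop("lead_lag requires a path with at least 2 points")
  k <- seq_len(2 * n - 1)
  cbind(path[ceiling((k + 1) / 2), , drop = FALSE],
        path[ceiling(k / 2), , drop = FALSE])
}

#' Learnt projection (pointwise affine embedding)
#'
#' Applies a linear map `x -> A x` to every path point, reducing the path
#' dimension to make the signature tractable for large vocabularies. In the
#' neural-signature model the matrix is the trainable token embedding.
#'
#' @param path an `n x d` numeric matrix.
#' @param A an `a x d` projection matrix.
#' @return An `n x a` matrix.
#' @export
learnt_projection <- function(path, A) {
  path <- as.matrix(path); A <- as.matrix(A)
  if (ncol(A) != ncol(path)) stop("projection matrix columns must match path dimension")
  path %*% t(A)
}

#' Apply an augmentation chain
#'
#' Applies the augmentations declared in an [augmentation_spec()] in the
#' fixed order: learnt projection, time channel (index or delta), lead-lag,
#' basepoint. The output shape is deterministic given the spec and input.
#'
#' @param path an `n x d` numeric matrix.
#' @param spec an [augmentation_spec()].
#' @param delta_days days-to-prediction per event; required when
#'   `spec$time == "delta"`.
#' @param projection the `a x d` projection matrix; required when
#'   `spec$proj_dim` is set.
#' @return The augmented path matrix.
#' @export
apply_chain <- function(path, spec, delta_days = NULL, projection = NULL) {
  stopifnot(inherits(spec, "augmentation_spec"))
  path <- as.matrix(path)
  if (!is.null(spec$proj_dim)) {
    if (is.null(projection)) stop("spec requests a learnt projection but none was given")
    if (nrow(as.matrix(projection)) != spec$proj_dim)
      stop("projection matrix rows must equal proj_dim")
    path <- learnt_projection(path, projection)
  }
  if (spec$time == "index") {
    path <- add_time_index(path)
  } else if (spec$time == "delta") {
    if (is.null(delta_days)) stop("time-delta augmentation requires delta_days")
    if (length(delta_days) != nrow(path)) stop("delta_days length must match path points")
    path <- cbind(path, add_time_delta(delta_days, spec$t_scale, spec$t_max))
  }
  if (spec$lead_lag) path <- lead_lag(path)
  if (spec$basepoint) path <- add_basepoint(path)
  path
}

# Output dimension of the chain for a given input dimension.
augmented_dim <- function(spec, d) {
  a <- if (!is.null(spec$proj_dim)) spec$proj_dim else d
  if (spec$time != "none") a <- a + 1
  if (spec$lead_lag) a <- 2 * a
  a
}
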