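# Synthetic EHR-like cohorts: timestamped categorical event sequences with a
# 1:9 case:control structure, skewed token usage, tied timestamps, a 90-day
# pre-index buffer, and a plantable class signal that is either order-based
# (invisible to bag-of-words models by construction), co-occurrence-based,
# or frequency-based (a bag-of-words-solvable control condition).

#' Cohort generator configuration
#'
#' @param n_patients total number of patients.
#' @param case_fraction fraction of cases; the cohort is split exactly
#'   (default 0.1, a 1:9 case:control ratio).
#' @param vocab_size number of distinct event tokens.
#' @param mean_events target mean sequence length (default 4.15, matching a
#'   primary-diagnosis-style corpus; use ~13.98 for an extended corpus with
#'   secondary diagnoses and procedures).
#' @param frac_single_event fraction of patients with exactly one background
#'   event (default 0.2).
#' @param signal_type `"order"` (token pair a-then-b in cases, b-then-a in
#'   controls; marginal token counts identical between classes),
#'   `"cooccurrence"` (pair co-occurs in cases only, marginal counts
#'   balanced), or `"frequency"` (marker token appears in cases only —
#'   solvable by token counts alone).
#' @param signal_strength probability that a patient carries the planted
#'   signal, in \[0, 1\].
#' @param buffer_days pre-index exclusion buffer in days (default 90); all
#'   generated events predate the index date by at least this much.
#' @param lookback_days event history window length in days (default 3650).
#' @param zipf_exponent skew of the background token distribution
#'   (probability of rank r proportional to `r^-zipf_exponent`).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1000, case_fraction = 0.1,
                          vocab_size = 50, mean_events = 4.15,
                          frac_single_event = 0.2,
                          signal_type = c("order", "cooccurrence", "frequency"),
                          signal_strength = 1, buffer_days = 90,
                          lookback_days = 3650, zipf_exponent = 1.1,
                          seed = 1) {
  signal_type <- match.arg(signal_type)
  if (case_fraction <= 0 || case_fraction >= 1) stop("case_fraction must be in (0, 1)")
  if (signal_strength < 0 || signal_strength > 1) stop("signal_strength must be in [0, 1]")
  if (vocab_size < 4) stop("vocab_size must be at least 4")
  # lengths: 1 with prob frac_single_event, else 2 + Poisson(lambda); solve
  # lambda so the overall mean matches.
  lambda <- (mean_events - frac_single_event - 2 * (1 - frac_single_event)) /
    (1 - frac_single_event)
  if (lambda < 0)
    stop("infeasible config: mean_events too small for the single-event fraction")
  structure(list(n_patients = as.integer(n_patients), case_fraction = case_fraction,
                 vocab_size = as.integer(vocab_size), mean_events = mean_events,
                 frac_single_event = frac_single_event, signal_type = signal_type,
                 signal_strength = signal_strength, buffer_days = as.integer(buffer_days),
                 lookback_days = as.integer(lookback_days),
                 zipf_exponent = zipf_exponent, length_lambda = lambda,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

new_event_sequence <- function(patient_id, times, tokens, label, index_date) {
  o <- order(times)
  structure(list(patient_id = patient_id, times = as.integer(times[o]),
                 tokens = as.character(tokens[o]), label = as.integer(label),
                 index_date = as.integer(index_date)),
            class = "event_sequence")
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence %s label=%d index_date=%d (%d events)>\n",
              x$patient_id, x$label, x$index_date, length(x$times)))
  invisible(x)
}

new_event_cohort <- function(sequences, vocab, config = NULL) {
  structure(list(sequences = sequences, vocab = vocab, config = config),
            class = "event_cohort")
}

#' @export
print.event_cohort <- function(x, ...) {
  labs <- cohort_labels(x)
  len <- vapply(x$sequences, function(s) length(s$times), 0)
  cat(sprintf("<event_cohort: %d patients (%d cases / %d controls), %d tokens>\n",
              length(labs), sum(labs == 1), sum(labs == 0),
              if (is.null(x$vocab)) NA_integer_ else nrow(x$vocab)))
  cat(sprintf("  events/patient: mean %.2f, single-event %.1f%%\n",
              mean(len), 100 * mean(len == 1)))
  invisible(x)
}

#' @export
summary.event_cohort <- function(object, ...) {
  labs <- cohort_labels(object)
  len <- vapply(object$sequences, function(s) length(s$times), 0)
  out <- list(n_patients = length(labs), n_cases = sum(labs == 1),
              case_fraction = mean(labs), mean_events = mean(len),
              frac_single_event = mean(len == 1),
              vocab_size = if (is.null(object$vocab)) NA_integer_ else nrow(object$vocab))
  class(out) <- "summary.event_cohort"
  out
}

#' @export
print.summary.event_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d patients: %d cases (%.1f%%), mean %.2f events/patient, %.1f%% single-event, vocabulary %d\n",
              x$n_patients, x$n_cases, 100 * x$case_fraction, x$mean_events,
              100 * x$frac_single_event, x$vocab_size))
  invisible(x)
}

#' @export
as.data.frame.event_cohort <- function(x, ...) {
  do.call(rbind, lapply(x$sequences, function(s) {
    data.frame(patient_id = s$patient_id, timestamp_days = s$times,
               token = s$tokens, label = s$label, index_date = s$index_date,
               stringsAsFactors = FALSE)
  }))
}

cohort_labels <- function(cohort) {
  vapply(cohort$sequences, function(s) s$label, 0L)
}

#' Build a token vocabulary
#'
#' Bijective mapping from token strings to contiguous integer indices
#' `0..V-1`, in sorted token order.
#'
#' @param tokens character vector of tokens (possibly with repeats), or an
#'   `event_cohort`.
#' @return A data frame with columns `token` and `index`.
#' @export
token_vocabulary <- function(tokens) {
  if (inherits(tokens, "event_cohort"))
    tokens <- unlist(lapply(tokens$sequences, function(s) s$tokens), use.names = FALSE)
  tok <- sort(unique(as.character(tokens)))
  data.frame(token = tok, index = seq_along(tok) - 1L, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Samples an event cohort with the structure described by a
#' [cohort_config()]: an exact case/control split, variable-length sequences
#' with a configurable single-event fraction, Zipf-skewed background tokens,
#' integer-day timestamps over a lookback window ending `buffer_days` before
#' the index date (controls inherit the index date of their matched case),
#' and a planted class signal. For the order signal, a designated token pair
#' is inserted as a-then-b in signal-carrying cases and b-then-a in
#' signal-carrying controls, so marginal token counts are identical between
#' classes and the signal is invisible to bag-of-words models. Signal tokens
#' are reserved (never drawn as background).
#'
#' @param config a [cohort_config()].
#' @return An `event_cohort` with fields `sequences`, `vocab` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  V <- config$vocab_size
  tokens_all <- sprintf("C%03d", seq_len(V))
  # reserved signal tokens at mid-frequency ranks
  sig_a <- tokens_all[max(2, floor(V / 3))]
  sig_b <- tokens_all[max(3, floor(2 * V / 3))]
  background <- setdiff(tokens_all, c(sig_a, sig_b))
  pr <- seq_along(background)^(-config$zipf_exponent)
  pr <- pr / sum(pr)

  n <- config$n_patients
  n_cases <- round(n * config$case_fraction)
  n_controls <- n - n_cases
  labels <- c(rep(1L, n_cases), rep(0L, n_controls))
  # matched structure: controls share the index date of their matched case
  case_index_dates <- if (n_cases > 0)
    sample(seq(config$lookback_days, config$lookback_days + 1825), n_cases, replace = TRUE)
  else integer(0)
  match_of <- if (n_cases > 0) rep_len(seq_len(n_cases), n_controls) else integer(0)
  index_dates <- c(case_index_dates, case_index_dates[match_of])

  seqs <- vector("list", n)
  for (i in seq_len(n)) {
    idx_date <- index_dates[i]
    lo <- idx_date - config$lookback_days
    hi <- idx_date - config$buffer_days
    len <- if (stats::runif(1) < config$frac_single_event) 1L
           else 2L + stats::rpois(1, config$length_lambda)
    times <- sample(lo:hi, len, replace = TRUE)
    toks <- sample(background, len, replace = TRUE, prob = pr)
    if (stats::runif(1) < config$signal_strength) {
      ins <- plant_signal(config$signal_type, labels[i], sig_a, sig_b, lo, hi)
      times <- c(times, ins$times)
      toks <- c(toks, ins$tokens)
    }
    ord <- order_with_random_ties(times)
    seqs[[i]] <- new_event_sequence(sprintf("P%05d", i), times[ord], toks[ord],
                                    labels[i], idx_date)
  }
  vocab <- data.frame(token = tokens_all, index = seq_len(V) - 1L,
                      stringsAsFactors = FALSE)
  cohort <- new_event_cohort(seqs, vocab, config)
  attr(cohort, "signal_tokens") <- c(a = sig_a, b = sig_b)
  cohort
}

# Planted signal events for one patient. Order: cases a-then-b, controls
# b-then-a at two distinct days. Co-occurrence: cases receive the pair,
# controls one of the two tokens twice (marginal counts balanced in
# expectation, but the pair never co-occurs in controls). Frequency: cases
# receive one extra marker token (bag-of-words-solvable by design).
plant_signal <- function(type, label, sig_a, sig_b, lo, hi) {
  two_days <- sort(sample(lo:hi, 2, replace = FALSE))
  if (type == "order") {
    toks <- if (label == 1) c(sig_a, sig_b) else c(sig_b, sig_a)
    list(times = two_days, tokens = toks)
  } else if (type == "cooccurrence") {
    if (label == 1) list(times = two_days, tokens = c(sig_a, sig_b))
    else list(times = two_days, tokens = rep(sample(c(sig_a, sig_b), 1), 2))
  } else {
    if (label == 1) list(times = sample(lo:hi, 1), tokens = sig_a)
    else list(times = integer(0), tokens = character(0))
  }
}

# Ordering permutation: non-decreasing in time, uniformly random within each
# tied-timestamp group (uses the current RNG stream).
order_with_random_ties <- function(times) {
  jitter <- stats::runif(length(times))
  order(times, jitter)
}

#' Randomly order tied events
#'
#' Events occurring on the same day are put in a uniformly random order
#' (under the given seed) while the order across distinct timestamps is
#' preserved. Mirrors the preprocessing rule applied when sequence order is
#' ambiguous in day-resolution records.
#'
#' @param events an `event_sequence`.
#' @param seed integer seed for the tie-breaking permutation.
#' @return The `event_sequence` with tied events permuted.
#' @export
random_order_ties <- function(events, seed = 1) {
  stopifnot(inherits(events, "event_sequence"))
  set.seed(seed)
  ord <- order_with_random_ties(events$times)
  events$times <- events$times[ord]
  events$tokens <- events$tokens[ord]
  events
}

#' Apply the pre-index buffer filter
#'
#' Removes all events falling inside the buffer window before the index
#' date: an event is kept iff `timestamp <= index_date - buffer_days`
#' (closed boundary on the allowed side). For controls the index date is the
#' diagnosis date of the matched case. A sequence left empty should be
#' excluded upstream.
#'
#' @param events an `event_sequence`.
#' @param buffer_days buffer length in days (default 90).
#' @return The filtered `event_sequence`.
#' @export
buffer_filter <- function(events, buffer_days = 90) {
  stopifnot(inherits(events, "event_sequence"))
  keep <- events$times <= events$index_date - buffer_days
  events$times <- events$times[keep]
  events$tokens <- events$tokens[keep]
  events
}

#' One-hot (or cumulative-count) path of an event sequence
#'
#' Maps each event to the one-hot vector of its token (`stream = "onehot"`),
#' or to the running count vector (`stream = "cumulative"`), whose final row
#' is the bag-of-words count vector and whose increments are exactly the
#' one-hot events — the stream the signature's increments act on.
#'
#' @param events an `event_sequence`.
#' @param vocab vocabulary data frame from [token_vocabulary()].
#' @param stream `"cumulative"` (default) or `"onehot"`.
#' @return An `n x V` numeric matrix.
#' @export
one_hot_path <- function(events, vocab, stream = c("cumulative", "onehot")) {
  stream <- match.arg(stream)
  idx <- match(events$tokens, vocab$token)
  if (anyNA(idx))
    stop("unknown token(s): ", paste(unique(events$tokens[is.na(idx)]), collapse = ", "))
  n <- length(idx); V <- nrow(vocab)
  m <- matrix(0, n, V)
  m[cbind(seq_len(n), idx)] <- 1
  if (stream == "cumulative" && n > 1) m <- apply(m, 2, cumsum)
  m
}

#' Write / read event sequences
#'
#' CSV schema: `patient_id,timestamp_days,token,label,index_date` (header
#' required; `index_date` optional on read). JSON-lines: one object per
#' patient with fields `patient_id`, `label`, `index_date` and an `events`
#' array of `{t, token}` records. Round trips are lossless and orderings
#' deterministic.
#'
#' @param cohort an `event_cohort`.
#' @param file path; format chosen by extension (`.csv` vs `.jsonl`/`.json`).
#' @return `write_events` returns `file` invisibly; `read_events` returns an
#'   `event_cohort` (vocabulary rebuilt from the observed tokens).
#' @export
write_events <- function(cohort, file) {
  stopifnot(inherits(cohort, "event_cohort"))
  if (grepl("\\.(jsonl|json)$", file)) {
    lines <- vapply(cohort$sequences, function(s) {
      jsonlite::toJSON(list(patient_id = s$patient_id, label = s$label,
                            index_date = s$index_date,
                            events = data.frame(t = s$times, token = s$tokens)),
                       auto_unbox = TRUE)
    }, "")
    writeLines(lines, file)
  } else {
    df <- as.data.frame(cohort)
    if (is.null(df)) df <- data.frame(patient_id = character(), timestamp_days = integer(),
                                      token = character(), label = integer(),
                                      index_date = integer())
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname write_events
#' @export
read_events <- function(file) {
  if (grepl("\\.(jsonl|json)$", file)) {
    lines <- readLines(file)
    lines <- lines[nzchar(lines)]
    seqs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop(sprintf("parse error at line %d: %s", i, conditionMessage(e))))
      for (f in c("patient_id", "label", "index_date"))
        if (is.null(rec[[f]])) stop(sprintf("parse error at line %d: missing field '%s'", i, f))
      ev <- rec$events
      new_event_sequence(rec$patient_id, if (length(ev)) ev$t else integer(0),
                         if (length(ev)) ev$token else character(0),
                         rec$label, rec$index_date)
    })
  } else {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    required <- c("patient_id", "timestamp_days", "token", "label")
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("event file is missing required column(s): ", paste(missing, collapse = ", "))
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$timestamp_days))))
    if (length(bad))
      stop(sprintf("parse error at line %d: non-numeric timestamp_days", bad[1] + 1L))
    if (is.null(df$index_date)) df$index_date <- NA_integer_
    seqs <- lapply(split(df, factor(df$patient_id, levels = unique(df$patient_id))),
                   function(g) new_event_sequence(g$patient_id[1], g$timestamp_days,
                                                  g$token, g$label[1], g$index_date[1]))
    names(seqs) <- NULL
  }
  vocab <- if (length(seqs)) token_vocabulary(
    unlist(lapply(seqs, function(s) s$tokens), use.names = FALSE)) else NULL
  new_event_cohort(seqs, vocab)
}

#' Write / read a token vocabulary as two-column TSV
#'
#' @param vocab data frame with columns `token`, `index`.
#' @param file path to a TSV file.
#' @return `write_vocab` returns `file` invisibly; `read_vocab` a data frame.
#' @export
write_vocab <- function(vocab, file) {
  utils::write.table(vocab[, c("token", "index")], file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("token", "index") %in% names(df))) stop("vocabulary file needs token and index columns")
  df
}
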