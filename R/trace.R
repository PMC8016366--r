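# Blockade-trace statistics: blocking-ratio conversion, event detection on
# two-state current recordings, dwell-time capture-frequency estimation,
# and a synthetic telegraph-trace generator for closed-loop testing.

#' Synthetic two-state blockade trace
#'
#' Generates an ionic-current recording from a two-state renewal process:
#' exponentially distributed open dwells with mean `1/f_capture`,
#' exponentially distributed blocked dwells with mean
#' `blockade_dwell_mean`, current levels `i0` (open) and `i0 * (1 - depth)`
#' (blocked), plus additive Gaussian noise.  The trace starts in the open
#' state at a renewal.
#'
#' @param f_capture True capture frequency (1/mean open dwell), Hz.
#' @param blockade_dwell_mean Mean blocked dwell, s.
#' @param i0 Open-level current, pA.
#' @param depth Fractional blockade depth b = (I0 - Ib)/I0, in (0, 1].
#' @param noise_sd Gaussian noise standard deviation, pA.
#' @param duration Trace length, s.
#' @param sampling_rate Sampling rate, Hz.  Both mean dwells must span at
#'   least 5 samples.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return A tibble of class `"current_trace"` with columns `time_s`,
#'   `current_pA`; attributes `sampling_rate`, `i0`, `depth`, `events`
#'   (ground-truth blocked intervals) and `params`.
#' @examples
#' tr <- synth_trace(f_capture = 0.2, blockade_dwell_mean = 2,
#'                   duration = 600, sampling_rate = 20, seed = 1)
#' @export
synth_trace <- function(f_capture, blockade_dwell_mean, i0 = 100,
                        depth = 0.7, noise_sd = 2, duration,
                        sampling_rate, seed = NULL) {
  stopifnot_positive(f_capture, "f_capture")
  stopifnot_positive(blockade_dwell_mean, "blockade_dwell_mean")
  stopifnot_positive(duration, "duration")
  stopifnot_positive(sampling_rate, "sampling_rate")
  if (depth <= 0 || depth > 1) stop("'depth' must be in (0, 1]", call. = FALSE)
  if (1 / f_capture * sampling_rate < 5 ||
        blockade_dwell_mean * sampling_rate < 5) {
    stop("sampling rate too low: mean dwell under 5 samples", call. = FALSE)
  }
  gen <- function() {
    # draw alternating dwells until the trace is covered
    t_end <- 0
    starts <- numeric(0)
    stops <- numeric(0)
    state_open <- TRUE
    while (t_end < duration) {
      dwell <- if (state_open) {
        stats::rexp(1, rate = f_capture)
      } else {
        stats::rexp(1, rate = 1 / blockade_dwell_mean)
      }
      if (!state_open) {
        starts <- c(starts, t_end)
        stops <- c(stops, min(t_end + dwell, duration))
      }
      t_end <- t_end + dwell
      state_open <- !state_open
    }
    n <- floor(duration * sampling_rate)
    tt <- (seq_len(n) - 1) / sampling_rate
    blocked <- rep(FALSE, n)
    for (j in seq_along(starts)) {
      blocked[tt >= starts[j] & tt < stops[j]] <- TRUE
    }
    cur <- ifelse(blocked, i0 * (1 - depth), i0) +
      stats::rnorm(n, sd = noise_sd)
    list(time = tt, current = cur,
         events = tibble::tibble(start_s = starts, end_s = stops,
                                 duration_s = stops - starts))
  }
  dat <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- tibble::tibble(time_s = dat$time, current_pA = dat$current)
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "i0") <- i0
  attr(out, "depth") <- depth
  attr(out, "events") <- dat$events
  attr(out, "params") <- list(f_capture = f_capture,
                              blockade_dwell_mean = blockade_dwell_mean,
                              noise_sd = noise_sd, seed = seed)
  class(out) <- c("current_trace", class(out))
  out
}

#' Blocking ratio of a current trace
#'
#' b(t) = (I0 - I(t)) / I0.  `i0` defaults to the trace attribute when
#' present, otherwise to the median current (robust open-level estimate for
#' mostly-open traces).
#'
#' @param trace A `"current_trace"` or any data frame with columns `time_s`
#'   and `current_pA`.
#' @param i0 Open-level current, pA (nonzero).
#' @return The input tibble with an added `blocking_ratio` column.
#' @export
blocking_ratio <- function(trace, i0 = NULL) {
  if (is.null(i0)) i0 <- attr(trace, "i0")
  if (is.null(i0)) i0 <- stats::median(trace$current_pA)
  if (i0 == 0) stop("'i0' must be nonzero", call. = FALSE)
  trace$blocking_ratio <- (i0 - trace$current_pA) / i0
  trace
}

#' Detect blockade events on a trace
#'
#' Maximal runs with blocking ratio above `threshold` lasting at least
#' `min_duration` are blockade events; the complement of the accepted
#' events forms the open intervals, so events and open intervals partition
#' the trace.  Event boundaries sit at the first/last sample exceeding the
#' threshold (no sub-sample interpolation); a run's duration is its sample
#' count over the sampling rate.
#'
#' @param trace A trace tibble; the blocking ratio is computed via
#'   [blocking_ratio()] if the column is absent.
#' @param threshold Blocking-ratio threshold b*, in (0, 1).  Default 0.5.
#' @param min_duration Minimum event duration, s.  The classic rule uses
#'   1 s on slow recordings; pass what matches your acquisition.
#' @param i0 Optional open-level current forwarded to [blocking_ratio()].
#' @return A tibble of class `"blockade_events"` with columns `state`
#'   (`"blocked"`/`"open"`), `start_s`, `end_s`, `duration_s`, `mean_b`.
#' @export
detect_events <- function(trace, threshold = 0.5, min_duration = 1,
                          i0 = NULL) {
  if (threshold <= 0 || threshold >= 1) {
    stop("'threshold' must be in (0, 1)", call. = FALSE)
  }
  if (min_duration < 0) stop("'min_duration' must be >= 0", call. = FALSE)
  rate <- attr(trace, "sampling_rate")
  empty <- tibble::tibble(state = character(), start_s = numeric(),
                          end_s = numeric(), duration_s = numeric(),
                          mean_b = numeric())
  class(empty) <- c("blockade_events", class(empty))
  if (nrow(trace) == 0) return(empty)
  if (is.null(rate)) {
    dt <- diff(trace$time_s)
    if (length(dt) == 0) dt <- 1
    rate <- 1 / stats::median(dt)
  }
  if (!"blocking_ratio" %in% names(trace)) {
    trace <- blocking_ratio(trace, i0 = i0)
  }
  b <- trace$blocking_ratio
  above <- b > threshold
  runs <- rle(above)
  n_run <- length(runs$lengths)
  stop_i <- cumsum(runs$lengths)
  start_i <- stop_i - runs$lengths + 1L
  dur <- runs$lengths / rate
  # blocked runs shorter than min_duration are folded back into open time
  blocked <- runs$values & dur >= min_duration
  # merge consecutive same-state stretches after the filter
  grp <- cumsum(c(TRUE, blocked[-1L] != blocked[-n_run]))
  rows <- lapply(split(seq_len(n_run), grp), function(idx) {
    i0_ <- start_i[idx[1L]]
    i1_ <- stop_i[idx[length(idx)]]
    tibble::tibble(
      state = if (blocked[idx[1L]]) "blocked" else "open",
      start_s = trace$time_s[i0_],
      end_s = trace$time_s[i0_] + (i1_ - i0_ + 1L) / rate,
      duration_s = (i1_ - i0_ + 1L) / rate,
      mean_b = mean(b[i0_:i1_])
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "sampling_rate") <- rate
  attr(out, "trace_duration") <- nrow(trace) / rate
  class(out) <- c("blockade_events", class(out))
  out
}

#' Capture statistics from open-interval durations
#'
#' The mean open-level dwell is the average capture time tau; its
#' statistical error is sigma/sqrt(N) with sigma the dwell standard
#' deviation and N the number of dwells.  The capture frequency is
#' f = 1/tau with err(f) = err(tau)/tau^2 by standard propagation.  An
#' open interval that runs into the end of the recording is censored and
#' excluded.
#'
#' @param x A `"blockade_events"` tibble (its `"open"` rows are used) or a
#'   numeric vector of open dwell durations in seconds.
#' @return A one-row tibble of class `"capture_stats"` with columns
#'   `n_events`, `tau_s`, `tau_sd_s`, `tau_se_s`, `f_hz`, `f_se_hz`.
#' @examples
#' capture_stats(c(1, 2, 3))  # tau = 2 s, se = 1/sqrt(3)
#' @export
capture_stats <- function(x) {
  if (inherits(x, "blockade_events") || is.data.frame(x)) {
    opens <- x[x$state == "open", , drop = FALSE]
    total <- attr(x, "trace_duration")
    if (!is.null(total) && nrow(opens) > 0) {
      censored <- abs(opens$end_s - total) < 1e-9
      opens <- opens[!censored, , drop = FALSE]
    }
    durations <- opens$duration_s
  } else {
    durations <- as.numeric(x)
  }
  n <- length(durations)
  if (n == 0) stop("no open intervals: cannot estimate tau", call. = FALSE)
  tau <- mean(durations)
  if (n == 1) {
    out <- tibble::tibble(n_events = 1L, tau_s = tau, tau_sd_s = NA_real_,
                          tau_se_s = NA_real_, f_hz = 1 / tau,
                          f_se_hz = NA_real_)
  } else {
    sd_ <- stats::sd(durations)
    se <- sd_ / sqrt(n)
    out <- tibble::tibble(n_events = n, tau_s = tau, tau_sd_s = sd_,
                          tau_se_s = se, f_hz = 1 / tau,
                          f_se_hz = se / tau^2)
  }
  class(out) <- c("capture_stats", class(out))
  out
}

#' Read / write traces as delimited text
#'
#' Plain CSV with columns `time_s`, `current_pA`.
#'
#' @param path File path.
#' @return `read_trace()`: a `"current_trace"` tibble.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "current_pA") %in% names(df))) {
    stop("trace file needs columns time_s, current_pA", call. = FALSE)
  }
  out <- tibble::as_tibble(df[c("time_s", "current_pA")])
  dt <- diff(out$time_s)
  if (length(dt)) attr(out, "sampling_rate") <- 1 / stats::median(dt)
  class(out) <- c("current_trace", class(out))
  out
}

#' @rdname read_trace
#' @param trace A trace tibble.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[c("time_s", "current_pA")], path, row.names = FALSE)
  invisible(path)
}
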