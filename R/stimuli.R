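#' Spike train objects
#'
#' A `spike_train` is the common currency between the stimulus generators,
#' the presynaptic vesicle-cycle simulator and the somatic output of the
#' compartmental neuron: an ordered set of event times (seconds) inside a
#' half-open observation window `[0, duration)`.
#'
#' @param times numeric vector of event times in seconds, strictly
#'   increasing, all in `[0, duration)`. May be empty.
#' @param duration total observation window in seconds (> 0).
#' @return An object of class `spike_train` with elements `times` and
#'   `duration`.
#' @examples
#' st <- spike_train(c(0.1, 0.5, 0.9), duration = 1)
#' length(st$times)
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("duration must be a single positive number", call. = FALSE)
  if (length(times)) {
    if (any(!is.finite(times)))
      stop("spike times must be finite", call. = FALSE)
    if (is.unsorted(times, strictly = TRUE))
      stop("spike times must be strictly increasing", call. = FALSE)
    if (times[1] < 0 || times[length(times)] >= duration)
      stop("spike times must lie in [0, duration)", call. = FALSE)
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d events over %.4g s (mean rate %.3g Hz)\n",
              length(x$times), x$duration, length(x$times) / x$duration))
  invisible(x)
}

#' Fixed-frequency (periodic) spike train
#'
#' Events are placed at `phase + k/frequency` for every integer `k >= 0`
#' with the event inside `[0, duration)`. The first spike sits at
#' `t = phase` (default 0).
#'
#' @param frequency firing frequency in Hz (>= 0; 0 gives an empty train).
#' @param duration window length in seconds (> 0).
#' @param phase offset of the first spike in seconds
#'   (`0 <= phase < 1/frequency`; ignored when `frequency = 0`).
#' @return A [spike_train()].
#' @examples
#' periodic_train(4, 10)   # 40 events at 0, 0.25, ..., 9.75 s
#' @export
periodic_train <- function(frequency, duration, phase = 0) {
  if (!is.finite(frequency) || frequency < 0)
    stop("frequency must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (frequency == 0) return(spike_train(numeric(0), duration))
  if (phase < 0 || phase >= 1 / frequency)
    stop("phase must satisfy 0 <= phase < 1/frequency", call. = FALSE)
  n <- floor((duration - phase) * frequency - 1e-12)
  times <- phase + (0:n) / frequency
  spike_train(times[times < duration], duration)
}

#' Homogeneous Poisson spike train
#'
#' Draws a Poisson process realization at the given rate; reproducible for
#' a fixed seed.
#'
#' @param rate mean rate in Hz (>= 0).
#' @param duration window length in seconds (> 0).
#' @param seed integer seed for the draw.
#' @return A [spike_train()].
#' @export
poisson_train <- function(rate, duration, seed) {
  if (!is.finite(rate) || rate < 0)
    stop("rate must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (rate == 0) return(spike_train(numeric(0), duration))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- rpois(1, rate * duration)
  times <- sort(runif(n, 0, duration))
  times <- times[!duplicated(times)]
  spike_train(times, duration)
}

# Save/restore the global RNG state so generators are reproducible without
# clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Gaussian-frequency episode schedule
#'
#' Draws `n_episodes` stimulation episodes, each of fixed duration, whose
#' firing frequencies are independent draws from `N(mean, sd^2)` truncated
#' at zero (negative draws are resampled). Used to emulate repeated
#' stimulation protocols in which each episode is a fixed-frequency train.
#'
#' @param mean mean episode frequency (Hz).
#' @param sd standard deviation of the episode frequency (Hz, >= 0).
#' @param episode_duration duration of one episode (s, > 0).
#' @param n_episodes number of episodes (>= 1).
#' @param seed integer seed.
#' @param gap optional silent gap between episodes (s, default 0).
#' @return An object of class `episode_schedule`: a data frame with columns
#'   `frequency` and `duration`, plus attributes `seed` and `gap`.
#' @export
gaussian_episode_schedule <- function(mean, sd, episode_duration, n_episodes,
                                      seed, gap = 0) {
  if (n_episodes < 1) stop("n_episodes must be >= 1", call. = FALSE)
  if (episode_duration <= 0) stop("episode_duration must be > 0", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  f <- rnorm(n_episodes, mean, sd)
  while (any(f < 0)) f[f < 0] <- rnorm(sum(f < 0), mean, sd)
  out <- data.frame(frequency = f, duration = rep(episode_duration, n_episodes))
  structure(out, class = c("episode_schedule", "data.frame"),
            seed = seed, gap = gap)
}

#' Render an episode schedule as a single spike train
#'
#' Concatenates one periodic train per episode (first spike at each episode
#' onset), separated by the schedule's inter-episode gap.
#'
#' @param schedule an [gaussian_episode_schedule()] result or any data frame
#'   with `frequency` and `duration` columns.
#' @return A [spike_train()] spanning all episodes.
#' @export
episode_train <- function(schedule) {
  gap <- attr(schedule, "gap")
  if (is.null(gap)) gap <- 0
  t0 <- 0
  times <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    f <- schedule$frequency[i]
    d <- schedule$duration[i]
    if (f > 0) {
      k <- floor(d * f - 1e-12)
      ti <- (0:k) / f
      times[[i]] <- t0 + ti[ti < d]
    } else times[[i]] <- numeric(0)
    t0 <- t0 + d + gap
  }
  spike_train(unlist(times), t0)
}

#' Read/write spike trains
#'
#' Plain-text serialization: a two-column whitespace-separated table
#' (event index, time in seconds) with the window duration on a `# duration`
#' header line, or JSON via [jsonlite::write_json()].
#'
#' @param train a [spike_train()].
#' @param path file path.
#' @param format `"table"` or `"json"`.
#' @return `write_spike_train()` returns `path` invisibly;
#'   `read_spike_train()` returns a [spike_train()].
#' @export
write_spike_train <- function(train, path, format = c("table", "json")) {
  format <- match.arg(format)
  if (format == "table") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# duration %.17g", train$duration), con)
    if (length(train$times))
      writeLines(sprintf("%d\t%.17g", seq_along(train$times), train$times), con)
  } else {
    jsonlite::write_json(list(duration = train$duration, times = train$times),
                         path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path, format = c("table", "json")) {
  format <- match.arg(format)
  if (format == "table") {
    lines <- readLines(path)
    dur_line <- grep("^# duration", lines, value = TRUE)
    duration <- as.numeric(sub("^# duration\\s+", "", dur_line[1]))
    body <- lines[!startsWith(lines, "#")]
    body <- body[nzchar(body)]
    times <- if (length(body))
      vapply(strsplit(body, "\t"), function(x) as.numeric(x[2]), 0)
    else numeric(0)
    spike_train(times, duration)
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    spike_train(as.numeric(x$times), x$duration)
  }
}
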