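#' Presynaptic calcium parameters
#'
#' Parameters of the presynaptic Ca2+ model. Each action potential raises
#' the free Ca2+ concentration by `delta_ca_ap` above rest, after which the
#' excess decays exponentially with `tau_ca`; most entering Ca2+ binds to
#' endogenous (`ks`) and exogenous (`kb_prime`) buffers, so the *total*
#' per-spike Ca2+ load is `delta_ca_ap * (1 + ks + kb_prime)`. Exocytosis
#' is permitted while the total transient remains above `threshold`, which
#' it does for `tau_total * log(total/threshold)` seconds after each spike.
#'
#' Defaults are the package's calibrated profile: rest 0.1 umol/L, per-spike
#' free increment 1.675 umol/L with an endogenous binding ratio of 99
#' (total load 167.5 umol/L), threshold at the low end (20 umol/L) of the
#' physiological 20-50 umol/L band, free-transient decay 33.4 ms (95%
#' recovery in ~100 ms) and total-transient decay 100 ms, which keeps the
#' gate open for ~212.5 ms per spike.
#'
#' @param ca_rest resting free Ca2+ concentration (umol/L).
#' @param delta_ca_ap per-spike free Ca2+ increment (umol/L).
#' @param tau_ca decay time constant of the free transient (s).
#' @param ks endogenous Ca2+ binding ratio (dimensionless).
#' @param kb_prime incremental binding ratio of the exogenous buffer.
#' @param threshold total-Ca2+ release threshold (umol/L), in \[20, 50\].
#' @param tau_total decay time constant of the total transient (s).
#' @param latency delay between a spike and gate opening (s).
#' @param accumulate if `TRUE`, spike increments of the free transient add
#'   on top of the residual excess (superposition); the default resets the
#'   excess to `delta_ca_ap` at each spike.
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(ca_rest = 0.1,
                           delta_ca_ap = 1.675,
                           tau_ca = 0.1 / log(20),
                           ks = 99,
                           kb_prime = 0,
                           threshold = 20,
                           tau_total = 0.1,
                           latency = 2e-4,
                           accumulate = FALSE) {
  stopifnot(ca_rest > 0, delta_ca_ap > 0, tau_ca > 0, tau_total > 0,
            ks >= 0, kb_prime >= 0, latency >= 0)
  if (threshold < 20 || threshold > 50)
    stop("threshold must lie in the physiological band [20, 50] umol/L",
         call. = FALSE)
  structure(list(ca_rest = ca_rest, delta_ca_ap = delta_ca_ap,
                 tau_ca = tau_ca, ks = ks, kb_prime = kb_prime,
                 threshold = threshold, tau_total = tau_total,
                 latency = latency, accumulate = isTRUE(accumulate)),
            class = "calcium_params")
}

#' Free presynaptic Ca2+ concentration
#'
#' Evaluates the free Ca2+ concentration on a grid of sample times: equal to
#' the resting level before the first spike; after each spike the excess
#' above rest is reset to `delta_ca_ap` (or added to the residual when
#' `accumulate = TRUE`) and decays exponentially with `tau_ca`.
#'
#' @param train a [spike_train()].
#' @param params a [calcium_params()].
#' @param grid sorted sample times (s) within `[0, train$duration]`.
#' @return Numeric vector of concentrations (umol/L), one per grid point.
#' @export
free_calcium <- function(train, params, grid) {
  if (length(grid) == 0) return(numeric(0))
  grid <- as.numeric(grid)
  if (is.unsorted(grid)) stop("grid must be sorted", call. = FALSE)
  if (grid[1] < 0 || grid[length(grid)] > train$duration)
    stop("grid must lie within [0, duration]", call. = FALSE)
  sp <- train$times
  if (!length(sp)) return(rep(params$ca_rest, length(grid)))
  if (!params$accumulate) {
    # excess resets at each spike: only the most recent spike matters
    idx <- findInterval(grid, sp)
    excess <- ifelse(idx == 0, 0,
                     params$delta_ca_ap *
                       exp(-(grid - sp[pmax(idx, 1)]) / params$tau_ca))
    params$ca_rest + excess
  } else {
    excess <- numeric(length(grid))
    for (s in sp) {
      after <- grid >= s
      excess[after] <- excess[after] +
        params$delta_ca_ap * exp(-(grid[after] - s) / params$tau_ca)
    }
    params$ca_rest + excess
  }
}

#' Total per-spike Ca2+ increment
#'
#' The total (free + buffer-bound) Ca2+ load delivered by one action
#' potential: `delta_ca_ap * (1 + ks + kb_prime)`.
#'
#' @param params a [calcium_params()].
#' @return Concentration in umol/L.
#' @export
total_calcium_increment <- function(params) {
  params$delta_ca_ap * (1 + params$ks + params$kb_prime)
}

#' Release-permission windows
#'
#' Computes the analytic release gate: each spike whose total Ca2+ load
#' exceeds the threshold opens a half-open window of length
#' `tau_total * log(total / threshold)`, delayed by the release latency;
#' overlapping windows are merged. If the load never exceeds the threshold
#' a warning flags the physiologically silent synapse.
#'
#' @param train a [spike_train()].
#' @param params a [calcium_params()].
#' @return An object of class `release_gate`: a two-column matrix
#'   (`start`, `end`) of merged, sorted windows, with attribute
#'   `window_length` (the single-spike window length in seconds).
#' @export
release_windows <- function(train, params) {
  total <- total_calcium_increment(params)
  if (total <= params$threshold) {
    if (length(train$times))
      warning("total Ca2+ increment (", signif(total, 4),
              " umol/L) never exceeds the release threshold (",
              signif(params$threshold, 4),
              " umol/L): synapse is silent", call. = FALSE)
    return(.release_gate(matrix(numeric(0), ncol = 2), 0))
  }
  tw <- params$tau_total * log(total / params$threshold)
  if (!length(train$times)) return(.release_gate(matrix(numeric(0), ncol = 2), tw))
  start <- train$times + params$latency
  end <- start + tw
  .release_gate(merge_intervals(start, end), tw)
}

.release_gate <- function(m, window_length) {
  colnames(m) <- c("start", "end")
  structure(m, class = "release_gate", window_length = window_length)
}

# Merge possibly-overlapping half-open intervals (inputs sorted by start).
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

#' @export
print.release_gate <- function(x, ...) {
  cat(sprintf("<release_gate> %d window(s), total open time %.4g s\n",
              nrow(x), gate_open_time(x)))
  invisible(x)
}

#' Total gate-open time
#'
#' @param gate a [release_windows()] result.
#' @param until optionally clip windows at this time (s).
#' @return Total open time in seconds.
#' @export
gate_open_time <- function(gate, until = Inf) {
  if (!nrow(gate)) return(0)
  s <- pmin(gate[, 1], until); e <- pmin(gate[, 2], until)
  sum(pmax(e - s, 0))
}

#' Export a calcium/gate trace as CSV
#'
#' Writes `time, ca_free, ca_total_excess, gate_open` sampled on a grid.
#' The total-excess column is the decaying total-Ca2+ transient of the most
#' recent spike; the gate flag marks release-permitted samples.
#'
#' @param train a [spike_train()].
#' @param params a [calcium_params()].
#' @param path output CSV path.
#' @param dt sampling interval (s).
#' @return The data frame, invisibly.
#' @export
export_calcium_trace <- function(train, params, path, dt = 1e-3) {
  grid <- seq(0, train$duration, by = dt)
  free <- free_calcium(train, params, grid)
  sp <- train$times
  idx <- findInterval(grid, sp)
  total <- ifelse(idx == 0, 0,
                  total_calcium_increment(params) *
                    exp(-(grid - sp[pmax(idx, 1)]) / params$tau_total))
  gate <- suppressWarnings(release_windows(train, params))
  open <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(gate)))
    open[grid >= gate[i, 1] & grid < gate[i, 2]] <- TRUE
  df <- data.frame(time = grid, ca_free = free, ca_total_excess = total,
                   gate_open = open)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
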