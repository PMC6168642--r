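# Shared fixtures: the calibrated default profile and a lazily built neuron
# (building is cheap; simulating is not, so individual tests keep runs short).

syn0 <- synapse_params()
ca0 <- calcium_params()

.fixtures <- new.env(parent = emptyenv())

test_neuron <- function() {
  if (is.null(.fixtures$neuron))
    .fixtures$neuron <- build_neuron(morphology_spec(), electrical_params())
  .fixtures$neuron
}

# independent interval-merge oracle for gate tests
merge_oracle <- function(start, end, grid_dt = 1e-4, horizon = NULL) {
  if (is.null(horizon)) horizon <- max(end) + grid_dt
  g <- seq(0, horizon, by = grid_dt)
  open <- rep(FALSE, length(g))
  for (i in seq_along(start)) open[g >= start[i] & g < end[i]] <- TRUE
  open
}

gate_open_at <- function(gate, times) {
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(gate)))
    out[times >= gate[i, 1] & times < gate[i, 2]] <- TRUE
  out
}
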