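# Small models and networks used across test files.

# Two-population toy circuit: a relay input layer and one integrating
# population wired by a single excitatory projection.
toy_model <- function(n_in = 20L, n_out = 10L, weight = 9e-3, delay = 4,
                      n_synapses = 80L, out_params = NULL) {
  if (is.null(out_params))
    out_params <- cell_params(0.003, 0, 2, 1.5, 0.5, 10, -84, -74, -42)
  pops <- data.frame(name = c("Glom", "GrC"), size = c(n_in, n_out),
                     stringsAsFactors = FALSE)
  pops$params <- list(NULL, out_params)
  pops$layer_bounds <- list(c(0, 100, 0, 100, 0, 100),
                            c(0, 100, 0, 100, 0, 100))
  prj <- data.frame(name = "Glom-GrC", source = "Glom", target = "GrC",
                    weight = weight, delay = delay,
                    n_synapses = as.integer(n_synapses),
                    stringsAsFactors = FALSE)
  structure(list(populations = pops, projections = prj),
            class = "cereb_model")
}

# Reduced version of the canonical circuit for fast end-to-end runs.
small_canonical <- function(scale = 0.02) {
  scale_network(canonical_model(), scale)
}

canonical_params <- function(name) {
  m <- canonical_model()
  m$populations$params[[match(name, m$populations$name)]]
}

# Continuous-time oracle: adaptive high-accuracy integration of the coupled
# membrane/conductance ODEs, with synaptic impulses applied as jumps in g.
# Returns a function of time for v (mV). Requires deSolve.
ode_oracle <- function(params, spikes_e = numeric(0), spikes_i = numeric(0),
                       w_e = 0, w_i = 0, t_end = 100, dt_out = 0.01) {
  gl <- params$cm / params$tau_m
  deriv <- function(t, y, parms) {
    ge <- y[["ge"]] / gl; gi <- y[["gi"]] / gl
    dv <- ((params$v_rest - y[["v"]]) + ge * (params$e_rev_e - y[["v"]]) +
             gi * (params$e_rev_i - y[["v"]]) +
             params$i_offset / gl) / params$tau_m
    list(c(dv, -y[["ge"]] / params$tau_syn_e, -y[["gi"]] / params$tau_syn_i))
  }
  events <- NULL
  ev <- rbind(
    if (length(spikes_e)) data.frame(var = "ge", time = spikes_e, value = w_e,
                                     method = "add"),
    if (length(spikes_i)) data.frame(var = "gi", time = spikes_i, value = w_i,
                                     method = "add"))
  y0 <- c(v = params$v_rest, ge = 0, gi = 0)
  times <- seq(0, t_end, by = dt_out)
  if (!is.null(ev)) {
    times <- sort(unique(c(times, ev$time)))
    events <- list(data = ev)
  }
  sol <- deSolve::ode(y0, times, deriv, NULL, events = events,
                      rtol = 1e-10, atol = 1e-12)
  list(t = sol[, 1], v = sol[, 2])
}
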