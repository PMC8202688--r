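# Canonical description of the cerebellar microcircuit: population sizes,
# cell/synapse constants and the sixteen projections. Units follow the PyNN
# convention: capacitance nF, current nA, time ms, potential mV, conductance
# uS. The leak conductance of a cell is cm / tau_m (uS).

#' Cell parameter set for a conductance-based LIF neuron
#'
#' @param cm membrane capacitance (nF)
#' @param i_offset constant injected current (nA)
#' @param tau_m membrane time constant (ms)
#' @param tau_refract absolute refractory period (ms)
#' @param tau_syn_e excitatory synaptic conductance decay constant (ms)
#' @param tau_syn_i inhibitory synaptic conductance decay constant (ms)
#' @param v_reset post-spike reset potential (mV)
#' @param v_rest resting potential (mV)
#' @param v_thresh spike threshold (mV)
#' @param e_rev_e excitatory reversal potential (mV)
#' @param e_rev_i inhibitory reversal potential (mV)
#'
#' @return an object of class `cell_params`
#' @export
cell_params <- function(cm, i_offset, tau_m, tau_refract,
                        tau_syn_e, tau_syn_i,
                        v_reset, v_rest, v_thresh,
                        e_rev_e = 0, e_rev_i = -90) {
  stopifnot(cm > 0, tau_m > 0, tau_syn_e > 0, tau_syn_i > 0, tau_refract >= 0)
  if (!(v_reset <= v_rest && v_rest < v_thresh))
    stop("cell_params: require v_reset <= v_rest < v_thresh")
  structure(list(cm = cm, i_offset = i_offset, tau_m = tau_m,
                 tau_refract = tau_refract,
                 tau_syn_e = tau_syn_e, tau_syn_i = tau_syn_i,
                 v_reset = v_reset, v_rest = v_rest, v_thresh = v_thresh,
                 e_rev_e = e_rev_e, e_rev_i = e_rev_i),
            class = "cell_params")
}

# Default stacking of layers along the 900 um axis of the 400 x 400 x 900 um
# volume. Only the relative arrangement matters (stimulus sphere selection and
# spatial partitioning); per-layer thicknesses are a configurable convention,
# not a measured quantity. Purkinje somata sit in a thin planar slab.
default_layer_bounds <- function() {
  list(
    DCNC = c(0, 400, 0, 400, 0, 50),
    Glom = c(0, 400, 0, 400, 50, 500),
    GrC  = c(0, 400, 0, 400, 50, 500),
    GoC  = c(0, 400, 0, 400, 50, 500),
    PC   = c(0, 400, 0, 400, 500, 515),
    SC   = c(0, 400, 0, 400, 515, 710),
    BC   = c(0, 400, 0, 400, 710, 900)
  )
}

#' Canonical cerebellum model: populations and projections
#'
#' Returns the seven populations (glomeruli `Glom`, granule cells `GrC`,
#' Golgi cells `GoC`, stellate cells `SC`, basket cells `BC`, Purkinje cells
#' `PC` and deep-cerebellar-nucleus cells `DCNC`) and the sixteen synaptic
#' projections of the 0.077 mm^3 mouse-cerebellum circuit: 96,737 neurons and
#' 4,214,215 synapses in total. `Glom` is a relay population (it emits
#' prescribed spike trains and has no membrane dynamics). Projection weights
#' are synaptic conductance increments in uS; a negative sign marks an
#' inhibitory synapse (it accumulates on the target's inhibitory conductance).
#'
#' @param layer_bounds named list of axis-aligned boxes
#'   `c(xmin, xmax, ymin, ymax, zmin, zmax)` (um) per population; defaults
#'   stack the granular, Purkinje and molecular layers along the 900 um axis.
#'
#' @return a list of class `cereb_model` with elements `populations`
#'   (data.frame: name, size plus a `params` list column) and `projections`
#'   (data.frame: name, source, target, weight, delay, n_synapses)
#' @export
canonical_model <- function(layer_bounds = default_layer_bounds()) {
  pars <- list(
    GrC  = cell_params(0.003,  0.0,    2.0,  1.5, 0.5,  10.0, -84, -74, -42),
    GoC  = cell_params(0.076,  0.0368, 21.0, 2.0, 0.5,  10.0, -75, -65, -55),
    SC   = cell_params(0.0146, 0.0156, 14.6, 1.6, 0.64, 2.0,  -78, -68, -53),
    BC   = cell_params(0.0146, 0.0156, 14.6, 1.6, 0.64, 2.0,  -78, -68, -53),
    PC   = cell_params(0.62,   0.6,    88.0, 0.8, 0.5,  1.6,  -72, -62, -47),
    DCNC = cell_params(0.089,  0.0558, 57.0, 3.7, 7.1,  13.6, -69, -59, -48)
  )
  populations <- data.frame(
    name = c("Glom", "GrC", "GoC", "SC", "BC", "PC", "DCNC"),
    size = c(7073L, 88158L, 219L, 603L, 603L, 69L, 12L),
    stringsAsFactors = FALSE
  )
  populations$params <- c(list(NULL), pars[populations$name[-1]])
  populations$layer_bounds <- lapply(populations$name, function(nm) {
    b <- layer_bounds[[nm]]
    if (is.null(b)) stop("no layer bounds for population ", nm)
    b
  })

  projections <- data.frame(
    name   = c("Glom-GrC", "Glom-GoC", "Glom-DCNC",
               "aa-GoC", "pf-GoC", "pf-SC", "pf-BC", "aa-PC", "pf-PC",
               "GoC-GrC", "GoC-GoC", "SC-SC", "SC-PC", "BC-BC", "BC-PC",
               "PC-DCNC"),
    source = c("Glom", "Glom", "Glom",
               "GrC", "GrC", "GrC", "GrC", "GrC", "GrC",
               "GoC", "GoC", "SC", "SC", "BC", "BC", "PC"),
    target = c("GrC", "GoC", "DCNC",
               "GoC", "GoC", "SC", "BC", "PC", "PC",
               "GrC", "GoC", "SC", "PC", "BC", "PC", "DCNC"),
    weight = c(9.0e-3, 2.0e-3, 0.006e-3,
               20.0e-3, 0.4e-3, 0.2e-3, 0.2e-3, 75.0e-3, 0.02e-3,
               -5.0e-3, -8.0e-3, -2.0e-3, -8.5e-3, -2.5e-3, -9.0e-3,
               -0.03e-3),
    delay  = c(4, 4, 4, 2, 5, 5, 5, 2, 5, 2, 1, 1, 2, 4, 4, 4),
    n_synapses = c(352474L, 14302L, 1763L,
                   79072L, 350399L, 615177L, 604489L, 17256L, 1957902L,
                   206092L, 7395L, 2411L, 1379L, 2411L, 1379L, 314L),
    stringsAsFactors = FALSE
  )
  model <- structure(list(populations = populations,
                          projections = projections),
                     class = "cereb_model")
  validate_model(model)
  model
}

#' Validate a cerebellum model object
#'
#' Checks structural invariants: positive sizes, projections referencing
#' known populations, delays within the 64-slot/0.1 ms delay buffer
#' (0 < delay <= 6.4 ms), non-negative synapse counts, and well-formed cell
#' parameters for every non-relay population.
#'
#' @param model a `cereb_model`
#' @return the model, invisibly; signals an error on violation
#' @export
validate_model <- function(model) {
  pop <- model$populations
  prj <- model$projections
  stopifnot(all(pop$size >= 1))
  if (anyDuplicated(pop$name)) stop("duplicate population names")
  for (i in seq_len(nrow(pop))) {
    p <- pop$params[[i]]
    if (pop$name[i] == "Glom") {
      if (!is.null(p)) stop("Glom is a relay population and takes no cell_params")
    } else if (!inherits(p, "cell_params")) {
      stop("population ", pop$name[i], " lacks cell_params")
    }
  }
  if (!all(prj$source %in% pop$name) || !all(prj$target %in% pop$name))
    stop("projection references unknown population")
  if (any(prj$delay <= 0 | prj$delay > 6.4))
    stop("projection delays must lie in (0, 6.4] ms (64 slots x 0.1 ms)")
  if (any(prj$n_synapses < 0)) stop("negative synapse count")
  if (any(prj$weight == 0)) stop("zero projection weight")
  invisible(model)
}

#' Mean afferent fan-in of a population
#'
#' Sum of realized synapse counts over all projections targeting the
#' population, divided by the population size.
#'
#' @param pop_name population name (non-relay populations have a defined
#'   fan-in; `Glom` receives no afferents and returns 0)
#' @param model a `cereb_model` (or a data.frame of projections plus a
#'   populations data.frame via `populations=`)
#' @return mean number of afferent synapses per neuron
#' @export
mean_fan_in <- function(pop_name, model) {
  pop <- model$populations
  if (!pop_name %in% pop$name) stop("unknown population: ", pop_name)
  prj <- model$projections
  sum(prj$n_synapses[prj$target == pop_name]) / pop$size[pop$name == pop_name]
}

#' Total neuron and synapse counts of a model
#'
#' @param model a `cereb_model`
#' @return list with `n_neurons` and `n_synapses`
#' @export
model_totals <- function(model) {
  list(n_neurons = sum(model$populations$size),
       n_synapses = sum(model$projections$n_synapses))
}

#' @export
print.cereb_model <- function(x, ...) {
  tot <- model_totals(x)
  cat(sprintf("cerebellum model: %d neurons in %d populations, %d synapses in %d projections\n",
              tot$n_neurons, nrow(x$populations), tot$n_synapses,
              nrow(x$projections)))
  fi <- vapply(x$populations$name, mean_fan_in, numeric(1), model = x)
  df <- data.frame(population = x$populations$name, size = x$populations$size,
                   mean_fan_in = round(fi, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export model constants to a JSON config file
#'
#' Writes populations (sizes, cell parameters, layer bounds) and projections
#' so an experiment can override any parameter and read the result back with
#' [read_model_config()].
#'
#' @param model a `cereb_model`
#' @param path output file path
#' @export
write_model_config <- function(model, path) {
  pops <- lapply(seq_len(nrow(model$populations)), function(i) {
    row <- model$populations[i, ]
    list(name = row$name, size = row$size,
         params = if (is.null(row$params[[1]])) NULL else unclass(row$params[[1]]),
         layer_bounds = row$layer_bounds[[1]])
  })
  prj <- model$projections
  jsonlite::write_json(list(populations = pops, projections = prj),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read model constants from a JSON config file
#'
#' @param path file written by [write_model_config()] (possibly edited)
#' @return a `cereb_model`
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  pops <- cfg$populations
  populations <- data.frame(name = vapply(pops, `[[`, "", "name"),
                            size = vapply(pops, function(p) as.integer(p$size), 0L),
                            stringsAsFactors = FALSE)
  populations$params <- lapply(pops, function(p) {
    if (length(p$params) == 0) NULL
    else do.call(cell_params, as.list(unlist(p$params)))
  })
  populations$layer_bounds <- lapply(pops, function(p) as.numeric(unlist(p$layer_bounds)))
  projections <- do.call(rbind, lapply(cfg$projections, function(p)
    data.frame(name = p$name, source = p$source, target = p$target,
               weight = p$weight, delay = p$delay,
               n_synapses = as.integer(p$n_synapses),
               stringsAsFactors = FALSE)))
  model <- structure(list(populations = populations, projections = projections),
                     class = "cereb_model")
  validate_model(model)
  model
}
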