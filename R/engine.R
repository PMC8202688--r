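# R surface of the network engine: flattening a `cereb_network` into the
# compact arrays the C++ core consumes, spike-raster and run-record
# containers, and the per-projection peak-input measurement used to build
# fixed-point weight codecs.

# Global neuron indexing: populations are laid out in model order; a neuron's
# global 0-based id is offset[population] + (local index - 1).
population_offsets <- function(model) {
  sizes <- model$populations$size
  stats::setNames(c(0L, cumsum(sizes))[seq_along(sizes)],
                  model$populations$name)
}

flatten_network <- function(network, dt, codecs = NULL) {
  model <- network$model
  pop <- model$populations
  off <- population_offsets(model)
  n <- sum(pop$size)
  type_of <- rep.int(seq_len(nrow(pop)) - 1L, pop$size)
  relay_type <- vapply(pop$params, is.null, TRUE)

  par <- matrix(0, nrow = nrow(pop), ncol = 11)
  for (i in seq_len(nrow(pop))) {
    p <- pop$params[[i]]
    if (is.null(p)) next
    par[i, ] <- c(p$cm, p$i_offset, p$tau_m, p$tau_refract,
                  p$tau_syn_e, p$tau_syn_i, p$v_reset, p$v_rest, p$v_thresh,
                  p$e_rev_e, p$e_rev_i)
  }

  prj <- model$projections
  n_edges <- sum(vapply(network$synapses, function(s) length(s$src), 0))
  src <- integer(n_edges); tgt <- integer(n_edges)
  wnorm <- numeric(n_edges); wraw <- numeric(n_edges)
  sign <- integer(n_edges); delay <- integer(n_edges); proj <- integer(n_edges)
  at <- 0L
  for (i in seq_len(nrow(prj))) {
    s <- network$synapses[[prj$name[i]]]
    m <- length(s$src)
    if (m == 0L) next
    idx <- at + seq_len(m)
    src[idx] <- s$src - 1L + off[[prj$source[i]]]
    tgt[idx] <- s$tgt - 1L + off[[prj$target[i]]]
    tp <- pop$params[[match(prj$target[i], pop$name)]]
    if (is.null(tp)) stop("projection ", prj$name[i], " targets a relay population")
    w <- abs(prj$weight[i])
    if (!is.null(codecs)) {
      cd <- codecs[[prj$name[i]]]
      if (is.null(cd)) stop("no weight codec for projection ", prj$name[i])
      w <- cd$encoded
    }
    wraw[idx] <- w
    wnorm[idx] <- w * tp$tau_m / tp$cm
    sign[idx] <- if (prj$weight[i] >= 0) 1L else -1L
    d <- as.integer(round(prj$delay[i] / dt))
    if (d < 1L || d > 64L)
      stop("projection ", prj$name[i], " delay of ", d,
           " timesteps does not fit the 64-slot delay buffer")
    delay[idx] <- d
    proj[idx] <- i - 1L
    at <- at + m
  }
  ord <- order(src, method = "radix")
  src <- src[ord]; tgt <- tgt[ord]; wnorm <- wnorm[ord]; wraw <- wraw[ord]
  sign <- sign[ord]; delay <- delay[ord]; proj <- proj[ord]
  edge_ptr <- c(0L, cumsum(tabulate(src + 1L, nbins = n)))

  list(n = n, type_of = type_of, relay_type = relay_type, par = par,
       edge_ptr = as.integer(edge_ptr), edge_tgt = tgt, edge_wnorm = wnorm,
       edge_wraw = wraw, edge_sign = sign, edge_delay = delay,
       edge_proj = proj, n_proj = nrow(prj), offsets = off)
}

#' Run a network simulation
#'
#' Clock-driven execution: per timestep, (1) matured delay-buffer slots are
#' delivered into each neuron's conductances, (2) every non-relay neuron is
#' advanced by `n_sc` exact-integration sub-cycles with threshold resolved at
#' timestep resolution, (3) spikes emitted this step (including relay input
#' spikes) are pushed into target buffers at `t + delay`. Deterministic given
#' (network, input, config).
#'
#' @param network a `cereb_network` from [build_network()]
#' @param input a `stim_input` from [build_protocol_input()], or a data.frame
#'   with columns `id` (1-based index into the relay population named by
#'   `input_population`) and `step` (0-based), or NULL for no input
#' @param duration run length (ms)
#' @param config a [sim_config()]
#' @param record named list of 1-based local neuron indices per population
#'   whose state traces (v, g_exc, g_inh) should be recorded every timestep;
#'   recording everything is refused for large networks (memory guard)
#' @param codecs named list of [build_codec()] objects per projection,
#'   required semantics for `arithmetic = "fixed"`: weights are delivered at
#'   their 16-bit encoded values. If omitted in fixed mode, each projection's
#'   codec is built with `peak = weight` (pure state-arithmetic emulation).
#' @param input_population name of the relay population the input ids index
#'   (default `"Glom"` when present, else the first relay population)
#' @param mem_limit refuse runs whose state is estimated to exceed this many
#'   bytes
#' @return a `run_record`: `raster` ([spike_raster]), `delivered` (total
#'   conductance injected per channel, uS), `saturations` (fixed mode),
#'   `proj_events` (delivered synaptic events per projection), `traces`,
#'   `config`, `duration`
#' @export
run_network <- function(network, input = NULL, duration, config = sim_config(),
                        record = NULL, codecs = NULL,
                        input_population = NULL, mem_limit = 6e9) {
  stopifnot(inherits(network, "cereb_network"))
  model <- network$model
  dt <- config$dt
  n_steps <- as.integer(round(duration / dt))
  fixed <- config$arithmetic == "fixed"
  if (fixed && is.null(codecs)) {
    prj <- model$projections
    codecs <- lapply(seq_len(nrow(prj)), function(i) {
      w <- abs(prj$weight[i])
      if (w == 0) list(encoded = 0, rel_error = 0) else build_codec(w, w)
    })
    names(codecs) <- prj$name
  }
  fl <- flatten_network(network, dt, codecs = if (fixed) codecs else NULL)

  est <- fl$n * (64 * 2 + 8) * 8 + length(fl$edge_tgt) * 40
  if (est > mem_limit)
    stop(sprintf("estimated engine memory %.1f GB exceeds limit %.1f GB; reduce scale",
                 est / 1e9, mem_limit / 1e9))

  # input spikes -> global 0-based ids, sorted by step
  if (is.null(input_population)) {
    relays <- model$populations$name[vapply(model$populations$params, is.null, TRUE)]
    input_population <- if ("Glom" %in% relays) "Glom" else relays[1]
  }
  if (is.null(input)) {
    in_id <- integer(0); in_step <- integer(0)
  } else {
    spikes <- if (inherits(input, "stim_input")) input$spikes else input
    keep <- spikes$step < n_steps
    spikes <- spikes[keep, , drop = FALSE]
    gid <- spikes$id - 1L + fl$offsets[[input_population]]
    ord <- order(spikes$step, gid, method = "radix")
    in_id <- as.integer(gid[ord]); in_step <- as.integer(spikes$step[ord])
  }

  rec_ids <- integer(0)
  if (!is.null(record)) {
    for (nm in names(record)) {
      o <- fl$offsets[[nm]]
      if (is.null(o)) stop("unknown population in record spec: ", nm)
      rec_ids <- c(rec_ids, as.integer(record[[nm]]) - 1L + o)
    }
    if (length(rec_ids) * n_steps > 5e7)
      stop("trace recording request too large; record a smaller subset")
  }

  res <- cpp_run_network(fl$type_of, fl$relay_type, fl$par,
                         fl$edge_ptr, fl$edge_tgt, fl$edge_wnorm, fl$edge_wraw,
                         fl$edge_sign, fl$edge_delay, fl$edge_proj, fl$n_proj,
                         in_id, in_step, n_steps, dt, config$n_sc, fixed,
                         rec_ids)

  raster <- spike_raster(res$spike_id, res$spike_step, dt, n_steps, model)
  traces <- NULL
  if (length(rec_ids)) {
    traces <- list(ids = rec_ids, v = res$trace_v,
                   g_exc = res$trace_ge, g_inh = res$trace_gi)
  }
  structure(list(raster = raster,
                 delivered = c(exc = res$delivered_exc, inh = res$delivered_inh),
                 saturations = res$saturations,
                 proj_events = stats::setNames(res$proj_events,
                                               model$projections$name),
                 traces = traces, config = config, duration = duration,
                 codecs = if (fixed) codecs else NULL,
                 network_seed = network$seed, mode = network$mode),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("run record: %.1f ms at dt %.2g ms (%s, n_sc %d), %d spikes",
              x$duration, x$config$dt, x$config$arithmetic, x$config$n_sc,
              nrow(x$raster$spikes)))
  if (x$config$arithmetic == "fixed")
    cat(sprintf(", %d saturations", as.integer(x$saturations)))
  cat("\n")
  invisible(x)
}

#' Spike raster container
#'
#' The universal currency between engine, analysis and profiler: global
#' (neuron id, timestep) events plus the timestep and a population index map.
#'
#' @param spike_id global 0-based neuron ids
#' @param spike_step 0-based timesteps
#' @param dt timestep (ms)
#' @param n_steps run length in steps
#' @param model the `cereb_model` defining the population layout
#' @return object of class `spike_raster` with `spikes` (data.frame id,
#'   step), `dt`, `n_steps` and `populations` (name, size, offset)
#' @export
spike_raster <- function(spike_id, spike_step, dt, n_steps, model) {
  if (any(spike_step < 0 | spike_step >= n_steps)) stop("spike step out of bounds")
  structure(list(spikes = data.frame(id = as.integer(spike_id),
                                     step = as.integer(spike_step)),
                 dt = dt, n_steps = as.integer(n_steps),
                 populations = data.frame(
                   name = model$populations$name,
                   size = model$populations$size,
                   offset = as.integer(population_offsets(model)),
                   stringsAsFactors = FALSE)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike raster: %d events over %d steps (dt %.2g ms), %d populations\n",
              nrow(x$spikes), x$n_steps, x$dt, nrow(x$populations)))
  invisible(x)
}

#' Extract one population's spikes with local 1-based ids
#'
#' @param raster a [spike_raster]
#' @param population population name
#' @return data.frame with columns `id` (1-based, local) and `step`
#' @export
population_spikes <- function(raster, population) {
  p <- raster$populations
  i <- match(population, p$name)
  if (is.na(i)) stop("unknown population: ", population)
  lo <- p$offset[i]; hi <- lo + p$size[i]
  s <- raster$spikes[raster$spikes$id >= lo & raster$spikes$id < hi, , drop = FALSE]
  data.frame(id = s$id - lo + 1L, step = s$step)
}

#' Per-neuron spike counts of one population
#'
#' @inheritParams population_spikes
#' @param steps optional 0-based `[from, to)` step window
#' @return integer vector of length `size`
#' @export
population_counts <- function(raster, population, steps = NULL) {
  s <- population_spikes(raster, population)
  if (!is.null(steps)) s <- s[s$step >= steps[1] & s$step < steps[2], , drop = FALSE]
  size <- raster$populations$size[match(population, raster$populations$name)]
  tabulate(s$id, nbins = size)
}

#' Measure per-projection peak per-timestep summed input
#'
#' For every projection, the largest summed synaptic conductance (uS) any
#' single target neuron receives from it within one timestep of the given
#' run. This is the empirical peak the fixed-point weight codec of that
#' projection must represent.
#'
#' @param record a `run_record`
#' @param network the network that produced it
#' @return named numeric vector (uS) per projection
#' @export
peak_projection_input <- function(record, network) {
  fl <- flatten_network(network, record$config$dt)
  sp <- record$raster$spikes
  ord <- order(sp$step, method = "radix")
  res <- cpp_projection_peaks(sp$id[ord], sp$step[ord],
                              fl$edge_ptr, fl$edge_tgt, fl$edge_proj,
                              fl$edge_wraw, fl$edge_sign,
                              fl$n, fl$n_proj)
  stats::setNames(res$peak, network$model$projections$name)
}

#' Write a raster as a two-column text file (global id, time ms)
#'
#' @param raster a [spike_raster]
#' @param path output file
#' @export
write_raster <- function(raster, path) {
  write_spike_trains(raster$spikes, raster$dt, path)
}
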