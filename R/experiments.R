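# Reproducible experiment drivers: single-spike tests, representative-rate
# single-cell tests, the 1 s large-scale protocol run, and helpers to run a
# one-neuron network with Poisson afferent groups.

#' Representative single-cell test configurations
#'
#' Afferent configuration of the low/high representative-rate single-cell
#' experiments: one cell per type, driven through its peak per-projection
#' fan-in by independent Poisson sources at the population rates observed
#' before (low) and during (high) stimulation. Source groups larger than 100
#' are reduced to a tenth with their rate increased tenfold. Weights and
#' delays come from the canonical projection table.
#'
#' @return data.frame: cell_type, projection, n_sources, sign, rate_low,
#'   rate_high (Hz per source)
#' @export
single_cell_conditions <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
cell_type projection n_sources rate_low rate_high
GrC  Glom-GrC    4   0.92   144.38
GrC  GoC-GrC     4  18.63   135.13
GoC  Glom-GoC   11   9.20  1443.80
GoC  aa-GoC     40  20.50   895.90
GoC  pf-GoC    160  20.50   895.90
GoC  GoC-GoC    50  18.63   135.13
SC   pf-SC     137  20.50   895.90
SC   SC-SC      11  31.68   220.75
BC   pf-BC     134  20.50   895.90
BC   BC-BC      12  27.93   193.04
PC   aa-PC      27  20.50   895.90
PC   pf-PC    2919  20.50   895.90
PC   SC-PC      20  31.68   220.75
PC   BC-PC      20  27.93   193.04
DCNC Glom-DCNC  14   0.92   144.38
DCNC PC-DCNC    30  47.68   381.82
")
  df
}

# Build a one-neuron network: one relay source population per afferent
# group, each source wired to the single target cell with one synapse.
single_cell_network <- function(cell_type, afferents, model = canonical_model()) {
  prj_tab <- model$projections
  tgt_params <- model$populations$params[[match(cell_type,
                                                model$populations$name)]]
  if (is.null(tgt_params)) stop("cell type ", cell_type, " is a relay population")
  pops <- data.frame(name = c(paste0("src_", afferents$projection), cell_type),
                     size = c(afferents$n_sources, 1L),
                     stringsAsFactors = FALSE)
  pops$params <- c(rep(list(NULL), nrow(afferents)), list(tgt_params))
  pops$layer_bounds <- rep(list(c(0, 1, 0, 1, 0, 1)), nrow(pops))
  prj <- do.call(rbind, lapply(seq_len(nrow(afferents)), function(i) {
    row <- prj_tab[match(afferents$projection[i], prj_tab$name), ]
    if (is.na(row$name[1])) stop("unknown projection ", afferents$projection[i])
    data.frame(name = row$name, source = paste0("src_", row$name),
               target = cell_type, weight = row$weight, delay = row$delay,
               n_synapses = afferents$n_sources[i], stringsAsFactors = FALSE)
  }))
  mdl <- structure(list(populations = pops, projections = prj),
                   class = "cereb_model")
  syn <- lapply(seq_len(nrow(prj)), function(i) {
    structure(list(projection = prj[i, ],
                   src = seq_len(prj$n_synapses[i]),
                   tgt = rep(1L, prj$n_synapses[i])),
              class = "synapse_list")
  })
  names(syn) <- prj$name
  structure(list(model = mdl, synapses = syn, mode = "uniform", seed = 0L),
            class = "cereb_network")
}

#' Run a single-cell experiment with Poisson afferent groups
#'
#' Wraps [run_network()] around a one-neuron network whose afferent groups
#' are relay populations emitting independent Poisson spike trains at
#' prescribed per-source rates.
#'
#' @param cell_type target cell type name
#' @param afferents data.frame: projection (canonical name, fixing weight
#'   and delay), n_sources, rate (Hz per source)
#' @param duration biological time (ms)
#' @param config a [sim_config()]
#' @param seed integer seed for the input trains
#' @param model model supplying cell/projection parameters
#' @param record record the target cell's state traces?
#' @return list: `record` (run_record), `rate` (output Hz), `n_spikes`
#' @export
run_single_cell <- function(cell_type, afferents, duration = 10000,
                            config = sim_config(), seed = 1L,
                            model = canonical_model(), record = FALSE) {
  net <- single_cell_network(cell_type, afferents, model)
  n_steps <- as.integer(round(duration / config$dt))
  set.seed(seed)
  spikes <- list()
  off <- 0L
  for (i in seq_len(nrow(afferents))) {
    sp <- population_poisson(afferents$n_sources[i], afferents$rate[i],
                             n_steps, config$dt)
    sp$id <- sp$id + off
    spikes[[i]] <- sp
    off <- off + afferents$n_sources[i]
  }
  spikes <- do.call(rbind, spikes)
  # ids above index the concatenated relay populations, which sit first in
  # the flattened network in afferent order
  rec_spec <- if (record) stats::setNames(list(1L), cell_type) else NULL
  rec <- run_network(net, spikes, duration, config, record = rec_spec,
                     input_population = paste0("src_", afferents$projection[1]))
  out_spikes <- population_spikes(rec$raster, cell_type)
  list(record = rec, rate = nrow(out_spikes) / (duration / 1000),
       n_spikes = nrow(out_spikes))
}

#' Representative-rate single-cell experiment
#'
#' Runs the low- or high-activity single-cell test for one cell type over
#' several seeds (10 s of biological time each) in the double-precision
#' reference mode and reports the mean output rate.
#'
#' @param cell_type one of GrC, GoC, SC, BC, PC, DCNC
#' @param condition `"low"` or `"high"`
#' @param seeds integer vector of seeds
#' @param duration biological time per run (ms)
#' @param config a [sim_config()]
#' @return list: `rates` per seed, `mean`, `sd`
#' @export
exp_single_cell <- function(cell_type, condition = c("low", "high"),
                            seeds = 1:5, duration = 10000,
                            config = sim_config()) {
  condition <- match.arg(condition)
  tab <- single_cell_conditions()
  tab <- tab[tab$cell_type == cell_type, ]
  if (!nrow(tab)) stop("no single-cell test for ", cell_type)
  aff <- data.frame(projection = tab$projection, n_sources = tab$n_sources,
                    rate = if (condition == "low") tab$rate_low else tab$rate_high)
  model <- canonical_model()
  rates <- vapply(seeds, function(s) {
    run_single_cell(cell_type, aff, duration, config, seed = s,
                    model = model)$rate
  }, numeric(1))
  list(cell_type = cell_type, condition = condition, rates = rates,
       mean = mean(rates), sd = stats::sd(rates))
}

#' Single-spike experiment for one projection
#'
#' A single source spike, weighted by the projection (connection delay
#' ignored), arrives at an isolated target cell at t = 10 ms; the cell is
#' simulated for `duration` ms in both arithmetic modes. Reports the state
#' traces, the lead/lag of the 100th spike between modes (driven by the
#' offset current for tonically active cells), or marks that fewer than 100
#' spikes occurred.
#'
#' @param projection_name canonical projection name
#' @param duration biological time (ms)
#' @param config base [sim_config()] (its arithmetic field is overridden)
#' @param weight_scale scale factor on the projection weight (use the
#'   empirical per-timestep peak divided by the weight for the
#'   maximum-spiking-input variant)
#' @param model the model
#' @return list: per mode `trace` and spike steps, `lead_lag_ms` of the
#'   100th spike (fixed - float; NA when either mode yields < 100 spikes),
#'   `n_spikes` per mode, `first_spike_step` per mode
#' @export
exp_single_spike <- function(projection_name, duration = 10000,
                             config = sim_config(), weight_scale = 1,
                             model = canonical_model()) {
  prj <- model$projections
  row <- prj[match(projection_name, prj$name), ]
  if (is.na(row$name[1])) stop("unknown projection ", projection_name)
  cell_type <- row$target
  aff <- data.frame(projection = projection_name, n_sources = 1L, rate = 0)
  net <- single_cell_network(cell_type, aff, model)
  net$model$projections$weight <- net$model$projections$weight * weight_scale
  # spike emitted so that it arrives at t = 10 ms (delay compensated)
  d_steps <- as.integer(round(row$delay / config$dt))
  arrive <- as.integer(round(10 / config$dt))
  spikes <- data.frame(id = 1L, step = arrive - d_steps)
  run_mode <- function(mode) {
    cfg <- sim_config(config$dt, config$n_sc, mode)
    rec <- run_network(net, spikes, duration, cfg,
                       record = stats::setNames(list(1L), cell_type),
                       input_population = paste0("src_", projection_name))
    st <- population_spikes(rec$raster, cell_type)$step
    list(record = rec, spikes = st)
  }
  fl <- run_mode("float64"); fx <- run_mode("fixed")
  lead_lag <- if (length(fl$spikes) >= 100 && length(fx$spikes) >= 100)
    (fx$spikes[100] - fl$spikes[100]) * config$dt else NA_real_
  first_fl <- if (length(fl$spikes)) fl$spikes[1] else NA_integer_
  first_fx <- if (length(fx$spikes)) fx$spikes[1] else NA_integer_
  list(projection = projection_name, target = cell_type,
       float64 = fl, fixed = fx,
       n_spikes = c(float64 = length(fl$spikes), fixed = length(fx$spikes)),
       first_spike_step = c(float64 = first_fl, fixed = first_fx),
       lead_lag_ms = lead_lag)
}

#' Large-scale protocol experiment
#'
#' Builds a synthetic network at the requested scale, generates the
#' burst-over-background input and runs the protocol, returning the run
#' record and the validation report (excited/inhibited classification with
#' shifted windows). Optionally runs both arithmetic modes on identical
#' inputs and reports the per-neuron cross-mode spike-train correlations.
#'
#' @param scale population/synapse scale factor in (0, 1]
#' @param duration run length (ms); the canonical protocol spans 1000 ms and
#'   may be truncated (e.g. 450 ms = 300 pre + 50 stim + 100 post)
#' @param protocol a [stimulus_protocol()]
#' @param config a [sim_config()]
#' @param seed integer seed (wiring, placement and input derive sub-seeds)
#' @param cross_mode also run fixed mode on identical input and report
#'   cross-mode correlations for the given populations
#' @param codecs weight codecs for fixed mode (default: built from the peaks
#'   measured on the float run)
#' @param model base model before scaling
#' @return list: `network`, `record`, `report`, and with `cross_mode` also
#'   `record_fixed` and `correlations`
#' @export
exp_large_scale <- function(scale = 1, duration = 450,
                            protocol = stimulus_protocol(),
                            config = sim_config(), seed = 1L,
                            cross_mode = NULL, codecs = NULL,
                            model = canonical_model()) {
  mdl <- scale_network(model, scale)
  if (protocol$selection == "nearest_n" && scale < 1) {
    n_glom <- mdl$populations$size[mdl$populations$name == "Glom"]
    protocol$n_select <- as.integer(round(protocol$n_select * scale))
    protocol$n_select <- min(protocol$n_select, n_glom)
  }
  net <- build_network(mdl, seed = seed)
  n_glom <- mdl$populations$size[mdl$populations$name == "Glom"]
  inp <- build_protocol_input(protocol, n_glom, dt = config$dt,
                              seed = seed + 7777L, duration = duration)
  rec <- run_network(net, inp, duration, config)
  ws <- window_spec(protocol$t_pre, protocol$t_stim,
                    protocol$t_pre + protocol$t_stim + protocol$t_post)
  report <- validation_report(rec$raster, ws)
  out <- list(network = net, input = inp, record = rec, report = report,
              window_spec = ws, seed = seed)
  if (!is.null(cross_mode)) {
    if (is.null(codecs)) {
      peaks <- peak_projection_input(rec, net)
      codecs <- network_codecs(mdl, peaks)
    }
    cfg_fx <- sim_config(config$dt, config$n_sc, "fixed")
    rec_fx <- run_network(net, inp, duration, cfg_fx, codecs = codecs)
    corr <- lapply(cross_mode, function(nm)
      spike_correlation(rec$raster, rec_fx$raster, nm, ws = ws))
    names(corr) <- cross_mode
    out$record_fixed <- rec_fx
    out$correlations <- corr
  }
  out
}

#' Build weight codecs for every projection from measured peaks
#'
#' @param model a `cereb_model`
#' @param peaks named per-projection peak conductances (uS), e.g. from
#'   [peak_projection_input()]; raised to the weight where smaller
#' @return named list of [build_codec()] objects
#' @export
network_codecs <- function(model, peaks) {
  prj <- model$projections
  out <- lapply(seq_len(nrow(prj)), function(i) {
    w <- abs(prj$weight[i])
    build_codec(w, max(w, peaks[[prj$name[i]]]))
  })
  names(out) <- prj$name
  out
}
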