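# Communication-load model: map neurons onto abstract processing cores and
# count multicast packets received per core per timestep. A source spike
# contributes one packet to every distinct core hosting at least one of its
# synaptic targets (source-routed multicast semantics), regardless of how
# many synapses terminate there.

#' Partition neurons onto processing cores
#'
#' Every core hosts at most `neurons_per_core` neurons of a single
#' population (`pc_per_core` for Purkinje cells, default 1 because of their
#' extreme afferent peaks). `"index"` chunks neurons consecutively;
#' `"random"` shuffles each population before chunking (the random-placement
#' baseline); `"spatial"` orders each population by a space-filling (Morton)
#' order of cell positions before chunking, so cores host spatially compact
#' groups.
#'
#' @param model a `cereb_model`
#' @param strategy `"index"`, `"random"` or `"spatial"`
#' @param positions named list of position matrices (required for spatial)
#' @param neurons_per_core neurons per core for non-PC populations
#' @param pc_per_core neurons per core for PC
#' @param seed seed for the random strategy
#' @return list of class `core_map`: `core_of` (0-based core id per global
#'   neuron), `n_cores`, `core_population` (population name per core)
#' @export
partition_cores <- function(model, strategy = c("index", "random", "spatial"),
                            positions = NULL, neurons_per_core = 64L,
                            pc_per_core = 1L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "spatial" && is.null(positions))
    stop("spatial partitioning requires cell positions")
  if (strategy == "random") set.seed(seed)
  pop <- model$populations
  core_of <- integer(sum(pop$size))
  core_pop <- character(0)
  off <- 0L; next_core <- 0L
  for (i in seq_len(nrow(pop))) {
    n <- pop$size[i]
    per <- if (pop$name[i] == "PC") pc_per_core else neurons_per_core
    ord <- switch(strategy,
      index = seq_len(n),
      random = sample.int(n),
      spatial = order(morton_order(positions[[pop$name[i]]])))
    k <- as.integer(ceiling(n / per))
    cores <- next_core + as.integer((seq_len(n) - 1L) %/% per)
    core_of[off + ord] <- cores
    core_pop <- c(core_pop, rep(pop$name[i], k))
    off <- off + n; next_core <- next_core + k
  }
  structure(list(core_of = core_of, n_cores = next_core,
                 core_population = core_pop, strategy = strategy),
            class = "core_map")
}

# Morton (z-order) key from 3D positions quantized to a 1024-cell grid per
# axis: interleaves the bits of the three coordinates.
morton_order <- function(pos) {
  q <- apply(pos, 2, function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0L, length(x))
    else as.integer(pmin(1023, floor((x - r[1]) / diff(r) * 1024)))
  })
  key <- numeric(nrow(pos))
  for (b in 9:0) {
    key <- key * 8 +
      4 * ((q[, 1] %/% 2^b) %% 2) +
      2 * ((q[, 2] %/% 2^b) %% 2) +
      ((q[, 3] %/% 2^b) %% 2)
  }
  key
}

#' @export
print.core_map <- function(x, ...) {
  cat(sprintf("core map (%s): %d cores\n", x$strategy, x$n_cores))
  print(table(x$core_population))
  invisible(x)
}

# distinct destination cores per source neuron, as a CSR list
destination_cores <- function(network, core_map, dt = 0.1) {
  fl <- flatten_network(network, dt)
  src_cores <- unique(data.frame(src = rep.int(seq_len(fl$n) - 1L,
                                               diff(fl$edge_ptr)),
                                 core = core_map$core_of[fl$edge_tgt + 1L]))
  src_cores <- src_cores[order(src_cores$src, src_cores$core), ]
  list(ptr = as.integer(c(0L, cumsum(tabulate(src_cores$src + 1L, nbins = fl$n)))),
       ids = as.integer(src_cores$core), n = fl$n)
}

#' Count multicast packets received per core
#'
#' @param raster a [spike_raster]
#' @param network the `cereb_network` the raster came from
#' @param core_map a [partition_cores()] map
#' @return list of class `packet_stats`: `core_max` (peak packets per
#'   timestep per core), `core_total`, `total` packets, `core_population`,
#'   and `by_population` (per population: max, mean, sd and 95th percentile
#'   of the per-core maxima)
#' @export
count_packets <- function(raster, network, core_map) {
  dc <- destination_cores(network, core_map, raster$dt)
  sp <- raster$spikes
  ord <- order(sp$step, method = "radix")
  res <- cpp_count_packets(sp$id[ord], sp$step[ord], dc$ptr, dc$ids,
                           core_map$n_cores)
  by_pop <- do.call(rbind, lapply(unique(core_map$core_population), function(nm) {
    m <- res$core_max[core_map$core_population == nm]
    data.frame(population = nm, n_cores = length(m), max = max(m),
               mean_peak = mean(m), sd_peak = stats::sd(m),
               q95_peak = unname(stats::quantile(m, 0.95)))
  }))
  structure(list(core_max = res$core_max, core_total = res$core_total,
                 total = res$total, core_population = core_map$core_population,
                 by_population = by_pop),
            class = "packet_stats")
}

#' @export
print.packet_stats <- function(x, ...) {
  cat(sprintf("packet stats: %.0f multicast packets total over %d cores\n",
              x$total, length(x$core_max)))
  print(x$by_population, row.names = FALSE)
  invisible(x)
}

#' Sweep a stimulus parameter and record peak packet load
#'
#' Re-runs the protocol for each value of `f_peak` (Hz) or `radius` /
#' `n_select` (stimulated-set size) and reports, per population, the mean and
#' sd over trials of the per-core peak packet counts.
#'
#' @param network a `cereb_network`
#' @param parameter `"f_peak"` or `"n_select"`
#' @param values sweep values
#' @param encoding `"poisson"` or `"periodic"`
#' @param trials independent trials per value
#' @param duration run length (ms)
#' @param config a [sim_config()]
#' @param core_map a [partition_cores()] map
#' @param protocol base [stimulus_protocol()]
#' @param seed base seed; trial t of value v uses `seed + 131*v + t`
#' @return data.frame: parameter value, population, mean and sd of mean peak
#' @export
sweep_stimulus <- function(network, parameter = c("f_peak", "n_select"),
                           values, encoding = "poisson", trials = 3L,
                           duration = 450, config = sim_config(),
                           core_map, protocol = stimulus_protocol(),
                           seed = 1L) {
  parameter <- match.arg(parameter)
  n_glom <- network$model$populations$size[
    network$model$populations$name == "Glom"]
  rows <- list()
  for (vi in seq_along(values)) {
    v <- values[vi]
    per_trial <- list()
    for (tr in seq_len(trials)) {
      p <- protocol
      p$encoding <- encoding
      if (parameter == "f_peak") p$f_peak <- v else p$n_select <- as.integer(v)
      inp <- build_protocol_input(p, n_glom, dt = config$dt,
                                  seed = seed + 131L * vi + tr,
                                  duration = duration)
      rec <- run_network(network, inp, duration, config)
      ps <- count_packets(rec$raster, network, core_map)
      per_trial[[tr]] <- ps$by_population[, c("population", "mean_peak")]
    }
    all_tr <- do.call(rbind, per_trial)
    agg_m <- stats::aggregate(mean_peak ~ population, all_tr, mean)
    agg_s <- stats::aggregate(mean_peak ~ population, all_tr, stats::sd)
    rows[[vi]] <- data.frame(value = v, population = agg_m$population,
                             mean_peak = agg_m$mean_peak,
                             sd_peak = agg_s$mean_peak)
  }
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "encoding") <- encoding
  out
}

#' Compare neuron-to-core placement strategies
#'
#' Relative reduction in peak packets per core achieved by one placement
#' over another, averaged over populations:
#' `mean((base_peak - alt_peak) / base_peak)`.
#'
#' @param raster a [spike_raster]
#' @param network the network it came from
#' @param positions cell positions (for the spatial strategy)
#' @param base,alt strategy names passed to [partition_cores()]
#' @param seed seed for the random strategy
#' @return list: `reduction` (scalar), `base`, `alt` (their `packet_stats`)
#' @export
compare_placement <- function(raster, network, positions = NULL,
                              base = "random", alt = "spatial", seed = 1L) {
  cm_base <- partition_cores(network$model, base, positions, seed = seed)
  cm_alt <- partition_cores(network$model, alt, positions, seed = seed)
  ps_base <- count_packets(raster, network, cm_base)
  ps_alt <- count_packets(raster, network, cm_alt)
  b <- ps_base$by_population; a <- ps_alt$by_population
  a <- a[match(b$population, a$population), ]
  keep <- b$mean_peak > 0
  reduction <- mean((b$mean_peak[keep] - a$mean_peak[keep]) / b$mean_peak[keep])
  list(reduction = reduction, base = ps_base, alt = ps_alt)
}
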