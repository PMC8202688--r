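# Mossy-fibre stimulation protocol: a burst to a selected set of glomeruli
# over a 1 Hz Poisson background. Timeline (defaults): 300 ms pre-stimulus
# background, 50 ms burst at f_peak to the selected Gloms, 650 ms
# post-stimulus background. Spike trains are resolved at the simulation
# timestep with at most one spike per source per timestep.

#' Stimulation protocol description
#'
#' @param t_pre,t_stim,t_post window durations (ms)
#' @param f_background background rate of every glomerulus (Hz)
#' @param f_peak burst rate of the selected glomeruli (Hz); sweepable
#' @param selection `"nearest_n"` (the `n_select` Gloms closest to the
#'   population centroid; reproduces the published active count exactly) or
#'   `"sphere"` (all Gloms within `radius` um of the centroid)
#' @param n_select number of Gloms for nearest-n selection
#' @param radius sphere radius (um)
#' @param encoding `"poisson"` (independent per-step Bernoulli) or
#'   `"periodic"` (synchronized spikes at a constant period)
#' @return list of class `stim_protocol`
#' @export
stimulus_protocol <- function(t_pre = 300, t_stim = 50, t_post = 650,
                              f_background = 1, f_peak = 150,
                              selection = c("nearest_n", "sphere"),
                              n_select = 2915L, radius = 140,
                              encoding = c("poisson", "periodic")) {
  selection <- match.arg(selection)
  encoding <- match.arg(encoding)
  stopifnot(t_pre >= 0, t_stim >= 0, t_post >= 0,
            f_background >= 0, f_peak >= 0, radius >= 0, n_select >= 0)
  structure(list(t_pre = t_pre, t_stim = t_stim, t_post = t_post,
                 f_background = f_background, f_peak = f_peak,
                 selection = selection, n_select = as.integer(n_select),
                 radius = radius, encoding = encoding),
            class = "stim_protocol")
}

#' Select the stimulated glomeruli
#'
#' Sphere mode returns the Gloms within `radius` of the Glom centroid;
#' nearest-n returns the `n_select` Gloms closest to the centroid (exact
#' count regardless of placement details).
#'
#' @param positions Glom position matrix (columns x, y, z)
#' @param protocol a [stimulus_protocol()]
#' @return integer vector of selected Glom indices
#' @export
select_stimulated <- function(positions, protocol) {
  centre <- colMeans(positions)
  d2 <- (positions[, 1] - centre[1])^2 + (positions[, 2] - centre[2])^2 +
    (positions[, 3] - centre[3])^2
  if (protocol$selection == "sphere") {
    which(d2 <= protocol$radius^2)
  } else {
    n <- protocol$n_select
    if (n > nrow(positions))
      stop("cannot select ", n, " of ", nrow(positions), " glomeruli")
    if (n == 0L) return(integer(0))
    order(d2)[seq_len(n)]
  }
}

#' Poisson spike train at timestep resolution
#'
#' Independent Bernoulli trial per timestep with p = rate * dt / 1000 (at
#' most one spike per step). Requires p < 1.
#'
#' @param rate firing rate (Hz)
#' @param duration train length (ms)
#' @param dt timestep (ms)
#' @param seed optional integer seed
#' @return integer vector of 0-based spike timesteps
#' @export
generate_poisson <- function(rate, duration, dt = 0.1, seed = NULL) {
  p <- rate * dt / 1000
  if (p >= 1) stop("rate * dt too large: need rate*dt/1000 < 1 (smaller dt)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration / dt))
  if (p <= 0 || n == 0L) return(integer(0))
  which(stats::runif(n) < p) - 1L
}

#' Periodic spike train at timestep resolution
#'
#' Spikes at timesteps `floor(k * 1000 / (rate * dt))`, k = 0, 1, ...; all
#' cells given this train are perfectly synchronized.
#'
#' @inheritParams generate_poisson
#' @return integer vector of 0-based spike timesteps
#' @export
generate_periodic <- function(rate, duration, dt = 0.1) {
  if (rate <= 0) stop("periodic train needs rate > 0")
  n <- as.integer(round(duration / dt))
  period <- 1000 / (rate * dt)  # in steps
  k <- 0:ceiling(n / max(period, 1e-12))
  steps <- unique(as.integer(floor(k * period)))
  steps[steps < n]
}

# Population Poisson spikes: independent per-step Bernoulli across n_cells
# cells and n_steps steps, sampled sparsely (total count ~ Binomial, then
# uniform placement over distinct (cell, step) pairs).
population_poisson <- function(n_cells, rate, n_steps, dt, step_offset = 0L,
                               cells = seq_len(n_cells)) {
  p <- rate * dt / 1000
  if (p >= 1) stop("rate * dt too large: need rate*dt/1000 < 1")
  n_pairs <- as.double(length(cells)) * n_steps
  if (p <= 0 || n_pairs == 0) return(data.frame(id = integer(0), step = integer(0)))
  total <- stats::rbinom(1, n_pairs, p)
  if (total == 0) return(data.frame(id = integer(0), step = integer(0)))
  idx <- sample(n_pairs, total)  # distinct pairs
  data.frame(id = cells[as.integer((idx - 1) %% length(cells)) + 1L],
             step = as.integer((idx - 1) %/% length(cells)) + step_offset)
}

#' Build the full protocol input for the glomerulus population
#'
#' Background Poisson spikes at `f_background` for every Glom over the whole
#' run; during the stimulation window the selected Gloms' background is
#' replaced by the `f_peak` process in the configured encoding. Deterministic
#' per seed.
#'
#' @param protocol a [stimulus_protocol()]
#' @param n_glom glomerulus population size
#' @param positions optional Glom position matrix (needed for sphere
#'   selection; nearest-n also uses it when given, otherwise the first
#'   `n_select` indices are used)
#' @param dt timestep (ms)
#' @param seed integer seed
#' @param duration optional total duration (ms); defaults to
#'   `t_pre + t_stim + t_post`, and may be shorter to truncate the run
#' @return list of class `stim_input`: `spikes` (data.frame id, step with
#'   0-based steps), `selected` (Glom indices), `duration`, `dt`, `protocol`
#' @export
build_protocol_input <- function(protocol, n_glom, positions = NULL,
                                 dt = 0.1, seed = 1L, duration = NULL) {
  set.seed(seed)
  total_ms <- protocol$t_pre + protocol$t_stim + protocol$t_post
  if (!is.null(duration)) total_ms <- min(duration, total_ms)
  n_steps <- as.integer(round(total_ms / dt))
  s0 <- as.integer(round(protocol$t_pre / dt))
  s1 <- min(as.integer(round((protocol$t_pre + protocol$t_stim) / dt)), n_steps)

  if (is.null(positions)) {
    if (protocol$selection == "sphere")
      stop("sphere selection requires Glom positions")
    selected <- seq_len(min(protocol$n_select, n_glom))
  } else {
    selected <- select_stimulated(positions, protocol)
  }
  unselected <- setdiff(seq_len(n_glom), selected)

  parts <- list(
    # background for unselected cells over the whole run
    population_poisson(n_glom, protocol$f_background, n_steps, dt,
                       cells = unselected),
    # background for selected cells outside the stimulation window
    population_poisson(n_glom, protocol$f_background, s0, dt,
                       cells = selected),
    population_poisson(n_glom, protocol$f_background, n_steps - s1, dt,
                       step_offset = s1, cells = selected)
  )
  if (s1 > s0 && length(selected)) {
    if (protocol$encoding == "poisson") {
      parts <- c(parts, list(
        population_poisson(n_glom, protocol$f_peak, s1 - s0, dt,
                           step_offset = s0, cells = selected)))
    } else {
      steps <- generate_periodic(protocol$f_peak, (s1 - s0) * dt, dt) + s0
      parts <- c(parts, list(
        data.frame(id = rep(selected, each = length(steps)),
                   step = rep(steps, times = length(selected)))))
    }
  }
  spikes <- do.call(rbind, parts)
  spikes <- spikes[order(spikes$step, spikes$id), , drop = FALSE]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, selected = selected,
                 duration = total_ms, dt = dt, protocol = protocol,
                 seed = seed),
            class = "stim_input")
}

#' Write spike trains as a two-column text file (neuron id, time ms)
#'
#' @param spikes data.frame with columns `id` and `step` (0-based)
#' @param dt timestep (ms)
#' @param path output file
#' @export
write_spike_trains <- function(spikes, dt, path) {
  utils::write.table(data.frame(id = spikes$id, time_ms = spikes$step * dt),
                     path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#'
#' @param path input file
#' @param dt timestep (ms)
#' @return data.frame with columns `id`, `step`
#' @export
read_spike_trains <- function(path, dt) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  data.frame(id = as.integer(df$id),
             step = as.integer(round(df$time_ms / dt)))
}
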