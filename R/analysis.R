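# Validation statistics: windowed firing rates with per-population latency
# shifts, excited/inhibited classification, ISI/CV, binned cross-run
# correlation and PSTH.

#' Analysis window specification
#'
#' Pre-stimulus, stimulus and post-stimulus windows, each shifted per
#' population by the spike-propagation latency from the input: every window
#' boundary moves by the population's shift (and is clipped to the run end).
#'
#' @param t_pre,t_stim end of the pre window and stimulation duration (ms)
#' @param t_total nominal run end (ms)
#' @param shifts named per-population latency shifts (ms)
#' @return list of class `window_spec`
#' @export
window_spec <- function(t_pre = 300, t_stim = 50, t_total = 1000,
                        shifts = c(Glom = 0, GrC = 4, GoC = 4, SC = 9,
                                   BC = 9, PC = 6, DCNC = 10)) {
  structure(list(t_pre = t_pre, t_stim = t_stim, t_total = t_total,
                 shifts = shifts),
            class = "window_spec")
}

# shifted [start, end) windows in ms for one population, clipped to run end
shifted_windows <- function(ws, population, run_end_ms) {
  s <- ws$shifts[[population]]
  if (is.null(s) || is.na(s)) s <- 0
  b <- s + c(0, ws$t_pre, ws$t_pre + ws$t_stim, ws$t_total)
  b <- pmin(b, run_end_ms)
  list(pre = c(b[1], b[2]), stim = c(b[2], b[3]), post = c(b[3], b[4]))
}

#' Per-neuron firing rates in the shifted analysis windows
#'
#' @param raster a [spike_raster]
#' @param population population name
#' @param ws a [window_spec()]
#' @return data.frame with one row per neuron: `pre`, `stim`, `post` rates
#'   (Hz)
#' @export
window_rates <- function(raster, population, ws = window_spec()) {
  run_end <- raster$n_steps * raster$dt
  w <- shifted_windows(ws, population, run_end)
  out <- lapply(w, function(b) {
    len_ms <- b[2] - b[1]
    if (len_ms <= 0) stop("empty analysis window for ", population)
    steps <- as.integer(round(b / raster$dt))
    population_counts(raster, population, steps) / (len_ms / 1000)
  })
  data.frame(pre = out$pre, stim = out$stim, post = out$post)
}

#' Classify neurons as excited, inhibited or neither
#'
#' Excited: stimulation-window rate at least double the pre-stimulation rate
#' (and non-zero). Inhibited: stimulation-window rate below half the
#' pre-stimulation rate. The partition is exhaustive and exclusive; a silent
#' neuron (pre = stim = 0) is neither.
#'
#' @param rates data.frame from [window_rates()] (columns `pre`, `stim`)
#' @return factor with levels excited, inhibited, neither
#' @export
classify_response <- function(rates) {
  excited <- rates$stim >= 2 * rates$pre & rates$stim > 0
  inhibited <- !excited & rates$stim < rates$pre / 2
  factor(ifelse(excited, "excited", ifelse(inhibited, "inhibited", "neither")),
         levels = c("excited", "inhibited", "neither"))
}

#' Inter-spike intervals and coefficient of variation per neuron
#'
#' ISIs are computed over the full run; CV = population-sd(ISI)/mean(ISI).
#' Neurons with fewer than 2 spikes contribute no ISIs; CV requires at least
#' 3 spikes (2 intervals). Insufficient neurons are omitted, not zero-filled.
#'
#' @param raster a [spike_raster]
#' @param population population name
#' @return list with `isi` (named list of ms vectors per neuron id) and `cv`
#'   (named numeric vector)
#' @export
isi_cv <- function(raster, population) {
  s <- population_spikes(raster, population)
  s <- s[order(s$id, s$step), , drop = FALSE]
  by_id <- split(s$step, s$id)
  isi <- lapply(by_id, function(st) diff(st) * raster$dt)
  isi <- isi[lengths(isi) >= 1]
  cv <- vapply(isi[lengths(isi) >= 2], function(x) {
    sqrt(mean((x - mean(x))^2)) / mean(x)
  }, numeric(1))
  list(isi = isi, cv = cv)
}

#' Per-neuron spike-train correlation between two runs
#'
#' Spike counts of matched neurons are binned over the (shifted) stimulation
#' window and the Pearson correlation is computed per neuron pair. Neurons
#' with zero count variance in either run are omitted (undefined
#' coefficient).
#'
#' @param raster_a,raster_b two [spike_raster]s over the same network
#' @param population population name
#' @param bin bin width (ms)
#' @param ws a [window_spec()] giving the stimulation window
#' @return named numeric vector of correlation coefficients
#' @export
spike_correlation <- function(raster_a, raster_b, population, bin = 5,
                              ws = window_spec()) {
  pa <- raster_a$populations; pb <- raster_b$populations
  if (pa$size[match(population, pa$name)] != pb$size[match(population, pb$name)])
    stop("population sizes differ between rasters")
  run_end <- min(raster_a$n_steps * raster_a$dt, raster_b$n_steps * raster_b$dt)
  w <- shifted_windows(ws, population, run_end)$stim
  if (diff(w) <= 0) stop("stimulation window empty")
  breaks <- seq(w[1], w[2], by = bin)
  if (breaks[length(breaks)] < w[2]) breaks <- c(breaks, w[2])
  bin_counts <- function(raster) {
    s <- population_spikes(raster, population)
    t_ms <- s$step * raster$dt
    keep <- t_ms >= w[1] & t_ms < w[2]
    s <- s[keep, , drop = FALSE]; t_ms <- t_ms[keep]
    b <- findInterval(t_ms, breaks, rightmost.closed = FALSE)
    size <- raster$populations$size[match(population, raster$populations$name)]
    m <- matrix(0L, nrow = size, ncol = length(breaks) - 1L)
    if (nrow(s)) for (k in seq_len(nrow(s))) m[s$id[k], b[k]] <- m[s$id[k], b[k]] + 1L
    m
  }
  ma <- bin_counts(raster_a); mb <- bin_counts(raster_b)
  keep <- apply(ma, 1, stats::sd) > 0 & apply(mb, 1, stats::sd) > 0
  out <- vapply(which(keep), function(i) stats::cor(ma[i, ], mb[i, ]), numeric(1))
  stats::setNames(out, which(keep))
}

#' Peristimulus time histogram
#'
#' Population spike counts per time bin.
#'
#' @param raster a [spike_raster]
#' @param population population name (NULL: all neurons)
#' @param bin bin width (ms); the default equals one timestep
#' @return data.frame with `time` (bin start, ms) and `count`
#' @export
psth <- function(raster, population = NULL, bin = 0.1) {
  steps <- if (is.null(population)) raster$spikes$step
           else population_spikes(raster, population)$step
  t_ms <- steps * raster$dt
  run_end <- raster$n_steps * raster$dt
  edges <- seq(0, run_end + bin, by = bin)
  idx <- findInterval(t_ms, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(time = edges[-length(edges)], count = counts)
}

#' Validation report: windowed rates of excited/inhibited subsets
#'
#' For every population: the number and fraction of excited and inhibited
#' cells, and mean +/- sd of the pre/stim/post rates over the excited subset
#' (over the inhibited subset where inhibition dominates, as for the
#' deep-nucleus cells). sd is the population standard deviation across the
#' classified subset.
#'
#' @param raster a [spike_raster]
#' @param ws a [window_spec()]
#' @return data.frame of class `validation_report`
#' @export
validation_report <- function(raster, ws = window_spec()) {
  pops <- raster$populations$name
  rows <- lapply(pops, function(nm) {
    r <- window_rates(raster, nm, ws)
    cls <- classify_response(r)
    n <- nrow(r)
    ne <- sum(cls == "excited"); ni <- sum(cls == "inhibited")
    subset <- if (ni > ne) "inhibited" else "excited"
    sel <- cls == subset
    psd <- function(x) if (length(x)) sqrt(mean((x - mean(x))^2)) else NA_real_
    mn <- function(x) if (length(x)) mean(x) else NA_real_
    data.frame(population = nm, n_cells = n,
               n_excited = ne, frac_excited = ne / n,
               n_inhibited = ni, frac_inhibited = ni / n,
               subset = subset,
               pre_mean = mn(r$pre[sel]), pre_sd = psd(r$pre[sel]),
               stim_mean = mn(r$stim[sel]), stim_sd = psd(r$stim[sel]),
               post_mean = mn(r$post[sel]), post_sd = psd(r$post[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  df <- as.data.frame(x)
  fmt <- function(m, s) ifelse(is.na(m), "-", sprintf("%.2f +/- %.1f", m, s))
  show <- data.frame(population = df$population, n = df$n_cells,
                     classified = sprintf("%d %s (%.2f%%)",
                                          ifelse(df$subset == "excited",
                                                 df$n_excited, df$n_inhibited),
                                          df$subset,
                                          100 * ifelse(df$subset == "excited",
                                                       df$frac_excited,
                                                       df$frac_inhibited)),
                     pre = fmt(df$pre_mean, df$pre_sd),
                     stim = fmt(df$stim_mean, df$stim_sd),
                     post = fmt(df$post_mean, df$post_sd))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write a validation report as text plus a machine-readable JSON twin
#'
#' @param report a [validation_report()]
#' @param path output path; the JSON twin gets extension `.json`
#' @export
write_validation_report <- function(report, path) {
  utils::write.table(format(as.data.frame(report), digits = 4), path,
                     quote = FALSE, sep = "\t", row.names = FALSE)
  jsonlite::write_json(as.data.frame(report),
                       paste0(sub("\\.[^.]*$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
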