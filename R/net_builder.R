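# Synthetic realization of the circuit: cell placement in the 400x400x900 um
# volume and edge-list generation matching the exact per-projection synapse
# counts (hence the published mean fan-ins). The original scaffold's
# anisotropic wiring rules are approximated statistically: "uniform" draws
# sources and targets uniformly (near-binomial in-degrees), "spatial" biases
# source choice toward laterally nearby cells with a Gaussian kernel while
# preserving the exact counts.

#' Place cells uniformly within their layer slabs
#'
#' Each population's cells are placed uniformly at random inside its
#' axis-aligned layer box; Purkinje cells end up in a thin planar slab by
#' construction of the default bounds. Deterministic per seed.
#'
#' @param model a `cereb_model`
#' @param seed integer seed
#' @return named list of `size x 3` matrices (columns x, y, z in um)
#' @export
place_cells <- function(model, seed = 1L) {
  set.seed(seed)
  pop <- model$populations
  out <- lapply(seq_len(nrow(pop)), function(i) {
    n <- pop$size[i]
    b <- pop$layer_bounds[[i]]
    cbind(x = stats::runif(n, b[1], b[2]),
          y = stats::runif(n, b[3], b[4]),
          z = stats::runif(n, b[5], b[6]))
  })
  names(out) <- pop$name
  out
}

#' Realize one projection as an explicit edge list
#'
#' Draws exactly `n_synapses` (source, target) pairs. In `"uniform"` mode
#' both ends are drawn uniformly, giving in-degrees that fluctuate around
#' the mean by O(sqrt(mean)). In `"spatial"` mode targets are drawn
#' uniformly but each target's sources are drawn with probability decaying
#' with lateral (x, y) distance as a Gaussian kernel of width `kernel_sd`;
#' as `kernel_sd -> Inf` this reduces to the uniform mode. Multiple edges
#' between the same pair are permitted (required to honour exact counts on
#' dense projections); `unique_pairs = TRUE` forbids them and errors if the
#' count cannot be realized.
#'
#' @param projection one row of a projections data.frame (list or data.frame
#'   with name, source, target, weight, delay, n_synapses)
#' @param sizes named integer vector of population sizes
#' @param mode `"uniform"` or `"spatial"`
#' @param seed integer seed
#' @param positions named list of position matrices (required for spatial
#'   mode; see [place_cells()])
#' @param kernel_sd Gaussian kernel width (um) for spatial mode
#' @param unique_pairs forbid multi-edges
#' @return list of class `synapse_list`: `projection` (the spec row) and
#'   integer vectors `src`, `tgt` (1-based indices into the populations)
#' @export
build_synapses <- function(projection, sizes, mode = c("uniform", "spatial"),
                           seed = 1L, positions = NULL, kernel_sd = 100,
                           unique_pairs = FALSE) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- as.integer(projection$n_synapses)
  ns <- sizes[[projection$source]]
  nt <- sizes[[projection$target]]
  if (is.null(ns) || is.null(nt)) stop("unknown source/target population")
  if (unique_pairs && n > as.double(ns) * nt)
    stop("cannot draw ", n, " unique pairs from ", ns, " x ", nt)
  if (n == 0L) {
    return(structure(list(projection = projection,
                          src = integer(0), tgt = integer(0)),
                     class = "synapse_list"))
  }
  if (mode == "uniform") {
    if (unique_pairs) {
      idx <- sample.int(as.double(ns) * nt, n)  # pair index, no replacement
      src <- as.integer((idx - 1) %% ns) + 1L
      tgt <- as.integer((idx - 1) %/% ns) + 1L
    } else {
      src <- sample.int(ns, n, replace = TRUE)
      tgt <- sample.int(nt, n, replace = TRUE)
    }
  } else {
    if (is.null(positions)) stop("spatial mode requires positions")
    ps <- positions[[projection$source]]
    pt <- positions[[projection$target]]
    tgt_counts <- stats::rmultinom(1, n, rep(1, nt))[, 1]
    src <- integer(n); tgt <- integer(n)
    at <- 1L
    for (j in which(tgt_counts > 0)) {
      k <- tgt_counts[j]
      d2 <- (ps[, 1] - pt[j, 1])^2 + (ps[, 2] - pt[j, 2])^2
      w <- exp(-d2 / (2 * kernel_sd^2))
      if (!any(w > 0)) w <- rep(1, ns)
      s <- sample.int(ns, k, replace = !unique_pairs, prob = w)
      src[at:(at + k - 1L)] <- s
      tgt[at:(at + k - 1L)] <- j
      at <- at + k
    }
  }
  structure(list(projection = projection, src = src, tgt = tgt),
            class = "synapse_list")
}

#' Build the full synthetic network
#'
#' Realizes every projection of the model (each with its own sub-seed derived
#' from `seed`) and bundles the result with the model for the engine.
#'
#' @param model a `cereb_model`
#' @param mode wiring mode, see [build_synapses()]
#' @param seed integer seed
#' @param positions cell positions (required for spatial mode)
#' @param kernel_sd Gaussian kernel width (um) for spatial mode
#' @return list of class `cereb_network`: `model`, `synapses` (named list of
#'   `synapse_list`), `mode`, `seed`
#' @export
build_network <- function(model, mode = c("uniform", "spatial"), seed = 1L,
                          positions = NULL, kernel_sd = 100) {
  mode <- match.arg(mode)
  sizes <- stats::setNames(model$populations$size, model$populations$name)
  prj <- model$projections
  syn <- lapply(seq_len(nrow(prj)), function(i) {
    build_synapses(prj[i, ], sizes, mode = mode, seed = seed + 1000L * i,
                   positions = positions, kernel_sd = kernel_sd)
  })
  names(syn) <- prj$name
  structure(list(model = model, synapses = syn, mode = mode, seed = seed),
            class = "cereb_network")
}

#' @export
print.cereb_network <- function(x, ...) {
  tot <- sum(vapply(x$synapses, function(s) length(s$src), 0))
  cat(sprintf("cerebellum network (%s wiring, seed %d): %d realized synapses in %d projections\n",
              x$mode, x$seed, tot, length(x$synapses)))
  invisible(x)
}

#' Scale a model down for desk-scale runs
#'
#' Population sizes and per-projection synapse counts are both scaled by
#' `factor` (rounded, minimum 1), which preserves mean fan-ins for
#' populations that scale and divides fan-ins proportionally for populations
#' held at full size. The small output-side populations (`PC`, `DCNC`) are
#' kept at their full printed sizes unless `scale_all = TRUE`; weights,
#' delays and cell parameters are never scaled.
#'
#' @param model a `cereb_model`
#' @param factor scale in (0, 1]
#' @param scale_all also scale PC and DCNC
#' @return scaled `cereb_model`
#' @export
scale_network <- function(model, factor, scale_all = FALSE) {
  if (factor <= 0) stop("scale factor must be positive")
  if (factor > 1) stop("scale factor must be <= 1")
  if (factor == 1) return(model)
  keep <- if (scale_all) character(0) else c("PC", "DCNC")
  pop <- model$populations
  scaled <- !(pop$name %in% keep)
  pop$size[scaled] <- pmax(1L, as.integer(round(pop$size[scaled] * factor)))
  prj <- model$projections
  prj$n_synapses <- pmax(1L, as.integer(round(prj$n_synapses * factor)))
  out <- structure(list(populations = pop, projections = prj),
                   class = "cereb_model")
  validate_model(out)
  out
}

#' Export a realized projection as a columnar edge-list file
#'
#' Four tab-separated columns: source index, target index, weight (uS,
#' signed) and delay (ms).
#'
#' @param synapses a `synapse_list`
#' @param path output file
#' @export
write_edge_list <- function(synapses, path) {
  df <- data.frame(source = synapses$src, target = synapses$tgt,
                   weight = synapses$projection$weight,
                   delay = synapses$projection$delay)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' In-degree distribution of a realized projection
#'
#' @param synapses a `synapse_list`
#' @param n_targets target population size
#' @return integer vector of per-target afferent counts
#' @export
in_degrees <- function(synapses, n_targets) {
  tabulate(synapses$tgt, nbins = n_targets)
}
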