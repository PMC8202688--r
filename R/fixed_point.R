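# Emulation of the neuromorphic target's fixed-point arithmetic: the s16.15
# "accum" state format and the 16-bit power-of-two-scaled representation of
# synaptic weights, plus the representability analysis (bits required,
# quantization error per projection).

#' Describe a fixed-point number format
#'
#' @param total_bits total width in bits (32 for the s16.15 state format,
#'   16 for weights)
#' @param frac_bits number of fractional bits; the quantum is `2^-frac_bits`
#' @param signed does the format carry a sign bit?
#' @return an object of class `fixed_format` with fields `total_bits`,
#'   `frac_bits`, `signed`, `quantum` and `max` (largest representable
#'   magnitude)
#' @export
fixed_format <- function(total_bits = 32L, frac_bits = 15L, signed = TRUE) {
  stopifnot(total_bits >= 1, frac_bits >= 0, frac_bits < total_bits + !signed)
  quantum <- 2^(-frac_bits)
  max_mag <- (2^(total_bits - as.integer(signed)) - 1) * quantum
  structure(list(total_bits = as.integer(total_bits),
                 frac_bits = as.integer(frac_bits),
                 signed = isTRUE(signed),
                 quantum = quantum, max = max_mag),
            class = "fixed_format")
}

#' @export
print.fixed_format <- function(x, ...) {
  cat(sprintf("%s%d.%d fixed point: quantum %g, max %g\n",
              if (x$signed) "s" else "u",
              x$total_bits - x$frac_bits - as.integer(x$signed),
              x$frac_bits, x$quantum, x$max))
  invisible(x)
}

#' Quantize values to a fixed-point grid
#'
#' Rounds to the nearest representable multiple of the format's quantum,
#' ties to even. Values beyond the representable range saturate to the
#' closest bound; saturation is never silent -- the count of saturated
#' elements is attached as attribute `"saturations"`.
#'
#' @param x numeric vector
#' @param format a [fixed_format()]
#' @return quantized vector with a `"saturations"` attribute
#' @export
quantize <- function(x, format = fixed_format()) {
  q <- format$quantum
  y <- round(x / q) * q  # round() ties to even per IEC 60559
  hi <- format$max
  lo <- if (format$signed) -hi else 0
  sat <- sum(y > hi | y < lo)
  y[y > hi] <- hi
  y[y < lo] <- lo
  attr(y, "saturations") <- sat
  y
}

#' Bits of precision needed to span a conductance range
#'
#' Number of bits separating the largest per-timestep summed synaptic input a
#' neuron must integrate from the smallest single-synapse conductance
#' increment it receives: `log2(peak / smallest_weight)`.
#'
#' @param peak largest per-timestep summed conductance (uS)
#' @param smallest_weight smallest single synaptic weight (uS)
#' @return bits (real-valued)
#' @export
bits_required <- function(peak, smallest_weight) {
  if (any(peak <= 0) || any(smallest_weight <= 0))
    stop("bits_required: inputs must be positive")
  if (any(peak < smallest_weight))
    stop("bits_required: peak must be >= smallest_weight")
  log2(peak / smallest_weight)
}

#' Build the 16-bit weight codec for one synapse type
#'
#' Weights are stored as non-negative 16-bit integers on a power-of-two grid.
#' The quantum `q = 2^k` is the smallest power of two such that the largest
#' code (2^16 - 1) still covers the peak per-timestep summed conductance the
#' accumulator must represent. The prescribed weight is then rounded to the
#' nearest multiple of `q`, with a floor of one quantum (a weight can never
#' round to silence).
#'
#' @param weight prescribed synaptic weight magnitude (uS)
#' @param peak largest per-timestep summed conductance to cover (uS)
#' @return list of class `weight_codec`: `quantum`, `scale_exponent` (k),
#'   `code` (integer), `encoded` (uS), `rel_error`
#'   ((encoded - prescribed)/prescribed), `bits` occupied by the code, and
#'   `peak`
#' @export
build_codec <- function(weight, peak) {
  stopifnot(length(weight) == 1, length(peak) == 1)
  if (weight <= 0) stop("build_codec: weight must be positive")
  if (peak < weight) stop("build_codec: peak must be >= weight")
  max_code <- 2^16 - 1
  k <- ceiling(log2(peak / max_code))
  q <- 2^k
  code <- max(1, round(weight / q))
  encoded <- code * q
  structure(list(quantum = q, scale_exponent = as.integer(k),
                 code = as.integer(code), encoded = encoded,
                 rel_error = (encoded - weight) / weight,
                 bits = as.integer(ceiling(log2(code + 1))),
                 peak = peak),
            class = "weight_codec")
}

#' @export
print.weight_codec <- function(x, ...) {
  cat(sprintf("16-bit weight codec: quantum 2^%d, code %d (%d bits), encoded %.6g uS (%+.2f%%), peak %.4g uS\n",
              x$scale_exponent, x$code, x$bits, x$encoded, 100 * x$rel_error,
              x$peak))
  invisible(x)
}

#' Normalize a synaptic weight by the target's leak conductance
#'
#' Synaptic conductances are scaled by `cm / tau_m` (the leak conductance, in
#' uS) before entering the neuron state update: the normalized weight
#' `weight * tau_m / cm` is dimensionless, which keeps the small raw weights
#' away from the fixed-point quantum and removes a multiplication from the
#' membrane update.
#'
#' @param weight synaptic weight (uS, sign preserved)
#' @param params target cell's [cell_params()]
#' @return dimensionless normalized weight
#' @export
normalize_weight <- function(weight, params) {
  weight * params$tau_m / params$cm
}

#' Weight-representation report for a set of projections
#'
#' Builds the 16-bit codec for every projection given the peak per-timestep
#' summed conductance its accumulator must represent, and tabulates the
#' encoding error. Under the default stimulation protocol all projections
#' encode within 5% of the prescribed weight except `pf-PC`, whose large peak
#' forces a single-bit representation at least 37% above the prescribed
#' weight.
#'
#' @param projections projections data.frame (see [canonical_model()])
#' @param peaks named numeric vector of peak conductances (uS) per projection
#'   name; see [peak_projection_input()] for measuring them from a pilot run.
#'   Peaks smaller than the weight itself are raised to the weight.
#' @return data.frame: projection, prescribed and encoded weight (uS),
#'   relative error, bits occupied, quantum
#' @export
weight_report <- function(projections, peaks) {
  missing <- setdiff(projections$name, names(peaks))
  if (length(missing))
    stop("weight_report: no peak given for ", paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(projections)), function(i) {
    w <- abs(projections$weight[i])
    pk <- max(peaks[[projections$name[i]]], w)
    cd <- build_codec(w, pk)
    data.frame(projection = projections$name[i], weight = w,
               peak = pk, encoded = cd$encoded, rel_error = cd$rel_error,
               bits = cd$bits, quantum = cd$quantum)
  })
  do.call(rbind, rows)
}

#' Write a weight-representation report as a columnar text table
#'
#' @param report data.frame from [weight_report()]
#' @param path output file
#' @export
write_weight_report <- function(report, path) {
  utils::write.table(format(report, digits = 6), path, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  invisible(path)
}
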