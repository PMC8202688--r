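# Synthetic rasters with known structure exercise the validation statistics.
make_raster <- function(spikes, model, dt = 0.1, n_steps = 10000L) {
  spike_raster(spikes$id, spikes$step, dt, n_steps, model)
}

test_that("window rates use shifted, clipped windows", {
  m <- toy_model(n_out = 3L)
  # GrC shift is 4 ms: windows [4,304), [304,354), [354,1004) clipped to 1000
  ws <- window_spec()
  # neuron 2 (local) spikes every 10 ms from t=0
  steps <- seq(0L, 9999L, by = 100L)
  sp <- data.frame(id = rep(19L + 1L, length(steps)), step = steps)  # global id of GrC local 1
  r <- make_raster(sp, m)
  rates <- window_rates(r, "GrC", ws)
  expect_equal(nrow(rates), 3L)
  expect_equal(rates$pre[3], 0)
  # 10 ms spacing -> 100 Hz in every window (up to boundary effects)
  expect_equal(rates$stim[1], 100, tolerance = 0.01)
  expect_equal(rates$pre[1], 100, tolerance = 0.01)
  # post window is [354, 1000): 64 spikes in 646 ms
  expect_equal(rates$post[1], 64 / 0.646, tolerance = 1e-6)
  # silent neuron: all zero
  expect_equal(unlist(rates[3, ]), c(pre = 0, stim = 0, post = 0))
})

test_that("excited/inhibited classification is exhaustive, exclusive and boundary-exact", {
  rates <- data.frame(pre = c(2, 10, 0, 0, 4, 3),
                      stim = c(4, 4.9, 0, 5, 7.9, 1.6))
  cls <- classify_response(rates)
  expect_identical(as.character(cls),
                   c("excited",    # doubling boundary counts as excited
                     "inhibited",  # below half
                     "neither",    # silent throughout
                     "excited",    # 0 -> positive trivially doubles
                     "neither",    # less than double, more than half
                     "neither"))   # rounding-safe middle case
  expect_false(any(is.na(cls)))
})

test_that("ISI and CV match hand-computed values and Poisson limits", {
  m <- toy_model(n_out = 5L)
  sp <- data.frame(id = 20L, step = c(0L, 100L, 300L))  # GrC local 1: 0, 10, 30 ms
  r <- make_raster(sp, m)
  out <- isi_cv(r, "GrC")
  expect_equal(out$isi[["1"]], c(10, 20))
  expect_equal(unname(out$cv["1"]), 1 / 3, tolerance = 1e-9)

  # perfectly regular train: CV = 0
  sp2 <- data.frame(id = 21L, step = seq(0L, 9900L, by = 100L))
  out2 <- isi_cv(make_raster(sp2, m), "GrC")
  expect_equal(unname(out2$cv["2"]), 0)

  # long Poisson train: CV -> 1
  set.seed(8)
  steps <- generate_poisson(200, 100000, 0.1)
  out3 <- isi_cv(make_raster(data.frame(id = 22L, step = steps), m,
                             n_steps = 1000000L), "GrC")
  expect_equal(unname(out3$cv["3"]), 1, tolerance = 0.05)

  # neurons with too few spikes are omitted, not zero-filled
  sp4 <- data.frame(id = c(23L, 24L), step = c(5L, 7L))
  out4 <- isi_cv(make_raster(sp4, m), "GrC")
  expect_false("4" %in% names(out4$cv) || "5" %in% names(out4$cv))
})

test_that("cross-run correlation is 1 for identical, ~0 for independent, <1 for shifted", {
  m <- toy_model(n_out = 40L)
  ws <- window_spec()
  set.seed(5)
  mk <- function(seed) {
    set.seed(seed)
    sp <- do.call(rbind, lapply(1:40, function(i)
      data.frame(id = 19L + i, step = generate_poisson(120, 1000, 0.1))))
    make_raster(sp, m)
  }
  ra <- mk(1)
  self <- spike_correlation(ra, ra, "GrC", ws = ws)
  expect_true(length(self) > 10)
  expect_true(all(abs(self - 1) < 1e-12))

  rb <- mk(2)
  ind <- spike_correlation(ra, rb, "GrC", ws = ws)
  expect_lt(abs(mean(ind)), 0.25)

  shifted <- ra
  shifted$spikes$step <- pmin(shifted$spikes$step + 60L, shifted$n_steps - 1L)
  sh <- spike_correlation(ra, shifted, "GrC", ws = ws)
  expect_lt(mean(sh), 0.999)
})

test_that("PSTH conserves spike counts", {
  m <- toy_model(n_out = 5L)
  set.seed(3)
  sp <- data.frame(id = sample(20:24, 500, TRUE),
                   step = sample(0:9999, 500, TRUE))
  r <- make_raster(sp, m)
  h <- psth(r, "GrC", bin = 0.1)
  expect_equal(sum(h$count), 500)
  h5 <- psth(r, "GrC", bin = 5)
  expect_equal(sum(h5$count), 500)
  empty <- psth(make_raster(sp[0, ], m), "GrC")
  expect_equal(sum(empty$count), 0)
})

test_that("validation report reflects an engineered inhibited population", {
  m <- toy_model(n_out = 12L)
  # all 12 cells tonic at 20 Hz outside [300, 350), silent inside (shift 4 ms)
  steps <- seq(0L, 9999L, by = 500L)
  steps <- steps[steps < 3040L | steps >= 3540L]
  sp <- do.call(rbind, lapply(1:12, function(i)
    data.frame(id = 19L + i, step = steps)))
  r <- make_raster(sp, m)
  rep <- validation_report(r, window_spec())
  row <- rep[rep$population == "GrC", ]
  expect_identical(row$n_inhibited, 12L)
  expect_equal(row$frac_inhibited, 1)
  expect_identical(row$subset, "inhibited")
  expect_equal(row$stim_mean, 0)
})
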