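test_that("index partitioning yields the published core count", {
  m <- canonical_model()
  cm <- partition_cores(m)
  expect_identical(cm$n_cores, 1583L)
  tab <- table(cm$core_population)
  expect_identical(unname(tab[["PC"]]), 69L)     # one Purkinje cell per core
  expect_identical(unname(tab[["GrC"]]), 1378L)  # ceil(88158/64)
  expect_identical(unname(tab[["DCNC"]]), 1L)
  # a population of exactly 64 neurons fits one core
  m2 <- toy_model(n_in = 64L, n_out = 64L)
  cm2 <- partition_cores(m2)
  expect_identical(cm2$n_cores, 2L)
  # every neuron on exactly one in-range core
  expect_true(all(cm$core_of >= 0 & cm$core_of < cm$n_cores))
})

test_that("multicast packets count distinct destination cores per spike", {
  # one source, 8 targets spread over cores of 4 -> 2 destination cores
  m <- toy_model(n_in = 1L, n_out = 8L, n_synapses = 8L)
  net <- build_network(m, seed = 1)
  net$synapses[[1]]$tgt <- 1:8  # one synapse on every target
  cm <- partition_cores(m, neurons_per_core = 4L)
  r <- spike_raster(0L, 10L, 0.1, 100L, m)  # the single Glom spikes once
  ps <- count_packets(r, net, cm)
  expect_equal(ps$total, 2)
  # all targets on one core -> one packet
  cm1 <- partition_cores(m, neurons_per_core = 64L)
  ps1 <- count_packets(r, net, cm1)
  expect_equal(ps1$total, 1)
})

test_that("packet totals are conserved against an independent recount", {
  m <- small_canonical(0.01)
  net <- build_network(m, seed = 2)
  n_glom <- m$populations$size[m$populations$name == "Glom"]
  inp <- build_protocol_input(stimulus_protocol(n_select = 30), n_glom,
                              seed = 2, duration = 400)
  rec <- run_network(net, inp, 400)
  cm <- partition_cores(m, neurons_per_core = 16L)
  ps <- count_packets(rec$raster, net, cm)

  # independent recount: sum over spikes of |distinct destination cores|
  edges <- do.call(rbind, lapply(net$synapses, function(s) {
    off <- stats::setNames(rec$raster$populations$offset,
                           rec$raster$populations$name)
    data.frame(src = s$src - 1L + off[[s$projection$source]],
               tgt = s$tgt - 1L + off[[s$projection$target]])
  }))
  edges$core <- cm$core_of[edges$tgt + 1L]
  ncores_of <- tapply(edges$core, edges$src, function(x) length(unique(x)))
  spikes_per_src <- table(rec$raster$spikes$id)
  common <- intersect(names(ncores_of), names(spikes_per_src))
  total <- sum(ncores_of[common] * spikes_per_src[common])
  expect_equal(ps$total, unname(total))
  expect_equal(sum(ps$core_total), ps$total)
  expect_true(all(ps$core_max <= ps$core_total))
})

test_that("peak packet load grows with the burst rate and periodic far exceeds Poisson", {
  m <- small_canonical(0.02)
  net <- build_network(m, seed = 3)
  cm <- partition_cores(m, neurons_per_core = 16L)
  sw <- sweep_stimulus(net, "f_peak", values = c(30, 200), trials = 2,
                       duration = 420, core_map = cm,
                       protocol = stimulus_protocol(n_select = 60), seed = 5)
  agg <- tapply(sw$mean_peak, sw$value, mean)
  expect_gt(agg[["200"]], agg[["30"]])

  # periodic synchronizes the burst: much larger peaks at equal rate
  sw_per <- sweep_stimulus(net, "f_peak", values = 150, encoding = "periodic",
                           trials = 2, duration = 420, core_map = cm,
                           protocol = stimulus_protocol(n_select = 60), seed = 5)
  sw_poi <- sweep_stimulus(net, "f_peak", values = 150, encoding = "poisson",
                           trials = 2, duration = 420, core_map = cm,
                           protocol = stimulus_protocol(n_select = 60), seed = 5)
  # compare on the input-driven population (GrC receives the Glom fan-out)
  per <- sw_per$mean_peak[sw_per$population == "GrC"]
  poi <- sw_poi$mean_peak[sw_poi$population == "GrC"]
  expect_gt(per, 3 * poi)
})

test_that("spatial placement reduces peak load only when wiring has locality", {
  m <- small_canonical(0.05)
  pos <- place_cells(m, seed = 6)
  n_glom <- m$populations$size[m$populations$name == "Glom"]

  run_one <- function(wiring_mode, kernel_sd) {
    net <- build_network(m, mode = wiring_mode, seed = 7, positions = pos,
                         kernel_sd = kernel_sd)
    p <- stimulus_protocol(selection = "sphere", radius = 120)
    inp <- build_protocol_input(p, n_glom, positions = pos$Glom,
                                seed = 8, duration = 420)
    rec <- run_network(net, inp, 420)
    compare_placement(rec$raster, net, positions = pos, seed = 9)
  }
  sp <- run_one("spatial", kernel_sd = 40)
  un <- run_one("uniform", kernel_sd = 40)
  # identical strategies: zero reduction by definition
  m0 <- small_canonical(0.02)
  net0 <- build_network(m0, seed = 1)
  inp0 <- build_protocol_input(stimulus_protocol(n_select = 50),
                               m0$populations$size[1], seed = 1,
                               duration = 350)
  rec0 <- run_network(net0, inp0, 350)
  same <- compare_placement(rec0$raster, net0, positions = place_cells(m0, 1),
                            base = "index", alt = "index")
  expect_equal(same$reduction, 0)
  # spatially wired: spatial chunking beats random placement
  expect_gt(sp$reduction, 0)
  # no locality to exploit under uniform wiring
  expect_lt(un$reduction, sp$reduction)
  expect_lt(abs(un$reduction), 0.2)
})
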