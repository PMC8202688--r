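test_that("a silent network with no offset current stays silent", {
  m <- toy_model()
  net <- build_network(m, seed = 1)
  rec <- run_network(net, NULL, duration = 200)
  expect_identical(nrow(rec$raster$spikes), 0L)
  expect_equal(unname(rec$delivered), c(0, 0))
})

test_that("delayed delivery lands exactly delay/dt steps after the source spike", {
  m <- toy_model(n_in = 1L, n_out = 1L, n_synapses = 1L, delay = 4)
  net <- build_network(m, seed = 1)
  spike_at <- 25L
  rec <- run_network(net, data.frame(id = 1L, step = spike_at), duration = 50,
                     record = list(GrC = 1L))
  ge <- rec$traces$g_exc[1, ]
  expect_true(all(ge[seq_len(spike_at + 40)] == 0))  # steps 0..spike+39
  expect_gt(ge[spike_at + 41], 0)                    # first change at +40
  # injected conductance equals the single weight
  expect_equal(unname(rec$delivered["exc"]), 9e-3)
  # relay spike appears in the raster at its scheduled step
  expect_identical(population_spikes(rec$raster, "Glom")$step, spike_at)
})

test_that("conductance delivery is conserved and per-projection events counted", {
  m <- small_canonical(0.01)
  net <- build_network(m, seed = 5)
  n_glom <- m$populations$size[m$populations$name == "Glom"]
  p <- stimulus_protocol(n_select = round(0.4 * n_glom))
  inp <- build_protocol_input(p, n_glom, seed = 6, duration = 400)
  rec <- run_network(net, inp, 400)

  # independent recomputation from the raster and the edge lists:
  # every spike of a source neuron delivers all its outgoing synapses
  sp <- rec$raster$spikes
  off <- stats::setNames(rec$raster$populations$offset,
                         rec$raster$populations$name)
  sizes <- stats::setNames(rec$raster$populations$size,
                           rec$raster$populations$name)
  exp_exc <- 0; exp_inh <- 0
  events <- stats::setNames(numeric(nrow(m$projections)), m$projections$name)
  for (nm in names(net$synapses)) {
    s <- net$synapses[[nm]]
    prj <- s$projection
    src_global <- s$src - 1L + off[[prj$source]]
    spikes_per_neuron <- tabulate(
      sp$id[sp$id >= off[[prj$source]] &
              sp$id < off[[prj$source]] + sizes[[prj$source]]] -
        off[[prj$source]] + 1L, sizes[[prj$source]])
    n_events <- sum(spikes_per_neuron[s$src])
    events[nm] <- n_events
    if (prj$weight >= 0) exp_exc <- exp_exc + n_events * prj$weight
    else exp_inh <- exp_inh + n_events * abs(prj$weight)
  }
  expect_equal(unname(rec$delivered["exc"]), exp_exc, tolerance = 1e-9)
  expect_equal(unname(rec$delivered["inh"]), exp_inh, tolerance = 1e-9)
  expect_equal(rec$proj_events, events)
})

test_that("runs are deterministic given (network, input, config) in both modes", {
  m <- small_canonical(0.01)
  net <- build_network(m, seed = 2)
  n_glom <- m$populations$size[m$populations$name == "Glom"]
  inp <- build_protocol_input(stimulus_protocol(n_select = 50), n_glom,
                              seed = 3, duration = 350)
  for (mode in c("float64", "fixed")) {
    cfg <- sim_config(arithmetic = mode)
    r1 <- run_network(net, inp, 350, cfg)
    r2 <- run_network(net, inp, 350, cfg)
    expect_identical(r1$raster$spikes, r2$raster$spikes)
  }
})

test_that("an unconnected DCNC population fires at its intrinsic rate", {
  m <- canonical_model()
  pops <- m$populations[m$populations$name == "DCNC", ]
  mdl <- structure(list(populations = pops,
                        projections = m$projections[0, ]),
                   class = "cereb_model")
  net <- structure(list(model = mdl, synapses = list(), mode = "uniform",
                        seed = 0L), class = "cereb_network")
  rec <- run_network(net, NULL, duration = 5000, input_population = "DCNC")
  rate <- nrow(rec$raster$spikes) / 12 / 5
  expect_equal(rate, intrinsic_rate(m$populations$params[[7]]),
               tolerance = 0.01)
})

test_that("membrane potential stays bounded and finite in both modes", {
  m <- small_canonical(0.01)
  net <- build_network(m, seed = 4)
  n_glom <- m$populations$size[m$populations$name == "Glom"]
  inp <- build_protocol_input(stimulus_protocol(n_select = 30), n_glom,
                              seed = 4, duration = 350)
  for (mode in c("float64", "fixed")) {
    rec <- run_network(net, inp, 350, sim_config(arithmetic = mode),
                       record = list(GrC = 1:5, PC = 1:3))
    v <- rec$traces$v
    expect_true(all(is.finite(v)))
    expect_gte(min(v), -90)
    expect_lte(max(v), 0)
  }
})

test_that("fixed mode saturation is counted, never silent", {
  # an absurdly strong weight overflows the s16.15 normalized conductance
  m <- toy_model(n_in = 4L, n_out = 1L, n_synapses = 4L, weight = 500)
  net <- build_network(m, seed = 1)
  inp <- data.frame(id = 1:4, step = rep(10L, 4))
  rec <- run_network(net, inp, 30, sim_config(arithmetic = "fixed"),
                     record = list(GrC = 1L))
  expect_gt(rec$saturations, 0)
  expect_true(all(is.finite(rec$traces$v)))
  rec_f <- run_network(net, inp, 30, sim_config())
  expect_identical(rec_f$saturations, 0)
})

test_that("delay buffer rejects delays beyond 64 slots", {
  m <- toy_model(delay = 6.5)
  expect_error(validate_model(m), "64-slot|6.4")
  m2 <- toy_model(delay = 6.4)
  net <- build_network(m2, seed = 1)
  expect_silent(run_network(net, NULL, 20))
})

test_that("memory guard refuses oversized runs with an estimate", {
  m <- canonical_model()
  net0 <- structure(list(model = m,
                         synapses = lapply(seq_len(nrow(m$projections)),
                                           function(i) structure(
                                             list(projection = m$projections[i, ],
                                                  src = integer(0), tgt = integer(0)),
                                             class = "synapse_list")),
                         mode = "uniform", seed = 0L),
                    class = "cereb_network")
  names(net0$synapses) <- m$projections$name
  expect_error(run_network(net0, NULL, 100, mem_limit = 1e6), "memory")
})
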