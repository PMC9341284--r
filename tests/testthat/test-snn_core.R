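test_that("LIF neuron at rest with zero current stays at rest and never fires", {
  pop <- neuron_population(3)
  for (i in 1:50) {
    res <- lif_step(pop, rep(0, 3))
    pop <- res$pop
    expect_length(res$fired, 0)
  }
  expect_equal(pop$potentials, rep(0, 3))
})

test_that("subthreshold trajectory matches the closed form to O(dt)", {
  RI <- 50  # below threshold: never fires
  closed <- function(t, tau) RI * (1 - exp(-t / tau))
  for (dt in c(1, 0.1)) {
    p <- lif_params(dt = dt)
    pop <- neuron_population(1, p)
    t_end <- 60
    for (i in seq_len(t_end / dt)) pop <- lif_step(pop, RI, p)$pop
    err <- abs(pop$potentials - closed(t_end, p$tau_m))
    # explicit Euler: global error proportional to dt
    expect_lt(err, 1.5 * dt)
  }
})

test_that("time to first spike under constant drive matches tau_m * ln 2 within one dt", {
  p <- lif_params()
  pop <- neuron_population(1, p)
  spike_t <- NA
  for (i in 1:60) {
    res <- lif_step(pop, 120, p)  # R*I twice threshold
    pop <- res$pop
    if (length(res$fired)) { spike_t <- pop$t; break }
  }
  expect_lt(abs(spike_t - 30 * log(2)), 1 + 1e-9)
  # after the spike the potential sits at the reset value
  expect_equal(pop$potentials[1], 0)
  expect_equal(pop$last_spike_times[1], spike_t)
})

test_that("lif_step rejects malformed input", {
  pop <- neuron_population(4)
  expect_error(lif_step(pop, c(1, 2)), "size")
  expect_error(lif_step(pop, c(1, 2, NA, 4)), "finite")
  expect_error(lif_params(dt = 40), "dt")
  expect_error(lif_params(u_th = -10), "u_th")
})

test_that("stdp_delta reproduces the exponential pair rule at +/-10 ms", {
  expect_equal(stdp_delta(100, 110), 0.25 * exp(-1))
  expect_equal(stdp_delta(110, 100), -0.01 * exp(-1))
  expect_equal(stdp_delta(100, 100), 0)  # coincident spikes: no change
  expect_equal(stdp_delta(0, 100), 0)    # beyond the window: truncated
  expect_equal(stdp_delta(100, 0), 0)
})

test_that("stdp_delta is sign-antisymmetric and decays with |delta t|", {
  lags <- 1:49
  pot <- stdp_delta(100 - lags, rep(100, length(lags)))
  dep <- stdp_delta(100 + lags, rep(100, length(lags)))
  expect_true(all(pot > 0))
  expect_true(all(dep < 0))
  expect_true(all(diff(pot) < 0))        # |dw| shrinks as the pre lead grows
  expect_true(all(diff(abs(dep)) < 0))
})

test_that("apply_stdp matches the brute-force all-pairs oracle on small rasters", {
  params <- stdp_params()
  for (seed in 1:8) {
    set.seed(seed)
    n_pre <- sample(1:4, 1); n_post <- sample(1:4, 1)
    pre <- record_raster("pre", sample(n_pre, 8, replace = TRUE),
                         sample(0:150, 8))
    post <- record_raster("post", sample(n_post, 9, replace = TRUE),
                          sample(0:150, 9))
    syn <- synapse_matrix(matrix(0.5, n_pre, n_post), plastic = TRUE,
                          params = params)
    got <- apply_stdp(syn, pre, post, params)
    want <- apply_stdp_bruteforce(syn, as.data.frame(pre), as.data.frame(post),
                                  params)
    expect_equal(got$weights, want)
  }
})

test_that("a single pre-before-post pair potentiates by A_plus * exp(-1)", {
  syn <- synapse_matrix(matrix(0.1, 1, 1), plastic = TRUE)
  pre <- record_raster("p", 1, 100)
  post <- record_raster("m", 1, 110)
  expect_equal(apply_stdp(syn, pre, post)$weights[1, 1], 0.1 + 0.25 * exp(-1))
})

test_that("apply_stdp respects contracts, bounds and masks", {
  syn <- synapse_matrix(matrix(0.5, 2, 2), plastic = FALSE)
  pre <- record_raster("p", 1, 10)
  expect_error(apply_stdp(syn, pre, pre), "non-plastic")

  # empty rasters leave weights untouched
  syn <- synapse_matrix(matrix(0.5, 2, 2), plastic = TRUE)
  expect_equal(apply_stdp(syn, record_raster(), record_raster())$weights,
               syn$weights)

  # saturation at w_max under heavy potentiation, w_min under depression
  syn <- synapse_matrix(matrix(0.99, 1, 1), plastic = TRUE)
  pre <- record_raster("p", rep(1, 10), seq(0, 90, by = 10))
  post <- record_raster("m", rep(1, 10), seq(5, 95, by = 10))
  expect_equal(apply_stdp(syn, pre, post)$weights[1, 1], 1)

  # weight bounds hold after arbitrary random raster sequences
  set.seed(42)
  syn <- synapse_matrix(matrix(runif(6), 2, 3), plastic = TRUE)
  for (i in 1:20) {
    pre <- record_raster("p", sample(2, 15, TRUE), sample(0:300, 15))
    post <- record_raster("m", sample(3, 15, TRUE), sample(0:300, 15))
    syn <- apply_stdp(syn, pre, post)
    expect_true(all(syn$weights >= 0 & syn$weights <= 1))
  }

  # masked (structurally absent) synapses never change
  mask <- matrix(c(1, 0, 1, 0, 1, 0), 2, 3)
  syn <- synapse_matrix(matrix(0.5, 2, 3) * mask, plastic = TRUE, mask = mask)
  syn2 <- apply_stdp(syn, record_raster("p", 1:2, c(10, 20)),
                     record_raster("m", 1:3, c(15, 25, 35)))
  expect_true(all(syn2$weights[mask == 0] == 0))
})

test_that("spike rasters validate, sort, and round-trip through CSV", {
  r <- record_raster(c("m", "e"), c(2, 1), c(30, 10))
  expect_equal(r$time_ms, c(10, 30))  # sorted by time
  expect_error(record_raster("m", 1, -5), "non-negative")

  path <- withr::local_tempfile(fileext = ".csv")
  write_raster(r, path)
  expect_equal(as.data.frame(read_raster(path)), as.data.frame(r))

  # empty raster writes a header-only file
  write_raster(record_raster(), path)
  expect_equal(nrow(utils::read.csv(path)), 0)
})
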