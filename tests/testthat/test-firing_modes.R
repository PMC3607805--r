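# Frontier detection, spike classification, spike-triggered averages,
# phase locking, and the external-rate coding analyses.

test_that("frontier detection recovers a known inter-mode minimum", {
  fx <- make_bimodal_isi_train(slow_rate = 30, fast_rate = 120,
                               weight_slow = 0.64, n_isi = 10000, seed = 5)
  fr <- find_mode_frontier(fx$rates_hz)
  expect_lt(abs(fr$frontier_hz - fx$truth$min_rate_hz),
            0.1 * fx$truth$min_rate_hz)
  expect_lt(abs(fr$frontier_hz - 60), 8)
  # mass on the slow side matches the mixture construction
  expect_equal(mean(fx$rates_hz < fx$truth$min_rate_hz), 0.64,
               tolerance = 0.035)
})

test_that("unimodal samples yield a typed no-frontier error", {
  set.seed(2)
  u <- make_bimodal_isi_train(weight_slow = 1, n_isi = 4000)
  expect_true(u$truth$unimodal)
  expect_error(find_mode_frontier(u$rates_hz), class = "eig_no_frontier")
  # unimodal exponential ISIs
  expect_error(find_mode_frontier(1000 / rexp(5000, 1 / 40)),
               class = "eig_no_frontier")
  expect_error(find_mode_frontier(runif(100, 1, 10)), "at least")
})

test_that("frontier recovery works across randomized mode placements", {
  set.seed(1)
  hits <- 0
  for (i in 1:20) {
    sl <- runif(1, 15, 40)
    fa <- sl * runif(1, 3.5, 6)
    fx <- make_bimodal_isi_train(slow_rate = sl, fast_rate = fa,
                                 weight_slow = runif(1, 0.4, 0.75),
                                 n_isi = 8000)
    fr <- find_mode_frontier(fx$rates_hz, test = FALSE)
    hits <- hits + (abs(fr$frontier_hz - fx$truth$min_rate_hz) < (fa - sl) / 2)
  }
  expect_gte(hits, 19)
})

test_that("spike classification follows the flanking-interval rule", {
  r <- data.frame(neuron = 1, time_ms = c(0, 5, 10, 100, 200))
  cls <- classify_spikes(r, frontier = 58.31)
  expect_equal(cls$spikes$label, c("fast", "fast", "fast", "slow", "slow"))
  expect_equal(cls$spikes$burst_first, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # every ISI is slow or fast, nothing else
  expect_equal(sum(cls$fractions[1, c("slow", "fast")]), 1)
  # all-slow train has no fast spikes
  r2 <- data.frame(neuron = 1, time_ms = seq(0, 500, by = 50))
  cls2 <- classify_spikes(r2, frontier = 58.31)
  expect_equal(sum(cls2$spikes$label == "fast"), 0)
  # a lone spike is unclassified
  r3 <- data.frame(neuron = 1:2, time_ms = c(10, 20))
  expect_equal(classify_spikes(r3, 50)$spikes$label,
               rep("unclassified", 2))
})

test_that("classification partitions all intervals per population", {
  sim <- default_trial(1)
  fr <- sapply(c(excitatory = "excitatory", inhibitory = "inhibitory"),
    function(p) find_mode_frontier(
      instantaneous_rates(sim, population = p)$rate_hz)$frontier_hz)
  cls <- classify_spikes(sim, fr)
  expect_equal(rowSums(cls$fractions[, c("slow", "fast")]), c(1, 1),
               ignore_attr = TRUE)
  expect_equal(nrow(cls$isis), nrow(instantaneous_rates(sim)))
})

test_that("spike-triggered averaging is exact on constructed signals", {
  fs <- 1000
  # constant signal: STA is that constant
  sta <- spike_triggered_average(rep(2.5, 2000), fs,
                                 spike_times = seq(100, 1900, by = 37))
  expect_true(all(sta$sta == 2.5))
  # spikes placed at a known phase of an oscillation reproduce its cycle
  t <- (1:4000 - 0.5) / fs
  x <- cos(2 * pi * 50 * t)
  spikes <- seq(100, 3900, by = 20)     # multiples of the 20 ms period
  sta2 <- spike_triggered_average(x, fs, spikes, window = c(-50, 20))
  i0 <- which(sta2$lag_ms == 0)
  expect_gt(sta2$sta[i0], 0.95)         # spike at the oscillation peak
  i10 <- which(sta2$lag_ms == 10)       # half a period later: trough
  expect_lt(sta2$sta[i10], -0.95)
  expect_error(spike_triggered_average(x, fs, numeric(0)), "no spikes")
  expect_error(spike_triggered_average(x, fs, c(10)), "window")
})

test_that("STA standard error shrinks as one over sqrt(spike count)", {
  set.seed(8)
  x <- rnorm(60000)
  s1 <- spike_triggered_average(x, 1000, runif(200, 100, 59000))
  s2 <- spike_triggered_average(x, 1000, runif(3200, 100, 59000))
  ratio <- mean(s1$se) / mean(s2$se)
  expect_equal(ratio, 4, tolerance = 0.35)
})

test_that("STA admission rule enforces the pre-spike gap", {
  r <- data.frame(neuron = 1,
                  time_ms = c(100, 130, 190, 196, 202, 400, 460),
                  population = "excitatory")
  cls <- classify_spikes(r, frontier = 58.31)
  sta_set <- select_mode_spikes(cls, "fast", "excitatory", "sta")
  # the burst at 190 is admitted (gap 60 >= 50 from 130)
  expect_equal(sta_set$time_ms, 190)
  slow_set <- select_mode_spikes(cls, "slow", "excitatory", "sta")
  # slow openers with >= 50 ms pre-gap (or none): 100 opens 100->130? no,
  # that ISI is 30 ms -> slow; gaps: 100 (none), 400 (198), 202 (6, fails)
  expect_setequal(slow_set$time_ms, c(100, 400))
})

test_that("preferred phase is recovered from locked fixtures", {
  for (kappa in c(1, 2)) {
    lk <- make_locked_spiketrain(rate = 60, kappa = kappa, preferred = pi,
                                 freq = 45, duration = 30000, fs = 2000,
                                 seed = 40 + kappa)
    ph <- spike_phases(lk$phase, lk$raster$time_ms)
    expect_gt(length(ph), 1000)
    cm <- circular_mean(ph)
    d <- abs((cm$mean - pi + pi) %% (2 * pi) - pi)
    expect_lt(d, if (kappa >= 2) 0.15 else 0.2)
  }
  # no locking: flat histogram
  lk0 <- make_locked_spiketrain(rate = 60, kappa = 0, duration = 20000,
                                fs = 2000, seed = 9)
  h <- phase_locking_histogram(spike_phases(lk0$phase, lk0$raster$time_ms),
                               n_bins = 12)
  chi <- sum((h$prop * h$n - h$n / 12)^2 / (h$n / 12))
  expect_lt(chi, qchisq(0.99, 11))
  expect_equal(sum(h$prop), 1)
})

test_that("external-rate scatter: long intervals average to the mean drive", {
  sim <- cached("sigma_scaled", run_simulation(
    network_config(drive = drive_params(sigma_scale = 1000)), seed = 3))
  sc <- external_rate_coding_scatter(sim)
  long <- sc[sc$isi_ms > 200, ]
  expect_gt(nrow(long), 100)
  expect_lt(abs(mean(long$mean_lambda_hz) - 8500), 100)
  expect_lt(sd(long$mean_lambda_hz), sd(sim$lambda) / 2)
  # fast-mode rates track the drive; slow-mode rates do not
  fr <- find_mode_frontier(sc$rate_hz)
  fast <- sc[sc$rate_hz > fr$frontier_hz, ]
  slow <- sc[sc$rate_hz <= fr$frontier_hz, ]
  expect_gt(cor(fast$mean_lambda_hz, fast$rate_hz, method = "spearman"), 0.2)
  expect_lt(abs(cor(slow$mean_lambda_hz, slow$rate_hz, method = "spearman")),
            0.1)
})

test_that("constant drive pins the scatter abscissa", {
  sim <- small_trial(11)
  sim$lambda <- rep(8500, length(sim$lambda))
  sc <- external_rate_coding_scatter(sim)
  expect_true(all(abs(sc$mean_lambda_hz - 8500) < 1e-9))
})

test_that("forbidden gap is measured between trimmed mode edges", {
  fx <- make_bimodal_isi_train(slow_rate = 20, fast_rate = 150,
                               weight_slow = 0.6, n_isi = 8000, seed = 6)
  g <- forbidden_gap(fx$rates_hz, frontier_hz = fx$truth$min_rate_hz)
  isi <- 1000 / fx$rates_hz
  fast <- isi[fx$rates_hz > fx$truth$min_rate_hz]
  slow <- isi[fx$rates_hz <= fx$truth$min_rate_hz]
  expect_equal(g$width_ms,
               unname(quantile(slow, 0.05) - quantile(fast, 0.95)))
  expect_gt(g$width_ms, 0)
})
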