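test_that("response function closed forms: endpoints and midpoint", {
  rf <- response_function(1, 101, 10, 2)
  expect_equal(eval_response_function(rf, 10), 51)     # half-maximal at K
  expect_equal(eval_response_function(rf, 0), 101)     # dJ_max at zero input
  expect_equal(eval_response_function(rf, 1e9), 1, tolerance = 1e-6)
  expect_error(eval_response_function(rf, -1), ">= 0")
  # strictly decreasing in J_in
  j <- seq(0, 100, by = 0.5)
  expect_true(all(diff(eval_response_function(rf, j)) < 0))
  expect_error(response_function(5, 3, 10, 2), "dJ_min < dJ_max")
})

test_that("sensor response averages on and off states", {
  s <- sensor_response(c(8, 9, 9, 10, 0, 0.2),
                       c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(s$dJ_on, 9)
  expect_equal(s$dJ_off, 0.1)
  expect_equal(sensor_response(c(0, 0, 5), c(FALSE, FALSE, TRUE))$dJ_off, 0)
  expect_error(sensor_response(c(1, 2), c(TRUE, TRUE)), "off state")
})

test_that("gate input flux sums promoter activities and read-through", {
  expect_equal(gate_input_flux(c(5, 7), 0.5), 12.5)
  expect_equal(gate_input_flux(3), 3)
  expect_equal(gate_input_flux(c(0, 0), 0), 0)
})

test_that("noiseless Hill observations are recovered to high precision", {
  truth <- response_function(1, 101, 10, 2)
  J <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  obs <- data.frame(J_in = J, dJ_out = eval_response_function(truth, J))
  fit <- fit_gate_response(obs)
  expect_true(fit$converged)
  for (p in c("dJ_min", "dJ_max", "K", "n_coop")) {
    expect_equal(fit$rf[[p]], truth[[p]], tolerance = 1e-3)
  }
  expect_lt(fit$residual, 1e-8)
})

test_that("degenerate and underdetermined gate fits are flagged", {
  flat <- data.frame(J_in = c(1, 2, 5, 10), dJ_out = rep(7, 4))
  fit <- fit_gate_response(flat)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_error(fit_gate_response(data.frame(J_in = 1:3, dJ_out = 1:3)),
               ">= 4 observations")
})

test_that("noisy Hill fits stay anchored to the generating parameters", {
  # with 10% lognormal noise on the measured activities the least-squares
  # K and n estimates scatter with median relative error around the noise
  # level and no gross mis-estimates
  truth <- response_function(1, 101, 10, 2)
  J <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  n_runs <- 20L
  errK <- errN <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(1000 + r)
    obs <- data.frame(
      J_in = J * rlnorm(8, 0, 0.1),
      dJ_out = eval_response_function(truth, J) * rlnorm(8, 0, 0.1))
    fit <- fit_gate_response(obs)
    errK[r] <- abs(fit$rf$K / truth$K - 1)
    errN[r] <- abs(fit$rf$n_coop / truth$n_coop - 1)
  }
  expect_lt(median(errK), 0.2)
  expect_lt(median(errN), 0.2)
  expect_true(all(errK < 0.6) && all(errN < 0.6))
})

test_that("two-sensor series deconvolution recovers the spec'd truth", {
  # truth: sensor1 (off 0 -> on 10), sensor2 (off 1 -> on 100)
  labels1 <- c(FALSE, FALSE, TRUE, TRUE)
  labels2 <- c(FALSE, TRUE, FALSE, TRUE)
  measured <- c(0 + 1, 0 + 100, 10 + 1, 10 + 100)
  fit <- fit_series(measured, "sensor+sensor",
                    list(dev1 = labels1, dev2 = labels2))
  expect_lt(fit$residual, 1e-12)
  expect_equal(fit$dev1$dJ_off, 0, tolerance = 1e-6)
  expect_equal(fit$dev1$dJ_on, 10, tolerance = 1e-6)
  expect_equal(fit$dev2$dJ_off, 1, tolerance = 1e-6)
  expect_equal(fit$dev2$dJ_on, 100, tolerance = 1e-6)
})

test_that("series fits reject confounded or underdetermined designs", {
  expect_error(
    fit_series(c(1, 2), "sensor+sensor",
               list(dev1 = c(TRUE, FALSE), dev2 = c(FALSE, TRUE))),
    "underdetermined")
  expect_error(
    fit_series(c(1, 2, 3, 4), "sensor+sensor",
               list(dev1 = c(TRUE, TRUE, FALSE, FALSE),
                    dev2 = c(TRUE, TRUE, FALSE, FALSE))),
    "confounded")
  expect_error(
    fit_series(c(1, 2, 3, 4), "sensor+sensor",
               list(dev1 = rep(TRUE, 4), dev2 = c(TRUE, FALSE, TRUE, FALSE))),
    "never changes state")
})

test_that("gate+gate series recovers gauge-invariant parameters", {
  g1 <- response_function(1, 101, 10, 2)
  g2 <- response_function(0.5, 50, 5, 1.5)
  J1 <- c(0.3, 1, 3, 8, 15, 30, 60, 120)
  J2 <- c(40, 12, 25, 2, 0.8, 6, 90, 0.2)
  measured <- eval_response_function(g1, J1) + eval_response_function(g2, J2)
  fit <- fit_series(measured, "gate+gate", list(dev1 = J1, dev2 = J2))
  expect_lt(fit$residual, 1e-8)
  expect_equal(fit$dev1$K, g1$K, tolerance = 0.01)
  expect_equal(fit$dev1$n_coop, g1$n_coop, tolerance = 0.01)
  expect_equal(fit$dev2$K, g2$K, tolerance = 0.01)
  expect_equal(fit$dev2$n_coop, g2$n_coop, tolerance = 0.01)
  # dynamic ranges are identifiable even though the min/max split is only
  # fixed by the gauge convention
  expect_equal(fit$dev1$dJ_max - fit$dev1$dJ_min, 100, tolerance = 0.01)
  expect_equal(fit$dev2$dJ_max - fit$dev2$dJ_min, 49.5, tolerance = 0.01)
})

test_that("split_series_activity splits proportionally and conserves", {
  expect_equal(split_series_activity(121, 11, 110), c(11, 110))
  expect_equal(split_series_activity(0, 3, 7), c(0, 0))
  expect_error(split_series_activity(5, 0, 0), "zero")
  set.seed(5)
  for (i in 1:20) {
    m <- runif(1, 0, 200); e1 <- runif(1, 0, 50); e2 <- runif(1, 1e-6, 50)
    out <- split_series_activity(m, e1, e2)
    expect_equal(sum(out), m)
  }
})
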