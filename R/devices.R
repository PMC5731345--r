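#' Construct a gate response function
#'
#' The steady-state response of a transcriptional inverter (NOT/NOR gate) is
#' a repressing Hill function of the total input RNAP flux:
#' `dJ_out = dJ_min + (dJ_max - dJ_min) * K^n / (K^n + J_in^n)`.
#'
#' @param dJ_min,dJ_max Minimal and maximal output promoter activity (au/s),
#'   `0 <= dJ_min < dJ_max`.
#' @param K Threshold input flux (au/s), > 0.
#' @param n_coop Hill cooperativity, > 0.
#' @return Object of class `ResponseFunction`.
#' @export
response_function <- function(dJ_min, dJ_max, K, n_coop) {
  if (dJ_min < 0 || dJ_max <= dJ_min) stop("require 0 <= dJ_min < dJ_max")
  if (K <= 0) stop("K must be > 0")
  if (n_coop <= 0) stop("n_coop must be > 0")
  structure(list(dJ_min = dJ_min, dJ_max = dJ_max, K = K, n_coop = n_coop),
            class = "ResponseFunction")
}

#' Evaluate a gate response function
#'
#' @param rf A [response_function()].
#' @param J_in Total input flux in au/s (vectorized), >= 0.
#' @return Output promoter activity dJ_out in au/s.
#' @export
eval_response_function <- function(rf, J_in) {
  if (any(J_in < 0)) stop("J_in must be >= 0")
  Kn <- rf$K^rf$n_coop
  rf$dJ_min + (rf$dJ_max - rf$dJ_min) * Kn / (Kn + J_in^rf$n_coop)
}

#' Sensor response from per-state promoter activities
#'
#' A sensor's response is the mean activity of its output promoter over the
#' states where its inducer is present (on) and absent (off).
#'
#' @param activities Named or plain numeric vector of output promoter
#'   activities per state (au/s).
#' @param on_states Logical vector: is the sensor's inducer present in each
#'   state?
#' @return Object of class `SensorResponse`: list with `dJ_on`, `dJ_off`,
#'   `on_states`, `off_states`.
#' @export
sensor_response <- function(activities, on_states) {
  stopifnot(length(activities) == length(on_states), is.logical(on_states))
  if (!any(on_states) || !any(!on_states)) {
    stop("need at least one on state and one off state")
  }
  structure(list(dJ_on = mean(activities[on_states]),
                 dJ_off = mean(activities[!on_states]),
                 on_states = which(on_states), off_states = which(!on_states)),
            class = "SensorResponse")
}

#' Total input flux into a gate
#'
#' For NOR gates the inputs sum: `J_in = sum(input promoter activities) +
#' J0`, where J0 is the transcriptional read-through from upstream of the
#' input promoters.
#'
#' @param input_activities Numeric vector of input promoter activities
#'   (au/s), floored at 0 upstream.
#' @param J0 Upstream read-through flux (au/s, default 0).
#' @return J_in in au/s.
#' @export
gate_input_flux <- function(input_activities, J0 = 0) {
  sum(input_activities) + J0
}

# E1-style log least squares error for a candidate response function
.hill_error <- function(par, J_in, dJ_obs, floor) {
  rf <- list(dJ_min = par[1], dJ_max = par[1] + par[2], K = par[3],
             n_coop = par[4])
  pred <- pmax(eval_response_function(rf, J_in), floor)
  sum((log(pmax(dJ_obs, floor)) - log(pred))^2)
}

#' Fit a gate response function to multi-state observations
#'
#' Minimizes the log-scale least-squares error
#' `E1 = sum_i [log(dJ_obs_i) - log(dJ_out(J_in_i))]^2` over the four Hill
#' parameters, with constraints `dJ_min > 0`, `dJ_max > dJ_min`, `K > 0`,
#' `n_coop` in (0.1, 8]. Observed outputs at or below `floor` are replaced
#' by `floor` before logging (off states can measure exactly 0). The
#' optimizer is constrained local minimization (L-BFGS-B) started from a
#' small grid (K at input-flux quantiles, n_coop in {1, 2, 4}); the best
#' error wins, ties broken by smaller n_coop.
#'
#' @param observations data.frame with columns `J_in` and `dJ_out` (au/s),
#'   one row per state; >= 4 rows.
#' @param floor Log floor in au/s (default 1e-2).
#' @return List with `rf` (a [response_function()]), `residual` (E1 at the
#'   optimum), `converged` (logical) and `degenerate` (TRUE when the
#'   observations have no dynamic range and K is unidentifiable).
#' @export
fit_gate_response <- function(observations, floor = 1e-2) {
  stopifnot(all(c("J_in", "dJ_out") %in% names(observations)))
  if (nrow(observations) < 4) {
    stop("need >= 4 observations to fit 4 response-function parameters")
  }
  J <- observations$J_in
  y <- pmax(observations$dJ_out, floor)
  degenerate <- diff(range(log(y))) < 1e-8
  lo <- c(floor * 1e-4, floor * 1e-4, 1e-6, 0.1)
  hi <- c(max(y) * 10, max(y) * 100, max(c(J, 1)) * 100, 8)
  Ks <- unique(pmax(quantile(J[J > 0], c(0.25, 0.5, 0.75), names = FALSE),
                    1e-3))
  if (length(Ks) == 0) Ks <- 1
  starts <- expand.grid(K = Ks, n = c(1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(max(min(y), lo[1]), max(max(y) - min(y), lo[2]),
              starts$K[i], starts$n[i])
    fit <- tryCatch(
      optim(par0, .hill_error, J_in = J, dJ_obs = y, floor = floor,
            method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[4] < best$par[4])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(list(rf = NULL, residual = NA_real_, converged = FALSE,
                degenerate = degenerate))
  }
  rf <- response_function(best$par[1], best$par[1] + best$par[2],
                          best$par[3], best$par[4])
  list(rf = rf, residual = best$value,
       converged = best$convergence == 0 && !degenerate,
       degenerate = degenerate)
}

#' Deconvolve two devices whose output promoters sit in series
#'
#' When two output promoters are insulated by a common downstream ribozyme,
#' only their combined activity dJ_1+2 is measurable per state. Given enough
#' states, the individual device parameters can be fitted by minimizing
#' `E2 = sum_i [log(dJ_1+2,i) - log(dJ_1,i + dJ_2,i)]^2`, where each
#' device's expected per-state activity is dJ_on/dJ_off selected by its
#' inducer label (sensors) or its Hill response evaluated at that state's
#' input flux (gates).
#'
#' @param measured Numeric vector of combined activities dJ_1+2 per state
#'   (au/s).
#' @param model `"sensor+sensor"`, `"sensor+gate"` or `"gate+gate"`.
#' @param inputs Per-device, per-state inputs: a list with elements `dev1`
#'   and `dev2`. For a sensor device the element is a logical vector of
#'   per-state inducer presence; for a gate device it is a numeric vector of
#'   per-state input fluxes J_in.
#' @param floor Log floor in au/s (default 1e-2), applied to measured and
#'   expected sums only (individual parameters may be 0).
#' @return List with `dev1` and `dev2` parameter lists (`dJ_off`/`dJ_on` for
#'   sensors; `dJ_min`, `dJ_max`, `K`, `n_coop` for gates), plus `residual`
#'   and `converged`.
#' @export
fit_series <- function(measured, model = c("sensor+sensor", "sensor+gate",
                                           "gate+gate"),
                       inputs, floor = 1e-2) {
  model <- match.arg(model)
  kinds <- strsplit(model, "+", fixed = TRUE)[[1]]
  n_states <- length(measured)
  n_par_each <- ifelse(kinds == "sensor", 2L, 4L)
  if (n_states < sum(n_par_each)) {
    stop("underdetermined: ", n_states, " states for ", sum(n_par_each),
         " parameters")
  }
  for (d in 1:2) {
    nm <- c("dev1", "dev2")[d]
    stopifnot(length(inputs[[nm]]) == n_states)
    if (kinds[d] == "sensor" && (!any(inputs[[nm]]) || all(inputs[[nm]]))) {
      stop("sensor ", nm, " never changes state; its on/off parameters are confounded")
    }
  }
  if (kinds[1] == "sensor" && kinds[2] == "sensor" &&
      identical(as.logical(inputs$dev1), as.logical(inputs$dev2))) {
    stop("sensors dev1 and dev2 never differ across states; the pair is confounded")
  }

  # expected per-state activity of one device given its parameter block
  dev_expected <- function(kind, par, input) {
    if (kind == "sensor") ifelse(input, par[2], par[1])  # (off, on)
    else eval_response_function(
      list(dJ_min = par[1], dJ_max = par[1] + par[2], K = par[3],
           n_coop = par[4]), input)
  }
  split_par <- function(par) {
    list(p1 = par[seq_len(n_par_each[1])],
         p2 = par[n_par_each[1] + seq_len(n_par_each[2])])
  }
  e2 <- function(par) {
    p <- split_par(par)
    expected <- dev_expected(kinds[1], p$p1, inputs$dev1) +
      dev_expected(kinds[2], p$p2, inputs$dev2)
    sum((log(pmax(measured, floor)) - log(pmax(expected, floor)))^2)
  }

  y <- pmax(measured, floor)
  sensor_start <- function(input) c(min(y) / 2, max(y) / 2)
  gate_start <- function(input, K, n) c(min(y) / 2, max(y) / 2, K, n)
  bounds_for <- function(kind) {
    if (kind == "sensor") list(lo = c(0, 0), hi = c(Inf, Inf))
    else list(lo = c(floor * 1e-4, floor * 1e-4, 1e-6, 0.1),
              hi = c(max(y) * 10, max(y) * 100,
                     max(c(unlist(inputs[sapply(kinds, identical, "gate")], use.names = FALSE), 1)) * 100, 8))
  }
  b1 <- bounds_for(kinds[1]); b2 <- bounds_for(kinds[2])
  lo <- c(b1$lo, b2$lo); hi <- c(b1$hi, b2$hi)

  start_list <- list()
  if (model == "sensor+sensor") {
    # rank-deficient linear least squares on the 0/1 design (the design has a
    # structural dependency; see gauge note below) gives an exact starting
    # point for noiseless data
    X <- cbind(!inputs$dev1, inputs$dev1, !inputs$dev2, inputs$dev2) * 1
    theta <- tryCatch({
      th <- qr.coef(qr(X), measured)
      th[is.na(th)] <- 0
      th
    }, error = function(e) NULL)
    if (!is.null(theta)) start_list[[1]] <- pmax(as.numeric(theta), 0)
    start_list[[length(start_list) + 1]] <- c(sensor_start(), sensor_start())
  } else {
    gate_inputs <- unlist(inputs[which(kinds == "gate") + 0L], use.names = FALSE)
    Ks <- unique(pmax(quantile(gate_inputs[gate_inputs > 0],
                               c(0.25, 0.75), names = FALSE, na.rm = TRUE), 1e-3))
    if (length(Ks) == 0 || all(is.na(Ks))) Ks <- 1
    for (K in Ks) for (n in c(1, 2, 4)) {
      s1 <- if (kinds[1] == "sensor") sensor_start() else gate_start(inputs$dev1, K, n)
      s2 <- if (kinds[2] == "sensor") sensor_start() else gate_start(inputs$dev2, K, n)
      start_list[[length(start_list) + 1]] <- c(s1, s2)
    }
  }

  best <- NULL
  for (par0 in start_list) {
    par0 <- pmin(pmax(par0, lo), ifelse(is.finite(hi), hi, par0))
    fit <- tryCatch(
      optim(par0, e2, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(factr = 1, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("series fit failed from every starting point")
  p <- split_par(best$par)

  # Gauge note: E2 depends only on per-state sums, and shifting a constant
  # activity delta from device 1's levels to device 2's (off/on for a
  # sensor, dJ_min and dJ_max jointly for a gate) leaves every sum -- hence
  # E2 -- unchanged. The individual levels are therefore only identifiable
  # up to this shift. We pin the gauge deterministically: device 1's lowest
  # level is pushed to its lower bound, attributing the shared baseline to
  # device 2. Differences (dJ_on - dJ_off, dJ_max - dJ_min) and gate K,
  # n_coop are gauge-invariant.
  lev1_lo <- if (kinds[1] == "sensor") 0 else lo[1]
  s <- (if (kinds[1] == "sensor") min(p$p1[1:2]) else p$p1[1]) - lev1_lo
  if (s > 0) {
    if (kinds[1] == "sensor") p$p1[1:2] <- p$p1[1:2] - s else
      p$p1[1] <- p$p1[1] - s
    if (kinds[2] == "sensor") p$p2[1:2] <- p$p2[1:2] + s else
      p$p2[1] <- p$p2[1] + s
  }

  as_dev <- function(kind, par) {
    if (kind == "sensor") list(dJ_off = par[1], dJ_on = par[2])
    else list(dJ_min = par[1], dJ_max = par[1] + par[2], K = par[3],
              n_coop = par[4])
  }
  list(dev1 = as_dev(kinds[1], p$p1), dev2 = as_dev(kinds[2], p$p2),
       residual = best$value, converged = best$convergence == 0)
}

#' Split a combined tandem-promoter activity into individual contributions
#'
#' The measured combined activity is divided in proportion to the expected
#' individual activities, so the estimates sum exactly to the measurement.
#'
#' @param measured Combined measured activity dJ_1+2 (au/s).
#' @param expected1,expected2 Expected individual activities (au/s); their
#'   sum must be > 0.
#' @return Numeric vector `c(dJ1_est, dJ2_est)`.
#' @export
split_series_activity <- function(measured, expected1, expected2) {
  total <- expected1 + expected2
  if (total <= 0) stop("expected activities sum to zero; cannot split")
  c(measured * expected1 / total, measured * expected2 / total)
}
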