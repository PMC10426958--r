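#' Jansen-Rit model parameters
#'
#' Defaults are the standard parameterization of the Jansen-Rit cortical
#' column: excitatory/inhibitory synaptic gains `A`, `B` (mV), PSP rate
#' constants `a`, `b` (ms^-1), intra-column connectivity constants `C1`-`C4`,
#' and the sigmoid constants `vmax` (half the maximum firing rate, ms^-1),
#' `r` (mV^-1) and `v0` (mV). With these values an isolated column crosses a
#' Hopf bifurcation as its mean input `p` grows, passing through a slow
#' high-amplitude limit cycle before settling into an alpha-band (8-12 Hz)
#' oscillation.
#'
#' @param A,B,a,b,C1,C2,C3,C4,vmax,r,v0 model constants, all strictly positive.
#' @return list of class `jr_parameters`.
#' @export
jr_parameters <- function(A = 3.25, B = 22, a = 0.1, b = 0.05,
                          C1 = 135, C2 = 108, C3 = 33.75, C4 = 33.75,
                          vmax = 0.0025, r = 0.56, v0 = 6) {
  p <- list(A = A, B = B, a = a, b = b, C1 = C1, C2 = C2, C3 = C3, C4 = C4,
            vmax = vmax, r = r, v0 = v0)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1))))
    stop("all Jansen-Rit parameters must be strictly positive scalars")
  structure(p, class = "jr_parameters")
}

#' Per-node drive configuration
#'
#' Each node receives an intrinsic Gaussian input of mean `p` and standard
#' deviation `eta` (both ms^-1). Cortical defaults are `p = 0.09`,
#' `eta = 2.2e-8` (a near-noise-free damped regime); regions matching
#' `driver_role` are overridden with `driver_p` and `driver_eta` to model
#' elevated subcortical afferences (reticular activating system and sensory
#' relays).
#'
#' @param sc a `structural_connectome` (supplies region count and roles).
#' @param cortical_p,cortical_eta baseline drive mean / noise std (ms^-1).
#' @param driver_role role tag of the driver group (NULL for no override).
#' @param driver_p,driver_eta drive mean / noise std for driver regions.
#' @return list of class `drive_config` with per-node vectors `p` and `eta`.
#' @export
drive_config <- function(sc, cortical_p = 0.09, cortical_eta = 2.2e-8,
                         driver_role = NULL, driver_p = cortical_p,
                         driver_eta = cortical_eta) {
  n <- sc$n_regions
  p <- rep(cortical_p, n)
  eta <- rep(cortical_eta, n)
  if (!is.null(driver_role)) {
    idx <- which(sc$roles == driver_role)
    p[idx] <- driver_p
    eta[idx] <- driver_eta
  }
  if (any(p < 0) || any(eta < 0)) stop("p and eta must be nonnegative")
  structure(list(p = p, eta = eta), class = "drive_config")
}

#' Network coupling configuration
#'
#' @param g global coupling factor (dimensionless, >= 0) scaling all
#'   connection weights.
#' @param speed conduction speed in mm/ms; tract lengths divided by `speed`
#'   give inter-regional delays.
#' @return list of class `coupling_config`.
#' @export
coupling_config <- function(g = 0, speed = 15) {
  if (g < 0 || speed <= 0) stop("g must be >= 0 and speed > 0")
  structure(list(g = g, speed = speed), class = "coupling_config")
}

#' Simulation configuration
#'
#' @param duration total simulated time (ms).
#' @param transient initial span (ms) marked as transient and excluded from
#'   analyses downstream.
#' @param dt integration step (ms), in (0, 1].
#' @param seed integer RNG seed; identical configs and seeds give bit-identical
#'   results.
#' @param output_fs output sampling rate (Hz); the raw trajectory is low-pass
#'   filtered and decimated to this rate.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration = 10000, transient = 2000, dt = 0.1,
                       seed = 42, output_fs = 1000) {
  if (dt <= 0 || dt > 1) stop("dt must be in (0, 1] ms")
  if (transient >= duration) stop("transient must be shorter than duration")
  if (output_fs > 1000 / dt) stop("output_fs cannot exceed the raw rate 1000/dt")
  structure(list(duration = duration, transient = transient, dt = dt,
                 seed = as.integer(seed), output_fs = output_fs),
            class = "sim_config")
}

#' Jansen-Rit sigmoid
#'
#' Converts an average membrane potential `v` (mV) into a population firing
#' rate (ms^-1): `S(v) = 2 vmax / (1 + exp(r (v0 - v)))`. Strictly
#' increasing with range (0, 2 vmax) and `S(v0) = vmax`.
#'
#' @param v membrane potential (mV), vectorized.
#' @param params a [jr_parameters()] object.
#' @return firing rate(s) in ms^-1.
#' @export
jr_sigmoid <- function(v, params = jr_parameters()) {
  2 * params$vmax / (1 + exp(params$r * (params$v0 - v)))
}

#' Jansen-Rit state derivatives for one node
#'
#' The six first-order equations of the column: `y0,y1,y2` are the pyramidal,
#' excitatory-interneuron and inhibitory-interneuron PSPs (mV) and `y3,y4,y5`
#' their derivatives. `input_value` (intrinsic drive plus network input,
#' ms^-1) enters only the excitatory-interneuron PSP equation.
#'
#' @param state numeric length-6 state vector `(y0..y5)`.
#' @param input_value total input (ms^-1).
#' @param params a [jr_parameters()] object.
#' @return numeric length-6 derivative vector.
#' @export
jr_derivatives <- function(state, input_value, params = jr_parameters()) {
  stopifnot(length(state) == 6, is.finite(input_value))
  y <- state
  with(params, c(
    y[4], y[5], y[6],
    A * a * jr_sigmoid(y[2] - y[3], params) - 2 * a * y[4] - a^2 * y[1],
    A * a * (input_value + C2 * jr_sigmoid(C1 * y[1], params)) -
      2 * a * y[5] - a^2 * y[2],
    B * b * C4 * jr_sigmoid(C3 * y[1], params) - 2 * b * y[6] - b^2 * y[3]
  ))
}

#' Total input to one node of the network
#'
#' Evaluates the drive entering node `i`: intrinsic mean, a noise sample, and
#' the coupling term `g * sum_j w_ji S[y1_j(t - d_ji) - y2_j(t - d_ji)]`
#' over delayed pyramidal outputs of all source nodes.
#'
#' @param node_i target node index.
#' @param delayed_outputs numeric vector: `y1_j - y2_j` of each node `j`
#'   evaluated at `t - d_ji`.
#' @param drive a [drive_config()].
#' @param coupling a [coupling_config()].
#' @param sc a `structural_connectome` (max-normalized internally, as in
#'   [simulate_network()]).
#' @param noise_sample noise value for node `i` (ms^-1).
#' @param params a [jr_parameters()].
#' @return scalar input (ms^-1).
#' @export
network_input <- function(node_i, delayed_outputs, drive, coupling, sc,
                          noise_sample = 0, params = jr_parameters()) {
  if (length(delayed_outputs) != sc$n_regions)
    stop("delayed_outputs must supply one value per source node")
  w <- sc$weights / max(sc$weights)
  drive$p[node_i] + noise_sample +
    coupling$g * sum(w[, node_i] * jr_sigmoid(delayed_outputs, params))
}

#' Simulate a Jansen-Rit brain network
#'
#' Integrates the delayed stochastic network with a stochastic Heun
#' (predictor-corrector) scheme. Connection weights are divided by their
#' maximum before `g` is applied, so `g` is comparable across connectomes;
#' delays are tract lengths / conduction speed rounded to integration steps
#' and served from a circular history buffer pre-filled with the initial
#' output. Per step and node, noise is drawn once from `N(0, eta^2)` and held
#' constant across both Heun stages. The recorded signal is the pyramidal
#' membrane potential `y1 - y2` per node, low-pass filtered (4th-order
#' Butterworth at 80% of the output Nyquist, forward-backward) and decimated
#' to `config$output_fs`.
#'
#' @param sc a `structural_connectome`.
#' @param params a [jr_parameters()].
#' @param drive a [drive_config()].
#' @param coupling a [coupling_config()].
#' @param config a [sim_config()].
#' @return object of class `jr_sim`: `signals` (n_regions x n_samples, mV),
#'   `fs` (Hz), `time` (ms), `transient_samples`, `final_state` (6 x n),
#'   `labels`, `roles`, and a config echo.
#' @export
simulate_network <- function(sc, params = jr_parameters(),
                             drive = drive_config(sc),
                             coupling = coupling_config(),
                             config = sim_config()) {
  n <- sc$n_regions
  stopifnot(length(drive$p) == n, length(drive$eta) == n)
  w <- sc$weights
  wmax <- max(w)
  if (wmax > 0) w <- w / wmax
  delay_steps <- matrix(as.integer(round(sc$lengths / coupling$speed /
                                           config$dt)), n, n)
  n_steps <- round(config$duration / config$dt)
  raw <- with_seed(config$seed, jr_simulate_cpp(
    w, delay_steps, drive$p, drive$eta, coupling$g,
    params$A, params$B, params$a, params$b,
    params$C1, params$C2, params$C3, params$C4,
    params$vmax, params$r, params$v0,
    config$dt, n_steps,
    matrix(0, 6, n)))
  fs_raw <- 1000 / config$dt
  stride <- round(fs_raw / config$output_fs)
  sig <- raw$signals
  if (stride > 1) {
    bf <- signal::butter(4, 0.8 * (config$output_fs / 2) / (fs_raw / 2),
                         type = "low")
    padlen <- round(fs_raw / config$output_fs * 50)
    sig <- t(apply(sig, 1, function(x) .filtfilt_padded(bf, x, padlen)))
    if (n == 1) sig <- matrix(sig, nrow = 1)
    sig <- sig[, seq(1, ncol(sig), by = stride), drop = FALSE]
  }
  fs <- fs_raw / stride
  structure(list(
    signals = sig, fs = fs,
    time = (seq_len(ncol(sig)) - 1) / fs * 1000,
    transient_samples = round(config$transient / 1000 * fs),
    final_state = raw$final_state,
    labels = sc$labels, roles = sc$roles,
    params = params, drive = drive, coupling = coupling, config = config),
    class = "jr_sim")
}

#' @export
print.jr_sim <- function(x, ...) {
  cat(sprintf("Jansen-Rit simulation: %d regions, %.1f s at %g Hz (g = %g, seed %d)\n",
              nrow(x$signals), ncol(x$signals) / x$fs, x$fs,
              x$coupling$g, x$config$seed))
  invisible(x)
}

#' Post-transient portion of simulated signals
#'
#' @param sim a `jr_sim` object.
#' @return matrix of signals with the transient columns dropped.
#' @export
post_transient <- function(sim) {
  sim$signals[, -seq_len(sim$transient_samples), drop = FALSE]
}

#' Fixed points of an uncoupled Jansen-Rit node
#'
#' Finds all equilibria of the six state equations for a constant input `p`
#' and no coupling. The system reduces to one equation in the pyramidal
#' potential `v = y1 - y2`; roots are bracketed on a grid and polished with
#' one-dimensional root finding, then mapped back to the full state and
#' checked against the six-equation residual. Stability is classified from
#' the eigenvalues of the numerical Jacobian.
#'
#' @param params a [jr_parameters()].
#' @param p constant input (ms^-1).
#' @param tolerance maximum residual of the six-equation right-hand side.
#' @return list of roots; each root has `state` (length 6), `v`, `residual`,
#'   `stable`. In the monostable range the list has length 1.
#' @export
fixed_point <- function(params = jr_parameters(), p = 0.09,
                        tolerance = 1e-10) {
  state_of_v <- function(v) {
    y0 <- params$A / params$a * jr_sigmoid(v, params)
    y1 <- params$A / params$a *
      (p + params$C2 * jr_sigmoid(params$C1 * y0, params))
    y2 <- params$B / params$b * params$C4 * jr_sigmoid(params$C3 * y0, params)
    c(y0, y1, y2, 0, 0, 0)
  }
  f <- function(v) { s <- state_of_v(v); (s[2] - s[3]) - v }
  grid <- seq(-90, 50, by = 0.25)
  fv <- vapply(grid, f, numeric(1))
  idx <- which(fv[-1] * fv[-length(fv)] <= 0 & is.finite(fv[-1]))
  roots <- lapply(idx, function(i) {
    v <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
    st <- state_of_v(v)
    resid <- max(abs(jr_derivatives(st, p, params)))
    # numerical Jacobian for stability
    J <- vapply(1:6, function(k) {
      h <- 1e-6
      e <- numeric(6); e[k] <- h
      (jr_derivatives(st + e, p, params) -
         jr_derivatives(st - e, p, params)) / (2 * h)
    }, numeric(6))
    list(state = st, v = v, residual = resid,
         stable = all(Re(eigen(J, only.values = TRUE)$values) < 0))
  })
  roots <- unique(roots)
  # drop duplicated brackets hitting the same root
  if (length(roots) > 1) {
    vs <- vapply(roots, `[[`, numeric(1), "v")
    roots <- roots[!duplicated(round(vs, 8))]
  }
  bad <- vapply(roots, function(rt) rt$residual > tolerance, logical(1))
  if (all(bad)) stop("fixed-point search did not reach the requested tolerance")
  roots[!bad]
}

#' Bifurcation scan over a model parameter
#'
#' Simulates the network along a one-dimensional parameter grid and records
#' the post-transient maximum and minimum of each node's signal, plus their
#' averages over the cortical and driver groups, the raw material of a
#' bifurcation diagram.
#'
#' @param sc a `structural_connectome`.
#' @param params a [jr_parameters()].
#' @param drive_template a [drive_config()] used as the base drive.
#' @param coupling_template a [coupling_config()] used as the base coupling.
#' @param scan_parameter one of `"g"`, `"p_driver"`, `"eta_driver"`.
#' @param grid numeric vector of parameter values.
#' @param sim_config a [sim_config()].
#' @param driver_role role tag of the driver group.
#' @return data.frame with one row per grid value and node group (`cortical`,
#'   `driver`, `all`): columns `value`, `group`, `vmax`, `vmin`.
#' @export
bifurcation_scan <- function(sc, params = jr_parameters(),
                             drive_template = drive_config(sc),
                             coupling_template = coupling_config(),
                             scan_parameter = c("g", "p_driver", "eta_driver"),
                             grid, sim_config = jrnet::sim_config(),
                             driver_role = "thalamic") {
  scan_parameter <- match.arg(scan_parameter)
  drv <- which(sc$roles == driver_role)
  cx <- which(sc$roles == "cortical")
  rows <- lapply(grid, function(val) {
    drive <- drive_template
    coupling <- coupling_template
    switch(scan_parameter,
           g = { coupling$g <- val },
           p_driver = { drive$p[drv] <- val },
           eta_driver = { drive$eta[drv] <- val })
    sim <- simulate_network(sc, params, drive, coupling, sim_config)
    x <- post_transient(sim)
    grp <- function(i) if (length(i)) {
      data.frame(vmax = mean(apply(x[i, , drop = FALSE], 1, max)),
                 vmin = mean(apply(x[i, , drop = FALSE], 1, min)))
    } else data.frame(vmax = NA_real_, vmin = NA_real_)
    cbind(value = val,
          group = c("cortical", "driver", "all"),
          rbind(grp(cx), grp(drv), grp(seq_len(sc$n_regions))))
  })
  do.call(rbind, rows)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic seed-splitting: child seeds stay below 2^31.
split_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + index * 7919) %% 2147483647)
}
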