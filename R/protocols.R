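## Activation profiles and simulation drivers: per-timestep loop, twitch,
## tetanus, work loops, and the sweep drivers.

#' Actin permissiveness activation profile
#'
#' Calcium/troponin/tropomyosin regulation is lumped into a single actin
#' permissiveness AP(t) in \[0,1\], the availability of binding sites. The
#' default is a Gaussian pulse `AP_max e^(-((t - tp)/w)^2)`; a biexponential
#' form (rising exponential times decaying exponential, emulating Ca2+ influx
#' and re-uptake) and a constant level (tetanus) are also available. In
#' work-loop mode the pulse onset is placed at `phase * period` each cycle
#' and the peak follows `onset_lag` later.
#'
#' @param form `"gaussian_pulse"`, `"biexponential"` or `"constant"`.
#' @param AP_max peak permissiveness in \[0,1\].
#' @param t_peak pulse peak time for an isolated twitch, ms.
#' @param width Gaussian width w, ms.
#' @param onset_lag onset-to-peak lag used in periodic (work-loop) mode, ms.
#' @param rise_tau,decay_tau time constants of the biexponential form, ms
#'   (defaults reproduce the ~13 ms onset-to-peak lag).
#' @return an object of class `activationProfile`.
#' @export
activationProfile <- function(form = c("gaussian_pulse", "biexponential",
                                       "constant"),
                              AP_max = 0.73, t_peak = 40, width = 14,
                              onset_lag = 13, rise_tau = 9, decay_tau = 28) {
  form <- match.arg(form)
  stopifnot(AP_max >= 0, AP_max <= 1, width > 0, rise_tau > 0, decay_tau > 0)
  structure(list(form = form, AP_max = AP_max, t_peak = t_peak,
                 width = width, onset_lag = onset_lag,
                 rise_tau = rise_tau, decay_tau = decay_tau),
            class = "activationProfile")
}

#' Evaluate an activation profile
#'
#' For an isolated twitch (`period = NULL`) the Gaussian pulse peaks at
#' `t_peak`. In periodic mode the pulse onset sits at `phase * period` in
#' every cycle, the peak `onset_lag` ms later, and times are wrapped to the
#' nearest pulse image.
#'
#' @param t time, ms (vectorised).
#' @param profile an [activationProfile()].
#' @param phase activation phase as a cycle fraction in \[0,1).
#' @param period strain-cycle period, ms, or `NULL` for an isolated pulse.
#' @return AP values in \[0,1\].
#' @export
activationValue <- function(t, profile = activationProfile(), phase = 0,
                            period = NULL) {
  stopifnot(inherits(profile, "activationProfile"))
  if (profile$form == "constant") return(rep_len(profile$AP_max, length(t)))
  if (profile$form == "gaussian_pulse") {
    if (is.null(period)) {
      dtp <- t - profile$t_peak
    } else {
      tpk <- phase * period + profile$onset_lag
      dtp <- ((t - tpk + period / 2) %% period) - period / 2
    }
    return(profile$AP_max * exp(-(dtp / profile$width)^2))
  }
  # biexponential: (1 - e^(-t'/rise)) e^(-t'/decay), scaled to peak AP_max
  rise <- profile$rise_tau; decay <- profile$decay_tau
  tpkrel <- rise * log(1 + decay / rise)
  smax <- (1 - exp(-tpkrel / rise)) * exp(-tpkrel / decay)
  onset <- if (is.null(period)) profile$t_peak - tpkrel else phase * period
  tp <- if (is.null(period)) pmax(t - onset, 0) else (t - onset) %% period
  profile$AP_max * (1 - exp(-tp / rise)) * exp(-tp / decay) / smax
}

#' Work-loop protocol
#'
#' Sinusoidal length oscillation `L(t) = L0 (1 + (strain_pp/2) cos(2 pi f
#' t))`, so t = 0 is maximum length and the start of shortening (phase 0).
#' The activation pulse onset is placed at `phase * period` in every cycle.
#'
#' @param frequency oscillation frequency, Hz.
#' @param strain_pp peak-to-peak strain amplitude (0.10 = 10%).
#' @param phase activation phase, cycle fraction in \[0,1).
#' @param n_cycles number of strain cycles.
#' @param dt timestep, ms; one period must be a whole number of steps. The
#'   default (0.0125 ms, ~0.08 nm of sliding per step at 25 Hz, 10% strain)
#'   keeps the work integral insensitive to the discretisation; see the
#'   methods vignette for the convergence study.
#' @param lattice a [latticeTrajectory()] or `NULL` (constant spacing at the
#'   configured actin-myosin spacing).
#' @return an object of class `workLoopProtocol`.
#' @export
workLoopProtocol <- function(frequency = 25, strain_pp = 0.10, phase = 0,
                             n_cycles = 20, dt = 0.0125, lattice = NULL) {
  stopifnot(frequency > 0, strain_pp > 0, strain_pp < 1,
            phase >= 0, phase < 1, n_cycles >= 1, dt > 0)
  period <- 1000 / frequency
  if (abs(period / dt - round(period / dt)) > 1e-9)
    stop("one period must be a whole number of timesteps", call. = FALSE)
  structure(list(frequency = frequency, strain_pp = strain_pp, phase = phase,
                 n_cycles = as.integer(n_cycles), dt = dt, period = period,
                 lattice = lattice),
            class = "workLoopProtocol")
}

#' Stress and mass scaling convention
#'
#' Converts lattice forces to stress and work to mass-specific work. Each
#' thick filament is assigned the hexagonal unit-cell cross-section
#' `(2/sqrt(3)) d10^2`; the muscle density converts the stress-strain loop
#' integral to J/kg.
#'
#' @param d10 reference d10 spacing for the cross-sectional area, nm.
#' @param cell_area_per_thick cross-sectional area per thick filament, nm^2.
#' @param density muscle density, kg/m^3.
#' @param n_thick thick filaments sharing the measured force.
#' @return an object of class `scalingConvention`.
#' @export
scalingConvention <- function(d10 = 47.5,
                              cell_area_per_thick = (2 / sqrt(3)) * d10^2,
                              density = 1060, n_thick = 4L) {
  stopifnot(cell_area_per_thick > 0, density > 0, n_thick >= 1)
  structure(list(d10 = d10, cell_area_per_thick = cell_area_per_thick,
                 density = density, n_thick = as.integer(n_thick)),
            class = "scalingConvention")
}

#' Convert net lattice force to stress
#'
#' `sigma = F / (n_thick * cell_area_per_thick)`, reported in mN/mm^2 (=
#' kPa).
#'
#' @param force net axial force of the simulated unit, pN (vectorised).
#' @param scaling a [scalingConvention()].
#' @return stress in mN/mm^2.
#' @export
stressFromForce <- function(force, scaling = scalingConvention()) {
  1e3 * force / (scaling$n_thick * scaling$cell_area_per_thick)
}

#' Net mass-specific work per cycle from a stress-strain series
#'
#' `W = -(1/rho) * closed-loop integral of sigma d epsilon` per cycle
#' (trapezoidal rule), positive when stress is higher during shortening
#' (motor-like).
#'
#' @param stress stress series, mN/mm^2.
#' @param strain strain series (dimensionless), same length.
#' @param scaling a [scalingConvention()] (only `density` is used).
#' @param samples_per_cycle steps per strain cycle; the series must hold an
#'   integer number of cycles plus the shared initial sample.
#' @return numeric vector of net work per cycle, J/kg.
#' @export
netWork <- function(stress, strain, scaling = scalingConvention(),
                    samples_per_cycle) {
  n <- length(stress)
  stopifnot(length(strain) == n)
  if (samples_per_cycle < 2 || (n - 1) %% samples_per_cycle != 0)
    stop("series must cover a whole number of cycles", call. = FALSE)
  ncyc <- (n - 1) %/% samples_per_cycle
  vapply(seq_len(ncyc), function(c) {
    i <- ((c - 1) * samples_per_cycle + 1):(c * samples_per_cycle + 1)
    s <- 1e3 * stress[i]  # mN/mm^2 -> Pa
    e <- strain[i]
    -sum(0.5 * (s[-1] + s[-length(s)]) * diff(e)) / scaling$density
  }, numeric(1))
}

## ---- core driver plumbing -------------------------------------------------

# run the compiled loop over the drive arrays and fold results back into st
.runCore <- function(st, cfgAll, hsV, amV, apV, dt) {
  cfg <- st$config
  out <- sim_core(st$thickX, st$thinX, st$headState, st$headR, st$headTheta,
                  st$boundSite, st$siteOcc,
                  st$headThick, st$headCrown, st$headThin, st$headPhase,
                  st$hsLength, st$am, cfg$thick_radius + cfg$thin_radius,
                  st$titinRest,
                  unclass(cfgAll$xb), unclass(cfgAll$rates),
                  unclass(cfgAll$springs), unclass(cfgAll$titin),
                  cfgAll$solver$tol, cfgAll$solver$max_iter,
                  hsV, amV, apV, dt)
  st$thickX <- out$thickX; st$thinX <- out$thinX
  st$headState <- out$headState; st$headR <- out$headR
  st$headTheta <- out$headTheta; st$boundSite <- out$boundSite
  st$siteOcc <- out$siteOcc
  st$hsLength <- hsV[length(hsV)]; st$am <- amV[length(amV)]
  st$time <- st$time + dt * length(hsV)
  st$equilibrated <- TRUE
  list(state = st, series = out)
}

# initial equilibrated state at a possibly non-rest length/spacing
.initState <- function(cfgAll, hs0, am0) {
  st <- buildHalfSarcomere(cfgAll$lattice, cfgAll$springs, cfgAll$titin)
  st$thinX <- st$thinX + (hs0 - st$hsLength)
  st$hsLength <- hs0
  st$am <- am0
  solveEquilibrium(st, cfgAll$springs, cfgAll$titin, cfgAll$xb,
                   cfgAll$solver)
}

# count bound heads and their axial forces in an equilibrated state
.boundForces <- function(st, xb) {
  nn <- st$config$nodes_per_thin
  fW <- fS <- 0; nW <- nS <- 0L
  for (i in which(st$headState > 1L)) {
    g <- st$headThin[i]; j <- st$boundSite[i] - (g - 1L) * nn
    dx <- st$thinX[j, g] - st$thickX[st$headCrown[i], st$headThick[i]]
    gax <- .xbAxialGrad(dx, st$am,
                        if (st$headState[i] == 2L) "weak" else "strong", xb)
    if (st$headState[i] == 2L) { fW <- fW + gax; nW <- nW + 1L }
    else { fS <- fS + gax; nS <- nS + 1L }
  }
  list(fWeak = fW, fStrong = fS, nWeak = nW, nStrong = nS)
}

#' Advance the simulation by one timestep
#'
#' Reference (R-level) composition of one step of the per-timestep loop:
#' thermal forcing of unbound heads, stochastic transitions at the current
#' actin permissiveness and geometry, prescribed length / lattice-spacing
#' update, then force balancing. The integrated drivers run the same loop in
#' compiled code.
#'
#' @param st a `halfSarcomere` state (equilibrated).
#' @param config a [runConfig()].
#' @param ap actin permissiveness during this step.
#' @param hs_new half-sarcomere length at the end of the step, nm.
#' @param am_new actin-myosin spacing at the end of the step, nm.
#' @param dt timestep, ms.
#' @return the updated, equilibrated state.
#' @export
runTimestep <- function(st, config = runConfig(), ap, hs_new = st$hsLength,
                        am_new = st$am, dt = 1) {
  draws <- thermalStep(sum(st$headState == 1L), config$xb)
  st$headR[st$headState == 1L] <- draws$r
  st$headTheta[st$headState == 1L] <- draws$theta
  st <- attemptTransitions(st, config$xb, config$rates, ap, dt)
  st$thinX <- st$thinX + (hs_new - st$hsLength)
  st$hsLength <- hs_new
  st$am <- am_new
  st$time <- st$time + dt
  solveEquilibrium(st, config$springs, config$titin, config$xb,
                   config$solver)
}

## ---- protocol drivers -----------------------------------------------------

.traceDF <- function(t, hs, strain, force, stress, ap, series0, series) {
  data.frame(
    t = t, hs_length = hs, strain = strain, force = force, stress = stress,
    ap = ap,
    n_weak = c(series0$nWeak, series$nWeak),
    n_strong = c(series0$nStrong, series$nStrong),
    f_weak = c(series0$fWeak, series$fWeak),
    f_strong = c(series0$fStrong, series$fStrong),
    f_titin = c(series0$titinF, series$titinF))
}

#' Simulate an isometric twitch
#'
#' Holds the half-sarcomere at rest length under a single activation pulse
#' (default: Gaussian, peak 0.73 at 40 ms, width 14 ms) and records the
#' force response.
#'
#' @param config a [runConfig()].
#' @param duration simulated time, ms.
#' @param seed integer seed for the Monte Carlo draws (optional).
#' @return an object of class `sarcTrace` with the time series and scaling.
#' @export
simulateTwitch <- function(config = runConfig(), duration = 200,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- config$protocol$dt
  nsteps <- ceiling(duration / dt)
  tEnd <- seq_len(nsteps) * dt
  am <- config$lattice$am_spacing
  hs0 <- config$lattice$rest_sarcomere_length * 1e3 / 2
  apV <- activationValue(tEnd - dt, config$activation)
  st <- .initState(config, hs0, am)
  b0 <- .boundForces(st, config$xb)
  series0 <- list(nWeak = b0$nWeak, nStrong = b0$nStrong, fWeak = b0$fWeak,
                  fStrong = b0$fStrong, titinF = NA_real_)
  f0 <- netAxialForce(st, config$springs)
  run <- .runCore(st, config, rep(hs0, nsteps), rep(am, nsteps), apV, dt)
  scl <- scalingConvention(d10 = d10FromAm(am, config$lattice$muscle_type),
                           density = config$scaling$density,
                           n_thick = config$lattice$n_thick)
  force <- c(f0, run$series$force)
  tr <- .traceDF(c(0, tEnd), rep(hs0, nsteps + 1), rep(0, nsteps + 1),
                 force, stressFromForce(force, scl),
                 activationValue(c(0, tEnd), config$activation),
                 series0, run$series)
  structure(list(series = tr, scaling = scl, config = config,
                 kind = "twitch", seed = seed,
                 state = run$state),
            class = "sarcTrace")
}

#' Simulate an isometric tetanus
#'
#' Activation is held at 1 (all binding sites available) at rest length;
#' reports the force plateau and the calibration statistics: mean axial force
#' per bound crossbridge and per strongly bound crossbridge over the plateau
#' (second half of the simulation).
#'
#' @inheritParams simulateTwitch
#' @param duration simulated time, ms.
#' @param level constant actin permissiveness (1 = saturating activation).
#' @return an object of class `sarcTrace`; component `plateau` holds the
#'   plateau statistics.
#' @export
simulateTetanus <- function(config = runConfig(), duration = 300,
                            seed = NULL, level = 1) {
  if (!is.null(seed)) set.seed(seed)
  dt <- config$protocol$dt
  nsteps <- ceiling(duration / dt)
  tEnd <- seq_len(nsteps) * dt
  am <- config$lattice$am_spacing
  hs0 <- config$lattice$rest_sarcomere_length * 1e3 / 2
  st <- .initState(config, hs0, am)
  b0 <- .boundForces(st, config$xb)
  series0 <- list(nWeak = b0$nWeak, nStrong = b0$nStrong, fWeak = b0$fWeak,
                  fStrong = b0$fStrong, titinF = NA_real_)
  f0 <- netAxialForce(st, config$springs)
  run <- .runCore(st, config, rep(hs0, nsteps), rep(am, nsteps),
                  rep(level, nsteps), dt)
  scl <- scalingConvention(d10 = d10FromAm(am, config$lattice$muscle_type),
                           density = config$scaling$density,
                           n_thick = config$lattice$n_thick)
  force <- c(f0, run$series$force)
  tr <- .traceDF(c(0, tEnd), rep(hs0, nsteps + 1), rep(0, nsteps + 1),
                 force, stressFromForce(force, scl),
                 rep(level, nsteps + 1), series0, run$series)
  pl <- tr$t > duration / 2
  nBound <- tr$n_weak[pl] + tr$n_strong[pl]
  fXb <- tr$f_weak[pl] + tr$f_strong[pl]
  plateau <- list(
    force_mean = mean(tr$force[pl]), force_sd = sd(tr$force[pl]),
    stress_mean = mean(tr$stress[pl]),
    n_weak_mean = mean(tr$n_weak[pl]), n_strong_mean = mean(tr$n_strong[pl]),
    force_per_bound = sum(fXb) / max(sum(nBound), 1),
    force_per_strong = sum(tr$f_strong[pl]) / max(sum(tr$n_strong[pl]), 1))
  structure(list(series = tr, scaling = scl, config = config,
                 kind = "tetanus", seed = seed, plateau = plateau,
                 state = run$state),
            class = "sarcTrace")
}

#' @export
print.sarcTrace <- function(x, ...) {
  cat(sprintf("sarclat %s trace: %d samples over %.0f ms\n", x$kind,
              nrow(x$series), max(x$series$t)))
  cat(sprintf("  peak stress %.2f mN/mm^2 at t = %.0f ms\n",
              max(x$series$stress),
              x$series$t[which.max(x$series$stress)]))
  if (!is.null(x$plateau))
    cat(sprintf(
      "  plateau: %.1f pN (%.2f mN/mm^2), %.1f weak / %.1f strong heads,\n  %.2f pN per bound and %.2f pN per strongly bound crossbridge\n",
      x$plateau$force_mean, x$plateau$stress_mean, x$plateau$n_weak_mean,
      x$plateau$n_strong_mean, x$plateau$force_per_bound,
      x$plateau$force_per_strong))
  invisible(x)
}

#' Simulate a work loop
#'
#' Runs `n_cycles` sinusoidal strain cycles with periodic activation and a
#' prescribed lattice-spacing trajectory, and integrates the stress-strain
#' loop into net mass-specific work per cycle.
#'
#' @param protocol a [workLoopProtocol()].
#' @param config a [runConfig()].
#' @param seed integer seed (optional but recommended; runs are bit
#'   reproducible given the seed).
#' @return an object of class `workLoopResult`: time series (`series`),
#'   per-cycle net work (`work_per_cycle`, J/kg), `work_mean`, `work_sd`,
#'   the protocol, scaling and final state.
#' @export
simulateWorkLoop <- function(protocol = workLoopProtocol(),
                             config = runConfig(), seed = NULL) {
  stopifnot(inherits(protocol, "workLoopProtocol"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config$lattice
  dt <- protocol$dt
  period <- protocol$period
  spc <- round(period / dt)
  if (abs(period / dt - spc) > 1e-9)
    stop("one period must be a whole number of timesteps", call. = FALSE)
  nsteps <- protocol$n_cycles * spc
  tEnd <- seq_len(nsteps) * dt
  L0 <- cfg$rest_sarcomere_length * 1e3 / 2
  amp <- protocol$strain_pp / 2

  lattice <- protocol$lattice
  if (is.null(lattice))
    lattice <- latticeTrajectory("constant",
                                 d_rest = d10FromAm(cfg$am_spacing,
                                                    cfg$muscle_type))
  strainAt <- function(t) amp * cos(2 * pi * t / period)
  amAt <- function(t) amFromD10(latticeSpacingAt(lattice, strainAt(t),
                                                 (t %% period) / period),
                                cfg$muscle_type)
  hsV <- L0 * (1 + strainAt(tEnd))
  amV <- amAt(tEnd)
  apV <- activationValue(tEnd - dt, config$activation, protocol$phase,
                         period)

  st <- .initState(config, L0 * (1 + strainAt(0)), amAt(0))
  b0 <- .boundForces(st, config$xb)
  series0 <- list(nWeak = b0$nWeak, nStrong = b0$nStrong, fWeak = b0$fWeak,
                  fStrong = b0$fStrong, titinF = NA_real_)
  f0 <- netAxialForce(st, config$springs)
  run <- .runCore(st, config, hsV, amV, apV, dt)

  scl <- scalingConvention(d10 = lattice$d_rest,
                           density = config$scaling$density,
                           n_thick = cfg$n_thick)
  force <- c(f0, run$series$force)
  strain <- strainAt(c(0, tEnd))
  stress <- stressFromForce(force, scl)
  tr <- .traceDF(c(0, tEnd), c(L0 * (1 + strain[1]), hsV), strain, force,
                 stress,
                 activationValue(c(0, tEnd), config$activation,
                                 protocol$phase, period),
                 series0, run$series)
  tr$d10 <- latticeSpacingAt(lattice, strain, (c(0, tEnd) %% period) / period)
  w <- netWork(stress, strain, scl, spc)
  structure(list(series = tr, work_per_cycle = w, work_mean = mean(w),
                 work_sd = sd(w), protocol = protocol, scaling = scl,
                 config = config, seed = seed, state = run$state),
            class = "workLoopResult")
}

#' @export
print.workLoopResult <- function(x, ...) {
  p <- x$protocol
  cat(sprintf(
    "work loop: %g Hz, %.0f%% peak-to-peak strain, phase %.2f, %d cycles\n",
    p$frequency, 100 * p$strain_pp, p$phase, p$n_cycles))
  lt <- if (is.null(p$lattice)) "constant" else p$lattice$mode
  cat(sprintf("  lattice: %s, d10 %.2f nm (AM %.2f nm)\n", lt,
              x$scaling$d10,
              amFromD10(x$scaling$d10, x$config$lattice$muscle_type)))
  cat(sprintf("  net work %.3f +/- %.3f J/kg (mean +/- s.d. over %d cycles)\n",
              x$work_mean, x$work_sd, length(x$work_per_cycle)))
  invisible(x)
}

#' Sweep a protocol parameter and collect net work
#'
#' Runs [simulateWorkLoop()] over a grid of one protocol dimension with
#' deterministic per-point seeds derived from `seed`, collecting net-work
#' mean and s.d. per point into a tidy data frame.
#'
#' * `"phase"`: activation phase, default grid 0 to 0.95 in steps of 0.05.
#' * `"lattice"`: constant actin-myosin spacing, default 12 to 18 nm.
#' * `"stiffness"`: crossbridge stiffness factors (0.5x, 1x, 1.5x) applied to
#'   the linear and torsional spring separately.
#' * `"titin"`: titin exponential stiffness b, default 0.004 to 0.010 1/nm.
#'
#' @param kind sweep dimension, see above.
#' @param grid grid values (vector; for `"stiffness"` a data frame with
#'   columns `spring` ("kr"/"ktheta") and `factor`); `NULL` for the default.
#' @param config a [runConfig()].
#' @param protocol base [workLoopProtocol()].
#' @param seed master seed; point i runs with `seed + i`.
#' @return a data frame with the grid, `work_mean`, `work_sd`, `n_cycles`,
#'   `seed` per point.
#' @export
sweepNetWork <- function(kind = c("phase", "lattice", "stiffness", "titin"),
                         grid = NULL, config = runConfig(),
                         protocol = workLoopProtocol(), seed = 1) {
  kind <- match.arg(kind)
  if (is.null(grid))
    grid <- switch(kind,
                   phase = seq(0, 0.95, by = 0.05),
                   lattice = 12:18,
                   stiffness = expand.grid(spring = c("kr", "ktheta"),
                                           factor = c(0.5, 1, 1.5),
                                           stringsAsFactors = FALSE),
                   titin = c(0.004, 0.007, 0.010))
  pts <- if (is.data.frame(grid)) nrow(grid) else length(grid)
  stopifnot(pts >= 1)
  rows <- vector("list", pts)
  for (i in seq_len(pts)) {
    cfg_i <- config
    prot_i <- protocol
    label <- NULL
    if (kind == "phase") {
      prot_i$phase <- grid[i]
      label <- data.frame(phase = grid[i])
    } else if (kind == "lattice") {
      cfg_i$lattice$am_spacing <- grid[i]
      label <- data.frame(am_spacing = grid[i])
    } else if (kind == "stiffness") {
      sp <- grid$spring[i]; fac <- grid$factor[i]
      cfg_i$xb[[sp]] <- cfg_i$xb[[sp]] * fac
      label <- data.frame(spring = sp, factor = fac)
    } else {
      cfg_i$titin$b <- grid[i]
      label <- data.frame(titin_b = grid[i])
    }
    seed_i <- seed + i
    res <- tryCatch(simulateWorkLoop(prot_i, cfg_i, seed = seed_i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("sweep point %d failed: %s", i, conditionMessage(res)))
      rows[[i]] <- cbind(label, work_mean = NA_real_, work_sd = NA_real_,
                         n_cycles = prot_i$n_cycles, seed = seed_i)
    } else {
      rows[[i]] <- cbind(label, work_mean = res$work_mean,
                         work_sd = res$work_sd,
                         n_cycles = prot_i$n_cycles, seed = seed_i)
    }
  }
  do.call(rbind, rows)
}
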