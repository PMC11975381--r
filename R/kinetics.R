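## Crossbridge kinetics: two-spring head energetics, three-state rate
## functions, transition probabilities, thermal forcing.

#' Two-spring crossbridge parameters
#'
#' Each myosin head is a torsional spring at its base (stiffness `ktheta`)
#' in series with a linear spring in the arm (stiffness `kr`). The power
#' stroke is a change of the rest length and rest angle: weak state
#' (rW, thetaW) to strong state (rS, thetaS). Angles are supplied in degrees
#' and stored in radians. `kT` is the thermal energy used to express free
#' energies (4.11 pN nm at 298 K).
#'
#' @param kr linear spring stiffness, pN/nm.
#' @param ktheta torsional spring stiffness, pN nm/rad^2.
#' @param rW,rS rest lengths of the weak and strong state, nm.
#' @param thetaW,thetaS rest angles of the weak and strong state, degrees
#'   (measured from the filament axis, increasing toward the thin filament).
#' @param kT thermal energy, pN nm.
#' @return an object of class `crossbridgeParams` (angles in radians).
#' @export
crossbridgeParams <- function(kr = 16, ktheta = 4000,
                              rW = 19.93, rS = 16.4,
                              thetaW = 47.16, thetaS = 73.2,
                              kT = 4.11) {
  stopifnot(kr > 0, ktheta > 0, kT > 0, rS < rW, thetaS > thetaW)
  structure(list(kr = kr, ktheta = ktheta, rW = rW, rS = rS,
                 thetaW = .deg2rad(thetaW), thetaS = .deg2rad(thetaS),
                 kT = kT),
            class = "crossbridgeParams")
}

#' Rate-function constants of the three-state scheme
#'
#' Constants of the binding, power-stroke and detachment rate functions, all
#' in 1/ms: `r12 = AP (tau e^(-d^2) + baseline)`,
#' `r23 = A (1 + tanh(C + D (U1 - U2)))`, `r31 = G Edist + H`, with reverse
#' rates from detailed balance `rji = rij e^(Ui - Uj)` and `r13 = 0`.
#' `dG_weak` and `dG_strong` are the free-energy drops (in kT) of the weakly
#' and strongly bound states relative to unbound; they are not spelled out by
#' the rate table and are exposed as calibrated configuration values (see the
#' methods vignette for the calibration against isometric tetanic force per
#' crossbridge).
#'
#' @param tau binding rate amplitude, 1/ms.
#' @param baseline distance-independent binding floor, 1/ms; through detailed
#'   balance it enforces the steep rise of the unbinding rate at extreme
#'   strain.
#' @param A,C,D power-stroke rate constants (A in 1/ms, C, D dimensionless;
#'   D multiplies a free-energy difference in kT).
#' @param G detachment rate slope, 1/ms per kT of strong-state distortion.
#' @param H detachment rate floor, 1/ms.
#' @param dG_weak,dG_strong free-energy drops of states 2 and 3, kT.
#' @param r31_shifted if `TRUE`, the detachment rate is driven by the full
#'   strong-state free energy `U2 = Estrong/kT - dG_strong` (clamped at 0),
#'   so low-distortion strong heads detach at the floor rate `H` and
#'   detachment switches on once the distortion exceeds `dG_strong`; if
#'   `FALSE`, by the distortion energy alone.
#' @return an object of class `rateConstants`.
#' @export
rateConstants <- function(tau = 72, baseline = 0.005,
                          A = 0.8, C = 6, D = 0.2, G = 0.6, H = 0.02,
                          dG_weak = 2, dG_strong = 140,
                          r31_shifted = FALSE) {
  stopifnot(tau >= 0, baseline >= 0, A >= 0, G >= 0, H >= 0,
            dG_strong > dG_weak)
  structure(list(tau = tau, baseline = baseline, A = A, C = C, D = D,
                 G = G, H = H, dG_weak = dG_weak, dG_strong = dG_strong,
                 r31_shifted = isTRUE(r31_shifted)),
            class = "rateConstants")
}

#' Elastic energy of a myosin head
#'
#' Sum of the two quadratic spring energies about the rest configuration of
#' the given state: `U = 1/2 kr (r - r0)^2 + 1/2 ktheta (theta - theta0)^2`.
#'
#' @param r head length (base to tip), nm; must be > 0.
#' @param theta head angle from the filament axis, radians.
#' @param state `"weak"` or `"strong"`.
#' @param p a [crossbridgeParams()].
#' @return energy in pN nm (vectorised).
#' @export
headEnergy <- function(r, theta, state = c("weak", "strong"),
                       p = crossbridgeParams()) {
  state <- match.arg(state)
  stopifnot(all(r > 0))
  r0 <- if (state == "weak") p$rW else p$rS
  t0 <- if (state == "weak") p$thetaW else p$thetaS
  0.5 * p$kr * (r - r0)^2 + 0.5 * p$ktheta * (theta - t0)^2
}

#' Force exerted by a myosin head at its tip
#'
#' Negative gradient of [headEnergy()] with respect to the tip position,
#' decomposed into axial (along the filament) and radial components. The
#' linear spring contributes a tension `kr (r - r0)` along the arm and the
#' torsional spring a transverse force `ktheta (theta - theta0) / r`.
#'
#' @inheritParams headEnergy
#' @return a list with components `axial` and `radial`, pN (vectorised).
#' @export
headForce <- function(r, theta, state = c("weak", "strong"),
                      p = crossbridgeParams()) {
  state <- match.arg(state)
  if (any(r == 0)) stop("singular geometry: r = 0", call. = FALSE)
  r0 <- if (state == "weak") p$rW else p$rS
  t0 <- if (state == "weak") p$thetaW else p$thetaS
  fl <- -p$kr * (r - r0)            # restoring force along the arm
  ft <- -p$ktheta * (theta - t0) / r  # restoring transverse force
  list(axial = fl * cos(theta) - ft * sin(theta),
       radial = fl * sin(theta) + ft * cos(theta))
}

#' State free energies of a head relative to a binding site
#'
#' The bound-state geometry is set by the axial offset `dx` between the
#' head's anchor node and the site, and the radial actin-myosin gap `am`:
#' `r = sqrt(dx^2 + am^2)`, `theta = atan2(am, dx)`. Free energies in kT:
#' `U0 = 0` (unbound reference), `U1 = Eweak/kT - dG_weak`,
#' `U2 = Estrong/kT - dG_strong`.
#'
#' @param dx axial offset site minus anchor, nm.
#' @param am radial actin-myosin gap, nm.
#' @param p a [crossbridgeParams()].
#' @param rc a [rateConstants()].
#' @return a list with `U0`, `U1`, `U2` (kT), the distortion energies
#'   `ew_kT`, `es_kT` (kT) and the bound geometry `r`, `theta`.
#' @export
stateFreeEnergies <- function(dx, am, p = crossbridgeParams(),
                              rc = rateConstants()) {
  r <- sqrt(dx^2 + am^2)
  theta <- atan2(am, dx)
  ew <- headEnergy(r, theta, "weak", p) / p$kT
  es <- headEnergy(r, theta, "strong", p) / p$kT
  list(U0 = 0, U1 = ew - rc$dG_weak, U2 = es - rc$dG_strong,
       ew_kT = ew, es_kT = es, r = r, theta = theta)
}

#' Binding rate r12
#'
#' `r12 = AP (tau e^(-d^2) + baseline)`, with `d` the axial separation (nm)
#' between the (thermally displaced) head tip and the candidate binding site,
#' and `AP` the actin permissiveness in \[0,1\] (0 blocks binding entirely).
#' The radial lattice spacing enters the cycle through the bound-state
#' distortion energies, not through `d`.
#'
#' @param d axial tip-to-site separation, nm (>= 0).
#' @param AP actin permissiveness in \[0,1\].
#' @param rc a [rateConstants()].
#' @return rate in 1/ms (vectorised).
#' @export
rateR12 <- function(d, AP = 1, rc = rateConstants()) {
  stopifnot(all(d >= 0), all(AP >= 0 & AP <= 1))
  AP * (rc$tau * exp(-d^2) + rc$baseline)
}

# exp with overflow guard: rates above ~1e30/ms saturate the per-step
# probability at 1 anyway
.expCap <- function(x) exp(pmin(x, 700))

#' All six transition rates of the three-state scheme
#'
#' Forward rates: `r12` as in [rateR12()]; `r23 = A (1 + tanh(C + D (U1 -
#' U2)))`; `r31 = max(0, G * U2 + H)` with `U2` the strong-state free energy
#' (or its distortion part if `r31_shifted = FALSE`) — the irreversible
#' ATP-consuming step, steepening with strain (`r13 = 0`). Reverse rates
#' from detailed balance of the unblocked chain: `r21 = (tau e^(-d^2) +
#' baseline) e^(U1 - U0)` (not multiplied by AP, so bound heads release after
#' activation ends) and `r32 = r23 e^(U2 - U1)`. For a bound head `d` is the
#' axial separation between the site and the tip the head would have at its
#' weak rest configuration, so at extreme strain `r21 ~ baseline *
#' e^(distortion/kT)` rises steeply (the baseline enforces the "infinite
#' well" of the unbinding rate).
#'
#' @param en free energies from [stateFreeEnergies()].
#' @param d axial tip-to-site separation for the binding leg, nm.
#' @param AP actin permissiveness in \[0,1\].
#' @param rc a [rateConstants()].
#' @return a list of rates `r12, r21, r23, r32, r31, r13` in 1/ms.
#' @export
ratesAll <- function(en, d, AP = 1, rc = rateConstants()) {
  base12 <- rc$tau * exp(-d^2) + rc$baseline
  r12 <- AP * base12
  r21 <- base12 * .expCap(en$U1 - en$U0)
  r23 <- rc$A * (1 + tanh(rc$C + rc$D * (en$U1 - en$U2)))
  r32 <- r23 * .expCap(en$U2 - en$U1)
  e31 <- if (isTRUE(rc$r31_shifted)) en$U2 else en$es_kT
  r31 <- pmax(0, rc$G * e31 + rc$H)
  list(r12 = r12, r21 = r21, r23 = r23, r32 = r32, r31 = r31, r13 = 0)
}

#' Per-step transition probabilities from rates
#'
#' For exit rates `r` out of the current state over a timestep `dt`, the
#' total exit probability is `1 - e^(-sum(r) dt)`, apportioned among
#' destinations proportionally to their rates (competing risks).
#'
#' @param rates numeric vector of exit rates, 1/ms.
#' @param dt timestep, ms.
#' @return vector of per-destination probabilities (sums to <= 1).
#' @export
transitionProbabilities <- function(rates, dt) {
  stopifnot(dt > 0, all(rates >= 0))
  tot <- sum(rates)
  if (tot == 0) return(rep(0, length(rates)))
  (1 - exp(-tot * dt)) * rates / tot
}

#' Thermal forcing of unbound heads
#'
#' Draws head length and angle from the Boltzmann distribution of the two
#' independent quadratic springs about the weak rest configuration:
#' `r ~ N(rW, sqrt(kT/kr))`, `theta ~ N(thetaW, sqrt(kT/ktheta))`; draws with
#' `r <= 0` are redrawn.
#'
#' @param n number of heads.
#' @param p a [crossbridgeParams()].
#' @return a list with vectors `r` (nm) and `theta` (rad).
#' @export
thermalStep <- function(n, p = crossbridgeParams()) {
  r <- rnorm(n, p$rW, sqrt(p$kT / p$kr))
  bad <- which(r <= 0)
  while (length(bad)) {
    r[bad] <- rnorm(length(bad), p$rW, sqrt(p$kT / p$kr))
    bad <- bad[r[bad] <= 0]
  }
  theta <- rnorm(n, p$thetaW, sqrt(p$kT / p$ktheta))
  list(r = r, theta = theta)
}

## ---- state-level kinetics (reference implementation) ----------------------

# Nearest eligible site for head i given its thermally displaced tip.
# Returns list(j, d) or NULL. Candidates: the axially nearest eligible node
# and its two neighbours one target-zone repeat away; occupied nodes are
# skipped; ties broken toward the M-line (larger j).
.candidateSite <- function(st, i, tipX) {
  g <- st$headThin[i]; ph <- st$headPhase[i]
  nn <- st$config$nodes_per_thin
  xg <- st$thinX[, g]
  elig <- seq.int(if (ph == 0L) 3L else ph, nn, by = 3L)
  dax <- abs(tipX - xg[elig])
  jbest <- elig[order(dax, -elig)[1]]
  cand <- jbest + c(-3L, 0L, 3L)
  cand <- cand[cand >= 1L & cand <= nn]
  cand <- cand[st$siteOcc[.siteIndex(st, g, cand)] == 0L]
  if (!length(cand)) return(NULL)
  d <- abs(tipX - xg[cand])
  j <- cand[order(d, -cand)[1]]
  list(j = j, d = min(d))
}

#' Attempt stochastic state transitions for every head
#'
#' Reference (R-level) implementation of one kinetic substep: each unbound
#' head targets the nearest eligible unoccupied site on its facing thin
#' filament and attempts to bind with probability from [rateR12()] on the
#' axial tip-to-site separation; weakly bound heads may unbind (releasing
#' the site) or execute the power stroke; strongly bound heads may reverse
#' the stroke or detach. Site occupancy remains one-to-one. The integrated
#' simulation drivers use a compiled implementation of the same rules.
#'
#' @param st a `halfSarcomere` state.
#' @param xb a [crossbridgeParams()].
#' @param rc a [rateConstants()].
#' @param AP actin permissiveness at this instant, \[0,1\].
#' @param dt timestep, ms.
#' @return the updated state (`equilibrated` is invalidated).
#' @export
attemptTransitions <- function(st, xb = crossbridgeParams(),
                               rc = rateConstants(), AP, dt) {
  stopifnot(inherits(st, "halfSarcomere"), AP >= 0, AP <= 1, dt > 0)
  nn <- st$config$nodes_per_thin
  for (i in seq_along(st$headState)) {
    f <- st$headThick[i]; cidx <- st$headCrown[i]
    xa <- st$thickX[cidx, f]
    s <- st$headState[i]
    if (s == 1L) {
      tipX <- xa + st$headR[i] * cos(st$headTheta[i])
      cs <- .candidateSite(st, i, tipX)
      if (is.null(cs)) next
      p12 <- 1 - exp(-rateR12(cs$d, AP, rc) * dt)
      if (runif(1) < p12) {
        g <- st$headThin[i]
        st$headState[i] <- 2L
        st$boundSite[i] <- .siteIndex(st, g, cs$j)
        st$siteOcc[st$boundSite[i]] <- i
        dx <- st$thinX[cs$j, g] - xa
        st$headR[i] <- sqrt(dx^2 + st$am^2)
        st$headTheta[i] <- atan2(st$am, dx)
      }
    } else {
      g <- st$headThin[i]
      j <- st$boundSite[i] - (g - 1L) * nn
      dx <- st$thinX[j, g] - xa
      en <- stateFreeEnergies(dx, st$am, xb, rc)
      dW <- abs(xa + xb$rW * cos(xb$thetaW) - st$thinX[j, g])
      rt <- ratesAll(en, dW, AP, rc)
      if (s == 2L) {
        pr <- transitionProbabilities(c(rt$r21, rt$r23), dt)
        u <- runif(1)
        if (u < pr[1]) {            # unbind
          st$siteOcc[st$boundSite[i]] <- 0L
          st$boundSite[i] <- 0L
          st$headState[i] <- 1L
          st$headR[i] <- xb$rW; st$headTheta[i] <- xb$thetaW
        } else if (u < pr[1] + pr[2]) {
          st$headState[i] <- 3L     # power stroke
        }
      } else {                      # strong
        pr <- transitionProbabilities(c(rt$r32, rt$r31), dt)
        u <- runif(1)
        if (u < pr[1]) {
          st$headState[i] <- 2L     # reverse stroke
        } else if (u < pr[1] + pr[2]) {
          st$siteOcc[st$boundSite[i]] <- 0L
          st$boundSite[i] <- 0L
          st$headState[i] <- 1L
          st$headR[i] <- xb$rW; st$headTheta[i] <- xb$thetaW
        }
      }
    }
  }
  st$equilibrated <- FALSE
  st
}
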