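## Filament mechanics: compliant thick/thin chains, titin, axial force
## balance.

#' Filament chain spring constants
#'
#' Thick and thin filaments are series chains of linear springs; stiffnesses
#' are per-segment values scaled from empirical whole-filament estimates by
#' the crown / binding-site repeat distances.
#'
#' @param k_thick,k_thin segment stiffness, pN/nm.
#' @param l0_thick,l0_thin segment rest length, nm.
#' @return an object of class `filamentSpringParams`.
#' @export
filamentSpringParams <- function(k_thick = 2020, l0_thick = 14.3,
                                 k_thin = 1760, l0_thin = 12.2) {
  stopifnot(k_thick > 0, k_thin > 0, l0_thick > 0, l0_thin > 0)
  structure(list(k_thick = k_thick, l0_thick = l0_thick,
                 k_thin = k_thin, l0_thin = l0_thin),
            class = "filamentSpringParams")
}

#' Titin parameters
#'
#' Titin (or its insect analogues) ties each thick-filament tip to the
#' z-disk with an exponential spring `F = a e^(b dL)`, `dL` being the
#' end-to-end length change from the rest configuration.
#'
#' @param a force scale, pN.
#' @param b exponential stiffness, 1/nm.
#' @return an object of class `titinParams`.
#' @export
titinParams <- function(a = 220, b = 0.0045) {
  stopifnot(a >= 0, b >= 0)
  structure(list(a = a, b = b), class = "titinParams")
}

#' Equilibrium solver settings
#'
#' @param tol maximum admissible node residual, pN.
#' @param max_iter maximum relaxation passes.
#' @param scheme `"node_relaxation"` (damped filament-wise Newton relaxation;
#'   the only scheme currently implemented).
#' @return an object of class `solverSettings`.
#' @export
solverSettings <- function(tol = 0.1, max_iter = 100,
                           scheme = "node_relaxation") {
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter), scheme = scheme),
            class = "solverSettings")
}

#' Titin force
#'
#' `F = a e^(b dL)` along the titin end-to-end vector; the axial projection
#' enters the force balance (lattice spacing is prescribed, so the radial
#' component is reported but not balanced).
#'
#' @param delta_L end-to-end length change from rest, nm.
#' @param tp a [titinParams()].
#' @return force magnitude, pN (vectorised).
#' @export
titinForce <- function(delta_L, tp = titinParams()) {
  tp$a * exp(tp$b * delta_L)
}

# axial derivative of bound-head energy wrt the site position:
# g = dU/d(dx); force on the thin node is -g, reaction +g on the anchor.
.xbAxialGrad <- function(dx, am, state, xb) {
  r <- sqrt(dx^2 + am^2)
  theta <- atan2(am, dx)
  r0 <- if (state == "weak") xb$rW else xb$rS
  t0 <- if (state == "weak") xb$thetaW else xb$thetaS
  xb$kr * (r - r0) * (dx / r) - xb$ktheta * (theta - t0) * (am / r^2)
}

# titin axial force on a thick filament tip (positive toward the z-disk)
.titinAxial <- function(tipX, hs, radCC, titinRest, tp) {
  dxa <- hs - tipX
  L <- sqrt(dxa^2 + radCC^2)
  titinForce(L - titinRest, tp) * dxa / L
}

#' Per-node axial force residuals
#'
#' Net axial force on every free node: the two adjacent filament-spring
#' tensions, plus the axial crossbridge force for nodes anchoring a bound
#' head or carrying an occupied site, plus the titin axial load at each
#' thick-filament tip. Boundary attachments (thick filaments at the M-line,
#' thin filaments at the z-disk) are position-clamped and carry the reaction.
#'
#' @param st a `halfSarcomere` state.
#' @param springs a [filamentSpringParams()].
#' @param titin a [titinParams()].
#' @param xb a [crossbridgeParams()].
#' @return a list with matrices `thick` (crowns x n_thick) and `thin`
#'   (nodes x n_thin) of residuals in pN.
#' @export
nodeResiduals <- function(st, springs = filamentSpringParams(),
                          titin = titinParams(), xb = crossbridgeParams()) {
  cfg <- st$config
  nc <- cfg$crowns_per_thick; nn <- cfg$nodes_per_thin
  hs <- st$hsLength
  radCC <- st$am + cfg$thick_radius + cfg$thin_radius

  resThick <- matrix(0, nc, cfg$n_thick)
  for (f in seq_len(cfg$n_thick)) {
    x <- c(0, st$thickX[, f])  # clamped M-line anchor at 0
    ten <- springs$k_thick * (diff(x) - springs$l0_thick)
    resThick[, f] <- -ten + c(ten[-1], 0)
    resThick[nc, f] <- resThick[nc, f] +
      .titinAxial(st$thickX[nc, f], hs, radCC, st$titinRest, titin)
  }
  resThin <- matrix(0, nn, cfg$n_thin)
  for (g in seq_len(cfg$n_thin)) {
    x <- c(hs, st$thinX[, g])  # clamped z-disk anchor
    ten <- springs$k_thin * (-diff(x) - springs$l0_thin)
    # tension pulls node j toward the z-disk (+x) from the segment on its
    # z-side and toward the M-line (-x) from the segment on its M-side
    resThin[, g] <- ten - c(ten[-1], 0)
  }
  bound <- which(st$headState > 1L)
  for (i in bound) {
    f <- st$headThick[i]; cidx <- st$headCrown[i]
    g <- st$headThin[i]; j <- st$boundSite[i] - (g - 1L) * nn
    dx <- st$thinX[j, g] - st$thickX[cidx, f]
    gax <- .xbAxialGrad(dx, st$am,
                        if (st$headState[i] == 2L) "weak" else "strong", xb)
    resThick[cidx, f] <- resThick[cidx, f] + gax
    resThin[j, g] <- resThin[j, g] - gax
  }
  list(thick = resThick, thin = resThin)
}

#' Solve the axial force balance
#'
#' Iteratively adjusts every free node's axial position until the
#' instantaneous axial force on each node is below `tol`, holding the
#' bound-head attachment map and the prescribed lattice spacing fixed.
#' Filament-wise Newton relaxation: each chain is solved by a tridiagonal
#' Newton step with crossbridge and titin loads linearised about the current
#' configuration, sweeping chains in turn until the exact residuals converge.
#' Bound heads' (r, theta) are recomputed from the anchor-to-site geometry
#' afterwards.
#'
#' @inheritParams nodeResiduals
#' @param settings a [solverSettings()].
#' @param trace if `TRUE`, attach per-iteration residual and elastic energy
#'   (attribute `"solver"`).
#' @return the state with updated node positions and `equilibrated = TRUE`.
#' @export
solveEquilibrium <- function(st, springs = filamentSpringParams(),
                             titin = titinParams(), xb = crossbridgeParams(),
                             settings = solverSettings(), trace = FALSE) {
  stopifnot(inherits(st, "halfSarcomere"))
  out <- solve_eq_cpp(st$thickX, st$thinX, st$headState, st$boundSite,
                      st$headThick, st$headCrown, st$headThin,
                      st$hsLength, st$am,
                      st$am + st$config$thick_radius + st$config$thin_radius,
                      st$titinRest,
                      unclass(springs), unclass(titin), unclass(xb),
                      settings$tol, settings$max_iter, isTRUE(trace))
  if (!out$converged)
    stop(sprintf("equilibrium solver did not converge in %d iterations (worst residual %.3g pN)",
                 settings$max_iter, out$residual), call. = FALSE)
  st$thickX <- out$thickX
  st$thinX <- out$thinX
  nn <- st$config$nodes_per_thin
  for (i in which(st$headState > 1L)) {
    g <- st$headThin[i]; j <- st$boundSite[i] - (g - 1L) * nn
    dx <- st$thinX[j, g] - st$thickX[st$headCrown[i], st$headThick[i]]
    st$headR[i] <- sqrt(dx^2 + st$am^2)
    st$headTheta[i] <- atan2(st$am, dx)
  }
  st$equilibrated <- TRUE
  if (trace)
    attr(st, "solver") <- list(iterations = out$iterations,
                               residual = out$residual,
                               energy = out$energy)
  st
}

#' Net axial force of the half-sarcomere
#'
#' Sum over thick filaments of the tension in the spring adjacent to the
#' M-line (the axial force the lattice exerts on the M-line boundary);
#' positive = contractile.
#'
#' @param st an equilibrated `halfSarcomere` state.
#' @param springs a [filamentSpringParams()].
#' @return force in pN.
#' @export
netAxialForce <- function(st, springs = filamentSpringParams()) {
  if (!isTRUE(st$equilibrated))
    stop("stale state: call solveEquilibrium() before netAxialForce()",
         call. = FALSE)
  sum(springs$k_thick * (st$thickX[1, ] - springs$l0_thick))
}

#' Net axial force at the z-disk boundary
#'
#' Axial load carried by the z-disk: tension of the thin-filament segments
#' adjacent to the z-disk plus the axial titin load. By global balance this
#' equals [netAxialForce()] at the M-line within solver tolerance.
#'
#' @inheritParams nodeResiduals
#' @return force in pN.
#' @export
zDiskForce <- function(st, springs = filamentSpringParams(),
                       titin = titinParams()) {
  if (!isTRUE(st$equilibrated))
    stop("stale state: call solveEquilibrium() first", call. = FALSE)
  cfg <- st$config
  hs <- st$hsLength
  thin <- sum(springs$k_thin * (hs - st$thinX[1, ] - springs$l0_thin))
  radCC <- st$am + cfg$thick_radius + cfg$thin_radius
  tit <- sum(.titinAxial(st$thickX[cfg$crowns_per_thick, ], hs, radCC,
                         st$titinRest, titin))
  thin + tit
}
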