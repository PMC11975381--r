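## Lattice geometry: filament lattice construction, d10 <-> actin-myosin
## spacing conversion, and prescribed lattice-spacing trajectories.

#' Lattice configuration
#'
#' Geometry of the simulated half-sarcomere: a periodic unit of 4 thick and 8
#' thin filaments (2:1 thin:thick, thin filaments at the trigonal interstices
#' of the hexagonal thick-filament lattice). Thick filaments carry crowns of
#' three myosin heads every 14.3 nm; thin filaments are chains of 12.2 nm
#' segments whose nodes are potential binding sites. Every third thin node
#' faces a given neighbouring thick filament, giving the ~38.7 nm target-zone
#' repeat out of register with the 14.3 nm crown repeat.
#'
#' @param n_thick number of thick filaments in the periodic unit (4).
#' @param n_thin number of thin filaments; must equal `2 * n_thick`.
#' @param crowns_per_thick crowns (head triplets) per thick filament.
#' @param heads_per_crown heads per crown (3).
#' @param nodes_per_thin spring nodes (candidate binding sites) per thin
#'   filament.
#' @param thick_rest_segment,thin_rest_segment rest segment lengths, nm.
#' @param crown_azimuth_step azimuthal separation of the heads of one crown,
#'   degrees.
#' @param crown_rotation_pattern azimuthal rotation between successive crowns,
#'   degrees, recycled along the filament.
#' @param rest_sarcomere_length rest sarcomere length, micrometres (the
#'   simulated half-sarcomere is half this).
#' @param am_spacing face-to-face actin-myosin spacing, nm.
#' @param muscle_type `"vertebrate"` or `"invertebrate_flight"`; fixes the
#'   d10 to actin-myosin spacing conversion.
#' @param thick_radius,thin_radius filament radii, nm.
#' @return an object of class `latticeConfig`.
#' @export
latticeConfig <- function(n_thick = 4L,
                          n_thin = 2L * n_thick,
                          crowns_per_thick = 60L,
                          heads_per_crown = 3L,
                          nodes_per_thin = 90L,
                          thick_rest_segment = 14.3,
                          thin_rest_segment = 12.2,
                          crown_azimuth_step = 120,
                          crown_rotation_pattern = c(60, 60, 0),
                          rest_sarcomere_length = 2.5,
                          am_spacing = 15,
                          muscle_type = c("invertebrate_flight", "vertebrate"),
                          thick_radius = 8,
                          thin_radius = 4.5) {
  muscle_type <- match.arg(muscle_type)
  cfg <- list(
    n_thick = as.integer(n_thick), n_thin = as.integer(n_thin),
    crowns_per_thick = as.integer(crowns_per_thick),
    heads_per_crown = as.integer(heads_per_crown),
    nodes_per_thin = as.integer(nodes_per_thin),
    thick_rest_segment = thick_rest_segment,
    thin_rest_segment = thin_rest_segment,
    crown_azimuth_step = crown_azimuth_step,
    crown_rotation_pattern = crown_rotation_pattern,
    rest_sarcomere_length = rest_sarcomere_length,
    am_spacing = am_spacing,
    muscle_type = muscle_type,
    thick_radius = thick_radius, thin_radius = thin_radius)
  class(cfg) <- "latticeConfig"
  validateLatticeConfig(cfg)
  cfg
}

validateLatticeConfig <- function(cfg) {
  if (cfg$n_thin != 2L * cfg$n_thick)
    stop("inconsistent counts: n_thin must be 2 * n_thick", call. = FALSE)
  if (cfg$n_thick != 4L)
    stop("the periodic hexagonal unit is built from 4 thick filaments (2 x 2 cells)",
         call. = FALSE)
  if (cfg$am_spacing <= 0) stop("am_spacing must be > 0", call. = FALSE)
  if (cfg$crowns_per_thick < 1L || cfg$nodes_per_thin < 3L)
    stop("inconsistent counts: too few crowns or thin nodes", call. = FALSE)
  stopifnot(cfg$thick_rest_segment > 0, cfg$thin_rest_segment > 0)
  half <- cfg$rest_sarcomere_length * 1e3 / 2
  if (cfg$crowns_per_thick * cfg$thick_rest_segment >= half)
    stop("thick filament does not fit in the half-sarcomere", call. = FALSE)
  if (cfg$nodes_per_thin * cfg$thin_rest_segment >= half)
    stop("thin filament does not fit in the half-sarcomere", call. = FALSE)
  invisible(cfg)
}

#' Convert measured d10 lattice spacing to actin-myosin surface spacing
#'
#' The x-ray d10 spacing measures the (1,0) crystallographic planes of the
#' hexagonal filament lattice; the model argument is the face-to-face gap
#' between thick and thin filament surfaces. In the vertebrate lattice the
#' thin filament sits at the trigonal point, centre-to-centre distance
#' (2/3) d10; in invertebrate flight muscle it lies midway between two thick
#' filaments, centre-to-centre d10/sqrt(3). Both filament radii
#' (8 + 4.5 nm) are subtracted.
#'
#' @param d10 d10 lattice spacing, nm.
#' @param muscle_type `"vertebrate"` or `"invertebrate_flight"`.
#' @param thick_radius,thin_radius filament radii, nm.
#' @return actin-myosin face-to-face spacing, nm.
#' @seealso [d10FromAm()] for the inverse.
#' @export
amFromD10 <- function(d10, muscle_type = c("invertebrate_flight", "vertebrate"),
                      thick_radius = 8, thin_radius = 4.5) {
  muscle_type <- match.arg(muscle_type)
  stopifnot(all(d10 > 0))
  cc <- switch(muscle_type,
               vertebrate = (2 / 3) * d10,
               invertebrate_flight = d10 / sqrt(3))
  am <- cc - thick_radius - thin_radius
  if (any(am <= 0))
    stop("infeasible spacing: d10 too small for the filament radii", call. = FALSE)
  am
}

#' Convert actin-myosin surface spacing to d10 lattice spacing
#'
#' Exact inverse of [amFromD10()].
#'
#' @inheritParams amFromD10
#' @param am actin-myosin face-to-face spacing, nm.
#' @return d10 spacing, nm.
#' @export
d10FromAm <- function(am, muscle_type = c("invertebrate_flight", "vertebrate"),
                      thick_radius = 8, thin_radius = 4.5) {
  muscle_type <- match.arg(muscle_type)
  stopifnot(all(am > 0))
  cc <- am + thick_radius + thin_radius
  switch(muscle_type,
         vertebrate = cc * 3 / 2,
         invertebrate_flight = cc * sqrt(3))
}

#' Lattice-spacing trajectory
#'
#' How the d10 lattice spacing evolves over a strain cycle: constant
#' (`mode = "constant"`, Poisson ratio 0), slaved to axial strain with a
#' Poisson ratio (`"poisson"`, nu = 0.5 is isovolumetric), or a prescribed
#' periodic table of (cycle fraction, d10) samples, e.g. digitised from
#' time-resolved x-ray diffraction (`"prescribed"`).
#'
#' @param mode one of `"constant"`, `"poisson"`, `"prescribed"`.
#' @param nu Poisson ratio (radial strain / axial strain); ignored for
#'   `"constant"` (0) and `"prescribed"`.
#' @param d_rest d10 at the mean strain, nm.
#' @param samples for `"prescribed"`: a two-column data frame or matrix of
#'   (cycle fraction in \[0,1), d10 nm), treated as one period of a periodic
#'   function.
#' @return an object of class `latticeTrajectory`.
#' @export
latticeTrajectory <- function(mode = c("constant", "poisson", "prescribed"),
                              nu = if (identical(mode, "poisson")) 0.5 else 0,
                              d_rest = 47.5, samples = NULL) {
  mode <- match.arg(mode)
  if (nu < 0) stop("nu must be >= 0", call. = FALSE)
  if (mode == "prescribed") {
    if (is.null(samples)) stop("prescribed mode requires samples", call. = FALSE)
    samples <- as.data.frame(samples)
    names(samples) <- c("cycle_fraction", "d10")
    if (any(samples$cycle_fraction < 0 | samples$cycle_fraction >= 1))
      stop("cycle_fraction samples must lie in [0, 1)", call. = FALSE)
    samples <- samples[order(samples$cycle_fraction), , drop = FALSE]
  }
  structure(list(mode = mode, nu = nu, d_rest = d_rest, samples = samples),
            class = "latticeTrajectory")
}

#' Evaluate a lattice-spacing trajectory
#'
#' For `"poisson"` mode the spacing change follows
#' `delta_d = d * (1 - (1 + strain)^-nu)`, i.e. `d10 = d_rest (1+strain)^-nu`;
#' `nu = 0.5` conserves `d10^2 * L` exactly (isovolumetric). Prescribed
#' trajectories are linearly interpolated with periodic wrap-around.
#'
#' @param traj a [latticeTrajectory()].
#' @param strain axial strain `delta L / L` (dimensionless), must be > -1.
#' @param cycle_fraction position in the strain cycle in \[0,1); only used by
#'   `"prescribed"` mode.
#' @return d10 spacing, nm (vectorised over `strain` / `cycle_fraction`).
#' @export
latticeSpacingAt <- function(traj, strain = 0, cycle_fraction = 0) {
  stopifnot(inherits(traj, "latticeTrajectory"))
  if (any(strain <= -1)) stop("strain must be > -1", call. = FALSE)
  switch(traj$mode,
    constant = rep_len(traj$d_rest, max(length(strain), length(cycle_fraction))),
    poisson = traj$d_rest * (1 + strain)^(-traj$nu),
    prescribed = {
      cf <- cycle_fraction %% 1
      s <- traj$samples
      # periodic linear interpolation: extend the table by one wrapped point
      x <- c(s$cycle_fraction, s$cycle_fraction[1] + 1)
      y <- c(s$d10, s$d10[1])
      approx(x, y, xout = ifelse(cf < x[1], cf + 1, cf))$y
    })
}

#' Read a lattice-spacing trajectory from a delimited text file
#'
#' Expects two whitespace- or comma-separated columns, cycle fraction in
#' \[0,1) and d10 in nm; a header line is detected and skipped.
#'
#' @param path file path.
#' @param d_rest d10 at mean strain; defaults to the mean of the samples.
#' @return a `"prescribed"` [latticeTrajectory()].
#' @export
readLatticeTrajectory <- function(path, d_rest = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE]+[\\s,]+[-+0-9.eE]+\\s*$", first)
  sep <- if (grepl(",", first)) "," else ""
  tab <- read.table(path, header = has_header, sep = sep,
                    comment.char = "#",
                    col.names = c("cycle_fraction", "d10"))
  if (is.null(d_rest)) d_rest <- mean(tab$d10)
  latticeTrajectory("prescribed", d_rest = d_rest, samples = tab)
}

## ---- lattice construction -------------------------------------------------

# 2D positions of the 4 thick and 8 thin filaments of the periodic unit on a
# unit-spacing hexagonal lattice (relative coordinates; only adjacency and
# azimuth matter, the radial gap used by the model is am_spacing).
.hexLayout <- function() {
  a1 <- c(1, 0); a2 <- c(0.5, sqrt(3) / 2)
  thick <- matrix(0, 4, 2)
  k <- 0L
  for (j in 0:1) for (i in 0:1) {
    k <- k + 1L
    thick[k, ] <- i * a1 + j * a2
  }
  thin <- matrix(0, 8, 2)
  k <- 0L
  for (j in 0:1) for (i in 0:1) {
    base <- i * a1 + j * a2
    k <- k + 1L; thin[k, ] <- base + (a1 + a2) / 3
    k <- k + 1L; thin[k, ] <- base + 2 * (a1 + a2) / 3
  }
  list(thick = thick, thin = thin, L1 = 2 * a1, L2 = 2 * a2)
}

# minimum-image displacement on the torus spanned by L1, L2
.minImage <- function(from, to, L1, L2) {
  best <- NULL; bestd <- Inf
  for (k1 in -1:1) for (k2 in -1:1) {
    d <- to + k1 * L1 + k2 * L2 - from
    dd <- sum(d^2)
    if (dd < bestd - 1e-12) { bestd <- dd; best <- d }
  }
  best
}

# For each thick filament: indices and azimuths (deg) of its 6 neighbouring
# thin filaments; for each thin filament: its 3 neighbouring thick filaments.
.neighborMap <- function() {
  lay <- .hexLayout()
  nbr <- vector("list", 4)
  for (t in 1:4) {
    ang <- dist <- numeric(0); idx <- integer(0)
    for (g in 1:8) {
      for (k1 in -1:1) for (k2 in -1:1) {
        d <- lay$thin[g, ] + k1 * lay$L1 + k2 * lay$L2 - lay$thick[t, ]
        dd <- sqrt(sum(d^2))
        if (dd < 1 / sqrt(3) + 1e-9) {
          idx <- c(idx, g); dist <- c(dist, dd)
          ang <- c(ang, (atan2(d[2], d[1]) * 180 / pi) %% 360)
        }
      }
    }
    o <- order(ang)
    nbr[[t]] <- list(thin = idx[o], angle = ang[o])
  }
  # thin -> thick residue assignment: for each thin, list its thick
  # neighbours (by construction each appears once) ordered by thick index;
  # residue 0,1,2 in that order.
  residue <- matrix(NA_integer_, 4, 8)
  for (g in 1:8) {
    ts <- sort(unique(unlist(lapply(1:4, function(t)
      if (g %in% nbr[[t]]$thin) t else NULL))))
    stopifnot(length(ts) == 3L)
    for (r in seq_along(ts)) residue[ts[r], g] <- r - 1L
  }
  list(nbr = nbr, residue = residue)
}

# cumulative crown azimuth (deg) for crowns 1..n given the rotation pattern
.crownAzimuths <- function(n, pattern) {
  rot <- cumsum(c(0, rep_len(pattern, n - 1)))
  rot %% 360
}

#' Build a half-sarcomere lattice at rest
#'
#' Constructs the spatial state: thick and thin filament node positions at
#' rest segment lengths, all heads unbound at the weak-state rest
#' configuration, all binding sites empty. A static neighbour map assigns each
#' head to one facing thin filament (via crown azimuth and periodic images) so
#' that each thick filament interacts with 6 thin filaments and each thin
#' filament serves the same number of heads; for a given thick filament only
#' every third thin node is an eligible binding site (the 3 x 12.2 = 36.6 nm
#' target-zone repeat), with eligibility rotating among the three thick
#' filaments surrounding each thin filament.
#'
#' @param config a [latticeConfig()].
#' @param springs a [filamentSpringParams()] (segment rest lengths are taken
#'   from `config`).
#' @param titin a [titinParams()]; titin rest length is set so that each titin
#'   spans thick-filament tip to z-disk at the rest configuration.
#' @return an object of class `halfSarcomere`.
#' @export
buildHalfSarcomere <- function(config = latticeConfig(),
                               springs = filamentSpringParams(),
                               titin = titinParams()) {
  validateLatticeConfig(config)
  nf <- config$n_thick; ng <- config$n_thin
  nc <- config$crowns_per_thick; nn <- config$nodes_per_thin
  hs <- config$rest_sarcomere_length * 1e3 / 2

  thickX <- matrix(rep(config$thick_rest_segment * seq_len(nc), nf), nc, nf)
  thinX <- matrix(rep(hs - config$thin_rest_segment * seq_len(nn), ng), nn, ng)

  map <- .neighborMap()
  nh <- nf * nc * config$heads_per_crown
  headThick <- headCrown <- headThin <- headPhase <- integer(nh)
  az <- .crownAzimuths(nc, config$crown_rotation_pattern)
  k <- 0L
  for (f in seq_len(nf)) {
    nbr <- map$nbr[[f]]
    for (c in seq_len(nc)) {
      side <- if (c %% 2L == 1L) 30 else -30  # alternate flanking direction
      for (h in seq_len(config$heads_per_crown)) {
        k <- k + 1L
        psi <- (az[c] + (h - 1L) * config$crown_azimuth_step) %% 360
        target <- (psi + side) %% 360
        dlt <- abs(((nbr$angle - target + 180) %% 360) - 180)
        g <- nbr$thin[which.min(dlt)]
        headThick[k] <- f; headCrown[k] <- c
        headThin[k] <- g; headPhase[k] <- map$residue[f, g]
      }
    }
  }

  # titin anchors: thin filament nearest azimuth 30 deg for each thick
  titinThin <- vapply(seq_len(nf), function(f) {
    nbr <- map$nbr[[f]]
    dlt <- abs(((nbr$angle - 30 + 180) %% 360) - 180)
    nbr$thin[which.min(dlt)]
  }, integer(1))
  rad_cc <- config$am_spacing + config$thick_radius + config$thin_radius
  tipX <- config$thick_rest_segment * nc
  titinRest <- sqrt((hs - tipX)^2 + rad_cc^2)

  xb <- crossbridgeParams()
  st <- list(
    config = config,
    thickX = thickX, thinX = thinX,
    headState = rep(1L, nh),
    headR = rep(xb$rW, nh), headTheta = rep(xb$thetaW, nh),
    boundSite = rep(0L, nh),
    siteOcc = rep(0L, ng * nn),
    headThick = headThick, headCrown = headCrown,
    headThin = headThin, headPhase = headPhase,
    titinThin = titinThin, titinRest = titinRest,
    hsLength = hs, am = config$am_spacing, time = 0,
    # titin preloads the chains even at rest, so a fresh lattice still needs
    # one solveEquilibrium() pass before forces are read out
    equilibrated = FALSE)
  class(st) <- "halfSarcomere"
  st
}

#' @export
print.halfSarcomere <- function(x, ...) {
  cfg <- x$config
  nh <- length(x$headState)
  cat("halfSarcomere lattice\n")
  cat(sprintf("  %d thick / %d thin filaments, %d heads (%d crowns x %d)\n",
              cfg$n_thick, cfg$n_thin, nh, cfg$crowns_per_thick,
              cfg$heads_per_crown))
  cat(sprintf("  half-sarcomere length %.1f nm, AM spacing %.2f nm (d10 %.2f nm, %s)\n",
              x$hsLength, x$am, d10FromAm(x$am, cfg$muscle_type),
              cfg$muscle_type))
  cat(sprintf("  heads: %d unbound, %d weak, %d strong; t = %.1f ms\n",
              sum(x$headState == 1L), sum(x$headState == 2L),
              sum(x$headState == 3L), x$time))
  invisible(x)
}

# global thin-node index for (filament g, node j)
.siteIndex <- function(st, g, j) (g - 1L) * st$config$nodes_per_thin + j
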