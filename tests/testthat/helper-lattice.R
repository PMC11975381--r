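# Keep long acceptance runs going past deliberate red criteria
options(testthat.progress.max_fails = 1000)

# Shared fixtures: a reduced lattice (short filaments, short half-sarcomere)
# that keeps thick-thin overlap so heads can bind, for fast unit tests.

smallLatticeConfig <- function(...) {
  latticeConfig(crowns_per_thick = 12L, nodes_per_thin = 26L,
                rest_sarcomere_length = 0.8, ...)
}

smallRunConfig <- function(...) {
  runConfig(lattice = smallLatticeConfig(), ...)
}

# equilibrated small passive state
smallState <- function(cfg = smallRunConfig()) {
  st <- buildHalfSarcomere(cfg$lattice, cfg$springs, cfg$titin)
  solveEquilibrium(st, cfg$springs, cfg$titin, cfg$xb, cfg$solver)
}

# weak-rest tip geometry of the default crossbridge
weakTip <- function(xb = crossbridgeParams()) {
  c(ax = xb$rW * cos(xb$thetaW), rad = xb$rW * sin(xb$thetaW))
}

# deterministically bind head i of a state to its axially nearest eligible
# site (no randomness), optionally promoting it to the strong state
bindHead <- function(st, i, strong = FALSE) {
  g <- st$headThin[i]
  ph <- st$headPhase[i]
  nn <- st$config$nodes_per_thin
  elig <- seq.int(if (ph == 0L) 3L else ph, nn, by = 3L)
  xa <- st$thickX[st$headCrown[i], st$headThick[i]]
  tip <- xa + weakTip()["ax"]
  j <- elig[which.min(abs(tip - st$thinX[elig, g]))]
  site <- (g - 1L) * nn + j
  stopifnot(st$siteOcc[site] == 0L)
  st$headState[i] <- if (strong) 3L else 2L
  st$boundSite[i] <- site
  st$siteOcc[site] <- i
  dx <- st$thinX[j, g] - xa
  st$headR[i] <- sqrt(dx^2 + st$am^2)
  st$headTheta[i] <- atan2(st$am, dx)
  st$equilibrated <- FALSE
  st
}
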