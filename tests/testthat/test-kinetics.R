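xb <- crossbridgeParams()
rc <- rateConstants()

test_that("head energy is zero at rest and quadratic around it", {
  expect_equal(headEnergy(xb$rW, xb$thetaW, "weak", xb), 0)
  expect_equal(headEnergy(xb$rS, xb$thetaS, "strong", xb), 0)
  # 1 nm of linear extension at kr = 16 costs 8 pN nm
  expect_equal(headEnergy(xb$rW + 1, xb$thetaW, "weak", xb), 8)
  # quadratic symmetry about the rest configuration
  d <- 0.7
  expect_equal(headEnergy(xb$rW + d, xb$thetaW + 0.1, "weak", xb),
               headEnergy(xb$rW - d, xb$thetaW - 0.1, "weak", xb))
})

test_that("head force is the negative gradient of the energy", {
  f0 <- headForce(xb$rW, xb$thetaW, "weak", xb)
  expect_equal(f0$axial, 0)
  expect_equal(f0$radial, 0)
  set.seed(3)
  h <- 1e-6
  for (k in 1:20) {
    r <- runif(1, 14, 24); th <- runif(1, 0.4, 1.6)
    s <- sample(c("weak", "strong"), 1)
    x <- r * cos(th); y <- r * sin(th)
    U <- function(x, y) headEnergy(sqrt(x^2 + y^2), atan2(y, x), s, xb)
    gx <- (U(x + h, y) - U(x - h, y)) / (2 * h)
    gy <- (U(x, y + h) - U(x, y - h)) / (2 * h)
    fr <- headForce(r, th, s, xb)
    expect_equal(fr$axial, -gx, tolerance = 1e-5)
    expect_equal(fr$radial, -gy, tolerance = 1e-5)
  }
  expect_error(headForce(0, 1, "weak", xb), "singular")
})

test_that("state free energies recover the configured drops at rest geometry", {
  tip <- unname(weakTip(xb))
  en <- stateFreeEnergies(tip[1], tip[2], xb, rc)
  expect_equal(en$U1, -rc$dG_weak, tolerance = 1e-12)
  enS <- stateFreeEnergies(xb$rS * cos(xb$thetaS), xb$rS * sin(xb$thetaS),
                           xb, rc)
  expect_equal(enS$U2, -rc$dG_strong, tolerance = 1e-12)
  # weak free energy grows quadratically with small axial offsets
  d1 <- stateFreeEnergies(tip[1] + 0.01, tip[2], xb, rc)$ew_kT
  d2 <- stateFreeEnergies(tip[1] + 0.02, tip[2], xb, rc)$ew_kT
  expect_equal(d2 / d1, 4, tolerance = 0.02)
})

test_that("binding rate r12 matches the printed constants", {
  expect_equal(rateR12(0, 1, rc), 72.005)
  expect_equal(rateR12(10, 1, rc), 0.005, tolerance = 1e-8)
  expect_equal(rateR12(c(0, 1, 5), 0, rc), c(0, 0, 0))
  expect_equal(rateR12(0, 0.5, rc), 0.5 * 72.005)
})

test_that("reverse rates satisfy detailed balance for random geometries", {
  set.seed(11)
  for (k in 1:25) {
    dx <- runif(1, 2, 20); am <- runif(1, 12, 18); d <- runif(1, 0, 3)
    en <- stateFreeEnergies(dx, am, xb, rc)
    rt <- ratesAll(en, d, AP = 1, rc)
    if (is.finite(rt$r21) && rt$r21 < 1e200)
      expect_equal(rt$r21 / rt$r12, exp(en$U1 - en$U0), tolerance = 1e-9)
    if (is.finite(rt$r32) && rt$r32 < 1e200)
      expect_equal(rt$r32 / rt$r23, exp(en$U2 - en$U1), tolerance = 1e-9)
    expect_true(all(unlist(rt) >= 0))
    expect_equal(rt$r13, 0)
  }
})

test_that("the power-stroke rate saturates at 2A and r31 floors at H", {
  # deep in the weak-unfavourable regime the tanh saturates at +1
  en <- stateFreeEnergies(6, 15, xb, rc) # strong well, weak highly strained
  expect_gt(en$U1 - en$U2, 40)
  expect_equal(ratesAll(en, 1, 1, rc)$r23, 2 * rc$A, tolerance = 1e-6)
  # zero strong-state distortion: r31 = H
  enS <- stateFreeEnergies(xb$rS * cos(xb$thetaS), xb$rS * sin(xb$thetaS),
                           xb, rc)
  expect_equal(ratesAll(enS, 1, 1, rc)$r31, rc$H, tolerance = 1e-9)
})

test_that("transition probabilities implement competing risks", {
  expect_equal(transitionProbabilities(0, dt = 1), 0)
  expect_equal(transitionProbabilities(1e9, dt = 1), 1)
  r <- c(0.7, 0.25)
  p <- transitionProbabilities(r, dt = 0.3)
  expect_equal(sum(p), 1 - exp(-sum(r) * 0.3))
  expect_equal(p[1] / p[2], r[1] / r[2])
  # monotone in dt
  expect_true(all(diff(vapply(c(0.1, 0.5, 2, 10), function(dt)
    sum(transitionProbabilities(r, dt)), numeric(1))) > 0))
})

test_that("thermal forcing samples the Boltzmann distribution", {
  # kT -> 0 pins the head at the weak rest configuration
  cold <- crossbridgeParams(kT = 1e-12)
  set.seed(5)
  draw <- thermalStep(100, cold)
  expect_equal(draw$r, rep(cold$rW, 100), tolerance = 1e-5)
  expect_equal(draw$theta, rep(cold$thetaW, 100), tolerance = 1e-5)
  # equipartition: two quadratic degrees of freedom carry kT on average
  set.seed(6)
  d <- thermalStep(2e4, xb)
  U <- headEnergy(d$r, d$theta, "weak", xb)
  expect_equal(mean(U), xb$kT, tolerance = 0.05)
  # U/kT is exponentially distributed (chi-squared with 2 dof over 2)
  set.seed(7)
  d <- thermalStep(1e5, xb)
  U <- headEnergy(d$r, d$theta, "weak", xb) / xb$kT
  ks <- suppressWarnings(stats::ks.test(U, "pexp"))
  expect_gt(ks$p.value, 1e-3)
})

test_that("compiled kinetics agree with the R reference formulas", {
  dx <- seq(-5, 20, by = 0.5)
  am <- 14.5
  cpp <- xb_diag_cpp(dx, am, unclass(xb), unclass(rc), 1)
  en <- stateFreeEnergies(dx, am, xb, rc)
  expect_equal(cpp$ew, en$ew_kT * xb$kT, tolerance = 1e-12)
  expect_equal(cpp$es, en$es_kT * xb$kT, tolerance = 1e-12)
  expect_equal(cpp$gw, sarclat:::.xbAxialGrad(dx, am, "weak", xb),
               tolerance = 1e-12)
  expect_equal(cpp$gs, sarclat:::.xbAxialGrad(dx, am, "strong", xb),
               tolerance = 1e-12)
  dW <- abs(unname(weakTip(xb)["ax"]) - dx)
  ref <- ratesAll(en, dW, AP = 1, rc)
  ok <- ref$r21 < 1e200
  expect_equal(cpp$r21[ok], ref$r21[ok], tolerance = 1e-9)
  expect_equal(cpp$r23, ref$r23, tolerance = 1e-12)
  expect_equal(cpp$r31, ref$r31, tolerance = 1e-12)
})

test_that("full inhibition (AP = 0) never produces a binding event", {
  cfg <- smallRunConfig()
  st <- smallState(cfg)
  set.seed(20)
  for (k in 1:10) {
    draws <- thermalStep(length(st$headState), cfg$xb)
    st$headR <- draws$r; st$headTheta <- draws$theta
    st <- attemptTransitions(st, cfg$xb, cfg$rates, AP = 0, dt = 1)
    expect_true(all(st$headState == 1L))
    expect_true(all(st$siteOcc == 0L))
  }
})

test_that("site occupancy stays one-to-one through stochastic transitions", {
  cfg <- smallRunConfig()
  st <- smallState(cfg)
  set.seed(21)
  for (k in 1:12) {
    free <- st$headState == 1L
    draws <- thermalStep(sum(free), cfg$xb)
    st$headR[free] <- draws$r
    st$headTheta[free] <- draws$theta
    st <- attemptTransitions(st, cfg$xb, cfg$rates, AP = 1, dt = 0.5)
    bound <- which(st$headState > 1L)
    expect_true(all(st$boundSite[bound] > 0L))
    expect_equal(sort(st$siteOcc[st$siteOcc > 0L]), sort(bound))
    expect_equal(st$siteOcc[st$boundSite[bound]], bound)
    expect_true(all(st$boundSite[st$headState == 1L] == 0L))
  }
  expect_gt(sum(st$headState > 1L), 0)
})
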