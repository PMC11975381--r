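test_that("default lattice has the published filament and head counts", {
  st <- buildHalfSarcomere()
  expect_equal(ncol(st$thickX), 4L)
  expect_equal(ncol(st$thinX), 8L)
  expect_length(st$headState, 720L)
  # freshly built: all unbound, no occupied sites
  expect_true(all(st$headState == 1L))
  expect_true(all(st$boundSite == 0L))
  expect_true(all(st$siteOcc == 0L))
  expect_equal(st$hsLength, 1250)
})

test_that("each thick filament interacts with 6 thin filaments and the load is balanced", {
  st <- buildHalfSarcomere()
  thin_per_thick <- vapply(1:4, function(f)
    length(unique(st$headThin[st$headThick == f])), integer(1))
  expect_true(all(thin_per_thick == 6L))
  # periodic-translation invariance: every thin filament serves the same
  # number of heads
  expect_true(all(table(st$headThin) == 720L / 8L))
  # eligibility residues partition each thin filament among 3 thick
  for (g in 1:8) {
    ph <- unique(st$headPhase[st$headThin == g])
    expect_setequal(ph, 0:2)
  }
})

test_that("node positions are ordered along the filaments at rest", {
  st <- buildHalfSarcomere()
  expect_true(all(apply(st$thickX, 2, function(x) all(diff(x) > 0))))
  # thin node index runs from the z-disk toward the M-line
  expect_true(all(apply(st$thinX, 2, function(x) all(diff(x) < 0))))
})

test_that("configuration invariants are enforced", {
  expect_error(latticeConfig(n_thin = 7), "n_thin")
  expect_error(latticeConfig(am_spacing = 0), "am_spacing")
  expect_error(latticeConfig(nodes_per_thin = 200), "fit")
})

test_that("d10 conversion matches the published worked pairs", {
  expect_equal(amFromD10(41.2, "vertebrate"), 14.966, tolerance = 1e-3)
  expect_equal(amFromD10(47.6, "invertebrate_flight"), 14.98, tolerance = 1e-3)
  expect_equal(amFromD10(45.9, "invertebrate_flight"), 14.00, tolerance = 1e-3)
  expect_equal(d10FromAm(15, "vertebrate"), 41.25)
  expect_equal(d10FromAm(15, "invertebrate_flight"), 27.5 * sqrt(3))
  expect_error(amFromD10(5, "invertebrate_flight"), "infeasible")
})

test_that("d10 and AM conversions are mutually inverse", {
  for (mt in c("vertebrate", "invertebrate_flight")) {
    x <- seq(30, 60, by = 0.7)
    expect_equal(d10FromAm(amFromD10(x, mt), mt), x, tolerance = 1e-12)
    y <- seq(10, 20, by = 0.3)
    expect_equal(amFromD10(d10FromAm(y, mt), mt), y, tolerance = 1e-12)
  }
})

test_that("lattice trajectories follow the Poisson-ratio law", {
  cst <- latticeTrajectory("constant", d_rest = 47.5)
  expect_equal(latticeSpacingAt(cst, strain = c(-0.05, 0, 0.05)),
               rep(47.5, 3))
  iso <- latticeTrajectory("poisson", nu = 0.5, d_rest = 47.5)
  # delta_d = d (1 - (1 + strain)^-nu)
  expect_equal(47.5 - latticeSpacingAt(iso, strain = 0.05), 1.1447,
               tolerance = 1e-3)
  # nu = 0 reduces to a constant lattice
  nu0 <- latticeTrajectory("poisson", nu = 0, d_rest = 47.5)
  expect_equal(latticeSpacingAt(nu0, strain = 0.04), 47.5)
  expect_error(latticeSpacingAt(iso, strain = -1.2), "strain")
})

test_that("isovolumetric mode conserves d10^2 * L to 1e-10", {
  iso <- latticeTrajectory("poisson", nu = 0.5, d_rest = 47.5)
  L0 <- 1250
  strains <- seq(-0.05, 0.05, by = 0.001)
  d <- latticeSpacingAt(iso, strains)
  vol <- d^2 * (L0 * (1 + strains))
  expect_equal(vol, rep(47.5^2 * L0, length(vol)), tolerance = 1e-10)
})

test_that("prescribed trajectories interpolate periodically", {
  samp <- data.frame(cf = c(0, 0.25, 0.5, 0.75), d10 = c(47, 48, 47, 46))
  tr <- latticeTrajectory("prescribed", d_rest = 47, samples = samp)
  expect_equal(latticeSpacingAt(tr, cycle_fraction = 0.25), 48)
  expect_equal(latticeSpacingAt(tr, cycle_fraction = 0.125), 47.5)
  # wrap-around between the last sample and the first of the next period
  expect_equal(latticeSpacingAt(tr, cycle_fraction = 0.875), 46.5)
  expect_equal(latticeSpacingAt(tr, cycle_fraction = 0),
               latticeSpacingAt(tr, cycle_fraction = 1))
  expect_error(latticeTrajectory("prescribed"), "samples")
})

test_that("lattice trajectory files round-trip through the text format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cycle_fraction\td10", "0\t47.0", "0.5\t48.0"), f)
  tr <- readLatticeTrajectory(f)
  expect_equal(tr$mode, "prescribed")
  expect_equal(latticeSpacingAt(tr, cycle_fraction = 0.5), 48)
  expect_equal(latticeSpacingAt(tr, cycle_fraction = 0.25), 47.5)
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,47.0", "0.5,48.0"), f2)  # headerless, comma separated
  tr2 <- readLatticeTrajectory(f2)
  expect_equal(tr2$samples$d10, c(47, 48))
})
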