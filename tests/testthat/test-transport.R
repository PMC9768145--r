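test_that("stopping power has Bethe-like behavior and scales with density", {
  bone <- boneMaterial()
  e <- seq(2, 20, by = 0.5)
  s <- stoppingPower(e, bone)
  expect_true(all(s > 0))
  expect_true(all(diff(s) < 0))  # increases as energy decreases over 2-20

  dense <- material("bone2x", bone@atomicFractions, 2 * bone@density)
  expect_equal(stoppingPower(e, dense), 2 * s, tolerance = 1e-12)

  expect_error(stoppingPower(0.1, bone), "cutoff")
})

test_that("CSDA range matches an independent adaptive quadrature", {
  bone <- boneMaterial()
  oracle <- stats::integrate(function(E) 1 / stoppingPower(E, bone),
                             0.2, 13.9619, rel.tol = 1e-10)$value
  expect_equal(csdaRange(13.9619, bone), oracle, tolerance = 0.01)
})

test_that("transport is reproducible and respects physical bounds", {
  bone <- boneMaterial()
  a <- simulateElectrons(13.9619, bone, n = 200, seed = 11,
                         keepPaths = FALSE)
  b <- simulateElectrons(13.9619, bone, n = 200, seed = 11,
                         keepPaths = FALSE)
  expect_identical(a@summary, b@summary)
  c2 <- simulateElectrons(13.9619, bone, n = 200, seed = 12,
                          keepPaths = FALSE)
  expect_false(identical(a@summary, c2@summary))

  sim <- mcSim()
  # radial reach bounded by the CSDA range (+ tiny residual-range slack)
  slack <- sim@csdaRange * 1.005
  expect_true(all(sim@summary$deMax <= slack))
  rad <- sqrt(sim@summary$finalX^2 + sim@summary$finalY^2 +
                sim@summary$finalZ^2)
  expect_true(all(rad <= slack))
  expect_true(all(sim@summary$pathLength <= slack))

  # energy bookkeeping: each electron deposits start minus cutoff
  expect_equal(sim@summary$deposited,
               rep(13.9619 - 0.2, nrow(sim@summary)), tolerance = 1e-6)

  expect_error(simulateElectrons(13.9619, bone, n = 0), "n must be")
})

test_that("vertex paths have strictly decreasing energies", {
  sim <- mcSimPaths()
  expect_true(all(vapply(sim@paths, function(p)
    all(diff(p[, "energy"]) < 0), logical(1))))
  # vertex-to-vertex segment lengths sum to the recorded path length
  pl <- vapply(sim@paths, function(p)
    sum(sqrt(rowSums(diff(p[, c("x", "y", "z")])^2))), numeric(1))
  expect_equal(pl, sim@summary$pathLength, tolerance = 1e-6)
})

test_that("electrons at the cutoff energy do not move", {
  sim <- simulateElectrons(0.2, boneMaterial(), n = 10, seed = 1,
                           keepPaths = FALSE)
  expect_true(all(sim@summary$deMax == 0))
  expect_true(all(sim@summary$pathLength == 0))
})

test_that("penetration distribution is symmetric with unit mass", {
  P <- mcP()
  expect_equal(sum(binMass(P)), 1, tolerance = 1e-12)
  expect_identical(binMass(P), rev(binMass(P)))  # exact mirror symmetry
  expect_identical(P@binEdges, -rev(P@binEdges))
  # support bounded by the CSDA range
  expect_lte(max(abs(P@binEdges)), mcSim()@csdaRange * 1.005)

  # a single electron at depth 1.0 um gives two bins at +/-1 with mass 1/2
  one <- new("ElectronTrajectories", energy = 1, material = "toy",
             seed = 1L, cutoff = 0.2, csdaRange = 2,
             summary = data.frame(deMax = 1, finalX = 1, finalY = 0,
                                  finalZ = 0, pathLength = 1,
                                  deposited = 0.8, nSteps = 1L),
             paths = list())
  P1 <- penetrationDistribution(one, nBins = 4)
  ctr <- binCenters(P1)
  expect_equal(sum(binMass(P1)[ctr > 0]), 0.5)
  expect_equal(ctr[binMass(P1) > 0], c(-0.875, 0.875), tolerance = 1e-6)
})

test_that("attenuation length recovers the scale of an exact Laplace tail", {
  Pl <- laplacePenetration(1.5)
  expect_equal(attenuationLength(Pl, method = "survival"), 1.5,
               tolerance = 0.02)
  expect_equal(attenuationLength(Pl, method = "tail_fit"), 1.5,
               tolerance = 0.02)

  # scale equivariance: doubling all distances doubles the length
  P2 <- laplacePenetration(3.0)
  expect_equal(attenuationLength(P2), 2 * attenuationLength(Pl),
               tolerance = 0.02)

  expect_error(attenuationLength(Pl, tailFraction = 0.7,
                                 method = "tail_fit"), "tailFraction")
})

test_that("denser matrices stop electrons over shorter distances", {
  col <- simulateElectrons(13.9619, materialPreset("collagen"), n = 600,
                           seed = 5, keepPaths = FALSE)
  mnl <- simulateElectrons(13.9619, materialPreset("mineral"), n = 600,
                           seed = 5, keepPaths = FALSE)
  expect_gt(col@csdaRange, mnl@csdaRange)
  Pc <- penetrationDistribution(col)
  Pm <- penetrationDistribution(mnl)
  expect_gt(attenuationLength(Pc), attenuationLength(Pm))
})
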