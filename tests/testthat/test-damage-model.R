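test_that("beam source is a rect with the midpoint edge convention", {
  expect_equal(beamSource(20, 0), 1)
  expect_equal(beamSource(20, 15), 0)
  expect_equal(beamSource(20, 10), 0.5)
  expect_equal(beamSource(20, -10), 0.5)
  expect_error(beamSource(0, 0), "w must be")
})

test_that("a point-mass kernel returns the beam profile itself", {
  P <- pointMassPenetration(0)
  eta <- energyDeposition(20, P)
  h <- eta@x[2] - eta@x[1]
  inner <- abs(eta@x) < 10 - h
  outer <- abs(eta@x) > 10 + 2 * h  # one cell of mass-splitting slack
  expect_true(all(abs(eta@value[inner] - 1) < 1e-9))
  expect_true(all(abs(eta@value[outer]) < 1e-6))
  edge <- which.min(abs(eta@x - 10))
  expect_equal(eta@value[edge], 0.5, tolerance = 0.2)
})

test_that("deposition conserves energy: area under eta equals w", {
  for (P in list(mcP(), laplacePenetration(1.5), pointMassPenetration(2))) {
    for (w in c(0.5, 5, 37.3, 100)) {
      eta <- energyDeposition(w, P)
      h <- eta@x[2] - eta@x[1]
      expect_equal(sum(eta@value) * h, w, tolerance = 1e-3)
      expect_identical(eta@value, rev(eta@value))  # exact symmetry
      expect_true(all(eta@value >= 0))
    }
  }
})

test_that("Laplace kernel deposition matches the analytic convolution", {
  lam <- 1.5; w <- 100
  eta <- energyDeposition(w, laplaceFine(lam))
  x <- eta@x
  cf <- exp(-abs(x) / lam) * sinh(w / (2 * lam))
  sel <- abs(x) > w / 2 + 2 & abs(x) < w / 2 + 12 * lam
  expect_lt(max(abs(eta@value[sel] - cf[sel]) / cf[sel]), 0.005)
})

test_that("too small a grid extent is rejected", {
  cfg <- damageModelConfig(gridExtent = 5)
  expect_error(energyDeposition(20, laplacePenetration(1.5), cfg),
               "grid_extent too small")
})

test_that("cumulative deposition is exact multiplication by exposure", {
  eta <- energyDeposition(20, mcP())
  expect_true(all(cumulativeDeposition(eta, 0)@value == 0))
  H1 <- cumulativeDeposition(eta, 160)
  H2 <- cumulativeDeposition(eta, 320)
  expect_identical(H2@value, 2 * H1@value)
  expect_identical(cumulativeDeposition(eta, 320)@value, 320 * eta@value)
  expect_error(cumulativeDeposition(eta, -1), "dt must be")
})

test_that("damage extent crosses the threshold where theory says", {
  # sharp beam: H is a rect, so x_w = w/2
  P0 <- pointMassPenetration(0)
  H <- cumulativeDeposition(energyDeposition(20, P0), 1)
  xw <- damageExtent(H, damageModelConfig(threshold = 0.05))
  expect_equal(xw, 10, tolerance = 0.01)

  # threshold above the maximum: no-damage sentinel, zeta = 0
  expect_true(is.na(damageExtent(H, damageModelConfig(threshold = 2))))
  expect_equal(relativeDamage(damageExtent(
    H, damageModelConfig(threshold = 2)), 20), 0)

  # Laplace tail: closed-form threshold crossing
  lam <- 1.5; w <- 100; dt <- 320; th <- 0.05
  Hc <- cumulativeDeposition(energyDeposition(w, laplaceFine(lam)), dt)
  xw <- damageExtent(Hc, damageModelConfig(threshold = th))
  xwExact <- w / 2 + lam * log(dt * (1 - exp(-w / lam)) / (2 * th))
  expect_equal(xw, xwExact, tolerance = 0.005)
})

test_that("relative damage ratios and volumes compose correctly", {
  expect_equal(relativeDamage(10, 20), 1)
  expect_equal(relativeDamage(20, 20), 2)
  expect_equal(relativeDamageVolume(1, 1), 1)
  expect_equal(relativeDamageVolume(1.5, 1), 1.5)
  # ellipse-area identity: Z = (pi a b) / (pi (w/2)^2)
  zh <- 1.7; zv <- 1.2; w <- 20
  a <- zh * w / 2; b <- zv * w / 2
  expect_equal(relativeDamageVolume(zh, zv),
               (pi * a * b) / (pi * (w / 2)^2), tolerance = 1e-12)
  expect_error(relativeDamageVolume(-1, 1), ">= 0")
})

test_that("damage grows with exposure and relative damage with smaller beams", {
  P <- mcP()
  sw <- damageSweep(P, widths = c(5, 10, 20, 100), dts = c(80, 160, 320))
  for (w in unique(sw$w_um)) {
    s <- sw[sw$w_um == w, ]
    s <- s[order(s$dt_s), ]
    expect_true(all(diff(s$xw_um) >= 0))
    expect_true(all(diff(s$zeta_h) >= 0))
    expect_true(all(diff(s$Z_percent) >= 0))
  }
  for (dt in unique(sw$dt_s)) {
    s <- sw[sw$dt_s == dt, ]
    s <- s[order(s$w_um), ]
    expect_true(all(diff(s$zeta_h) <= 0))  # smaller beam, larger ratio
  }
})

test_that("first-order exponential fits recover their parameters", {
  # constant series at 100%: rate indistinguishable from zero
  f0 <- fitFirstOrderExponential(seq(0, 320, 40), rep(100, 9))
  expect_equal(f0$k, 0)

  # noise-free self-consistency
  d <- genDamageCurve(k = 0.07, plateau = 150, noiseSd = 0, nPoints = 20,
                      seed = 1)
  f <- fitFirstOrderExponential(d$time_s, d$damage_pct)
  expect_equal(f$k, 0.07, tolerance = 1e-6)
  expect_equal(f$plateau, 150, tolerance = 1e-6)

  # simulation study with known ground truth: 100 seeded replicates with
  # Gaussian noise; the mean recovered rate stays within 15% of truth
  ks <- vapply(1:100, function(s) {
    d <- genDamageCurve(k = 0.07, plateau = 150, noiseSd = 2.5,
                        nPoints = 20, seed = s)
    fitFirstOrderExponential(d$time_s, d$damage_pct)$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.07) / 0.07, 0.15)
  expect_gt(mean(abs(ks - 0.07) / 0.07 < 0.5), 0.9)
})
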