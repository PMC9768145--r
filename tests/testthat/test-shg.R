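test_that("z-projections reduce stacks per pixel", {
  set.seed(1)
  v <- array(stats::runif(20 * 30 * 10), c(20, 30, 10))
  st <- imageStack(v, pixelSize = 0.6)

  single <- imageStack(v[, , 1, drop = FALSE])
  expect_equal(zProject(single, "max")@pixels, v[, , 1])
  expect_true(all(zProject(imageStack(array(2, c(5, 5, 4))),
                           "std")@pixels == 0))

  # brute-force per-pixel oracle
  mx <- zProject(st, "max")@pixels
  for (i in c(1, 7, 20)) for (j in c(1, 15, 30))
    expect_equal(mx[i, j], max(v[i, j, ]))
  sd2 <- zProject(st, "std")@pixels
  expect_equal(sd2[3, 4], stats::sd(v[3, 4, ]))
})

test_that("imprint detection finds programmed ellipses and nothing else", {
  uniform <- new("ShgProjection", pixels = matrix(1, 80, 80),
                 pixelSize = 0.6, mode = "max")
  expect_length(detectImprints(uniform), 0)

  one <- flatEllipseImage(centers = cbind(40, 30),
                          axesUm = cbind(25, 18), dip = 0.4)
  imps <- detectImprints(one, dropThreshold = 0.2)
  expect_length(imps, 1)

  two <- flatEllipseImage(dim = c(120, 220),
                          centers = rbind(c(35, 32), c(95, 32)),
                          axesUm = rbind(c(24, 18), c(24, 18)), dip = 0.5)
  imps2 <- detectImprints(two, dropThreshold = 0.2)
  expect_length(imps2, 2)
  ctrs <- sort(vapply(imps2, function(i) i@center[["x"]], numeric(1)))
  expect_equal(ctrs, c(35, 95), tolerance = 0.03)  # within ~1 px

  # invariance to global intensity scaling
  sc <- new("ShgProjection", pixels = two@pixels * 37.5, pixelSize = 0.6,
            mode = "max")
  impsSc <- detectImprints(sc, dropThreshold = 0.2)
  expect_length(impsSc, 2)
  expect_equal(vapply(impsSc, function(i) i@center[["x"]], numeric(1)),
               vapply(imps2, function(i) i@center[["x"]], numeric(1)))
})

test_that("full-width extents recover programmed ellipse axes", {
  # the mineralized-pike scale: 27.16 x 22.13 um imprint at 0.6 um/px
  img <- flatEllipseImage(dim = c(100, 120), centers = cbind(36, 30),
                          axesUm = cbind(27.16, 22.13), dip = 0.6)
  im <- detectImprints(img)[[1]]
  im <- imprintExtents(img, im)
  expect_equal(im@extentH, 27.16, tolerance = 0.6 / 27.16)  # 1 px
  expect_equal(im@extentV, 22.13, tolerance = 0.6 / 22.13)

  # circular imprint: extents agree within a pixel
  circ <- flatEllipseImage(dim = c(100, 100), centers = cbind(30, 30),
                           axesUm = cbind(24, 24), dip = 0.6)
  imc <- imprintExtents(circ, detectImprints(circ)[[1]])
  expect_lt(abs(imc@extentH - imc@extentV), 0.6)

  # rotating the ellipse by 90 degrees swaps the extents
  rot <- flatEllipseImage(dim = c(120, 100), centers = cbind(30, 36),
                          axesUm = cbind(22.13, 27.16), dip = 0.6)
  imr <- imprintExtents(rot, detectImprints(rot)[[1]])
  expect_equal(imr@extentH, im@extentV, tolerance = 0.05)
  expect_equal(imr@extentV, im@extentH, tolerance = 0.05)
})

test_that("imprints touching the border are reported as errors", {
  img <- flatEllipseImage(dim = c(60, 60), centers = cbind(3, 18),
                          axesUm = cbind(20, 14), dip = 0.6)
  imps <- detectImprints(img, minArea = 10)
  expect_length(imps, 1)
  expect_error(imprintExtents(img, imps[[1]]), "border")
})

test_that("relative damaged area is the product of axis ratios", {
  im <- new("DamageImprint", center = c(x = 0, y = 0), extentH = 20,
            extentV = 20, meanIntensityDrop = 0.5,
            mask = matrix(TRUE, 1, 1), pixelSize = 0.6)
  beam <- beamSpec(widthH = 20, widthV = 20)
  expect_equal(relativeDamagedArea(im, beam), 100)
  im@extentH <- 30
  expect_equal(relativeDamagedArea(im, beam), 150)
})

test_that("the SHG pipeline round-trips generator ground truth", {
  scen <- syntheticScenario(seed = 1, penetration = mcP())
  gen <- genShgStack(scen)
  expect_true(all(diff(gen$truth$extent_h_um) > 0))  # ladder monotonic

  proj <- zProject(gen$stack, "max")
  imps <- detectImprints(proj)
  expect_length(imps, nrow(gen$truth))
  ps <- gen$stack@pixelSize
  for (im in imps) {
    im <- imprintExtents(proj, im)
    tr <- gen$truth[which.min(abs(gen$truth$center_x_um -
                                    im@center[["x"]])), ]
    expect_lt(abs(im@extentH - tr$extent_h_um), ps * 1.5)
    expect_lt(abs(im@extentV - tr$extent_v_um), ps * 1.5)
    expect_lt(abs(relativeDamagedArea(im, scen@beam) - tr$Z_percent) /
                tr$Z_percent, 0.05)
  }
})

test_that("stacks survive a TIFF write/read cycle up to global scale", {
  scen <- syntheticScenario(seed = 2, penetration = laplacePenetration(1.5))
  gen <- genShgStack(scen, nSlices = 2)
  path <- tempfile(fileext = ".tif")
  writeShgStack(gen$stack, path)
  back <- readShgStack(path, pixelSize = gen$stack@pixelSize)
  expect_equal(dim(back@voxels), dim(gen$stack@voxels))
  a <- gen$stack@voxels / max(gen$stack@voxels)
  expect_equal(back@voxels, a, tolerance = 1e-4)  # 16-bit quantization
  unlink(path)
})
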