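## Voigt line shape via the Faddeeva function w(z), computed with
## Humlicek's four-region rational approximations (relative accuracy
## ~1e-4, ample for peak fitting). Vectorized over z with Im(z) >= 0.

.faddeeva <- function(x, y) {
  t <- complex(real = y, imaginary = -x)
  s <- abs(x) + y
  w <- complex(length.out = length(x))

  r1 <- s >= 15
  if (any(r1)) {
    tt <- t[r1]
    w[r1] <- tt * 0.5641896 / (0.5 + tt * tt)
  }
  r2 <- !r1 & s >= 5.5
  if (any(r2)) {
    tt <- t[r2]; u <- tt * tt
    w[r2] <- tt * (1.410474 + u * 0.5641896) / (0.75 + u * (3 + u))
  }
  r3 <- !r1 & !r2 & (y >= 0.195 * abs(x) - 0.176)
  if (any(r3)) {
    tt <- t[r3]
    w[r3] <- (16.4955 + tt * (20.20933 + tt * (11.96482 +
               tt * (3.778987 + tt * 0.5642236)))) /
             (16.4955 + tt * (38.82363 + tt * (39.27121 +
               tt * (21.69274 + tt * (6.699398 + tt)))))
  }
  r4 <- !r1 & !r2 & !r3
  if (any(r4)) {
    tt <- t[r4]; u <- tt * tt
    num <- tt * (36183.31 - u * (3321.9905 - u * (1540.787 -
             u * (219.0313 - u * (35.76683 - u * (1.320522 -
             u * 0.56419))))))
    den <- 32066.6 - u * (24322.84 - u * (9022.228 -
             u * (2186.181 - u * (364.2191 - u * (61.57037 -
             u * (1.841439 - u))))))
    w[r4] <- exp(u) - num / den
  }
  w
}

#' Voigt profile density
#'
#' Convolution of a Gaussian (sd `sigma`) and a Lorentzian (HWHM `gamma`),
#' normalized to unit area. Degenerate limits (sigma or gamma ~ 0) reduce
#' to the pure Lorentzian/Gaussian.
#'
#' @param x evaluation points
#' @param center peak center
#' @param sigma Gaussian standard deviation (>= 0)
#' @param gamma Lorentzian half width at half maximum (>= 0)
#' @export
voigtProfile <- function(x, center, sigma, gamma) {
  if (sigma < 0 || gamma < 0) stop("sigma and gamma must be >= 0")
  if (sigma < 1e-12)
    return(stats::dcauchy(x, location = center, scale = max(gamma, 1e-12)))
  if (gamma < 1e-12)
    return(stats::dnorm(x, mean = center, sd = sigma))
  u <- (x - center) / (sigma * sqrt(2))
  a <- gamma / (sigma * sqrt(2))
  Re(.faddeeva(u, rep(a, length(u)))) / (sigma * sqrt(2 * pi))
}
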