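## Saturating-exponential fitting shared by damage-accumulation and
## strain-relaxation analyses: y(t) = plateau - (plateau - y0) exp(-k t),
## anchored at y(0) = y0.

.fitSaturatingExponential <- function(times, y, y0, maxRestarts = 6) {
  stopifnot(length(times) == length(y))
  if (length(times) < 3) stop("need at least 3 time points")
  amp <- max(y) - y0
  # degenerate flat series: rate indistinguishable from 0
  if (abs(amp) < 1e-8 * max(1, abs(y0)) || stats::sd(y) < 1e-12)
    return(list(k = 0, plateau = y0, kSe = NA_real_, plateauSe = NA_real_,
                fit = NULL))
  df <- data.frame(t = times, y = y)
  tScale <- max(times[times > 0], 1)
  kStarts <- c(2 / tScale, 0.5 / tScale, 8 / tScale, 0.05 / tScale,
               30 / tScale, 1e-3 / tScale)[seq_len(maxRestarts)]
  lastErr <- NULL
  for (k0 in kStarts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ plateau - (plateau - y0) * exp(-k * t),
                        data = df,
                        start = list(plateau = max(y) + 0.05 * abs(amp),
                                     k = k0),
                        lower = c(plateau = -Inf, k = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      co <- stats::coef(fit)
      se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                     error = function(e) c(NA_real_, NA_real_))
      return(list(k = unname(co["k"]), plateau = unname(co["plateau"]),
                  kSe = unname(se["k"]), plateauSe = unname(se["plateau"]),
                  fit = fit))
    }
    lastErr <- fit
  }
  stop("saturating-exponential fit failed after ", length(kStarts),
       " restarts: ", conditionMessage(lastErr))
}

#' First-order exponential damage-accumulation fit
#'
#' Fits D(t) = D_inf - (D_inf - 100) exp(-k t), anchored at D(0) = 100%
#' (no damage spread at zero exposure), by Levenberg-Marquardt least
#' squares with documented multi-starts in k. A constant series at 100%
#' returns k = 0.
#'
#' @param times exposure times in s (>= 3 points)
#' @param damagePct relative damaged volume in percent (>= 100)
#' @return list with k (%/s scale-free rate, 1/s), plateau (D_inf, %),
#'   their standard errors and the underlying nls fit
#' @export
fitFirstOrderExponential <- function(times, damagePct) {
  if (any(damagePct < 0)) stop("damage percentages must be >= 0")
  .fitSaturatingExponential(times, damagePct, y0 = 100)
}
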