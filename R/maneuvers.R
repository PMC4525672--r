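# Chest-pressure waveform library: quiet ventilation, manual chest
# physiotherapy, and high-frequency chest wall oscillation (HFCWO).

#' Specify a chest-pressure maneuver
#'
#' Every maneuver rides on the quiet-ventilation waveform
#' `P_v (1 - cos(2 pi t / 5)) / 2` (period 5 s, amplitude `P_v` = -5 cmH2O by
#' default). The maneuver term is added inside the session window only:
#' \describe{
#'   \item{ventilation}{no added term.}
#'   \item{manual}{`P_cp * max(sin(2 pi t / 5), 0)` -- positive chest
#'     pressure on the expiratory half-cycles.}
#'   \item{hfcwo}{`P_s + (P_o / 2) * sin(2 pi f t)` -- a static compression
#'     plus a high-frequency oscillation. Chest-compression (CC) devices use
#'     `P_s > 0`; focused-pulse (FPT) devices use `P_s = 0` with equivalent
#'     piston pressures folded into `P_o`.}
#' }
#' The default session lasts 230 s with quiet ventilation in the first and
#' last 10 s; the maneuver term is ramped linearly over 10-15 s and 215-220 s.
#'
#' @param family one of `"ventilation"`, `"manual"`, `"hfcwo"`.
#' @param P_v ventilation amplitude, cmH2O (non-positive).
#' @param P_cp manual chest-pressure amplitude, cmH2O.
#' @param P_s,P_o,f HFCWO static pressure (cmH2O), oscillation amplitude
#'   (cmH2O, peak-to-peak) and frequency (Hz).
#' @param session list with `duration`, `lead_in`, `ramp_up`, `ramp_down`,
#'   `tail` (seconds).
#' @return an object of class `maneuver_spec` (pressures stored in Pa).
#' @export
maneuver_spec <- function(family = c("ventilation", "manual", "hfcwo"),
                          P_v = -5, P_cp = 0, P_s = 0, P_o = 0, f = 20,
                          session = default_session()) {
  family <- match.arg(family)
  if (P_v > 0) stop("P_v must be non-positive (chest depression)")
  if (P_cp < 0 || P_s < 0 || P_o < 0) {
    stop("maneuver amplitudes must be non-negative")
  }
  if (family == "hfcwo" && f <= 0) stop("f must be positive for hfcwo")
  if (family != "ventilation") {
    # the schedule only gates the maneuver term
    stopifnot(session$ramp_up[1] >= session$lead_in,
              session$ramp_up[2] > session$ramp_up[1],
              session$ramp_down[1] > session$ramp_up[2],
              session$ramp_down[2] <= session$duration - session$tail + 1e-9)
  }
  structure(list(
    family = family,
    P_v = cmh2o(P_v), P_cp = cmh2o(P_cp),
    P_s = cmh2o(P_s), P_o = cmh2o(P_o), f = f,
    session = session
  ), class = "maneuver_spec")
}

#' Default 230-second session schedule
#'
#' @return list with `duration` 230 s, `lead_in` and `tail` 10 s, linear
#'   ramps on 10-15 s and 215-220 s.
#' @export
default_session <- function() {
  list(duration = 230, lead_in = 10, ramp_up = c(10, 15),
       ramp_down = c(215, 220), tail = 10)
}

#' @export
print.maneuver_spec <- function(x, ...) {
  cat(sprintf("Maneuver '%s': P_v = %.1f cmH2O", x$family, to_cmh2o(x$P_v)))
  if (x$family == "manual") cat(sprintf(", P_cp = %.1f cmH2O", to_cmh2o(x$P_cp)))
  if (x$family == "hfcwo") {
    cat(sprintf(", P_s = %.1f cmH2O, P_o = %.1f cmH2O at %g Hz",
                to_cmh2o(x$P_s), to_cmh2o(x$P_o), x$f))
  }
  cat(sprintf("; session %g s\n", x$session$duration))
  invisible(x)
}

# Linear ramp multiplier for the maneuver term: 0 before the session window,
# rising on ramp_up, 1 in between, falling on ramp_down, 0 after.
.ramp_factor <- function(session, t) {
  up <- session$ramp_up; dn <- session$ramp_down
  f <- numeric(length(t))
  f[t >= up[2] & t <= dn[1]] <- 1
  i <- t > up[1] & t < up[2]
  f[i] <- (t[i] - up[1]) / (up[2] - up[1])
  i <- t > dn[1] & t < dn[2]
  f[i] <- (dn[2] - t[i]) / (dn[2] - dn[1])
  f
}

#' Chest pressure at time t
#'
#' Evaluates the maneuver waveform: the ventilation term is always active,
#' the maneuver term is multiplied by the session ramp factor (zero outside
#' the session window).
#'
#' @param spec a [maneuver_spec()].
#' @param t time, s (vectorized).
#' @return chest pressure `P_ext`, Pa.
#' @export
external_pressure <- function(spec, t) {
  p <- spec$P_v * (1 - cos(2 * pi * t / 5)) / 2
  if (spec$family == "ventilation") return(p)
  ramp <- .ramp_factor(spec$session, t)
  term <- switch(spec$family,
    manual = spec$P_cp * pmax(sin(2 * pi * t / 5), 0),
    hfcwo = spec$P_s + (spec$P_o / 2) * sin(2 * pi * spec$f * t)
  )
  p + ramp * term
}
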