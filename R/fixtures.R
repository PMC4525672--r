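# Initial mucus distributions and scenario presets.

#' Default initial mucus distribution
#'
#' Fill fractions (mucus cross-section over bronchus lumen, at rest) for the
#' 17 conducting generations: homogeneous at 10% over generations 0-5, rising
#' through generations 6-7 to a 50% peak at generation 8, then decaying to
#' zero at generation 16. The rise and decay values are fixed constants,
#' pinned once so that the rest-state mean mucus position equals 7.34 (the
#' distribution's single quantitative anchor), and frozen.
#'
#' This distribution does not represent any specific pathology; it models a
#' lung with excess secretions around the eighth generation and is chosen so
#' that quiet rest ventilation leaves it unmoved.
#'
#' @return an object of class `mucus_profile`: list with `fill` (length 17).
#' @export
default_mucus_profile <- function() {
  fill <- c(rep(0.10, 6), 0.20, 0.35, 0.50,
            # frozen power-law decay (exponent 1.801) pinning rest mmp = 7.34
            0.393117, 0.297814, 0.214454, 0.143480, 0.085461, 0.041173,
            0.011815, 0)
  mucus_profile(fill)
}

#' Construct a mucus profile
#'
#' @param fill 17 fill fractions in `[0, 1)` for generations 0..16.
#' @return an object of class `mucus_profile`.
#' @export
mucus_profile <- function(fill) {
  fill <- as.numeric(fill)
  if (length(fill) != 17L || any(fill < 0) || any(fill >= 1)) {
    stop("fill must give 17 fractions in [0, 1)")
  }
  structure(list(fill = fill), class = "mucus_profile")
}

#' @export
print.mucus_profile <- function(x, ...) {
  cat("Mucus profile (fill fraction per generation 0..16):\n")
  print(round(x$fill, 4))
  invisible(x)
}

#' Zero-mucus profile
#' @return a `mucus_profile` with no mucus anywhere.
#' @export
clean_lung_profile <- function() mucus_profile(rep(0, 17L))

#' Scenario presets
#'
#' Fully specified run inputs for the standard numerical experiments:
#' \describe{
#'   \item{ventilation}{quiet rest ventilation only.}
#'   \item{manual_sweep}{manual chest physiotherapy at amplitude `P_cp`
#'     (default 20 cmH2O, the reference manual case).}
#'   \item{hfcwo_example}{chest compression at `P_s` = 5.6 cmH2O with
#'     `P_o` = 1.2 cmH2O oscillation at 20 Hz.}
#'   \item{static_sweep}{HFCWO with `P_o` = 1.2 cmH2O, 20 Hz and a caller-
#'     chosen static pressure `P_s`.}
#'   \item{amplitude_sweep}{HFCWO at `P_s` = 0.6 cmH2O (so the default total
#'     maneuver pressure oscillates between 0 and 1.2 cmH2O), 20 Hz and a
#'     caller-chosen `P_o`.}
#'   \item{frequency_sweep}{HFCWO at `P_s` = 0.6, `P_o` = 1.2 cmH2O and a
#'     caller-chosen frequency.}
#' }
#'
#' @param name preset name.
#' @param P_cp,P_s,P_o,f overriding parameters, cmH2O and Hz.
#' @return list with `maneuver` ([maneuver_spec()]), `profile`
#'   ([mucus_profile]), `stepper` ([stepper_config()]).
#' @export
scenario_preset <- function(name = c("ventilation", "manual_sweep",
                                     "hfcwo_example", "static_sweep",
                                     "amplitude_sweep", "frequency_sweep"),
                            P_cp = 20, P_s = NULL, P_o = NULL, f = NULL) {
  name <- match.arg(name)
  man <- switch(name,
    ventilation = maneuver_spec("ventilation"),
    manual_sweep = maneuver_spec("manual", P_cp = P_cp),
    hfcwo_example = maneuver_spec("hfcwo", P_s = P_s %||% 5.6,
                                  P_o = P_o %||% 1.2, f = f %||% 20),
    static_sweep = maneuver_spec("hfcwo", P_s = P_s %||% 5.6,
                                 P_o = 1.2, f = 20),
    amplitude_sweep = maneuver_spec("hfcwo", P_s = 0.6,
                                    P_o = P_o %||% 1.2, f = 20),
    frequency_sweep = maneuver_spec("hfcwo", P_s = 0.6, P_o = 1.2,
                                    f = f %||% 20)
  )
  list(maneuver = man, profile = default_mucus_profile(),
       stepper = stepper_config())
}

#' Write or read a mucus profile as CSV
#'
#' Two-column CSV (`generation`, `fill`).
#'
#' @param profile a `mucus_profile`.
#' @param path file path.
#' @return `read_mucus_profile` returns a `mucus_profile`.
#' @export
write_mucus_profile <- function(profile, path) {
  utils::write.csv(data.frame(generation = 0:16, fill = profile$fill),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mucus_profile
#' @export
read_mucus_profile <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("generation", "fill") %in% names(tab)) ||
      !identical(as.integer(tab$generation), 0:16)) {
    stop("profile CSV must have generations 0..16 in order")
  }
  mucus_profile(tab$fill)
}
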