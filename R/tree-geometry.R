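# Geometry of the idealized 23-generation symmetric bifurcating airway tree.
#
# Generations 0-16 are conducting airways with Lambert pressure-area constants;
# generations 17-22 are alveolar ducts (acini), each carrying 58 alveoli.
# Internal units are strictly SI (m, m^2, m^3, Pa, s); cmH2O is accepted only
# at user-facing boundaries.

#' Pascals per centimetre of water
#'
#' Conversion factor used at every user-facing pressure boundary:
#' 1 cmH2O = 98.07 Pa.
#' @export
CMH2O_PA <- 98.07

#' Convert pressures between cmH2O and Pa
#'
#' @param x pressure in cmH2O (`cmh2o`) or in Pa (`to_cmh2o`).
#' @return pressure in Pa (`cmh2o`) or in cmH2O (`to_cmh2o`).
#' @export
cmh2o <- function(x) x * CMH2O_PA

#' @rdname cmh2o
#' @export
to_cmh2o <- function(x) x / CMH2O_PA

#' Read the packaged conducting-airway constants
#'
#' Returns the per-generation lengths, reference (FRC) diameters and Lambert
#' sigmoid constants for the 17 conducting generations, as shipped in
#' `inst/extdata/lambert_airways.csv` (printed units: cm, cm^2, 1e-3/Pa).
#'
#' @param path optional path to a user override CSV with the same columns.
#' @return a data.frame with one row per generation 0..16.
#' @export
lambert_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lambert_airways.csv", package = "bronchosim",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("z", "l_cm", "d_cm", "alpha0", "alpha0_prime_e3_per_pa",
            "n1", "n2", "A_m_cm2")
  if (!all(need %in% names(tab))) {
    stop("airway constants file must contain columns: ",
         paste(need, collapse = ", "))
  }
  if (!identical(as.integer(tab$z), 0:16)) {
    stop("airway constants file must have exactly generations 0..16 in order")
  }
  tab
}

#' Build the default tree specification
#'
#' Assembles the full 23-generation symmetric tree: conducting-airway lengths,
#' FRC diameters and Lambert constants (generations 0-16, converted to SI),
#' alveolar-duct lengths (0.7 mm, generations 17-22), alveolar counts
#' (58 alveoli per duct, 480e6 in total) and the duct volume fraction
#' alpha = 0.17 of an alveolar-duct unit.
#'
#' Area constants `A_m` are generation-summed: they are the maximal lumen area
#' of all `2^z` airways of generation `z` taken together, so the per-airway
#' maximal area is `A_m / 2^z`.
#'
#' @param path optional CSV override for the conducting-airway constants.
#' @param alpha_duct duct volume fraction of an alveolar-duct unit.
#' @return an object of class `tree_spec`.
#' @export
build_tree_spec <- function(path = NULL, alpha_duct = 0.17) {
  tab <- lambert_table(path)
  L_ad <- 0.7e-3
  n_gen <- 23L
  z <- 0:22
  spec <- list(
    z = z,
    n_gen = n_gen,
    n_conducting = 17L,
    length = c(tab$l_cm / 100, rep(L_ad, 6L)),
    ref_diameter = c(tab$d_cm / 100, rep(NA_real_, 6L)),
    alpha0 = c(tab$alpha0, rep(NA_real_, 6L)),
    alpha0_prime = c(tab$alpha0_prime_e3_per_pa * 1e-3, rep(NA_real_, 6L)),
    n1 = c(tab$n1, rep(NA_real_, 6L)),
    n2 = c(tab$n2, rep(NA_real_, 6L)),
    A_m = c(tab$A_m_cm2 * 1e-4, rep(NA_real_, 6L)),
    n_alv = c(rep(0L, 17L), rep(58L, 6L)),
    n_airways = 2^z,
    L_ad = L_ad,
    N_a = 480e6,
    ducts_per_acinus = 63L,
    n_adu_total = 2^17 * 63,
    alpha_duct = alpha_duct,
    # Table 1 caption volume, stored as metadata only (see package vignette).
    table1_frc_litre = 1.75
  )
  # Lambert half-pressures of the two sigmoid branches, P1 > 0 and P2 < 0.
  spec$P1 <- spec$alpha0 * spec$n1 / spec$alpha0_prime
  spec$P2 <- -spec$n2 * (1 - spec$alpha0) / spec$alpha0_prime
  stopifnot(
    all(spec$length > 0),
    all(spec$alpha0[1:17] > 0 & spec$alpha0[1:17] < 1),
    all(spec$alpha0_prime[1:17] > 0),
    all(spec$A_m[1:17] > 0),
    round(spec$N_a / spec$n_adu_total) == 58
  )
  class(spec) <- "tree_spec"
  spec
}

#' @export
print.tree_spec <- function(x, ...) {
  cat("Idealized symmetric airway tree: 23 generations\n")
  cat(sprintf("  conducting generations 0-16, acinar generations 17-22 (L_ad = %.1f mm)\n",
              x$L_ad * 1e3))
  cat(sprintf("  alveoli: %g total, 58 per alveolar duct, %d duct units\n",
              x$N_a, x$n_adu_total))
  cat(sprintf("  duct volume fraction alpha = %.2f\n", x$alpha_duct))
  invisible(x)
}

#' Reference lung volumes
#'
#' Standard scaling of the model lung: TLC 6.5 L, VC 5 L, RV 1.5 L, tidal
#' volume at rest 0.5 L. FRC sits at 35% of VC above RV, hence 3.25 L.
#' All fields are stored in m^3.
#'
#' @return an object of class `lung_volumes`.
#' @export
lung_volumes <- function() {
  v <- list(
    TLC = 6.5e-3,
    VC = 5e-3,
    RV = 1.5e-3,
    tidal_rest = 0.5e-3
  )
  v$FRC <- v$RV + 0.35 * v$VC
  stopifnot(v$RV < v$FRC, v$FRC < v$TLC, abs(v$VC - (v$TLC - v$RV)) < 1e-12)
  class(v) <- "lung_volumes"
  v
}

#' @export
print.lung_volumes <- function(x, ...) {
  cat(sprintf("Lung volumes: TLC %.2f L, VC %.2f L, RV %.2f L, FRC %.2f L\n",
              x$TLC * 1e3, x$VC * 1e3, x$RV * 1e3, x$FRC * 1e3))
  invisible(x)
}

#' Alveolar constants derived from the FRC decomposition
#'
#' Given the total alveolar volume at FRC, distributes it over the 480e6
#' alveoli, assumes spherical alveoli, and returns the single-alveolus volume,
#' its diameter and the total gas-exchange surface.
#'
#' @param tree a `tree_spec`.
#' @param vols a `lung_volumes` (unused beyond validation, kept for interface
#'   symmetry).
#' @param frc_alveoli_volume total alveolar volume at FRC, m^3.
#' @return list with `v_a` (m^3), `alveolus_diameter` (m), `exchange_surface`
#'   (m^2).
#' @export
derived_alveolar_constants <- function(tree, vols, frc_alveoli_volume) {
  if (!is.numeric(frc_alveoli_volume) || frc_alveoli_volume <= 0) {
    stop("frc_alveoli_volume must be a positive volume in m^3")
  }
  v_a <- frc_alveoli_volume / tree$N_a
  d <- (6 * v_a / pi)^(1 / 3)
  list(
    v_a = v_a,
    alveolus_diameter = d,
    exchange_surface = tree$N_a * pi * d^2
  )
}

#' Conducting-airway volume implied by the printed reference diameters
#'
#' Sums `2^z * pi * (d/2)^2 * l` over the 17 conducting generations using the
#' tabulated reference diameters. This is a static bookkeeping quantity (the
#' live model always takes lumen areas from the Lambert law, never from the
#' reference diameters).
#'
#' @param tree a `tree_spec`.
#' @return volume in m^3.
#' @export
reference_conducting_volume <- function(tree) {
  i <- 1:17
  sum(tree$n_airways[i] * pi * (tree$ref_diameter[i] / 2)^2 * tree$length[i])
}
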