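# Static mechanics: Lambert sigmoid pressure-area laws for the conducting
# airways, reconstructed quasi-static respiratory-system pressure-volume
# curves for the acini, and the lung-volume fixed point that couples them.

# Vectorized Lambert law over all 17 conducting generations.
# dP: transmural pressure vector of length 17 (Pa, distending positive).
# Returns generation-summed lumen areas (m^2).
.lambert_all <- function(tree, dP) {
  i <- 1:17
  a0 <- tree$alpha0[i]; Am <- tree$A_m[i]
  n1 <- tree$n1[i]; n2 <- tree$n2[i]
  P1 <- tree$P1[i]; P2 <- tree$P2[i]
  neg <- dP <= 0
  S <- numeric(17L)
  if (any(neg)) {
    S[neg] <- a0[neg] * (1 - dP[neg] / P1[neg])^(-n1[neg]) * Am[neg]
  }
  if (any(!neg)) {
    S[!neg] <- (1 - (1 - a0[!neg]) * (1 - dP[!neg] / P2[!neg])^(-n2[!neg])) *
      Am[!neg]
  }
  S
}

# Precompute the conducting-generation Lambert constants as bare vectors
# (hot-loop form; avoids repeated list slicing).
.lambert_consts <- function(tree) {
  i <- 1:17
  list(a0 = tree$alpha0[i], Am = tree$A_m[i], n1 = tree$n1[i],
       n2 = tree$n2[i], P1 = tree$P1[i], P2 = tree$P2[i],
       one_m_a0 = 1 - tree$alpha0[i], l = tree$length[i])
}

# Fused value + derivative of the Lambert law on precomputed constants.
.lambert_vd <- function(lc, dP) {
  S <- dS <- numeric(17L)
  neg <- dP <= 0
  if (any(neg)) {
    b <- 1 - dP[neg] / lc$P1[neg]
    pw <- b^(-lc$n1[neg] - 1)
    S[neg] <- lc$a0[neg] * pw * b * lc$Am[neg]
    dS[neg] <- lc$a0[neg] * lc$n1[neg] / lc$P1[neg] * pw * lc$Am[neg]
  }
  pos <- !neg
  if (any(pos)) {
    b <- 1 - dP[pos] / lc$P2[pos]
    pw <- b^(-lc$n2[pos] - 1)
    S[pos] <- (1 - lc$one_m_a0[pos] * pw * b) * lc$Am[pos]
    dS[pos] <- -lc$one_m_a0[pos] * lc$n2[pos] / lc$P2[pos] * pw * lc$Am[pos]
  }
  list(S = S, dS = dS)
}

# Derivative dS/d(dP) of the Lambert law, same conventions as .lambert_all.
.lambert_all_deriv <- function(tree, dP) {
  i <- 1:17
  a0 <- tree$alpha0[i]; Am <- tree$A_m[i]
  n1 <- tree$n1[i]; n2 <- tree$n2[i]
  P1 <- tree$P1[i]; P2 <- tree$P2[i]
  neg <- dP <= 0
  d <- numeric(17L)
  if (any(neg)) {
    d[neg] <- a0[neg] * n1[neg] / P1[neg] *
      (1 - dP[neg] / P1[neg])^(-n1[neg] - 1) * Am[neg]
  }
  if (any(!neg)) {
    d[!neg] <- -(1 - a0[!neg]) * n2[!neg] / P2[!neg] *
      (1 - dP[!neg] / P2[!neg])^(-n2[!neg] - 1) * Am[!neg]
  }
  d
}

#' Lambert pressure-area law for a conducting generation
#'
#' Generation-summed lumen area of all `2^z` airways of generation `z` as a
#' sigmoid function of transmural pressure `dP` (positive distending):
#' for `dP <= 0`, `alpha0 (1 - dP/P1)^(-n1) A_m`; for `dP > 0`,
#' `(1 - (1 - alpha0)(1 - dP/P2)^(-n2)) A_m`, with
#' `P1 = alpha0 n1 / alpha0'` and `P2 = -n2 (1 - alpha0) / alpha0'`.
#' The law is C1 at `dP = 0` (value `alpha0 A_m`, slope `alpha0' A_m`) and
#' increases from 0 to the maximal area `A_m`.
#'
#' @param tree a `tree_spec`.
#' @param z generation index or vector of indices (0..16).
#' @param dP transmural pressure(s), Pa; recycled against `z`.
#' @param deriv if TRUE return dS/d(dP) instead of S.
#' @return generation-summed lumen area(s), m^2 (or m^2/Pa if `deriv`).
#' @export
lambert_area <- function(tree, z, dP, deriv = FALSE) {
  if (any(z < 0 | z > 16)) {
    stop("the Lambert law applies to conducting generations 0..16 only")
  }
  if (any(!is.finite(dP))) stop("dP must be finite")
  n <- max(length(z), length(dP))
  z <- rep_len(as.integer(z), n); dP <- rep_len(dP, n)
  i <- z + 1L
  a0 <- tree$alpha0[i]; Am <- tree$A_m[i]
  n1 <- tree$n1[i]; n2 <- tree$n2[i]
  P1 <- tree$P1[i]; P2 <- tree$P2[i]
  neg <- dP <= 0
  out <- numeric(n)
  if (!deriv) {
    out[neg] <- a0[neg] * (1 - dP[neg] / P1[neg])^(-n1[neg]) * Am[neg]
    out[!neg] <- (1 - (1 - a0[!neg]) * (1 - dP[!neg] / P2[!neg])^(-n2[!neg])) *
      Am[!neg]
  } else {
    out[neg] <- a0[neg] * n1[neg] / P1[neg] *
      (1 - dP[neg] / P1[neg])^(-n1[neg] - 1) * Am[neg]
    out[!neg] <- -(1 - a0[!neg]) * n2[!neg] / P2[!neg] *
      (1 - dP[!neg] / P2[!neg])^(-n2[!neg] - 1) * Am[!neg]
  }
  out
}

#' Rest-state transmural pressure consistent with the reference diameters
#'
#' The transmural pressure at which the Lambert laws reproduce the tabulated
#' conducting-airway volume (each generation's reference diameter individually
#' matches the sigmoid within about 1 Pa of this common value, which is the
#' anchor that also reproduces the printed FRC decomposition of the lung into
#' bronchial-tree and alveolar volumes).
#'
#' @param tree a `tree_spec`.
#' @return transmural pressure, Pa (about 50 Pa).
#' @export
table1_transmural <- function(tree = build_tree_spec()) {
  ref <- reference_conducting_volume(tree)
  l <- tree$length[1:17]
  stats::uniroot(function(dp) sum(.lambert_all(tree, rep(dp, 17L)) * l) - ref,
                 c(1, 400), tol = 1e-10)$root
}

#' Build the respiratory-system pressure-volume curves
#'
#' The quasi-static mechanics of the parenchyma and thorax are carried by two
#' monotone curves: `static_volume(dP)`, the relaxed respiratory-system volume
#' under a uniform airway-minus-thorax pressure difference `dP`, and
#' `tissue_pressure(V)`, the distending pressure the lung tissue applies on
#' the bronchi at lung volume `V`.
#'
#' Default closed forms: a logistic volume curve
#' `V(dP) = RV + VC / (1 + exp(-(dP - P_half)/P_scale))` anchored so that
#' `V(0) = FRC` and so that the quasi-static excursion under a `P_v` chest
#' depression equals the rest tidal volume (0.5 L, giving a rest compliance of
#' about 0.1 L/cmH2O); and an exponential recoil curve
#' `P_tissue(V) = A (exp(k (V - RV)) - 1)` anchored at
#' `P_tissue(FRC) = frc_transmural` (500 Pa, the nominal rest transmural
#' pressure) and `P_tissue(TLC) = p_tlc` (30 cmH2O). The alternative anchor
#' [table1_transmural()] (about 50 Pa) makes the conducting airways take
#' their tabulated reference diameters at rest and reproduces the printed
#' FRC volume decomposition exactly, but leaves so little recoil under
#' strong chest compressions that mid-tree airways collapse onto their mucus
#' and trap the gas; the 500 Pa default preserves the documented maneuver
#' dynamics. Either curve may be replaced by a user-tabulated monotone
#' table (two-column: pressure cmH2O, volume L), interpolated with monotone
#' splines.
#'
#' @param vols a `lung_volumes`.
#' @param tidal_target rest tidal volume used to anchor the volume curve, m^3.
#' @param P_v ventilation amplitude used for the anchor, Pa (negative).
#' @param frc_transmural tissue (transmural) pressure at FRC, Pa.
#' @param p_tlc tissue pressure at TLC, Pa.
#' @param volume_table,tissue_table optional data.frames
#'   (`pressure_cmh2o`, `volume_l`) overriding the closed forms.
#' @return an object of class `pv_curves`: list of functions `static_volume`,
#'   `static_volume_inv`, `static_volume_deriv`, `tissue_pressure`,
#'   `tissue_pressure_deriv`, plus `vols` and the calibrated parameters.
#' @export
build_pv_curves <- function(vols = lung_volumes(),
                            tidal_target = vols$tidal_rest,
                            P_v = cmh2o(-5),
                            frc_transmural = 500,
                            p_tlc = cmh2o(30),
                            volume_table = NULL,
                            tissue_table = NULL) {
  RV <- vols$RV; TLC <- vols$TLC; VC <- TLC - RV
  f0 <- (vols$FRC - RV) / VC                    # 0.35
  f1 <- f0 + tidal_target / VC                  # fraction at peak inspiration
  if (f1 >= 1) stop("tidal_target too large for the logistic volume curve")
  logit <- function(p) log(p / (1 - p))
  P_scale <- -P_v / (logit(f1) - logit(f0))
  P_half <- P_scale * (-logit(f0))
  if (P_scale <= 0) stop("volume-curve calibration failed (non-positive scale)")

  if (is.null(volume_table)) {
    static_volume <- function(dP) RV + VC / (1 + exp(-(dP - P_half) / P_scale))
    static_volume_inv <- function(V) {
      if (any(V <= RV | V >= TLC)) stop("volume outside (RV, TLC)")
      P_half + P_scale * log((V - RV) / (TLC - V))
    }
    static_volume_deriv <- function(dP) {
      s <- 1 / (1 + exp(-(dP - P_half) / P_scale))
      VC * s * (1 - s) / P_scale
    }
  } else {
    fns <- .monotone_curve(volume_table, value = "volume")
    static_volume <- fns$fun
    static_volume_inv <- fns$inv
    static_volume_deriv <- fns$deriv
  }

  # Exponential recoil tissue curve: solve k from the two pressure anchors.
  if (is.null(tissue_table)) {
    ratio <- p_tlc / frc_transmural
    g <- function(k) {
      (exp(k * (TLC - RV)) - 1) / (exp(k * (vols$FRC - RV)) - 1) - ratio
    }
    k <- stats::uniroot(g, c(1e-6, 600 / (TLC - RV)), tol = 1e-12)$root
    A <- frc_transmural / (exp(k * (vols$FRC - RV)) - 1)
    tissue_pressure <- function(V) A * (exp(k * (V - RV)) - 1)
    tissue_pressure_deriv <- function(V) A * k * exp(k * (V - RV))
  } else {
    fns <- .monotone_curve(tissue_table, value = "pressure")
    tissue_pressure <- fns$fun
    tissue_pressure_deriv <- fns$deriv
    k <- NA_real_; A <- NA_real_
  }

  structure(list(
    static_volume = static_volume,
    static_volume_inv = static_volume_inv,
    static_volume_deriv = static_volume_deriv,
    tissue_pressure = tissue_pressure,
    tissue_pressure_deriv = tissue_pressure_deriv,
    vols = vols,
    params = list(P_half = P_half, P_scale = P_scale,
                  recoil_A = A, recoil_k = k,
                  frc_transmural = frc_transmural, p_tlc = p_tlc)
  ), class = "pv_curves")
}

# Monotone interpolator for a user-supplied two-column curve table
# (pressure cmH2O, volume L). `value` names the output axis.
.monotone_curve <- function(tab, value = c("volume", "pressure")) {
  value <- match.arg(value)
  if (!all(c("pressure_cmh2o", "volume_l") %in% names(tab))) {
    stop("curve table needs columns pressure_cmh2o and volume_l")
  }
  p <- cmh2o(tab$pressure_cmh2o)
  v <- tab$volume_l * 1e-3
  if (is.unsorted(p, strictly = TRUE) || is.unsorted(v, strictly = TRUE)) {
    stop("curve table must be strictly increasing in both columns")
  }
  if (value == "volume") {
    fun <- stats::splinefun(p, v, method = "hyman")
    inv <- stats::splinefun(v, p, method = "hyman")
    list(fun = fun, inv = inv,
         deriv = function(x) fun(x, deriv = 1L))
  } else {
    fun <- stats::splinefun(v, p, method = "hyman")
    list(fun = fun, inv = NULL,
         deriv = function(x) fun(x, deriv = 1L))
  }
}

#' @export
print.pv_curves <- function(x, ...) {
  cat("Respiratory-system pressure-volume curves\n")
  cat(sprintf("  static_volume(0) = %.3f L; tissue_pressure(FRC) = %.0f Pa\n",
              x$static_volume(0) * 1e3, x$tissue_pressure(x$vols$FRC)))
  cat(sprintf("  rest compliance = %.4f L/cmH2O\n",
              x$static_volume_deriv(0) * 1e3 * CMH2O_PA))
  invisible(x)
}

#' Tracheobronchial tree volume
#'
#' Volume of the 17 conducting generations at lung volume `V_L` and
#' mid-airway pressures `P_air`: the sum over generations of the
#' generation-summed Lambert area at transmural pressure
#' `P_tissue(V_L) - P_air` times the airway length.
#'
#' @param curves a `pv_curves`.
#' @param tree a `tree_spec`.
#' @param V_L lung volume, m^3, strictly inside (RV, TLC).
#' @param P_air mid-airway pressure, Pa: scalar or vector of length 17 or 23
#'   (only the first 17 entries are used).
#' @return volume in m^3.
#' @export
tracheobronchial_volume <- function(curves, tree, V_L, P_air = 0) {
  if (V_L <= curves$vols$RV || V_L >= curves$vols$TLC) {
    stop("V_L outside the open interval (RV, TLC)")
  }
  P_air <- rep_len(P_air, max(17L, length(P_air)))[1:17]
  Pt <- curves$tissue_pressure(V_L)
  sum(.lambert_all(tree, Pt - P_air) * tree$length[1:17])
}

#' Alveolar-duct-unit mechanics
#'
#' Volume of one alveolar-duct unit (an alveolar duct plus its 58 alveoli) in
#' an acinar generation, from the relaxed respiratory-system curve: the lung
#' volume that the whole lung would take under the uniform pressure difference
#' `P_air_z - P_ext`, minus the tracheobronchial volume in that configuration
#' (airway pressures at the atmospheric reference), divided by the number of
#' duct units. A fixed fraction `alpha` of the unit volume is duct lumen, the
#' rest is shared by the 58 alveoli.
#'
#' @param curves a `pv_curves`.
#' @param tree a `tree_spec`.
#' @param P_air_z air pressure in the duct, Pa.
#' @param P_ext chest pressure, Pa.
#' @return list with `v_adu` (m^3), `duct_area` (per-airway lumen area, m^2),
#'   `v_alv` (single-alveolus volume, m^3).
#' @export
alveolar_duct_unit <- function(curves, tree, P_air_z, P_ext) {
  V_rs <- curves$static_volume(P_air_z - P_ext)
  v_adu <- (V_rs - tracheobronchial_volume(curves, tree, V_rs, 0)) /
    tree$n_adu_total
  list(
    v_adu = v_adu,
    duct_area = tree$alpha_duct * v_adu / tree$L_ad,
    v_alv = (1 - tree$alpha_duct) * v_adu / 58
  )
}

# Fast internal acinar evaluation for the 6 acinar generations at once.
# P_acin: vector of 6 duct pressures (generations 17..22). Returns list with
# per-unit volumes and derived areas/volumes, all vectors of length 6.
.acinar_units <- function(curves, tree, P_acin, P_ext) {
  dP <- P_acin - P_ext
  V_rs <- curves$static_volume(dP)
  # V_tbt at the relaxed configuration with atmospheric airway pressure
  Pt <- curves$tissue_pressure(V_rs)
  l <- tree$length[1:17]
  vtbt <- vapply(Pt, function(p) sum(.lambert_all(tree, rep(p, 17L)) * l),
                 numeric(1))
  v_adu <- (V_rs - vtbt) / tree$n_adu_total
  list(
    v_adu = v_adu,
    duct_area = tree$alpha_duct * v_adu / tree$L_ad,
    v_alv = (1 - tree$alpha_duct) * v_adu / 58
  )
}

#' Solve the lung-volume fixed point
#'
#' The lung volume is the sum of the acinar volume (a function of the acinar
#' duct pressures and the chest pressure only) and of the tracheobronchial
#' volume, which itself depends on the lung volume through the tissue
#' pressure. This solves `V = V_ac + V_tbt(V, P_air)` by a safeguarded Newton
#' iteration (bisection fallback) to an absolute residual below `tol` m^3.
#'
#' @param curves a `pv_curves`.
#' @param tree a `tree_spec`.
#' @param P_air mid-airway pressures, Pa: scalar or vector of length 23.
#' @param P_ext chest pressure, Pa.
#' @param tol residual tolerance, m^3.
#' @param V_init optional warm start, m^3.
#' @return lung volume, m^3.
#' @export
solve_lung_volume <- function(curves, tree, P_air = 0, P_ext = 0,
                              tol = 1e-9, V_init = NULL) {
  P_air <- rep_len(P_air, 23L)
  ac <- .acinar_units(curves, tree, P_air[18:23], P_ext)
  V_ac <- sum(tree$n_airways[18:23] * ac$v_adu)
  .solve_VL(curves, tree, P_air[1:17], V_ac, tol = tol, V_init = V_init)
}

# Scalar Newton with bisection safeguard for V = V_ac + V_tbt(V, P_cond).
# The default tolerance is far below the user-facing 1e-9 m^3 contract: the
# stepper differentiates this solve numerically, so residual noise must stay
# below the finite-difference scale.
.solve_VL <- function(curves, tree, P_cond, V_ac, tol = 1e-14, V_init = NULL,
                      lc = NULL) {
  RV <- curves$vols$RV; TLC <- curves$vols$TLC
  if (is.null(lc)) lc <- .lambert_consts(tree)
  l <- lc$l
  tissue <- curves$tissue_pressure
  tissue_d <- curves$tissue_pressure_deriv
  fval <- function(V) {
    V - V_ac - sum(.lambert_vd(lc, tissue(V) - P_cond)$S * l)
  }
  lo <- RV + 1e-9; hi <- TLC - 1e-9
  # under extreme candidate pressures the fixed point can leave (RV, TLC);
  # pin at the boundary so the outer iteration sees a continuous (rejected)
  # configuration instead of an abort
  if (fval(lo) > 0) return(lo)
  if (fval(hi) < 0) return(hi)
  V <- if (!is.null(V_init) && V_init > lo && V_init < hi) V_init else
    V_ac / (1 - 0.05)  # crude start: tbt is a few percent of the total
  if (V <= lo || V >= hi) V <- (lo + hi) / 2
  for (it in 1:60) {
    vd <- .lambert_vd(lc, tissue(V) - P_cond)
    f <- V - V_ac - sum(vd$S * l)
    if (abs(f) < tol) return(V)
    if (f > 0) hi <- V else lo <- V
    slope <- 1 - sum(vd$dS * l) * tissue_d(V)
    V_new <- V - f / slope
    if (!is.finite(V_new) || V_new <= lo || V_new >= hi) V_new <- (lo + hi) / 2
    V <- V_new
  }
  stop("lung-volume solve did not converge; last residual ", format(f))
}

#' Airway mechanics map
#'
#' The vectorial mechanics map: given the chest pressure and the 23 mid-airway
#' pressures, returns the generation-summed bronchus lumen areas. Conducting
#' generations follow the Lambert law at transmural pressure
#' `P_tissue(V_L) - P_air`; acinar generations get `alpha * v_adu / L_ad` per
#' duct. The lung volume is solved internally.
#'
#' @param curves a `pv_curves`.
#' @param tree a `tree_spec`.
#' @param P_ext chest pressure, Pa.
#' @param P_air mid-airway pressures, Pa (scalar or length 23).
#' @param V_init optional lung-volume warm start.
#' @return list with `S_b` (23 generation-summed areas, m^2), `V_L` (m^3),
#'   `P_tissue` (Pa), `v_adu` and `v_alv` (length-6 acinar vectors, m^3).
#' @export
mechanics_map <- function(curves, tree, P_ext, P_air = 0, V_init = NULL) {
  P_air <- rep_len(P_air, 23L)
  ac <- .acinar_units(curves, tree, P_air[18:23], P_ext)
  V_ac <- sum(tree$n_airways[18:23] * ac$v_adu)
  V_L <- .solve_VL(curves, tree, P_air[1:17], V_ac, V_init = V_init)
  Pt <- curves$tissue_pressure(V_L)
  S_b <- numeric(23L)
  S_b[1:17] <- .lambert_all(tree, Pt - P_air[1:17])
  S_b[18:23] <- ac$duct_area * tree$n_airways[18:23]
  list(S_b = S_b, V_L = V_L, P_tissue = Pt,
       v_adu = ac$v_adu, v_alv = ac$v_alv)
}
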