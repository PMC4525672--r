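# Closed-form hydrodynamics of a Newtonian air core surrounded by a Bingham
# mucus annulus in a rigid cylinder, under fully developed axisymmetric
# Stokes flow.
#
# With a uniform axial pressure gradient C = dp/dz (z oriented from the mouth
# toward the alveoli), the shear stress is tau(r) = C r / 2.  Mucus yields
# only where |tau| > sigma0, i.e. outside the yield radius r0 = |2 sigma0/C|:
#   r0 >= r_b : the whole annulus is rigid and anchored at the wall;
#   r0 <= r_a : the whole annulus is sheared;
#   r_a < r0 < r_b : a rigid plug (attached to the interface) rides on a
#                    sheared layer against the wall.
# Velocity profiles integrate in closed form, so both fluxes and the inverse
# map flow -> gradient are piecewise-analytic.  Flux sign is -sign(C): flow
# runs down the pressure gradient, and a negative flux points up the tree,
# toward the mouth.

#' Physical constants of air and mucus
#'
#' Air is Newtonian (viscosity 1.8e-5 Pa s, density 1 kg/m^3); mucus is a
#' Bingham fluid with yield stress 0.1 Pa and post-yield viscosity 0.1 Pa s,
#' density of water. Densities are metadata only: the flow model is inertialess.
#'
#' @param mu_air,rho_air,sigma0,mu_mucus,rho_mucus override any constant.
#' @return an object of class `fluid_constants`.
#' @export
fluid_constants <- function(mu_air = 1.8e-5, rho_air = 1,
                            sigma0 = 0.1, mu_mucus = 0.1, rho_mucus = 1000) {
  stopifnot(mu_air > 0, rho_air > 0, sigma0 >= 0, mu_mucus > 0, rho_mucus > 0)
  structure(list(mu_air = mu_air, rho_air = rho_air, sigma0 = sigma0,
                 mu_mucus = mu_mucus, rho_mucus = rho_mucus),
            class = "fluid_constants")
}

#' @export
print.fluid_constants <- function(x, ...) {
  cat(sprintf(
    "Fluids: air mu = %.2g Pa s; mucus sigma0 = %.2g Pa, mu = %.2g Pa s\n",
    x$mu_air, x$sigma0, x$mu_mucus))
  invisible(x)
}

#' Annulus geometry from lumen areas
#'
#' Converts per-airway air and bronchus lumen areas (disk shaped) to radii.
#' Generation-summed areas must be divided by `2^z` before calling.
#'
#' @param S_a,S_b per-airway air and bronchus lumen areas, m^2.
#' @return list with `r_a`, `r_b` (m).
#' @export
annulus_geometry <- function(S_a, S_b) {
  if (any(S_a <= 0) || any(S_b <= 0)) stop("degenerate geometry: areas must be positive")
  if (any(S_a > S_b * (1 + 1e-12))) stop("air lumen cannot exceed bronchus lumen")
  list(r_a = sqrt(pmin(S_a, S_b) / pi), r_b = sqrt(S_b / pi))
}

#' Bingham yield radius
#'
#' Radius at which the shear stress `|C| r / 2` reaches the mucus yield
#' stress: `r0 = |2 sigma0 / C|`, with `Inf` for a vanishing gradient
#' (mucus rigid everywhere).
#'
#' @param C pressure gradient, Pa/m.
#' @param sigma0 yield stress, Pa.
#' @return radius, m (possibly `Inf`).
#' @export
yield_radius <- function(C, sigma0 = 0.1) {
  ifelse(C == 0, Inf, abs(2 * sigma0 / C))
}

# Internal vectorized kernel: air and mucus fluxes for gradient C in a tube
# with core radius ra and wall radius rb.  All arguments recycled to a common
# length.  Returns list(phi_air, phi_mucus).
.flows_kernel <- function(C, ra, rb, mu_a, mu_m, sigma0,
                          rigid_interface = FALSE) {
  n <- max(length(C), length(ra), length(rb))
  C <- rep_len(C, n); ra <- rep_len(ra, n); rb <- rep_len(rb, n)
  s <- sign(C)
  absC <- abs(C)
  no_muc <- ra >= rb * (1 - 1e-14)
  # yield radius; Inf for C == 0
  r0 <- ifelse(C == 0, Inf, 2 * sigma0 / pmax(absC, .Machine$double.xmin))
  solid <- (r0 >= rb) | no_muc
  full <- (!solid) & (r0 <= ra)
  part <- (!solid) & (!full)

  # interface velocity of the air core
  u_i <- numeric(n)
  if (!rigid_interface) {
    if (any(full)) {
      u_i[full] <- (C[full] / (4 * mu_m)) * (ra[full]^2 - rb[full]^2) -
        (sigma0 * s[full] / mu_m) * (ra[full] - rb[full])
    }
    if (any(part)) {
      rp <- r0[part]
      u_i[part] <- (C[part] / (4 * mu_m)) * (rp^2 - rb[part]^2) -
        (sigma0 * s[part] / mu_m) * (rp - rb[part])
    }
  }
  u_i[no_muc] <- 0
  phi_air <- pi * ra^2 * u_i - C * pi * ra^4 / (8 * mu_a)

  # mucus flux: plug + sheared layer
  phi_m <- numeric(n)
  yielded <- full | part
  if (any(yielded)) {
    a <- pmax(r0[yielded], ra[yielded])   # inner edge of the sheared layer
    b <- rb[yielded]
    Cy <- C[yielded]; sy <- s[yielded]
    I1 <- -(pi / 2) * (b^2 - a^2)^2
    I2 <- 2 * pi * (-b^3 / 6 - a^3 / 3 + b * a^2 / 2)
    phi_shear <- (Cy / (4 * mu_m)) * I1 - (sigma0 * sy / mu_m) * I2
    u_plug <- (Cy / (4 * mu_m)) * (a^2 - b^2) - (sigma0 * sy / mu_m) * (a - b)
    phi_plug <- pi * (a^2 - ra[yielded]^2) * u_plug
    phi_m[yielded] <- phi_shear + phi_plug
  }
  phi_m[no_muc] <- 0
  list(phi_air = phi_air, phi_mucus = phi_m)
}

#' Air and mucus fluxes from the pressure gradient
#'
#' Closed-form fluxes of the core-annular flow (see the module header).
#' Limiting cases: with no mucus the air flux is pure Poiseuille
#' `-C pi r_b^4 / (8 mu_a)`; with a rigid annulus (`r0 >= r_b`) the air flux
#' is Poiseuille in the core radius and the mucus flux is exactly zero.
#'
#' @param C pressure gradient, Pa/m (vectorized).
#' @param geom list with `r_a`, `r_b` (see [annulus_geometry()]).
#' @param fluids a [fluid_constants()].
#' @param rigid_interface if TRUE, hold the air-mucus interface still when
#'   computing the air flux (sensitivity variant; mucus flux is unchanged).
#' @return list with `phi_air`, `phi_mucus` (m^3/s); negative values point
#'   toward the mouth.
#' @export
flows_from_gradient <- function(C, geom, fluids = fluid_constants(),
                                rigid_interface = FALSE) {
  if (any(geom$r_a <= 0)) stop("degenerate geometry: r_a must be positive")
  .flows_kernel(C, geom$r_a, geom$r_b, fluids$mu_air, fluids$mu_mucus,
                fluids$sigma0, rigid_interface = rigid_interface)
}

# Internal vectorized inverse: pressure gradient C from the air flux.
# Piecewise-analytic: linear on the rigid-annulus branch, quadratic on the
# partially yielded branch, linear again on the fully yielded branch.
.gradient_kernel <- function(phi, ra, rb, mu_a, mu_m, sigma0,
                             rigid_interface = FALSE) {
  n <- max(length(phi), length(ra), length(rb))
  phi <- rep_len(phi, n); ra <- rep_len(ra, n); rb <- rep_len(rb, n)
  k_core <- pi * ra^4 / (8 * mu_a)          # |phi| per |C| on the rigid branch
  no_muc <- ra >= rb * (1 - 1e-14)
  if (rigid_interface) {
    return(-phi / k_core)
  }
  C <- numeric(n)
  s <- -sign(phi)                            # flux runs against the gradient
  ap <- abs(phi)
  Cy <- 2 * sigma0 / rb                      # |C| at yield onset
  Cf <- 2 * sigma0 / ra                      # |C| at full yield
  b1 <- k_core * Cy                          # |phi| at yield onset
  rigid <- no_muc | (ap <= b1)
  C[rigid] <- -phi[rigid] / k_core[rigid]
  todo <- !rigid
  if (any(todo)) {
    # |phi| at the partial/full-yield boundary (|C| = Cf)
    kf <- .flows_kernel(-Cf[todo], ra[todo], rb[todo], mu_a, mu_m, sigma0)
    b2 <- kf$phi_air                         # positive
    idx <- which(todo)
    partial <- idx[ap[idx] <= b2]
    fully <- setdiff(idx, partial)
    if (length(partial)) {
      # solve a C^2 + b C + c = 0 on the signed branch
      sp <- s[partial]
      a_q <- -(pi * ra[partial]^2 * rb[partial]^2 / (4 * mu_m) +
                 pi * ra[partial]^4 / (8 * mu_a))
      b_q <- pi * ra[partial]^2 * sigma0 * sp * rb[partial] / mu_m -
        phi[partial]
      c_q <- -pi * ra[partial]^2 * sigma0^2 / mu_m
      disc <- sqrt(pmax(b_q^2 - 4 * a_q * c_q, 0))
      # both roots share sign(sp); select by forward verification (robust
      # even when rounding pushes a root marginally across the regime edge)
      C1 <- (-b_q + disc) / (2 * a_q)
      C2 <- (-b_q - disc) / (2 * a_q)
      f1 <- .flows_kernel(C1, ra[partial], rb[partial], mu_a, mu_m,
                          sigma0)$phi_air
      f2 <- .flows_kernel(C2, ra[partial], rb[partial], mu_a, mu_m,
                          sigma0)$phi_air
      C[partial] <- ifelse(abs(f1 - phi[partial]) <= abs(f2 - phi[partial]),
                           C1, C2)
    }
    if (length(fully)) {
      sf <- s[fully]
      slope <- pi * ra[fully]^2 * (ra[fully]^2 - rb[fully]^2) / (4 * mu_m) -
        pi * ra[fully]^4 / (8 * mu_a)        # negative
      inter <- -pi * ra[fully]^2 * sigma0 * sf * (ra[fully] - rb[fully]) / mu_m
      C[fully] <- (phi[fully] - inter) / slope
    }
  }
  C
}

#' Pressure gradient from the air flux (the inverse map F)
#'
#' Inverts the strictly decreasing map `C -> phi_air` of
#' [flows_from_gradient()]. The inversion is piecewise-analytic: exactly
#' linear while the mucus annulus is rigid, the root of a quadratic on the
#' partially yielded branch, and linear again once the annulus is fully
#' sheared.
#'
#' @inheritParams flows_from_gradient
#' @param phi_air air flux, m^3/s (vectorized).
#' @return pressure gradient `C`, Pa/m.
#' @export
gradient_from_airflow <- function(phi_air, geom, fluids = fluid_constants(),
                                  rigid_interface = FALSE) {
  if (any(geom$r_a <= 0)) stop("degenerate geometry: r_a must be positive")
  .gradient_kernel(phi_air, geom$r_a, geom$r_b, fluids$mu_air,
                   fluids$mu_mucus, fluids$sigma0,
                   rigid_interface = rigid_interface)
}

#' Mucus flux from the pressure gradient (the map G)
#'
#' Mucus moves only where the air-driven shear exceeds the yield stress:
#' the flux is exactly zero whenever `|C| <= 2 sigma0 / r_b`, and otherwise
#' equals the closed-form annulus flux of [flows_from_gradient()]. Negative
#' values point up the tree, toward the mouth.
#'
#' @inheritParams flows_from_gradient
#' @return mucus flux, m^3/s.
#' @export
mucus_outflow <- function(C, geom, fluids = fluid_constants()) {
  flows_from_gradient(C, geom, fluids)$phi_mucus
}

#' Quadrature oracle for the annular profiles
#'
#' Independent validation path for the closed forms: builds the radial
#' velocity profile by numerical quadrature of `du/dr = tau/mu` (air core)
#' and `du/dr = (tau - sigma0 sign(tau))/mu_m` (sheared mucus) inward from
#' the no-slip wall, then integrates `2 pi r u(r)` numerically for both
#' fluxes. Test-only; never called by the time stepper.
#'
#' @inheritParams flows_from_gradient
#' @param rel.tol quadrature tolerance.
#' @return list with `phi_air`, `phi_mucus` (m^3/s).
#' @export
profile_oracle <- function(C, geom, fluids = fluid_constants(),
                           rel.tol = 1e-10) {
  stopifnot(length(C) == 1L)
  ra <- geom$r_a; rb <- geom$r_b
  mu_a <- fluids$mu_air; mu_m <- fluids$mu_mucus; sigma0 <- fluids$sigma0
  tau <- function(r) C * r / 2
  du_mucus <- function(r) {
    t <- tau(r)
    ifelse(abs(t) > sigma0, (t - sigma0 * sign(t)) / mu_m, 0)
  }
  u_mucus <- function(r) {
    # velocity at radius r in the annulus, integrating from the wall
    vapply(r, function(ri) {
      if (ri >= rb) return(0)
      -stats::integrate(du_mucus, ri, rb, rel.tol = rel.tol,
                        abs.tol = 0)$value
    }, numeric(1))
  }
  if (ra >= rb * (1 - 1e-14)) {
    u_i <- 0
    phi_m <- 0
  } else {
    r0 <- yield_radius(C, sigma0)
    u_i <- u_mucus(min(max(r0, ra), rb))
    phi_m <- stats::integrate(function(r) 2 * pi * r * u_mucus(pmax(r, min(r0, rb))),
                              ra, rb, rel.tol = rel.tol, abs.tol = 0)$value
    # note: within the plug (r < r0) the velocity is that at r0, which the
    # pmax() above enforces.
  }
  u_air <- function(r) {
    u_i + vapply(r, function(ri)
      stats::integrate(function(x) tau(x) / mu_a, ra, ri,
                       rel.tol = rel.tol, abs.tol = 0)$value, numeric(1))
  }
  phi_a <- stats::integrate(function(r) 2 * pi * r * u_air(r), 0, ra,
                            rel.tol = rel.tol, abs.tol = 0)$value
  list(phi_air = phi_a, phi_mucus = phi_m)
}

#' Air-core hydrodynamic resistance
#'
#' Per-airway Poiseuille resistance of the air core,
#' `8 mu_a l / (pi r_a^4)` (rigid-interface approximation).
#'
#' @param r_a air-core radius, m (vectorized).
#' @param length airway length, m.
#' @param fluids a [fluid_constants()].
#' @return resistance, Pa s/m^3.
#' @export
airway_air_resistance <- function(r_a, length, fluids = fluid_constants()) {
  if (any(r_a <= 0)) stop("degenerate geometry: r_a must be positive")
  8 * fluids$mu_air * length / (pi * r_a^4)
}

#' Tree hydrodynamic resistance
#'
#' Aggregates per-airway air-core resistances over the conducting tree:
#' generations in series, the `2^z` identical airways of a generation in
#' parallel.
#'
#' @param S_a generation-summed air lumen areas (length >= 17; only the
#'   conducting generations are used), m^2.
#' @param tree a `tree_spec`.
#' @param fluids a [fluid_constants()].
#' @return resistance, Pa s/m^3.
#' @export
tree_resistance <- function(S_a, tree, fluids = fluid_constants()) {
  i <- 1:17
  r_a <- sqrt(S_a[i] / tree$n_airways[i] / pi)
  sum(airway_air_resistance(r_a, tree$length[i], fluids) / tree$n_airways[i])
}
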