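# Coupled quasi-static time integration on the airway tree.
#
# The unknown of each backward-Euler step is the 23-vector of mid-airway
# pressures P_air.  A candidate P_air determines, through the mechanics map,
# the lung volume (an inner scalar Newton solve), the bronchus areas and the
# alveolar volumes; backward differences of the air areas and alveolar
# volumes give the air flows by a leaf-to-root recursion; the two-phase
# closed forms convert flows to pressure gradients; and accumulating the
# gradients from the trachea (atmospheric reference) yields the pressures the
# candidate must reproduce.  A damped chord-Newton iteration (finite-
# difference Jacobian, reused across steps) drives that residual to zero.
# Mucus areas are updated with end-of-step fluxes, iterated to consistency
# (fully implicit mode) or applied once after convergence (semi-implicit).
#
# Sign conventions: fluxes are positive down the tree (mouth to alveoli), so
# a negative mucus flux moves toward the mouth and a negative trachea mucus
# flux feeds the expelled volume; C = dp/d(depth), so fluxes carry the sign
# of -C.

#' Time-stepper configuration
#'
#' @param dt time step, s. The default resolves a 20 Hz oscillation with 10
#'   steps per period.
#' @param newton_tol convergence tolerance on the pressure residual, Pa.
#' @param newton_tol_fallback acceptance tolerance, Pa, for steps where the
#'   damped iteration provably stalls on a small positive residual floor
#'   (this happens at mucus yield-transition events, where the implicit
#'   system of a full-size step can have no exact root); such steps are
#'   counted in the diagnostics and retried at halved dt first.
#' @param max_iter maximum Newton iterations per attempt.
#' @param r_a_floor_frac air-core radius floor, as a fraction of the bronchus
#'   radius (guards the flux closed forms against occlusion).
#' @param mucus_mode `"implicit"` iterates the mucus areas inside the step;
#'   `"semi"` updates them once from the converged air state.
#' @param wall_tau relaxation time, s, with which conducting bronchus walls
#'   track their static (Lambert) lumen area. Zero recovers strictly
#'   quasi-static walls; the small default regularizes the compressive
#'   feedback loop (the Lambert compliance times the fourth-power core
#'   resistance, amplified by `1/dt`) whose gain otherwise exceeds one at
#'   airway-collapse folds, where the strictly quasi-static implicit system
#'   provably loses its root. Equilibria are unaffected. Acinar mechanics
#'   stays fully quasi-static.
#' @param max_outer maximum mucus iterations per step (implicit mode).
#' @param outer_tol convergence tolerance on mucus areas, m^2.
#' @param max_substep_depth levels of automatic step halving on Newton
#'   failure.
#' @param jac_min_refresh refresh the chord Jacobian at least every this many
#'   accepted solves (it is also refreshed adaptively whenever convergence
#'   degrades).
#' @return an object of class `stepper_config`.
#' @export
stepper_config <- function(dt = 5e-3, newton_tol = 1e-4,
                           newton_tol_fallback = 2e-2, max_iter = 30,
                           r_a_floor_frac = 1e-2,
                           mucus_mode = c("implicit", "semi"),
                           wall_tau = 2e-2,
                           max_outer = 8, outer_tol = 1e-10,
                           max_substep_depth = 4, jac_min_refresh = 200) {
  mucus_mode <- match.arg(mucus_mode)
  stopifnot(dt > 0, newton_tol > 0, newton_tol_fallback >= newton_tol,
            max_iter >= 1, wall_tau >= 0,
            r_a_floor_frac > 0, r_a_floor_frac < 1, outer_tol > 0)
  structure(list(dt = dt, newton_tol = newton_tol,
                 newton_tol_fallback = newton_tol_fallback,
                 max_iter = max_iter,
                 r_a_floor_frac = r_a_floor_frac, mucus_mode = mucus_mode,
                 wall_tau = wall_tau,
                 max_outer = max_outer, outer_tol = outer_tol,
                 max_substep_depth = max_substep_depth,
                 jac_min_refresh = jac_min_refresh),
            class = "stepper_config")
}

#' Bundle the model components
#'
#' Collects the tree, the pressure-volume curves and the fluid constants and
#' precomputes what the stepper needs, including a fine interpolation table
#' for the alveolar-duct-unit volume as a function of duct-to-chest pressure
#' difference (the exact curve is smooth; the table is accurate to about
#' 1e-12 relative and removes the dominant per-step cost).
#'
#' @param tree a `tree_spec`.
#' @param curves a `pv_curves`.
#' @param fluids a `fluid_constants`.
#' @param vadu_range pressure-difference range covered by the interpolation
#'   table, Pa.
#' @param rigid_interface if TRUE the pressure-gradient map F treats the
#'   air-mucus interface as stationary (core Poiseuille); mucus fluxes keep
#'   the full Bingham physics either way. See [flows_from_gradient()].
#' @return an object of class `lung_model`.
#' @export
build_model <- function(tree = build_tree_spec(), curves = build_pv_curves(),
                        fluids = fluid_constants(),
                        vadu_range = c(-8000, 4000),
                        rigid_interface = FALSE) {
  grid <- seq(vadu_range[1], vadu_range[2], by = 4)
  V_rs <- curves$static_volume(grid)
  Pt <- curves$tissue_pressure(V_rs)
  l17 <- tree$length[1:17]
  # V_tbt at the relaxed configuration (atmospheric airway pressure)
  SV <- vapply(Pt, function(p) sum(.lambert_all(tree, rep(p, 17L)) * l17),
               numeric(1))
  v_adu_grid <- (V_rs - SV) / tree$n_adu_total
  vadu_fun <- stats::splinefun(grid, v_adu_grid, method = "fmm")
  structure(list(
    tree = tree, curves = curves, fluids = fluids,
    vadu_fun = vadu_fun, vadu_range = vadu_range,
    rigid_interface = rigid_interface,
    l = tree$length, n_air = tree$n_airways, n_alv = tree$n_alv,
    lc = .lambert_consts(tree)
  ), class = "lung_model")
}

#' @export
print.lung_model <- function(x, ...) {
  cat("Quasi-static lung model (23-generation symmetric tree)\n")
  print(x$curves)
  print(x$fluids)
  invisible(x)
}

# Mechanics at candidate pressures, stepper path (uses the v_adu table).
.mech_fast <- function(model, P, P_ext, V_init = NULL) {
  # (V_init is the warm start for the inner volume solve)
  tree <- model$tree; curves <- model$curves
  dP <- P[18:23] - P_ext
  if (any(dP < model$vadu_range[1] | dP > model$vadu_range[2])) {
    v_adu <- .acinar_units(curves, tree, P[18:23], P_ext)$v_adu
  } else {
    v_adu <- model$vadu_fun(dP)
  }
  V_ac <- sum(model$n_air[18:23] * v_adu)
  V_L <- .solve_VL(curves, tree, P[1:17], V_ac, V_init = V_init,
                   lc = model$lc)
  Pt <- curves$tissue_pressure(V_L)
  S_b <- numeric(23L)
  S_b[1:17] <- .lambert_vd(model$lc, Pt - P[1:17])$S
  S_b[18:23] <- tree$alpha_duct * v_adu / tree$L_ad * model$n_air[18:23]
  list(S_b = S_b, v_alv = (1 - tree$alpha_duct) * v_adu / 58,
       V_L = V_L, P_tissue = Pt)
}

# One full residual evaluation at candidate pressures P.  Conducting
# bronchus areas relax toward their static (Lambert) value with time
# constant wall_tau (implicit first-order filter); acinar mechanics is
# strictly quasi-static.
.step_residual <- function(model, prev, P, P_ext, A_muc, dt,
                           floor_frac = 1e-2, full = FALSE, wall_tau = 0,
                           venv = NULL) {
  mech <- .mech_fast(model, P, P_ext,
                     V_init = (if (!is.null(venv)) venv$V) %||% prev$V_L)
  if (!is.null(venv)) venv$V <- mech$V_L
  S_b <- mech$S_b
  if (wall_tau > 0) {
    w <- dt / (dt + wall_tau)
    S_b[1:17] <- prev$S_b[1:17] + w * (S_b[1:17] - prev$S_b[1:17])
  }
  fl2 <- floor_frac^2
  # incompressible mucus holds the wall open: the lumen cannot shrink below
  # the mucus area plus the floored air core
  S_b[1:17] <- pmax(S_b[1:17], A_muc / (1 - fl2))
  S_a <- S_b
  S_a[1:17] <- pmax(S_b[1:17] - A_muc, fl2 * S_b[1:17])
  dSa <- (S_a - prev$S_a) / dt
  dva <- (mech$v_alv - prev$v_alv) / dt
  # leaf-to-root per-airway flow recursion (positive = down the tree)
  phi <- numeric(23L)
  own <- dSa * model$l / model$n_air
  phi[23] <- own[23] + 58 * dva[6]
  for (i in 22:18) phi[i] <- own[i] + 2 * phi[i + 1] + 58 * dva[i - 17]
  for (i in 17:1) phi[i] <- own[i] + 2 * phi[i + 1]
  r_b <- sqrt(S_b / model$n_air / pi)
  r_a <- sqrt(S_a / model$n_air / pi)
  C <- .gradient_kernel(phi, r_a, r_b, model$fluids$mu_air,
                        model$fluids$mu_mucus, model$fluids$sigma0,
                        rigid_interface = isTRUE(model$rigid_interface))
  Cl <- C * model$l
  P_implied <- Cl / 2 + c(0, cumsum(Cl)[1:22])
  res <- P - P_implied
  if (!full) return(res)
  list(residual = res, P = P, P_implied = P_implied,
       S_b = S_b, S_a = S_a, v_alv = mech$v_alv,
       V_L = mech$V_L, P_tissue = mech$P_tissue, phi = phi, C = C,
       r_a = r_a, r_b = r_b)
}

#' Pressure residual of one implicit step
#'
#' Exposes the stepper's residual map for a candidate pressure vector: the
#' difference between the candidate mid-airway pressures and the pressures
#' implied by the flows that the candidate itself generates. A converged step
#' has `max(abs(residual)) < newton_tol`; an equilibrium state has a zero
#' residual at its own pressures.
#'
#' @param model a `lung_model`.
#' @param prev previous `lung_state`.
#' @param P_air_candidate candidate mid-airway pressures, Pa (length 23).
#' @param P_ext chest pressure at the end of the step, Pa.
#' @param cfg a `stepper_config`.
#' @param A_muc end-of-step generation-summed mucus areas (length 17);
#'   defaults to the previous state's.
#' @return numeric length-23 residual, Pa.
#' @export
step_residual <- function(model, prev, P_air_candidate, P_ext,
                          cfg = stepper_config(), A_muc = prev$A_muc) {
  .step_residual(model, prev, P_air_candidate, P_ext, A_muc, cfg$dt,
                 floor_frac = cfg$r_a_floor_frac, wall_tau = cfg$wall_tau)
}

# Finite-difference Jacobian of the residual, 23 x 23.
.residual_jacobian <- function(model, prev, P, P_ext, A_muc, dt, floor_frac,
                               h = 1e-2, wall_tau = 0) {
  r0 <- .step_residual(model, prev, P, P_ext, A_muc, dt, floor_frac,
                       wall_tau = wall_tau)
  J <- matrix(0, 23L, 23L)
  for (j in 1:23) {
    Pj <- P
    Pj[j] <- Pj[j] + h
    J[, j] <- (.step_residual(model, prev, Pj, P_ext, A_muc, dt, floor_frac,
                              wall_tau = wall_tau) - r0) / h
  }
  J
}

# Damped chord-Newton solve.  cache carries the Jacobian between steps; it
# is refreshed adaptively whenever convergence degrades (the system is
# strongly nonlinear while airways are narrow and the acinar compliance
# couples every pressure to every gradient).  Returns the full residual
# pieces at the solution (including $P), or NULL on failure.
.newton_solve <- function(model, prev, P0, P_ext, A_muc, dt, cfg, cache,
                          tol = cfg$newton_tol, best_effort = FALSE) {
  P <- P0
  wt <- cfg$wall_tau
  venv <- new.env(parent = emptyenv())
  resid_at <- function(P) .step_residual(model, prev, P, P_ext, A_muc, dt,
                                         cfg$r_a_floor_frac, wall_tau = wt,
                                         venv = venv)
  line_search <- function(P, step, nrm) {
    best_nrm <- Inf; best_P <- NULL; best_res <- NULL; n_ev <- 0L
    for (lambda in c(1, 1.25, 0.5, 0.25, 0.125, 1 / 16, 1 / 32, 1 / 64)) {
      P_try <- P - lambda * step
      res_try <- resid_at(P_try)
      n_ev <- n_ev + 1L
      nrm_try <- max(abs(res_try))
      if (is.finite(nrm_try) && nrm_try < best_nrm) {
        best_nrm <- nrm_try; best_P <- P_try; best_res <- res_try
      }
      if (lambda == 1 && is.finite(nrm_try) && nrm_try < 0.2 * nrm) break
    }
    list(nrm = best_nrm, P = best_P, res = best_res, n_ev = n_ev)
  }
  res <- resid_at(P)
  nrm <- max(abs(res))
  iters <- 0L
  # phase 1: chord iteration on the cached Jacobian (the cheap path that
  # carries all calm stretches of a trajectory)
  if (is.null(cache$J) || cache$since_refresh > cfg$jac_min_refresh) {
    cache$J <- .residual_jacobian(model, prev, P, P_ext, A_muc, dt,
                                  cfg$r_a_floor_frac, wall_tau = wt)
    cache$since_refresh <- 0L
    iters <- iters + 23L
  }
  while (nrm >= tol && iters < cfg$max_iter) {
    step <- tryCatch(solve(cache$J, res), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    ls <- line_search(P, step, nrm)
    iters <- iters + ls$n_ev
    if (!is.finite(ls$nrm) || ls$nrm >= 0.7 * nrm) break
    P <- ls$P; res <- ls$res; nrm <- ls$nrm
  }
  # phase 2: full Newton, fresh Jacobian every iteration (strong curvature
  # near yield transitions and airway-collapse folds)
  if (nrm >= tol) {
    for (it in seq_len(cfg$max_iter)) {
      J <- .residual_jacobian(model, prev, P, P_ext, A_muc, dt,
                              cfg$r_a_floor_frac, wall_tau = wt)
      iters <- iters + 23L
      if (!all(is.finite(J))) break
      cache$J <- J
      cache$since_refresh <- 0L
      step <- tryCatch(solve(J, res), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      ls <- line_search(P, step, nrm)
      iters <- iters + ls$n_ev
      if (!is.finite(ls$nrm) || ls$nrm >= nrm) break   # stalled floor
      P <- ls$P; res <- ls$res; nrm <- ls$nrm
      if (nrm < tol) break
    }
  }
  if (nrm >= tol && !best_effort) return(NULL)
  cache$since_refresh <- (cache$since_refresh %||% 0L) + 1L
  out <- .step_residual(model, prev, P, P_ext, A_muc, dt,
                        cfg$r_a_floor_frac, full = TRUE, wall_tau = wt)
  out$iters <- iters
  out$resid_norm <- nrm
  out$forced <- nrm >= tol
  out
}

# Mucus transport update from the converged air state.  Outflows are capped
# by the mucus present at the start of the step, which keeps the tree +
# expelled mass balance exact even when an airway runs dry.
.mucus_update <- function(model, prev, sol, dt) {
  i <- 1:17
  phiO <- .flows_kernel(sol$C[i], sol$r_a[i], sol$r_b[i],
                        model$fluids$mu_air, model$fluids$mu_mucus,
                        model$fluids$sigma0)$phi_mucus
  phiO[17] <- min(phiO[17], 0)   # mucus cannot reach the alveoli
  cap <- prev$A_muc * model$l[i] / model$n_air[i] / dt
  capped <- abs(phiO) > cap
  phiO[capped] <- sign(phiO[capped]) * cap[capped]
  phiI <- 0.5 * c(0, pmax(0, phiO[1:16])) - 2 * c(pmin(0, phiO[2:17]), 0)
  A_new <- prev$A_muc + dt * model$n_air[i] * (phiI - abs(phiO)) / model$l[i]
  list(A_new = A_new, v_out_inc = dt * abs(min(phiO[1], 0)),
       phi_m = phiO, n_capped = sum(capped))
}

#' Mucus inflow into one generation
#'
#' The inflow of a generation-`z` airway collects the down-tree (positive)
#' outflow of its parent, halved over the two daughters, and the up-tree
#' (negative) outflows of its two daughters: `0.5 max(0, out[z-1]) - 2
#' min(0, out[z+1])`. The trachea has no parent term; generation 16 has no
#' daughter term and its own outflow is clamped to be non-positive (mucus
#' cannot reach the acini).
#'
#' @param phi_m_out per-airway mucus outflows of the 17 conducting
#'   generations, m^3/s.
#' @param z generation index, 0..16.
#' @return inflow, m^3/s (non-negative).
#' @export
mucus_inflow <- function(phi_m_out, z) {
  if (length(phi_m_out) != 17L) stop("phi_m_out must have length 17")
  if (z < 0 || z > 16) stop("z must be in 0..16")
  phi_m_out[17] <- min(phi_m_out[17], 0)
  parent <- if (z >= 1) 0.5 * max(0, phi_m_out[z]) else 0
  daughter <- if (z <= 15) -2 * min(0, phi_m_out[z + 2]) else 0
  parent + daughter
}

#' Equilibrium state at zero chest pressure
#'
#' Builds the rest (FRC) state: atmospheric pressure everywhere, lung volume
#' from the volume fixed point, bronchus areas from the mechanics map, and
#' the air lumen reduced by the requested mucus fill fractions.
#'
#' @param model a `lung_model`.
#' @param profile a `mucus_profile` (or a bare numeric vector of 17 fill
#'   fractions in `[0, 1)`).
#' @return an object of class `lung_state`.
#' @export
find_rest_state <- function(model, profile = default_mucus_profile()) {
  fill <- if (inherits(profile, "mucus_profile")) profile$fill else profile
  if (length(fill) != 17L || any(fill < 0) || any(fill >= 1)) {
    stop("mucus profile must give 17 fill fractions in [0, 1)")
  }
  mech <- .mech_fast(model, rep(0, 23L), 0)
  S_b <- mech$S_b
  A_muc <- fill * S_b[1:17]
  S_a <- S_b
  S_a[1:17] <- S_b[1:17] - A_muc
  structure(list(
    t = 0, P_ext = 0, P_air = rep(0, 23L), A_muc = A_muc,
    S_a = S_a, S_b = S_b, v_alv = mech$v_alv,
    V_L = mech$V_L, P_tissue = mech$P_tissue,
    v_out = 0, phi_a = rep(0, 23L), C = rep(0, 23L), phi_m = rep(0, 17L)
  ), class = "lung_state")
}

#' @export
print.lung_state <- function(x, ...) {
  cat(sprintf(
    "Lung state at t = %.3f s: V_L = %.3f L, expelled mucus = %.3g mL\n",
    x$t, x$V_L * 1e3, x$v_out * 1e6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Advance the state by one implicit step
#'
#' Backward-Euler step to chest pressure `P_ext_next`: solves the pressure
#' residual by damped chord Newton, updates the mucus areas with end-of-step
#' fluxes (iterated to self-consistency in fully implicit mode), and
#' accumulates expelled mucus from the trachea outflow. On Newton failure the
#' step is retried as two half steps, up to `max_substep_depth` levels.
#'
#' @param model a `lung_model`.
#' @param state current `lung_state`.
#' @param P_ext_next chest pressure at the end of the step, Pa.
#' @param cfg a `stepper_config`.
#' @param cache optional environment carrying the chord Jacobian between
#'   steps (created if missing).
#' @return the new `lung_state`; diagnostics (`iters`, `outer`, `n_capped`,
#'   `n_spilled`, `n_substeps`) are attached as attributes.
#' @export
advance <- function(model, state, P_ext_next, cfg = stepper_config(),
                    cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$since_refresh)) cache$since_refresh <- 0L
  .advance_rec(model, state, P_ext_next, cfg, cache, cfg$dt, 0L)
}

.advance_rec <- function(model, state, P_ext_next, cfg, cache, dt, depth) {
  # fold-mode hysteresis: while the trajectory crosses a quasi-static fold
  # window (consecutive steps without an exact root), skip the expensive
  # substep escalation and accept the best-available balance directly; the
  # mode clears as soon as a step converges strictly again.
  if (depth == 0L && isTRUE(cache$fold_mode)) {
    out <- .advance_once(model, state, P_ext_next, cfg, cache, dt)
    if (!is.null(out)) {
      cache$fold_mode <- FALSE
      return(out)
    }
    out <- .advance_once(model, state, P_ext_next, cfg, cache, dt,
                         tol = cfg$newton_tol_fallback, best_effort = TRUE)
    if (!is.null(out) &&
        (attr(out, "resid_norm") %||% 0) <= 1000 * cfg$newton_tol_fallback) {
      if ((attr(out, "resid_norm") %||% 0) >= cfg$newton_tol) {
        attr(out, "n_forced") <- 1L
      }
      return(out)
    }
  }
  out <- .advance_once(model, state, P_ext_next, cfg, cache, dt)
  if (!is.null(out)) {
    if (depth == 0L) cache$fold_mode <- FALSE
    return(out)
  }
  if (depth >= 1L) {
    # at reduced dt, accept a step that stalls on the (physically
    # negligible) residual floor of a yield-transition event
    out <- .advance_once(model, state, P_ext_next, cfg, cache, dt,
                         tol = cfg$newton_tol_fallback)
    if (!is.null(out)) {
      attr(out, "n_soft") <- 1L
      return(out)
    }
  }
  if (depth >= cfg$max_substep_depth) {
    # last resort: the implicit system of this (sub)step has no reachable
    # root (a quasi-static fold); accept the best stalled iterate and record
    # its residual so the caller can audit the trajectory
    out <- .advance_once(model, state, P_ext_next, cfg, cache, dt,
                         tol = cfg$newton_tol_fallback, best_effort = TRUE)
    if (is.null(out) ||
        (attr(out, "resid_norm") %||% Inf) > 1e4 * cfg$newton_tol_fallback) {
      # only an unbounded imbalance aborts; bounded snap-through residuals
      # are accepted and exposed through the diagnostics
      stop("implicit step failed at t = ", format(state$t + dt),
           " s even after repeated step halving (best residual ",
           format(attr(out, "resid_norm") %||% NA), " Pa)")
    }
    attr(out, "n_forced") <- 1L
    cache$fold_mode <- TRUE
    return(out)
  }
  cache$J <- NULL
  # two half steps, interpolating the chest pressure in time
  P_mid <- (state$P_ext + P_ext_next) / 2
  half <- .advance_rec(model, state, P_mid, cfg, cache, dt / 2, depth + 1L)
  out <- .advance_rec(model, half, P_ext_next, cfg, cache, dt / 2, depth + 1L)
  attr(out, "n_substeps") <- (attr(out, "n_substeps") %||% 0L) + 2L
  attr(out, "n_soft") <- (attr(out, "n_soft") %||% 0L) +
    (attr(half, "n_soft") %||% 0L)
  attr(out, "n_forced") <- (attr(out, "n_forced") %||% 0L) +
    (attr(half, "n_forced") %||% 0L)
  attr(out, "resid_norm") <- max(attr(out, "resid_norm") %||% 0,
                                 attr(half, "resid_norm") %||% 0)
  out
}

.advance_once <- function(model, state, P_ext_next, cfg, cache, dt,
                          tol = cfg$newton_tol, best_effort = FALSE) {
  fl2 <- cfg$r_a_floor_frac^2
  A_cand <- state$A_muc
  P0 <- state$P_air + (cache$dP_last %||% rep(0, 23L))
  max_outer <- if (cfg$mucus_mode == "implicit") cfg$max_outer else 1L
  outer_used <- 0L
  sol <- NULL
  upd <- NULL
  for (outer in seq_len(max_outer)) {
    outer_used <- outer
    sol <- .newton_solve(model, state, P0, P_ext_next, A_cand, dt, cfg, cache,
                         tol = tol, best_effort = best_effort)
    if (is.null(sol) && outer == 1L) {
      # retry from the trapped-gas predictor: with flow blocked (a mucus
      # plug), airway pressures track the chest pressure one for one
      P_trap <- state$P_air + (P_ext_next - state$P_ext)
      sol <- .newton_solve(model, state, P_trap, P_ext_next, A_cand, dt, cfg,
                           cache, tol = tol, best_effort = best_effort)
    }
    if (is.null(sol)) return(NULL)
    upd <- .mucus_update(model, state, sol, dt)
    A_new <- pmax(upd$A_new, 0)
    if (max(abs(A_new - A_cand)) < cfg$outer_tol) {
      A_cand <- A_new
      break
    }
    # damp after the first passes to break yield-boundary flip-flops
    A_cand <- if (outer >= 3L) (A_cand + A_new) / 2 else A_new
    P0 <- sol$P
  }
  n_spilled <- 0L  # mucus incompressibility supports the wall; no overfill
  cache$dP_last <- sol$P - state$P_air
  S_a <- sol$S_b
  S_a[1:17] <- pmax(sol$S_b[1:17] - A_cand, fl2 * sol$S_b[1:17])
  new_state <- structure(list(
    t = state$t + dt, P_ext = P_ext_next, P_air = sol$P, A_muc = A_cand,
    S_a = S_a, S_b = sol$S_b, v_alv = sol$v_alv,
    V_L = sol$V_L, P_tissue = sol$P_tissue,
    v_out = state$v_out + upd$v_out_inc,
    phi_a = sol$phi, C = sol$C, phi_m = upd$phi_m
  ), class = "lung_state")
  attr(new_state, "iters") <- sol$iters
  attr(new_state, "outer") <- outer_used
  attr(new_state, "n_capped") <- upd$n_capped
  attr(new_state, "n_spilled") <- n_spilled
  attr(new_state, "resid_norm") <- sol$resid_norm
  new_state
}

#' Run a maneuver simulation
#'
#' Integrates the coupled system over a session under the chest-pressure
#' waveform of `maneuver`, starting from the rest state with the given mucus
#' profile. The state is recorded every `record_stride` steps (plus the final
#' step).
#'
#' @param maneuver a [maneuver_spec()].
#' @param profile a [mucus_profile] (17 fill fractions).
#' @param cfg a [stepper_config()].
#' @param model a `lung_model` (built with defaults if omitted).
#' @param t_end simulated duration, s; defaults to the session duration.
#' @param record_stride recording stride, in steps.
#' @param stop_on_expulsion if TRUE, stop as soon as any mucus has left the
#'   trachea (used by threshold searches; the recorded traces are truncated
#'   at the stopping step).
#' @param verbose if TRUE, print a progress line every 10 simulated seconds.
#' @return an object of class `lung_sim`: recorded traces (`times`, `P_ext`,
#'   `V_L`, `v_out`, matrices `S_a`, `S_b`, `P_air`, `phi_a`, `C` of one
#'   column per record, `A_muc` 17 x n), the `baseline` rest state, the final
#'   state, the inputs, and solver diagnostics.
#' @export
run_simulation <- function(maneuver, profile = default_mucus_profile(),
                           cfg = stepper_config(), model = NULL,
                           t_end = NULL, record_stride = 10L,
                           stop_on_expulsion = FALSE, verbose = FALSE) {
  if (is.null(model)) model <- build_model()
  if (is.null(t_end)) t_end <- maneuver$session$duration
  n_steps <- as.integer(round(t_end / cfg$dt))
  record_stride <- as.integer(record_stride)
  n_rec <- length(unique(c(seq(0L, n_steps, by = record_stride), n_steps)))
  times <- numeric(n_rec); P_ext_tr <- numeric(n_rec)
  V_L_tr <- numeric(n_rec); v_out_tr <- numeric(n_rec)
  Pt_tr <- numeric(n_rec)
  S_a_tr <- matrix(0, 23L, n_rec); S_b_tr <- matrix(0, 23L, n_rec)
  P_air_tr <- matrix(0, 23L, n_rec); phi_tr <- matrix(0, 23L, n_rec)
  C_tr <- matrix(0, 23L, n_rec); A_tr <- matrix(0, 17L, n_rec)
  state <- find_rest_state(model, profile)
  baseline <- state
  cache <- new.env(parent = emptyenv())
  cache$since_refresh <- 0L
  rec <- function(k, st) {
    times[k] <<- st$t
    P_ext_tr[k] <<- external_pressure(maneuver, st$t)
    V_L_tr[k] <<- st$V_L; v_out_tr[k] <<- st$v_out; Pt_tr[k] <<- st$P_tissue
    S_a_tr[, k] <<- st$S_a; S_b_tr[, k] <<- st$S_b
    P_air_tr[, k] <<- st$P_air; phi_tr[, k] <<- st$phi_a; C_tr[, k] <<- st$C
    A_tr[, k] <<- st$A_muc
  }
  k <- 1L
  rec(k, state)
  tot_iters <- 0; tot_capped <- 0L; tot_spilled <- 0L; tot_substeps <- 0L
  tot_soft <- 0L; tot_forced <- 0L; max_resid <- 0
  for (s in seq_len(n_steps)) {
    t_next <- s * cfg$dt
    state <- .advance_rec(model, state, external_pressure(maneuver, t_next),
                          cfg, cache, cfg$dt, 0L)
    tot_iters <- tot_iters + (attr(state, "iters") %||% 0L)
    tot_capped <- tot_capped + (attr(state, "n_capped") %||% 0L)
    tot_spilled <- tot_spilled + (attr(state, "n_spilled") %||% 0L)
    tot_substeps <- tot_substeps + (attr(state, "n_substeps") %||% 0L)
    tot_soft <- tot_soft + (attr(state, "n_soft") %||% 0L)
    tot_forced <- tot_forced + (attr(state, "n_forced") %||% 0L)
    max_resid <- max(max_resid, attr(state, "resid_norm") %||% 0)
    if (verbose && s %% round(10 / cfg$dt) == 0L) {
      cat(sprintf("t = %.1f s  V_L = %.3f L  v_out = %.4g mL  forced = %d\n",
                  state$t, state$V_L * 1e3, state$v_out * 1e6, tot_forced))
    }
    stopped <- stop_on_expulsion && state$v_out > 1e-12
    if (s %% record_stride == 0L || s == n_steps || stopped) {
      k <- k + 1L
      rec(k, state)
    }
    if (stopped) break
  }
  if (k < n_rec) {
    keep <- seq_len(k)
    times <- times[keep]; P_ext_tr <- P_ext_tr[keep]; V_L_tr <- V_L_tr[keep]
    v_out_tr <- v_out_tr[keep]; Pt_tr <- Pt_tr[keep]
    S_a_tr <- S_a_tr[, keep, drop = FALSE]
    S_b_tr <- S_b_tr[, keep, drop = FALSE]
    P_air_tr <- P_air_tr[, keep, drop = FALSE]
    phi_tr <- phi_tr[, keep, drop = FALSE]
    C_tr <- C_tr[, keep, drop = FALSE]
    A_tr <- A_tr[, keep, drop = FALSE]
  }
  structure(list(
    times = times, P_ext = P_ext_tr, V_L = V_L_tr, v_out = v_out_tr,
    P_tissue = Pt_tr, S_a = S_a_tr, S_b = S_b_tr, P_air = P_air_tr,
    phi_a = phi_tr, C = C_tr, A_muc = A_tr,
    baseline = baseline, final_state = state,
    maneuver = maneuver, profile = profile, cfg = cfg, model = model,
    diagnostics = list(newton_iters = tot_iters, n_capped = tot_capped,
                       n_spilled = tot_spilled, n_substeps = tot_substeps,
                       n_soft = tot_soft, n_forced = tot_forced,
                       max_resid = max_resid, n_steps = n_steps)
  ), class = "lung_sim")
}

#' @export
print.lung_sim <- function(x, ...) {
  cat(sprintf("Simulation: %s, %g s (%d steps, dt = %g s)\n",
              x$maneuver$family, max(x$times), x$diagnostics$n_steps,
              x$cfg$dt))
  cat(sprintf("  final V_L = %.3f L, expelled mucus = %.3g mL\n",
              x$final_state$V_L * 1e3, x$final_state$v_out * 1e6))
  invisible(x)
}

#' Total mucus volume held in the tree
#'
#' @param state a `lung_state` (or a `lung_sim`, in which case the final
#'   state is used).
#' @param model the `lung_model` providing airway lengths.
#' @return volume, m^3.
#' @export
tree_mucus_volume <- function(state, model) {
  if (inherits(state, "lung_sim")) state <- state$final_state
  sum(state$A_muc * model$l[1:17])
}
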