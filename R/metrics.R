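# Scalar outcome measures of a maneuver: expelled volume, FRC-referenced
# relative resistance, mean mucus position, Shrek number, comfort number.

#' FRC-referenced relative hydrodynamic resistance
#'
#' Ratio of the tree air-core resistance of `state` to that of `baseline`,
#' both evaluated on an FRC-referenced configuration: pressures reset to rest
#' (chest and airway pressures zero, bronchus areas from the rest mechanics)
#' with the state's CURRENT mucus volumes carving the air lumen. By
#' construction the pre-maneuver rest state scores exactly 1.
#'
#' @param state a `lung_state` (its mucus areas are used).
#' @param baseline the pre-maneuver rest `lung_state`.
#' @param model the `lung_model`.
#' @return dimensionless resistance ratio.
#' @export
relative_resistance <- function(state, baseline, model) {
  .frc_resistance(state$A_muc, baseline, model) /
    .frc_resistance(baseline$A_muc, baseline, model)
}

# Tree resistance with rest-state bronchus areas and the given mucus areas
# (mucus in excess of the rest lumen holds the wall open).
.frc_resistance <- function(A_muc, baseline, model, floor_frac = 1e-2) {
  fl2 <- floor_frac^2
  S_b <- pmax(baseline$S_b[1:17], A_muc / (1 - fl2))
  S_a <- pmax(S_b - A_muc, fl2 * S_b)
  tree_resistance(c(S_a, baseline$S_b[18:23]), model$tree, model$fluids)
}

#' Relative-resistance trace of a simulation
#'
#' Applies [relative_resistance()] to every recorded mucus distribution.
#'
#' @param sim a `lung_sim`.
#' @return data.frame with `time` and `r`.
#' @export
relative_resistance_trace <- function(sim) {
  base_R <- .frc_resistance(sim$baseline$A_muc, sim$baseline, sim$model)
  r <- apply(sim$A_muc, 2L,
             function(A) .frc_resistance(A, sim$baseline, sim$model)) / base_R
  data.frame(time = sim$times, r = r)
}

#' Mean mucus position
#'
#' Mucus-volume-weighted mean generation index, with the expelled volume
#' entering the numerator with weight -1:
#' `mmp = (-v_out + sum_z z A_z l_z) / (v_out + sum_z A_z l_z)` over the
#' conducting generations (generation-summed mucus areas `A_z`).
#'
#' @param state a `lung_state`.
#' @param model the `lung_model`.
#' @return dimensionless generation index.
#' @export
mean_mucus_position <- function(state, model) {
  vol <- state$A_muc * model$l[1:17]
  tot <- state$v_out + sum(vol)
  if (tot <= 0) stop("mean mucus position undefined: no mucus anywhere")
  (-state$v_out + sum((0:16) * vol)) / tot
}

#' Shrek number: air shear over mucus yield stress
#'
#' The instantaneous Shrek number averages, over the `N` conducting
#' generations, the ratio of the air shear stress `4 mu_a |phi| / (pi r^3)`
#' in one airway (flow `phi`, air-lumen radius `r`) to the mucus yield stress
#' `sigma0`. The approximate form replaces the per-generation sum with
#' `R_aw |phi_mouth| / (12 N sigma0)`, exact when every airway has a
#' length-to-diameter ratio of 3. For a simulation, both are evaluated on
#' the recorded trace, and the session Shrek number `Sh` is the time average
#' of `iSh` (trapezoidal rule).
#'
#' @param x a `lung_state` or a `lung_sim`.
#' @param model the `lung_model` (taken from a `lung_sim` automatically).
#' @param N number of generations averaged over.
#' @return for a state: list with `iSh`, `iSh_approx`. For a simulation:
#'   list with `Sh`, `Sh_approx` and the `iSh`, `iSh_approx` traces.
#' @export
shrek <- function(x, model = NULL, N = 17L) {
  fl <- function(phi, S_a, S_b, mdl) {
    i <- seq_len(N)
    r_a <- sqrt(S_a[i] / mdl$n_air[i] / pi)
    iSh <- mean(4 * mdl$fluids$mu_air * abs(phi[i]) /
                  (pi * r_a^3 * mdl$fluids$sigma0))
    R_aw <- tree_resistance(S_a, mdl$tree, mdl$fluids)
    iSh_approx <- R_aw * abs(phi[1]) / (12 * N * mdl$fluids$sigma0)
    c(iSh, iSh_approx)
  }
  if (inherits(x, "lung_state")) {
    if (is.null(model)) stop("model required for a lung_state")
    v <- fl(x$phi_a, x$S_a, x$S_b, model)
    return(list(iSh = v[1], iSh_approx = v[2]))
  }
  stopifnot(inherits(x, "lung_sim"))
  mdl <- model %||% x$model
  n <- length(x$times)
  tr <- vapply(seq_len(n),
               function(k) fl(x$phi_a[, k], x$S_a[, k], x$S_b[, k], mdl),
               numeric(2))
  Sh <- .trapz(x$times, tr[1, ]) / diff(range(x$times))
  Sh_approx <- .trapz(x$times, tr[2, ]) / diff(range(x$times))
  list(Sh = Sh, Sh_approx = Sh_approx,
       iSh = tr[1, ], iSh_approx = tr[2, ], times = x$times)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Comfort number: tissue-pressure shift relative to quiet breathing
#'
#' The instantaneous comfort number compares the lung tissue pressure of a
#' maneuver with that of a ventilation-only run on the same time grid:
#' `iCom = |(P_t(V_L) - P_t(V_L_ventil)) / P_t(V_L_ventil)|`; the session
#' comfort number is its time average. Zero when only ventilation occurs;
#' larger values mean larger compressive stresses in the lung tissue.
#'
#' @param result a `lung_sim` for the maneuver.
#' @param reference a ventilation-only `lung_sim` with the same time grid.
#' @return list with `Com` and the `iCom` trace.
#' @export
comfort <- function(result, reference) {
  if (length(result$times) != length(reference$times) ||
      max(abs(result$times - reference$times)) > 1e-9) {
    stop("comfort requires matching time grids")
  }
  Pt <- result$model$curves$tissue_pressure
  p_ref <- Pt(reference$V_L)
  iCom <- abs((Pt(result$V_L) - p_ref) / p_ref)
  list(Com = .trapz(result$times, iCom) / diff(range(result$times)),
       iCom = iCom, times = result$times)
}

#' Summary metrics of a simulation
#'
#' @param sim a `lung_sim`.
#' @param reference optional ventilation-only `lung_sim` for the comfort
#'   number.
#' @return list with `v_out_final` (m^3), `r_final`, `mmp_initial`,
#'   `mmp_final`, `Sh`, and `Com` (NA without a reference).
#' @export
simulation_summary <- function(sim, reference = NULL) {
  list(
    v_out_final = sim$final_state$v_out,
    r_final = relative_resistance(sim$final_state, sim$baseline, sim$model),
    mmp_initial = mean_mucus_position(sim$baseline, sim$model),
    mmp_final = mean_mucus_position(sim$final_state, sim$model),
    Sh = shrek(sim)$Sh,
    Com = if (is.null(reference)) NA_real_ else comfort(sim, reference)$Com
  )
}
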