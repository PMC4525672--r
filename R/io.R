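# Run configuration, result serialization and the programmatic entry point
# behind the command-line script.
#
# Config files are YAML or JSON with blocks `maneuver`, `fixture`, `stepper`,
# `curves`, `output`; pressures are in cmH2O at this boundary.

.known_config_keys <- list(
  top = c("maneuver", "fixture", "stepper", "curves", "output"),
  maneuver = c("family", "P_v", "P_cp", "P_s", "P_o", "f", "duration"),
  fixture = c("preset", "fill", "path"),
  stepper = c("dt", "newton_tol", "newton_tol_fallback", "max_iter",
              "r_a_floor_frac", "mucus_mode", "wall_tau",
              "max_outer", "max_substep_depth"),
  curves = c("tidal_target_l", "frc_transmural_pa", "p_tlc_cmh2o",
             "volume_table", "tissue_table"),
  output = c("stride", "dir")
)

#' Read and validate a run configuration
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return validated configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  .check_keys <- function(block, name) {
    unknown <- setdiff(names(block), .known_config_keys[[name]])
    if (length(unknown)) {
      stop("unknown key(s) in '", name, "' block: ",
           paste(unknown, collapse = ", "))
    }
  }
  .check_keys(cfg, "top")
  for (b in intersect(names(cfg), names(.known_config_keys))) {
    if (b != "top") .check_keys(cfg[[b]], b)
  }
  st <- cfg$stepper
  if (!is.null(st$dt) && st$dt <= 0) stop("stepper dt must be positive")
  if (!is.null(cfg$maneuver$family) &&
      !cfg$maneuver$family %in% c("ventilation", "manual", "hfcwo")) {
    stop("unknown maneuver family: ", cfg$maneuver$family)
  }
  structure(cfg, class = "run_config")
}

# Assemble run inputs from a validated config.
.config_inputs <- function(cfg) {
  m <- cfg$maneuver %||% list()
  session <- default_session()
  if (!is.null(m$duration)) {
    # rescale the schedule proportionally for non-standard durations
    sc <- m$duration / session$duration
    session <- list(duration = m$duration,
                    lead_in = session$lead_in * sc,
                    ramp_up = session$ramp_up * sc,
                    ramp_down = session$ramp_down * sc,
                    tail = session$tail * sc)
  }
  maneuver <- maneuver_spec(
    family = m$family %||% "ventilation",
    P_v = m$P_v %||% -5, P_cp = m$P_cp %||% 0,
    P_s = m$P_s %||% 0, P_o = m$P_o %||% 0, f = m$f %||% 20,
    session = session)
  fx <- cfg$fixture %||% list()
  profile <- if (!is.null(fx$path)) read_mucus_profile(fx$path)
  else if (!is.null(fx$fill)) mucus_profile(fx$fill)
  else if (identical(fx$preset, "clean")) clean_lung_profile()
  else default_mucus_profile()
  st <- cfg$stepper %||% list()
  stepper <- stepper_config(
    dt = st$dt %||% 5e-3, newton_tol = st$newton_tol %||% 1e-4,
    max_iter = st$max_iter %||% 30,
    r_a_floor_frac = st$r_a_floor_frac %||% 1e-2,
    mucus_mode = st$mucus_mode %||% "implicit",
    wall_tau = st$wall_tau %||% 2e-2,
    max_outer = st$max_outer %||% 8,
    max_substep_depth = st$max_substep_depth %||% 3)
  cv <- cfg$curves %||% list()
  curves <- build_pv_curves(
    tidal_target = (cv$tidal_target_l %||% 0.5) * 1e-3,
    frc_transmural = cv$frc_transmural_pa %||% 500,
    p_tlc = cmh2o(cv$p_tlc_cmh2o %||% 30),
    volume_table = if (!is.null(cv$volume_table))
      utils::read.csv(cv$volume_table),
    tissue_table = if (!is.null(cv$tissue_table))
      utils::read.csv(cv$tissue_table))
  list(maneuver = maneuver, profile = profile, stepper = stepper,
       model = build_model(curves = curves),
       stride = (cfg$output %||% list())$stride %||% 10L)
}

#' Execute a configured run and write its outputs
#'
#' Runs the simulation described by a config (file or list) and serializes
#' the results: a tidy per-time CSV (`trace.csv`), a wide per-generation CSV
#' (`generations.csv`), a metric summary (`summary.json`) and a manifest
#' echoing the full configuration (`manifest.json`).
#'
#' @param cfg a `run_config` (or a path to one).
#' @param out_dir output directory, created if needed.
#' @param reference optional ventilation-only `lung_sim` for the comfort
#'   number; if omitted and the run is not ventilation-only, a matching
#'   reference run is performed.
#' @return the `lung_sim`, invisibly.
#' @export
run_from_config <- function(cfg, out_dir, reference = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  inp <- .config_inputs(cfg)
  sim <- run_simulation(inp$maneuver, inp$profile, inp$stepper,
                        model = inp$model, record_stride = inp$stride)
  if (is.null(reference) && inp$maneuver$family != "ventilation") {
    ref_man <- maneuver_spec("ventilation",
                             P_v = to_cmh2o(inp$maneuver$P_v),
                             session = inp$maneuver$session)
    reference <- run_simulation(ref_man, inp$profile, inp$stepper,
                                model = inp$model, record_stride = inp$stride)
  } else if (inp$maneuver$family == "ventilation") {
    reference <- sim
  }
  write_simulation(sim, out_dir, reference = reference, config = cfg)
  invisible(sim)
}

#' Serialize a simulation to disk
#'
#' @param sim a `lung_sim`.
#' @param out_dir output directory.
#' @param reference optional ventilation-only reference for the comfort
#'   number.
#' @param config optional configuration echoed into the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir, reference = NULL, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tidy <- tidy_trace(sim, reference)
  utils::write.csv(format(tidy, digits = 12, scientific = TRUE, trim = TRUE),
                   file.path(out_dir, "trace.csv"),
                   row.names = FALSE, quote = FALSE)
  wide <- wide_trace(sim)
  utils::write.csv(format(wide, digits = 12, scientific = TRUE, trim = TRUE),
                   file.path(out_dir, "generations.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- simulation_summary(sim, reference)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "bronchosim",
    config = if (!is.null(config)) unclass(config),
    maneuver = unclass(sim$maneuver), stepper = unclass(sim$cfg),
    profile = sim$profile$fill,
    diagnostics = sim$diagnostics
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Tidy per-time trace of a simulation
#'
#' @param sim a `lung_sim`.
#' @param reference optional reference run for the comfort trace.
#' @return data.frame with one row per recorded time: `t`, `P_ext_cmh2o`,
#'   `V_L_l`, `phi_mouth_ml_s`, `v_out_ml`, `r`, `mmp`, `iSh`, `iCom`.
#' @export
tidy_trace <- function(sim, reference = NULL) {
  rtr <- relative_resistance_trace(sim)
  sh <- shrek(sim)
  lc <- sim$model$l[1:17]
  mmp <- vapply(seq_along(sim$times), function(k) {
    vol <- sim$A_muc[, k] * lc
    tot <- sim$v_out[k] + sum(vol)
    if (tot <= 0) NA_real_ else (-sim$v_out[k] + sum((0:16) * vol)) / tot
  }, numeric(1))
  icom <- if (is.null(reference)) rep(NA_real_, length(sim$times))
  else comfort(sim, reference)$iCom
  data.frame(
    t = sim$times,
    P_ext_cmh2o = to_cmh2o(sim$P_ext),
    V_L_l = sim$V_L * 1e3,
    phi_mouth_ml_s = sim$phi_a[1, ] * 1e6,
    v_out_ml = sim$v_out * 1e6,
    r = rtr$r,
    mmp = mmp,
    iSh = sh$iSh,
    iCom = icom
  )
}

#' Wide per-generation trace of a simulation
#'
#' @param sim a `lung_sim`.
#' @return data.frame with one row per (time, generation): areas, pressure,
#'   gradient and flow.
#' @export
wide_trace <- function(sim) {
  n <- length(sim$times)
  data.frame(
    t = rep(sim$times, each = 23L),
    generation = rep(0:22, n),
    S_a = as.vector(sim$S_a),
    S_b = as.vector(sim$S_b),
    P_air = as.vector(sim$P_air),
    C = as.vector(sim$C),
    phi_a = as.vector(sim$phi_a)
  )
}
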