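# Heavier shared simulations for the acceptance checks.

# Full-session manual run at 17 cmH2O, stopping at first expelled mucus.
manual17_run <- function() {
  cached("manual17_stop",
         run_simulation(maneuver_spec("manual", P_cp = 17),
                        default_mucus_profile(), stepper_config(dt = 1e-2),
                        model = default_model(), record_stride = 50L,
                        stop_on_expulsion = TRUE))
}

# Short HFCWO sessions (40 s) for comfort-ordering checks.
hfcwo_pair <- function() {
  cached("hfcwo_pair", {
    short <- default_session()
    short$duration <- 40; short$ramp_down <- c(30, 35); short$tail <- 5
    cfg <- stepper_config()
    model <- default_model()
    list(
      cc = run_simulation(maneuver_spec("hfcwo", P_s = 5.6, P_o = 1.2,
                                        f = 20, session = short),
                          default_mucus_profile(), cfg, model = model,
                          record_stride = 2L),
      fpt = run_simulation(maneuver_spec("hfcwo", P_s = 0, P_o = 1.2,
                                         f = 20, session = short),
                           default_mucus_profile(), cfg, model = model,
                           record_stride = 2L),
      ref = run_simulation(maneuver_spec("ventilation", session = short),
                           default_mucus_profile(), cfg, model = model,
                           t_end = 40, record_stride = 2L)
    )
  })
}
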