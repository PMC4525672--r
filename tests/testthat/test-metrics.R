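model <- default_model()

test_that("relative resistance is 1 at baseline and drops without mucus", {
  st <- find_rest_state(model, default_mucus_profile())
  expect_equal(relative_resistance(st, st, model), 1, tolerance = 1e-12)
  clean <- st
  clean$A_muc <- rep(0, 17)
  expect_lt(relative_resistance(clean, st, model), 1)
})

test_that("relative resistance is invariant to air-viscosity rescaling", {
  st <- find_rest_state(model, default_mucus_profile())
  st2 <- st; st2$A_muc <- st$A_muc * 0.5
  model2 <- model
  model2$fluids <- fluid_constants(mu_air = 3.6e-5)
  expect_equal(relative_resistance(st2, st, model),
               relative_resistance(st2, st, model2), tolerance = 1e-12)
})

test_that("mean mucus position weights generations by mucus volume", {
  st <- find_rest_state(model, clean_lung_profile())
  st$A_muc[9] <- 1e-5   # all mucus in generation 8
  expect_equal(mean_mucus_position(st, model), 8)
  # expelled volume pulls the mean down (weight -1 in the numerator)
  st$v_out <- sum(st$A_muc * model$l[1:17])  # as much outside as inside
  expect_equal(mean_mucus_position(st, model), (8 - 1) / 2)
  # scaling all mucus volumes leaves mmp unchanged when v_out = 0
  st$v_out <- 0
  st2 <- st; st2$A_muc <- st$A_muc * 3
  expect_equal(mean_mucus_position(st2, model),
               mean_mucus_position(st, model))
  st$A_muc[] <- 0
  expect_error(mean_mucus_position(st, model), "undefined")
})

test_that("instantaneous Shrek number matches its defining formula", {
  st <- find_rest_state(model, clean_lung_profile())
  expect_equal(shrek(st, model)$iSh, 0)
  # single-airway check: a flow chosen so the shear equals sigma0 in the
  # trachea contributes exactly 1/N
  r0 <- sqrt(st$S_a[1] / pi)
  st$phi_a[1] <- model$fluids$sigma0 * pi * r0^3 / (4 * model$fluids$mu_air)
  expect_equal(shrek(st, model)$iSh, 1 / 17, tolerance = 1e-12)
})

test_that("exact and approximate Shrek numbers agree within a factor 2", {
  sim <- ventilation_run(clean_lung_profile())
  sh <- shrek(sim)
  expect_gt(sh$Sh / sh$Sh_approx, 0.5)
  expect_lt(sh$Sh / sh$Sh_approx, 2)
})

test_that("comfort is zero against itself and non-negative otherwise", {
  sim <- ventilation_run(clean_lung_profile())
  cf <- comfort(sim, sim)
  expect_equal(cf$Com, 0)
  expect_true(all(cf$iCom >= 0))
  bad <- sim; bad$times <- sim$times + 1
  expect_error(comfort(bad, sim), "time grids")
})

test_that("chest compression is less comfortable than focused pulses", {
  # short sessions, identical oscillation, with/without static pressure
  short <- default_session()
  short$duration <- 40; short$ramp_down <- c(30, 35); short$tail <- 5
  cfg <- stepper_config()
  cc <- run_simulation(maneuver_spec("hfcwo", P_s = 5.6, P_o = 1.2, f = 20,
                                     session = short),
                       default_mucus_profile(), cfg, model = model,
                       record_stride = 2L)
  fpt <- run_simulation(maneuver_spec("hfcwo", P_s = 0, P_o = 1.2, f = 20,
                                      session = short),
                        default_mucus_profile(), cfg, model = model,
                        record_stride = 2L)
  ref <- run_simulation(maneuver_spec("ventilation", session = short),
                        default_mucus_profile(), cfg, model = model,
                        t_end = 40, record_stride = 2L)
  com_cc <- comfort(cc, ref)$Com
  com_fpt <- comfort(fpt, ref)$Com
  expect_gt(com_cc, com_fpt)
  expect_gt(com_cc, 0)
})

test_that("simulation summary collects the standard scalar outcomes", {
  sim <- ventilation_run()
  s <- simulation_summary(sim, sim)
  expect_named(s, c("v_out_final", "r_final", "mmp_initial", "mmp_final",
                    "Sh", "Com"))
  expect_equal(s$v_out_final, 0)
  expect_equal(s$r_final, 1, tolerance = 1e-9)
  expect_equal(s$mmp_initial, 7.34, tolerance = 1e-3)
  expect_equal(s$Com, 0)
})
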