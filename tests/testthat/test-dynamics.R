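model <- default_model()

test_that("rest state sits at FRC with consistent areas", {
  st <- find_rest_state(model, default_mucus_profile())
  expect_equal(st$V_L, 3.25e-3, tolerance = 1e-6)
  expect_equal(st$P_air, rep(0, 23))
  expect_true(all(st$S_a[1:16] < st$S_b[1:16]))  # filled generations
  expect_equal(st$S_a[17:23], st$S_b[17:23])      # no mucus at gen 16+
  clean <- find_rest_state(model, clean_lung_profile())
  expect_equal(clean$S_a, clean$S_b)
  expect_error(find_rest_state(model, rep(1.2, 17)), "\\[0, 1\\)")
})

test_that("equilibrium is a fixed point of the stepper", {
  cfg <- stepper_config()
  st <- find_rest_state(model, default_mucus_profile())
  res <- step_residual(model, st, st$P_air, 0, cfg)
  expect_equal(max(abs(res)), 0, tolerance = 1e-9)
  st2 <- advance(model, st, 0, cfg)
  expect_equal(st2$V_L, st$V_L, tolerance = 1e-10)
  expect_equal(st2$S_a, st$S_a, tolerance = 1e-10)
  expect_equal(st2$P_air, st$P_air, tolerance = 1e-6)
  expect_equal(st2$v_out, 0)
})

test_that("mucus inflow routing follows the daughter/parent sign rules", {
  out <- rep(0, 17)
  # parent flowing down (+2) and daughters flowing up (-3), unit flows
  out[8] <- 2; out[10] <- -3
  expect_equal(mucus_inflow(out, 8), 0.5 * 2 + 2 * 3)
  # opposite signs do not account
  out2 <- rep(0, 17); out2[8] <- -1; out2[10] <- 1
  expect_equal(mucus_inflow(out2, 8), 0)
  # the trachea has no parent term
  out3 <- rep(0, 17); out3[2] <- -0.5
  expect_equal(mucus_inflow(out3, 0), 1)
  expect_equal(mucus_inflow(rep(1, 17), 16), 0.5)  # no daughter term
  expect_error(mucus_inflow(rep(0, 16), 0), "17")
})

test_that("trachea air flow accounts for the total gas volume change", {
  cfg <- stepper_config()
  st <- find_rest_state(model, default_mucus_profile())
  gas <- function(s) sum(s$S_a * model$l) +
    sum(model$n_air[18:23] * 58 * s$v_alv)
  man <- maneuver_spec("ventilation")
  for (k in 1:12) {
    st2 <- advance(model, st, external_pressure(man, k * cfg$dt), cfg)
    dV <- (gas(st2) - gas(st)) / cfg$dt
    expect_equal(st2$phi_a[1], dV, tolerance = 1e-6)
    st <- st2
  }
})

test_that("quiet breathing leaves the default mucus distribution unmoved", {
  sim <- ventilation_run()
  expect_equal(sim$final_state$v_out, 0)
  rel <- max(abs(sim$final_state$A_muc - sim$baseline$A_muc) /
               pmax(sim$baseline$A_muc, 1e-30))
  expect_lt(rel, 1e-6)
})

test_that("ventilation reaches the rest tidal volume", {
  sim <- ventilation_run()
  last <- sim$times >= 20
  tidal <- max(sim$V_L[last]) - min(sim$V_L[last])
  expect_equal(tidal * 1e3, 0.5, tolerance = 0.02)
})

test_that("mechanics are reversible without mucus", {
  # a clean lung returned to zero chest pressure recovers FRC: no hysteresis
  cfg <- stepper_config(dt = 0.01)
  st <- find_rest_state(model, clean_lung_profile())
  cache <- new.env(parent = emptyenv())
  # compress over 1 s, hold, release over 1 s, settle 2 s
  tt <- seq(cfg$dt, 5, by = cfg$dt)
  pexts <- cmh2o(5) * pmin(1, pmax(0, ifelse(tt < 2, tt, 3 - tt)))
  for (p in pexts) st <- advance(model, st, p, cfg, cache)
  for (k in 1:200) st <- advance(model, st, 0, cfg, cache)
  expect_equal(st$V_L, 3.25e-3, tolerance = 1e-5)
  expect_equal(st$v_out, 0)
})

test_that("halving dt changes the trajectory at first order", {
  man <- maneuver_spec("ventilation")
  end_VL <- vapply(c(5e-3, 2.5e-3, 1.25e-3), function(dtt) {
    run_simulation(man, clean_lung_profile(), stepper_config(dt = dtt),
                   model = model, t_end = 2.5,
                   record_stride = 1000L)$final_state$V_L
  }, numeric(1))
  e1 <- abs(end_VL[1] - end_VL[3])
  e2 <- abs(end_VL[2] - end_VL[3])
  expect_lt(e2, e1)          # refining dt converges
  expect_gt(e1 / e2, 1.5)    # at roughly first order
})

test_that("mucus mass is conserved and v_out is monotone under forcing", {
  # a short strong manual segment that mobilizes mucus
  sim <- cached("manual_seg", run_simulation(
    maneuver_spec("manual", P_cp = 20), default_mucus_profile(),
    stepper_config(), model = model, t_end = 18, record_stride = 5L))
  mass <- apply(sim$A_muc, 2, function(a) sum(a * model$l[1:17])) + sim$v_out
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-9)
  expect_true(all(diff(sim$v_out) >= 0))
  expect_true(all(sim$S_a > 0))
  expect_true(all(sim$S_a <= sim$S_b * (1 + 1e-12)))
  # mucus actually moved
  expect_gt(max(abs(sim$A_muc[, ncol(sim$A_muc)] - sim$A_muc[, 1])), 0)
})
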