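fl <- fluid_constants()

test_that("yield radius follows |2 sigma0 / C| with an infinite dead case", {
  expect_equal(yield_radius(2, 0.1), 0.1)
  expect_equal(yield_radius(-2000, 0.1), 1e-4)
  expect_identical(yield_radius(0, 0.1), Inf)
})

test_that("no-mucus and rigid-annulus limits reduce to Poiseuille", {
  r <- 1e-3
  geom <- annulus_geometry(pi * r^2, pi * r^2)
  f <- flows_from_gradient(-2000, geom, fl)
  expect_equal(f$phi_air, 2000 * pi * r^4 / (8 * fl$mu_air), tolerance = 1e-12)
  expect_identical(f$phi_mucus, 0)
  # rigid annulus: |C| below yield onset, Poiseuille in the core radius
  geom2 <- annulus_geometry(pi * (0.7e-3)^2, pi * (1e-3)^2)
  C <- -0.9 * 2 * fl$sigma0 / 1e-3   # r0 = 2 sigma0/|C| > r_b
  f2 <- flows_from_gradient(C, geom2, fl)
  expect_equal(f2$phi_air, -C * pi * (0.7e-3)^4 / (8 * fl$mu_air),
               tolerance = 1e-12)
  expect_identical(f2$phi_mucus, 0)
})

test_that("mucus flux has a yield dead-zone and is antisymmetric", {
  geom <- annulus_geometry(pi * (0.5e-3)^2, pi * (1e-3)^2)
  Cy <- 2 * fl$sigma0 / 1e-3
  expect_identical(mucus_outflow(c(-0.99, 0.5, 0.99) * Cy, geom, fl),
                   c(0, 0, 0))
  for (C in c(1.3, 2.5, 8) * Cy) {
    expect_equal(mucus_outflow(C, geom, fl), -mucus_outflow(-C, geom, fl),
                 tolerance = 1e-14)
  }
  # toward the mouth (negative) under a positive gradient
  expect_lt(mucus_outflow(3 * Cy, geom, fl), 0)
})

test_that("fluxes are continuous and monotone non-increasing in C", {
  geom <- annulus_geometry(pi * (0.6e-3)^2, pi * (1.1e-3)^2)
  C <- seq(-3000, 3000, length.out = 6001)
  f <- flows_from_gradient(C, geom, fl)
  expect_true(all(diff(f$phi_air) < 0))
  expect_true(all(diff(f$phi_mucus) <= 0))
  # continuity: no step exceeds a small multiple of the local median step
  da <- abs(diff(f$phi_air))
  expect_lt(max(da), 10 * stats::median(da))
})

test_that("closed forms match the quadrature oracle across regimes", {
  set.seed(11)
  n <- 120  # three regimes x 40 random draws
  worst <- 0
  for (k in seq_len(n)) {
    rb <- 10^stats::runif(1, -4, -2.3)
    ra <- rb * stats::runif(1, 0.15, 0.85)
    regime <- k %% 3
    Cy <- 2 * fl$sigma0 / rb
    Cf <- 2 * fl$sigma0 / ra
    C <- switch(regime + 1,
                stats::runif(1, 0.05, 0.95) * Cy,          # rigid
                stats::runif(1, 1.05 * Cy, 0.95 * Cf),     # partial
                stats::runif(1, 1.1, 20) * Cf) *           # fully yielded
      sample(c(-1, 1), 1)
    geom <- list(r_a = ra, r_b = rb)
    cf <- flows_from_gradient(C, geom, fl)
    or <- profile_oracle(C, geom, fl)
    worst <- max(worst,
                 abs(cf$phi_air - or$phi_air) / abs(or$phi_air),
                 if (abs(or$phi_mucus) > 0)
                   abs(cf$phi_mucus - or$phi_mucus) / abs(or$phi_mucus)
                 else abs(cf$phi_mucus))
  }
  expect_lt(worst, 1e-7)
})

test_that("the gradient map F inverts the flux map exactly", {
  set.seed(23)
  for (k in 1:1000) {
    rb <- 10^stats::runif(1, -4.2, -2)
    ra <- rb * stats::runif(1, 0.05, 1)
    C0 <- sample(c(-1, 1), 1) * 10^stats::runif(1, -1, 5)
    geom <- list(r_a = ra, r_b = rb)
    phi <- flows_from_gradient(C0, geom, fl)$phi_air
    C1 <- gradient_from_airflow(phi, geom, fl)
    expect_equal(C1, C0, tolerance = 1e-8)
  }
  geom <- list(r_a = 5e-4, r_b = 1e-3)
  expect_identical(gradient_from_airflow(0, geom, fl), 0)
})

test_that("Poiseuille inversion matches the closed form", {
  geom <- annulus_geometry(pi * 1e-6, pi * 1e-6)  # r = 1 mm, no mucus
  C <- gradient_from_airflow(1e-6, geom, fl)      # 1 mL/s
  expect_equal(C, -8 * fl$mu_air * 1e-6 / (pi * (1e-3)^4), tolerance = 1e-12)
  expect_equal(C, -45.84, tolerance = 1e-3)
})

test_that("air flux approaches the rigid-annulus value as mu_m grows", {
  geom <- annulus_geometry(pi * (0.5e-3)^2, pi * (1e-3)^2)
  C <- -40  # well beyond yield for r_b = 1 mm
  rigid <- C * -pi * (0.5e-3)^4 / (8 * fl$mu_air)
  prev_gap <- Inf
  for (mu in 10^seq(-1, 4, by = 1)) {
    f <- flows_from_gradient(C, geom, fluid_constants(mu_mucus = mu))
    gap <- abs(f$phi_air - rigid)
    expect_lt(gap, prev_gap + 1e-18)
    prev_gap <- gap
  }
  expect_lt(prev_gap / rigid, 1e-4)
})

test_that("airway and tree resistances follow the fourth-power law", {
  expect_equal(airway_air_resistance(1e-3, 0.01, fl),
               8 * fl$mu_air * 0.01 / (pi * 1e-12), tolerance = 1e-12)
  expect_equal(airway_air_resistance(0.5e-3, 0.01, fl) /
                 airway_air_resistance(1e-3, 0.01, fl), 16, tolerance = 1e-12)
  tree <- build_tree_spec()
  model <- default_model()
  rest <- find_rest_state(model, clean_lung_profile())
  R <- tree_resistance(rest$S_a, tree, fl)
  manual <- sum(airway_air_resistance(
    sqrt(rest$S_a[1:17] / 2^(0:16) / pi), tree$length[1:17], fl) / 2^(0:16))
  expect_equal(R, manual, tolerance = 1e-12)
  expect_error(airway_air_resistance(0, 0.01, fl), "degenerate")
})
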