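tree <- build_tree_spec()

test_that("Lambert law hits its printed anchors and asymptotes", {
  # area at zero transmural pressure is alpha0 * A_m (trachea: 0.882 * 2.37 cm^2)
  expect_equal(lambert_area(tree, 0, 0) * 1e4, 0.882 * 2.37, tolerance = 1e-12)
  # upper asymptote is A_m
  for (z in c(0, 8, 16)) {
    expect_equal(lambert_area(tree, z, 1e9), tree$A_m[z + 1], tolerance = 1e-4)
  }
  # strictly increasing and bounded in (0, A_m)
  dP <- seq(-3000, 3000, length.out = 500)
  for (z in c(0, 5, 11, 16)) {
    S <- lambert_area(tree, rep(z, 500), dP)
    expect_true(all(diff(S) > 0))
    expect_true(all(S > 0 & S < tree$A_m[z + 1]))
  }
  expect_error(lambert_area(tree, 17, 0), "0..16")
})

test_that("Lambert formula matches an independent high-precision evaluation", {
  # generation 16 at +500 Pa, re-derived digit by digit from the table row
  # (printed alpha0' of 24.3 is in units of 1e-3 / Pa)
  a0 <- 0.039
  a0p <- 24.3 * 1e-3
  n2 <- 7; Am <- 180e-4
  P2 <- -n2 * (1 - a0) / a0p
  S_expect <- (1 - (1 - a0) * (1 - 500 / P2)^(-n2)) * Am
  expect_equal(lambert_area(tree, 16, 500), S_expect, tolerance = 1e-12)
})

test_that("Lambert law is C1 at zero transmural pressure for all generations", {
  eps <- 1e-7
  for (z in 0:16) {
    i <- z + 1
    # value from both branches
    expect_equal(lambert_area(tree, z, -1e-300),
                 tree$alpha0[i] * tree$A_m[i], tolerance = 1e-12)
    expect_equal(lambert_area(tree, z, 1e-300),
                 tree$alpha0[i] * tree$A_m[i], tolerance = 1e-10)
    # analytic slope from both branches equals alpha0' * A_m
    slope <- tree$alpha0_prime[i] * tree$A_m[i]
    expect_equal(lambert_area(tree, z, -eps, deriv = TRUE), slope,
                 tolerance = 1e-5)
    expect_equal(lambert_area(tree, z, +eps, deriv = TRUE), slope,
                 tolerance = 1e-5)
    # analytic derivative agrees with finite differences away from zero
    for (dP in c(-200, 150)) {
      fd <- (lambert_area(tree, z, dP + eps) -
               lambert_area(tree, z, dP - eps)) / (2 * eps)
      expect_equal(lambert_area(tree, z, dP, deriv = TRUE), fd,
                   tolerance = 1e-5)
    }
  }
})

test_that("default volume curve meets its anchors and is invertible", {
  curves <- build_pv_curves()
  vols <- curves$vols
  expect_equal(curves$static_volume(0), 3.25e-3, tolerance = 1e-12)
  # quasi-static excursion at -5 cmH2O equals the rest tidal volume
  expect_equal(curves$static_volume(cmh2o(5)) - curves$static_volume(0),
               0.5e-3, tolerance = 1e-10)
  # rest compliance about 0.1 L/cmH2O
  expect_equal(curves$static_volume_deriv(0) * 1e3 * CMH2O_PA, 0.1,
               tolerance = 0.06)
  # monotone on a grid over +/- 30 cmH2O
  g <- seq(cmh2o(-30), cmh2o(30), length.out = 1000)
  expect_true(all(diff(curves$static_volume(g)) > 0))
  # inverse round trip
  V <- curves$static_volume(g)
  expect_equal(curves$static_volume_inv(V), g, tolerance = 1e-9)
  # tissue curve anchors
  expect_equal(curves$tissue_pressure(vols$FRC), 500, tolerance = 1e-8)
  expect_equal(curves$tissue_pressure(vols$TLC), cmh2o(30), tolerance = 1e-8)
  expect_true(all(diff(curves$tissue_pressure(seq(1.6e-3, 6.4e-3,
                                                  length.out = 400))) > 0))
})

test_that("the reference-diameter rest-transmural reading stays available", {
  # the anchor at which the Lambert laws reproduce the tabulated diameters
  expect_equal(table1_transmural(), 50, tolerance = 0.01)
  curves <- build_pv_curves(frc_transmural = table1_transmural())
  expect_equal(curves$tissue_pressure(curves$vols$FRC), table1_transmural(),
               tolerance = 1e-8)
  # at that anchor the rest decomposition matches the reference geometry
  tree <- build_tree_spec()
  VL <- solve_lung_volume(curves, tree, 0, 0)
  expect_equal(tracheobronchial_volume(curves, tree, VL, 0),
               reference_conducting_volume(tree), tolerance = 1e-3)
})

test_that("user-supplied curve tables are validated and interpolated", {
  tab <- data.frame(pressure_cmh2o = seq(-40, 40, by = 2))
  tab$volume_l <- 1.5 + 5 / (1 + exp(-(tab$pressure_cmh2o - 7) / 12))
  curves <- build_pv_curves(volume_table = tab)
  expect_equal(curves$static_volume(cmh2o(10)) * 1e3,
               1.5 + 5 / (1 + exp(-(10 - 7) / 12)), tolerance = 1e-4)
  bad <- tab; bad$volume_l[3] <- bad$volume_l[5]
  expect_error(build_pv_curves(volume_table = bad), "increasing")
})

test_that("rest equilibrium reproduces the FRC decomposition", {
  curves <- build_pv_curves()
  V_L <- solve_lung_volume(curves, tree, 0, 0)
  expect_equal(V_L, 3.25e-3, tolerance = 1e-6)
  vtbt <- tracheobronchial_volume(curves, tree, V_L, 0)
  adu <- alveolar_duct_unit(curves, tree, 0, 0)
  V_ac <- sum(tree$n_airways[18:23]) * adu$v_adu
  # bronchial tree (conducting + duct lumens) about 0.67 L; the
  # reconstructed quasi-static curves shift these by a few percent
  expect_equal((vtbt + tree$alpha_duct * V_ac) * 1e3, 0.67, tolerance = 0.1)
  # alveoli about 2.58 L
  expect_equal((1 - tree$alpha_duct) * V_ac * 1e3, 2.58, tolerance = 0.1)
  # duct volume fraction is exactly alpha
  expect_equal(adu$duct_area * tree$L_ad / adu$v_adu, 0.17, tolerance = 1e-12)
  # re-substituted residual below the solver contract
  resid <- V_L - V_ac - tracheobronchial_volume(curves, tree, V_L, 0)
  expect_lt(abs(resid), 1e-9)
})

test_that("lung volume solve matches a brute-force residual scan", {
  curves <- build_pv_curves()
  set.seed(7)
  grid <- seq(curves$vols$RV + 1e-6, curves$vols$TLC - 1e-6,
              length.out = 10000)
  for (k in 1:20) {
    P_air <- rnorm(23, sd = 100)
    P_ext <- runif(1, -600, 600)
    V <- solve_lung_volume(curves, tree, P_air, P_ext)
    ac <- sum(tree$n_airways[18:23] *
                bronchosim:::.acinar_units(curves, tree, P_air[18:23],
                                           P_ext)$v_adu)
    res <- abs(grid - ac -
                 vapply(grid, function(v)
                   tracheobronchial_volume(curves, tree, v, P_air), 1))
    expect_lt(abs(V - grid[which.min(res)]), diff(grid[1:2]) * 1.5)
  }
})

test_that("mechanics map is monotone in chest pressure and self-consistent", {
  curves <- build_pv_curves()
  m0 <- mechanics_map(curves, tree, 0, 0)
  expect_equal(m0$V_L, 3.25e-3, tolerance = 1e-6)
  # re-summing areas x lengths reproduces the volume decomposition
  vtbt <- sum(m0$S_b[1:17] * tree$length[1:17])
  expect_equal(vtbt, tracheobronchial_volume(curves, tree, m0$V_L, 0),
               tolerance = 1e-10)
  # compressing the chest shrinks every lumen
  m1 <- mechanics_map(curves, tree, cmh2o(5), 0)
  expect_true(all(m1$S_b < m0$S_b))
  expect_lt(m1$V_L, m0$V_L)
  # and acinar volumes shrink with external pressure
  a0 <- alveolar_duct_unit(curves, tree, 0, 0)$v_adu
  a1 <- alveolar_duct_unit(curves, tree, 0, 200)$v_adu
  expect_lt(a1, a0)
})
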