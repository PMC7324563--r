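# Oxygen reaction-diffusion model: domain construction, steady-state
# validation against closed-form slab profiles, transient conservation and
# ordering properties.

test_that("domain construction encodes the two culture geometries", {
  dom_tw <- build_domain(culture_config("transwell"), resolution = coarse_res())
  expect_identical(dom_tw$bc_bottom, "zeroflux")
  expect_identical(dom_tw$bc_top, "dirichlet")
  dom_pfc <- build_domain(culture_config("pfc"), resolution = coarse_res())
  expect_identical(dom_pfc$bc_bottom, "dirichlet")
  expect_identical(dom_pfc$bc_top, "dirichlet")

  # tissue occupies the slice footprint, surrounded laterally by medium
  expect_true(any(dom_tw$tissue))
  expect_true(all(dom_tw$phase[1, ] == "medium"))
  expect_true(all(dom_tw$phase[dom_tw$nx, ] == "medium"))
  # every node has exactly one phase, drawn from the declared set
  expect_true(all(dom_tw$phase %in% c("medium", "tissue")))

  expect_error(culture_config("transwell", slice_thickness = 0),
               "slice_thickness")
  expect_error(culture_config("transwell", lateral_margin = -1),
               "lateral_margin")
  expect_error(build_domain(culture_config("pfc"),
                            phases = list(medium = default_phases()$medium)),
               "tissue")
  expect_error(domain_resolution(nz_tissue = 2), "3 nodes")
})

test_that("steady state matches the closed-form zeroth-order slab", {
  kin <- oxygen_kinetics(r_max = 0.03, km = 0, shutoff = FALSE)
  K <- default_phases()$tissue$permeability_K
  L <- 120e-6

  d <- slab_domain(120, n = 64, bc_bottom = 150, bc_top = 150)
  f <- steady_state(d, kin)
  analytic <- 150 + kin$r_max / (2 * K) * (d$z^2 - L * d$z)
  # midplane value p0 - r L^2 / (8 K) = 127.5 mmHg
  expect_equal(min(f$po2), 127.5, tolerance = 5e-3)
  expect_lt(max(abs(f$po2[1, ] - analytic) / analytic), 0.005)

  # insulated bottom face: p(0) = p0 - r L^2 / (2 K) = 60 mmHg
  d2 <- slab_domain(120, n = 64, bc_bottom = NA, bc_top = 150)
  f2 <- steady_state(d2, kin)
  expect_equal(f2$po2[1, 1], 60, tolerance = 5e-3)

  # no consumption: uniform field at the boundary value
  f3 <- steady_state(d, oxygen_kinetics(r_max = 0, km = 0, shutoff = FALSE))
  expect_equal(as.vector(f3$po2), rep(150, 64), tolerance = 1e-10)
})

test_that("spatial scheme is second order under mesh refinement", {
  kin <- oxygen_kinetics(r_max = 0.03, km = 0, shutoff = FALSE)
  K <- default_phases()$tissue$permeability_K
  L <- 120e-6
  err <- vapply(c(32, 64, 128), function(n) {
    d <- slab_domain(120, n = n, bc_bottom = 150, bc_top = 150)
    f <- steady_state(d, kin)
    analytic <- 150 + kin$r_max / (2 * K) * (d$z^2 - L * d$z)
    max(abs(f$po2[1, ] - analytic))
  }, 1)
  # halving h should reduce the midplane-sampling error ~4x
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5)
  expect_gt(err[2] / err[3], 3)
  expect_lt(err[2] / err[3], 5)
})

test_that("transient solver conserves mass and honours the maximum principle", {
  dom <- build_domain(culture_config("transwell"), resolution = coarse_res())
  sim <- simulate_oxygen(dom, oxygen_kinetics(0.03, km = 0.44),
                         duration_h = 3, dt = 120)
  expect_lt(sim$mass_balance$rel_error, 1e-4)
  expect_true(all(sim$final >= 0))
  expect_true(all(sim$final <= dom$gas_po2 + 1e-9))

  dom_p <- build_domain(culture_config("pfc"), resolution = coarse_res())
  sim_p <- simulate_oxygen(dom_p, oxygen_kinetics(0.05, km = 0.44),
                           duration_h = 3, dt = 120)
  expect_lt(sim_p$mass_balance$rel_error, 1e-4)
  expect_true(all(sim_p$final >= 0))
  expect_true(all(sim_p$final <= dom_p$gas_po2 + 1e-9))
})

test_that("zero consumption at equilibrium leaves the field constant", {
  dom <- build_domain(culture_config("pfc"), resolution = coarse_res())
  sim <- simulate_oxygen(dom, oxygen_kinetics(r_max = 0),
                         duration_h = 1, dt = 300)
  expect_equal(as.vector(sim$final), rep(dom$gas_po2, length(sim$final)),
               tolerance = 1e-10)
  expect_equal(sim$anoxic_fraction, rep(0, length(sim$anoxic_fraction)))
})

test_that("core pO2 decays monotonically from an equilibrated start", {
  # smooth kinetics: the reaction-diffusion semigroup is order-preserving,
  # so starting at/above steady state the field can only decrease
  dom <- build_domain(culture_config("transwell"), resolution = coarse_res())
  sim <- simulate_oxygen(dom, oxygen_kinetics(0.03, km = 0.44, shutoff = FALSE),
                         duration_h = 4, dt = 120)
  expect_true(all(diff(sim$core_po2) <= 1e-9))
})

test_that("anoxic fraction counts tissue below threshold, volume weighted", {
  m <- matrix(c(0.05, 0.2, 0.09, 5.0), 2, 2)
  tis <- matrix(TRUE, 2, 2)
  expect_equal(anoxic_fraction(m, tis, 0.1), 0.5)
  expect_equal(anoxic_fraction(matrix(150, 3, 3), matrix(TRUE, 3, 3), 0.1), 0)
  expect_equal(anoxic_fraction(matrix(0.05, 3, 3), matrix(TRUE, 3, 3), 0.1), 1)
  expect_error(anoxic_fraction(m, matrix(FALSE, 2, 2), 0.1), "empty tissue")
})

test_that("anoxia onset is the first threshold crossing", {
  trace <- data.frame(time_h = c(0, 8, 16), po2 = c(10, 1, 0.05))
  expect_equal(anoxia_onset(trace, 0.1), 16)
  never <- data.frame(time_h = c(0, 8, 16), po2 = c(10, 5, 2))
  expect_true(is.na(anoxia_onset(never, 0.1)))
  expect_error(anoxia_onset(data.frame(t = 0, p = 1)), "2 snapshots")
})

test_that("anoxic fraction is monotone in OCR and PFC never exceeds transwell", {
  sw <- ocr_sweep(list(culture_config("transwell"), culture_config("pfc")),
                  ocr_values = c(0.01, 0.03, 0.05), duration_h = 4,
                  resolution = coarse_res(), dt = 120)
  tw <- sw$anoxic_fraction[sw$mode == "transwell"]
  pf <- sw$anoxic_fraction[sw$mode == "pfc"]
  expect_false(is.unsorted(tw))
  expect_false(is.unsorted(pf))
  expect_true(all(pf <= tw + 1e-12))
  # zero consumption leaves no anoxia
  dom <- build_domain(culture_config("transwell"), resolution = coarse_res())
  s0 <- simulate_oxygen(dom, oxygen_kinetics(r_max = 0), 1, dt = 300)
  expect_equal(max(s0$anoxic_fraction), 0)
})

test_that("PFC keeps identical kinetics above threshold at every snapshot", {
  kin <- oxygen_kinetics(0.03, km = 0.44, shutoff = FALSE)
  sim_tw <- simulate_oxygen(build_domain(culture_config("transwell"),
                                         resolution = coarse_res()),
                            kin, duration_h = 4, dt = 120)
  sim_pf <- simulate_oxygen(build_domain(culture_config("pfc"),
                                         resolution = coarse_res()),
                            kin, duration_h = 4, dt = 120)
  expect_true(all(sim_pf$anoxic_fraction <= sim_tw$anoxic_fraction + 1e-12))
})
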