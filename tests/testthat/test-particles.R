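test_that("configs derive the Einstein mobility and a stable default dt", {
  cfg <- reduced_config(30)
  expect_equal(cfg$mu, 1)                    # D/RT with RT = 1
  w <- cfg$potential$interface_width
  f_max <- cfg$potential$U_max / (4 * w)
  expect_equal(cfg$mu * f_max * cfg$dt, w / 25, tolerance = 1e-12)

  # the spec-level stability bound is a hard refusal
  bad <- reduced_config(30, dt = 1)
  expect_error(run_brownian(bad), "stability bound")
  err <- tryCatch(run_brownian(bad), error = function(e) conditionMessage(e))
  expect_match(err, "use dt <=")
})

test_that("identical config and seed give bit-identical results", {
  cfg <- reduced_config(10, N = 500, n_steps = 2000, seed = 99)
  a <- run_brownian(cfg)
  b <- run_brownian(cfg)
  expect_identical(a$mean_force_per_area, b$mean_force_per_area)
  expect_identical(a$concentration_histogram, b$concentration_histogram)
  expect_identical(a$final_positions, b$final_positions)
  # a different seed gives a different trajectory
  c2 <- run_brownian(reduced_config(10, N = 500, n_steps = 2000, seed = 100))
  expect_false(identical(a$mean_force_per_area, c2$mean_force_per_area))
})

test_that("particles are conserved exactly", {
  cfg <- reduced_config(30, N = 1500, n_steps = 5000, seed = 4)
  res <- run_brownian(cfg)
  expect_identical(length(res$final_positions), 1500L)
  expect_true(all(res$final_positions >= cfg$box[1] &
                    res$final_positions <= cfg$box[2]))
  # histogram occupancy integrates back to N per step
  bw <- diff(cfg$box) / cfg$n_bins
  total <- sum(res$concentration_histogram$c) * bw * cfg$cross_section_area
  expect_equal(total, 1500, tolerance = 1e-9)
})

test_that("free diffusion gives a flat profile and zero membrane force", {
  pot <- membrane_potential("plateau", U_max = 0, h = 20, interface_width = 1)
  cfg <- particle_sim_config(pot, N = 2000, D_s = 1, reduced = TRUE,
                             n_steps = 10000, seed = 8)
  res <- run_brownian(cfg)
  expect_identical(res$mean_force_per_area, 0)
  ref <- equilibrium_profile(pot, 1, temperature = 1 / R_gas,
                             grid = spatial_grid(20, chamber_width = 100))
  cmp <- measure_concentration_profile(res, ref)
  expect_lt(cmp$max_abs_z, 4.5)
})

test_that("membrane force per area recovers the osmotic pressure (3 sigma)", {
  # impermeable barrier: full van 't Hoff pressure RT c_b
  res30 <- run_brownian(reduced_config(30, N = 2000, n_steps = 30000, seed = 1))
  expect_equal(res30$rt_c_reference, res30$c_bulk *
                 (1 - exp(-30)), tolerance = 1e-12)
  expect_lt(abs(res30$mean_force_per_area - res30$rt_c_reference),
            3 * res30$stderr)
  # finite 2 RT barrier: reduced by the Boltzmann leak factor
  res2 <- run_brownian(reduced_config(2, N = 2000, n_steps = 30000, seed = 1))
  expect_equal(res2$rt_c_reference, res2$c_bulk * (1 - exp(-2)),
               tolerance = 1e-12)
  expect_lt(abs(res2$mean_force_per_area - res2$rt_c_reference),
            3 * res2$stderr)
})

test_that("force per area is independent of barrier shape at fixed U_max", {
  a <- run_brownian(reduced_config(30, shape = "plateau", N = 2000,
                                   n_steps = 30000, seed = 2))
  b <- run_brownian(reduced_config(30, shape = "gaussian", N = 2000,
                                   n_steps = 30000, seed = 12))
  # the geometries hold different bulk concentrations, so compare each
  # pressure normalized to its own RT c_b: both must sit at 1
  ra <- a$mean_force_per_area / a$rt_c_reference
  rb <- b$mean_force_per_area / b$rt_c_reference
  diff_se <- sqrt((a$stderr / a$rt_c_reference)^2 +
                    (b$stderr / b$rt_c_reference)^2)
  expect_lt(abs(ra - rb), 3.5 * diff_se)
})

test_that("van 't Hoff z-scores over independent seeds look standard normal", {
  zs <- vapply(1:10, function(s)
    run_brownian(reduced_config(30, N = 800, n_steps = 50000, seed = s))$z_score,
    numeric(1))
  expect_lt(abs(mean(zs)), 1.5)          # no systematic bias
  expect_gt(ks.test(zs, "pnorm")$p.value, 0.01)
})

test_that("sampled concentration profile matches the Boltzmann closed form", {
  cfg <- reduced_config(5, N = 4000, n_steps = 30000, seed = 6)
  res <- run_brownian(cfg)
  ref <- equilibrium_profile(cfg$potential, 1, temperature = 1 / R_gas,
                             grid = spatial_grid(20, chamber_width = 100))
  cmp <- measure_concentration_profile(res, ref)
  expect_lt(cmp$max_abs_z, 4.5)
  expect_lt(cmp$max_deviation, 0.05 * max(cmp$per_bin$p_ref))
})

test_that("block standard errors shrink like one over sqrt(steps)", {
  short <- run_brownian(reduced_config(5, N = 1000, n_steps = 10000, seed = 3))
  long <- run_brownian(reduced_config(5, N = 1000, n_steps = 40000, seed = 3))
  sel <- short$concentration_histogram$c > 0.2 * max(short$concentration_histogram$c)
  cmp_s <- apply(short$hist_blocks / rowSums(short$hist_blocks), 2, sd)[sel]
  cmp_l <- apply(long$hist_blocks / rowSums(long$hist_blocks), 2, sd)[sel]
  ratio <- stats::median(cmp_s / cmp_l)
  # quadrupling the steps should halve the per-block spread (CLT scaling);
  # allow a generous band for the chi-square noise of each sd estimate
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("geometry mismatches between simulation and reference are caught", {
  cfg <- reduced_config(5, N = 300, n_steps = 2000, seed = 2)
  res <- run_brownian(cfg)
  other <- membrane_potential("plateau", U_max = 5, h = 35, interface_width = 1)
  ref <- equilibrium_profile(other, 1, temperature = 1 / R_gas,
                             grid = spatial_grid(35, chamber_width = 100))
  expect_error(measure_concentration_profile(res, ref), "geometry mismatch")
})
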