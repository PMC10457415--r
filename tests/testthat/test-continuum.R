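test_that("no membrane means uniform concentration and pressure", {
  pot <- membrane_potential("plateau", U_max = 0, h = 5e-9)
  prof <- equilibrium_profile(pot, c_bulk_right = 120, P_right = 5e4,
                              temperature = 300)
  right <- prof$x >= pot$h / 2
  expect_equal(prof$c[right], rep(120, sum(right)))
  expect_equal(prof$P[right], rep(5e4, sum(right)), tolerance = 1e-12)
  expect_identical(prof$phi_V, 0)
})

test_that("equilibrium chamber pressure difference is RT c_r (van 't Hoff)", {
  temperature <- 300
  pot <- std_plateau(30, temperature)
  prof <- equilibrium_profile(pot, 100, 0, temperature)
  dP <- chamber_pressure_difference(prof)
  expect_equal(dP, R_gas * temperature * 100, tolerance = 1e-12)
  expect_equal(dP, 249420, tolerance = 1e-10)
})

test_that("the membrane force profile cancels from the chamber pressure difference", {
  temperature <- 300
  ref <- chamber_pressure_difference(
    equilibrium_profile(std_plateau(30, temperature), 100, 0, temperature))
  for (U_rt in c(30, 45, 70, 100)) {
    for (make in list(std_plateau, std_gaussian)) {
      for (wfac in c(1 / 30, 1 / 20, 1 / 10)) {
        pot <- make(U_rt, temperature, h = 5e-9, width = 5e-9 * wfac)
        dP <- chamber_pressure_difference(
          equilibrium_profile(pot, 100, 0, temperature))
        expect_equal(dP, ref, tolerance = 1e-6)
      }
    }
  }
})

test_that("equilibrium profile satisfies the slice force balance dP/dx = c F", {
  temperature <- 300
  pot <- std_plateau(5, temperature)
  grid <- spatial_grid(pot$h, n = 8001)
  prof <- equilibrium_profile(pot, 100, 0, temperature, grid)
  x <- prof$x
  dx <- x[2] - x[1]
  inner <- 2:(length(x) - 1)
  dPdx <- (prof$P[inner + 1] - prof$P[inner - 1]) / (2 * dx)
  cF <- prof$c[inner] * membrane_force(pot, x[inner])
  expect_lt(max(abs(dPdx - cF)) / max(abs(cF)), 1e-2)
})

test_that("exclusion approaches completeness monotonically as the barrier grows", {
  temperature <- 300
  ratios <- sapply(c(5, 10, 20, 30, 50), function(U_rt) {
    prof <- equilibrium_profile(std_plateau(U_rt, temperature), 100, 0, temperature)
    chamber_pressure_difference(prof) / (R_gas * temperature * 100)
  })
  expect_true(all(diff(ratios) >= 0))
  expect_gt(ratios[2], ratios[1])
  expect_true(all(ratios <= 1))
  expect_equal(ratios[5], 1, tolerance = 1e-12)
})

test_that("steady state with identical chambers is fluxless and flat in the bulk", {
  temperature <- 300
  pot <- std_plateau(30, temperature)
  st <- solution_state(80, 2e4, temperature)
  prof <- steady_state_profile(pot, 1e-12, st, st)
  expect_identical(prof$phi_V, 0)
  bulk <- abs(prof$x - pot$h / 2) > 3.5 * pot$h
  expect_equal(max(prof$P[bulk]) - min(prof$P[bulk]), 0, tolerance = 1e-9 * 2e4)
  # symmetric equilibrium: the membrane interior sits RT c below both chambers
  expect_equal(2e4 - min(prof$P), R_gas * temperature * 80, tolerance = 1e-10)
})

test_that("osmotic steady state: flux, Vegard drop and linear interior", {
  temperature <- 300
  Lp <- 1e-12
  pot <- std_plateau(30, temperature)
  left <- solution_state(0, 0, temperature)
  right <- solution_state(100, 0, temperature)
  prof <- steady_state_profile(pot, Lp, left, right)

  rtc <- R_gas * temperature * 100
  # flux equals the combined law, toward the solution
  expect_equal(prof$phi_V, Lp * rtc, tolerance = 1e-12)
  expect_equal(prof$phi_V, 2.4942e-7, tolerance = 1e-12)
  # interface drop RT c_r
  expect_equal(vegard_drop(prof), rtc, tolerance = 1e-8)
  # intramembrane pressure drop from face to face equals RT c_r (Fig-style
  # profile: P returns to the chamber value across the solution interface)
  interior <- prof$x > 0 & prof$x < pot$h
  fit <- lm(P ~ x, data = data.frame(x = prof$x[interior][abs(prof$x[interior] - pot$h / 2) < pot$h / 8],
                                     P = prof$P[interior][abs(prof$x[interior] - pot$h / 2) < pot$h / 8]))
  slope <- coef(fit)[[2]]
  expect_equal(slope, -prof$phi_V / (pot$h * Lp), tolerance = 1e-8)
  expect_equal(slope * pot$h, -rtc, tolerance = 1e-8)
})

test_that("chamber pressures at the van 't Hoff balance reproduce equilibrium", {
  temperature <- 300
  pot <- std_plateau(30, temperature)
  dP <- van_t_hoff_delta_p(100, temperature)
  prof <- steady_state_profile(pot, 1e-12,
                               left = solution_state(0, 0, temperature),
                               right = solution_state(100, dP, temperature))
  expect_equal(prof$phi_V, 0, tolerance = 1e-20)
  eq <- equilibrium_profile(pot, 100, P_right = dP, temperature = temperature)
  expect_equal(prof$c, eq$c, tolerance = 1e-10)
  expect_equal(prof$P, eq$P, tolerance = 1e-6)
})

test_that("steady-state flux is linear in both drivers with coefficient -Lp", {
  temperature <- 300
  Lp <- 2.5e-13
  pot <- std_plateau(30, temperature)
  dPs <- c(-2e5, -1e5, 0, 1e5, 2e5)
  phi_P <- sapply(dPs, function(dp)
    steady_state_profile(pot, Lp, solution_state(0, 0, temperature),
                         solution_state(0, dp, temperature))$phi_V)
  fitP <- lm(phi_P ~ dPs)
  dcs <- c(0, 25, 50, 100, 200)
  phi_c <- sapply(dcs, function(dc)
    steady_state_profile(pot, Lp, solution_state(0, 0, temperature),
                         solution_state(dc, 0, temperature))$phi_V)
  rtdc <- R_gas * temperature * dcs
  fitc <- lm(phi_c ~ rtdc)

  expect_equal(coef(fitP)[[2]], -Lp, tolerance = 1e-8)
  expect_equal(coef(fitc)[[2]], Lp, tolerance = 1e-8)
  expect_equal(abs(coef(fitc)[[2]] / coef(fitP)[[2]]), 1, tolerance = 1e-8)
  expect_lt(max(abs(residuals(fitP))), 1e-8 * max(abs(phi_P)))
})

test_that("Vegard drop is the same at equilibrium and in the steady state", {
  temperature <- 300
  pot <- std_plateau(30, temperature)
  eq <- equilibrium_profile(pot, 100, 0, temperature)
  ss <- steady_state_profile(pot, 1e-12, solution_state(0, 0, temperature),
                             solution_state(100, 0, temperature))
  expect_equal(vegard_drop(eq), vegard_drop(ss), tolerance = 1e-8)
  # no solute, no drop
  ss0 <- steady_state_profile(pot, 1e-12, solution_state(0, 0, temperature),
                              solution_state(0, 5e4, temperature))
  expect_equal(vegard_drop(ss0), 0, tolerance = 1e-9 * 5e4)
})

test_that("leaky membranes are refused by the steady-state solver", {
  temperature <- 300
  pot <- std_plateau(5, temperature)
  expect_error(
    steady_state_profile(pot, 1e-12, solution_state(0, 0, temperature),
                         solution_state(100, 0, temperature)),
    "impermeable"
  )
})

test_that("direct ODE integration matches the Boltzmann closed form", {
  temperature <- 300
  for (make in list(std_plateau, std_gaussian)) {
    for (U_rt in c(2, 10, 30)) {
      pot <- make(U_rt, temperature)
      closed <- equilibrium_profile(pot, 100, 0, temperature)
      numeric <- numeric_ode_solution(pot, 100, 0, temperature)
      expect_lt(max(abs(numeric$c - closed$c)) / 100, 1e-8)
      expect_lt(max(abs(numeric$P - closed$P)) /
                  max(abs(closed$P - closed$P[length(closed$P)])), 1e-8)
    }
  }
})

test_that("numeric chamber pressure difference converges with grid refinement", {
  temperature <- 300
  pot <- std_gaussian(10, temperature)
  target <- R_gas * temperature * 100 * (1 - exp(-10))
  errs <- sapply(c(2001, 8001), function(n) {
    prof <- numeric_ode_solution(pot, 100, 0, temperature,
                                 grid = spatial_grid(pot$h, n = n))
    abs(chamber_pressure_difference(prof) - target) / target
  })
  expect_lt(errs[2], 1e-8)
  expect_lte(errs[2], errs[1] + 1e-12)
})
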