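test_that("pump-leak derivatives vanish at the known fixed points", {
  # balanced cell, no impermeant: nothing moves
  par <- donnan_params(k = 0.05, A_e = 300, lam = 1e-16)
  d <- donnan_rhs(donnan_state(w = 1e-15, A_in = 300), par)
  expect_equal(unname(d), c(0, 0))

  # impermeant load without compensation: always swelling
  par_b <- donnan_params(k = 0.05, A_e = 300, b = 3e-14, lam = 1e-16)
  d_b <- donnan_rhs(donnan_state(w = 1e-15, A_in = 300), par_b)
  expect_equal(d_b[["dA_in"]], 0)
  expect_equal(d_b[["dw"]], 1e-16 * 3e-14 / 1e-15)
  expect_gt(d_b[["dw"]], 0)

  # pump fixed point: A_in = A_e - p/k and b/w = p/k
  k <- 0.05; p <- 0.5; b <- 3e-14
  par_p <- donnan_params(k = k, A_e = 300, b = b, p = p, lam = 1e-16)
  st <- donnan_state(w = b / (p / k), A_in = 300 - p / k)
  d_p <- donnan_rhs(st, par_p)
  expect_equal(unname(d_p), c(0, 0), tolerance = 1e-12)
})

test_that("permeant kinetics relax exponentially at rate k", {
  # rigid cell (lam = 0) isolates the exchange kinetics
  par <- donnan_params(k = 0.05, A_e = 300, lam = 0)
  out <- simulate_donnan(donnan_state(w = 1e-15, A_in = 120), par,
                         t_end = 200, n_out = 101)
  expect_equal(out$A_in, donnan_A_closed(out$t, 120, 300, 0.05),
               tolerance = 1e-6)
  expect_equal(out$w, rep(1e-15, nrow(out)), tolerance = 1e-9)

  # balanced pliant cell: volume stays put because nothing is out of balance
  par_bal <- donnan_params(k = 0.05, A_e = 300, lam = 1e-16)
  out_bal <- simulate_donnan(donnan_state(w = 1e-15, A_in = 300), par_bal,
                             t_end = 200, n_out = 51)
  expect_equal(out_bal$w, rep(1e-15, nrow(out_bal)), tolerance = 1e-9)

  # with a pump the plateau shifts to A_e - p/k
  par_p <- donnan_params(k = 0.05, A_e = 300, b = 3e-14, p = 0.5, lam = 1e-16)
  out_p <- simulate_donnan(donnan_state(w = 1e-15, A_in = 300), par_p,
                           t_end = 400, n_out = 101)
  expect_equal(out_p$A_in, donnan_A_closed(out_p$t, 300, 300, 0.05, p = 0.5),
               tolerance = 1e-6)
})

test_that("an uncompensated impermeant load swells the cell without bound", {
  par <- donnan_params(k = 0.05, A_e = 300, b = 3e-14, lam = 1e-16)
  out <- simulate_donnan(donnan_state(w = 1e-15, A_in = 300), par,
                         t_end = 1e4, n_out = 400)
  expect_gt(out$w[nrow(out)], 10 * out$w[1])
  # monotone growth once the permeant has equilibrated
  late <- out$t > 5 / par$k
  expect_true(all(diff(out$w[late]) > 0))
  # and the osmotic imbalance b/w decays but never reverses
  expect_true(all(out$osm_in[late] > out$osm_out[late]))
})

test_that("external impermeant and pumping stabilize the volume at the fixed point", {
  k <- 0.05; b <- 3e-14
  # external impermeant: w* = b / B_e
  par_e <- donnan_params(k = k, A_e = 300, b = b, B_e = 20, lam = 1e-16)
  out_e <- simulate_donnan(donnan_state(w = 1e-15, A_in = 300), par_e,
                           t_end = 50 / k, n_out = 200)
  expect_equal(out_e$w[nrow(out_e)], b / 20, tolerance = 1e-3)

  # pump: w* = b k / p, checked at t_end = 50/k per the relaxation scale
  p <- 0.5
  par_p <- donnan_params(k = k, A_e = 300, b = b, p = p, lam = 1e-16)
  out_p <- simulate_donnan(donnan_state(w = 1e-15, A_in = 300), par_p,
                           t_end = 50 / k, n_out = 200)
  expect_equal(out_p$w[nrow(out_p)], b * k / p, tolerance = 1e-3)
})

test_that("regime classification matches the fixed-point algebra", {
  expect_identical(as.character(classify_regime(
    donnan_params(k = 0.05, A_e = 300, lam = 1e-16))), "stable")
  r_sw <- classify_regime(donnan_params(k = 0.05, A_e = 300, b = 3e-14,
                                        lam = 1e-16))
  expect_identical(as.character(r_sw), "unbounded-swelling")
  expect_identical(attr(r_sw, "w_star"), Inf)

  r_e <- classify_regime(donnan_params(k = 0.05, A_e = 300, b = 3e-14,
                                       B_e = 20, lam = 1e-16))
  expect_identical(as.character(r_e), "externally-stabilized")
  expect_equal(attr(r_e, "w_star"), 3e-14 / 20)

  # pump-stabilized, including the printed worked example b = 1e-12, p/k = 10
  r_p <- classify_regime(donnan_params(k = 1, A_e = 300, b = 1e-12, p = 10,
                                       lam = 1e-16))
  expect_identical(as.character(r_p), "pump-stabilized")
  expect_equal(attr(r_p, "w_star"), 1e-13)

  # both defences present: combined fixed point b / (B_e + p/k)
  r_both <- classify_regime(donnan_params(k = 0.05, A_e = 300, b = 3e-14,
                                          B_e = 20, p = 0.5, lam = 1e-16))
  expect_identical(as.character(r_both), "pump-stabilized")
  expect_equal(attr(r_both, "w_star"), 3e-14 / (20 + 10))
})

test_that("classification predicts long-horizon simulation outcomes", {
  set.seed(31)
  for (i in 1:8) {
    k <- stats::runif(1, 0.02, 0.2)
    b <- 10^stats::runif(1, -14.5, -13)
    B_e <- sample(c(0, stats::runif(1, 5, 50)), 1)
    p <- sample(c(0, stats::runif(1, 0.1, 1)), 1)
    par <- donnan_params(k = k, A_e = 300, b = b, B_e = B_e, p = p, lam = 1e-16)
    regime <- classify_regime(par)
    out <- simulate_donnan(donnan_state(w = 3e-16, A_in = 300), par,
                           t_end = 100 / k, n_out = 300)
    w_end <- out$w[nrow(out)]
    if (as.character(regime) == "unbounded-swelling") {
      expect_gt(w_end, out$w[1])
      expect_true(all(diff(out$w[out$t > 5 / k]) > 0))
    } else {
      expect_equal(w_end, attr(regime, "w_star"), tolerance = 5e-2)
    }
  }
})

test_that("rescaling the osmotic coupling rescales time but not the regime", {
  base <- donnan_params(k = 0.05, A_e = 300, b = 3e-14, lam = 1e-19)
  fast <- donnan_params(k = 0.05, A_e = 300, b = 3e-14, lam = 4e-19)
  expect_identical(as.character(classify_regime(base)),
                   as.character(classify_regime(fast)))
  t_thresh <- function(par) {
    out <- simulate_donnan(donnan_state(w = 1e-15, A_in = 300), par,
                           t_end = 4e3, n_out = 8001)
    min(out$t[out$w > 3e-15])
  }
  # after the (lam-independent) permeant relaxation, swelling follows
  # w dw/dt = lam b: time-to-threshold shrinks roughly with 1/lam
  t1 <- t_thresh(base); t2 <- t_thresh(fast)
  expect_lt(t2, t1)
  expect_equal(t1 / t2, 4, tolerance = 0.25)
})

test_that("nonphysical volumes are rejected", {
  expect_error(donnan_state(w = 0, A_in = 10), "> 0")
  expect_error(donnan_params(k = -1, A_e = 10), ">= 0")
})
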