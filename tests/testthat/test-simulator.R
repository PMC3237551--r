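tg8h <- seq(0, hours(8), by = hours(0.5))

test_that("ODE oracle agrees with the closed form on the standard grid", {
  for (k in c(1e-5, 1e-4, 1e-3)) {
    traj <- simulate_exchange(equivalent_protocol(), default_rates(k), tg8h)
    dev <- max(abs(extract_R(traj)$R - exchange_ratio(k, tg8h)))
    expect_lt(dev, 1e-6)
  }
})

test_that("exchange curve is independent of k_on over four orders", {
  for (kon in c(1e4, 1e6, 1e8)) {
    traj <- simulate_exchange(equivalent_protocol(),
                              rate_constants(kon, 1e-4), tg8h)
    expect_lt(max(abs(extract_R(traj)$R - exchange_ratio(1e-4, tg8h))), 1e-6)
  }
})

test_that("free subunits and tagged-complex total are conserved (equivalent lysates)", {
  traj <- simulate_exchange(equivalent_protocol(), default_rates(1e-4), tg8h)
  for (s in c("A_TU", "B_U", "A_L", "B_L")) {
    x <- traj$conc[, s]
    expect_lt(max(abs(x - x[1])) / x[1], 1e-6)
  }
  tot <- traj$conc[, "A_TU_B_U"] + traj$conc[, "A_TU_B_L"]
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
})

test_that("proposition report passes on long equivalent-lysate runs and is gated on horizon", {
  k <- 1e-3
  traj <- simulate_exchange(equivalent_protocol(), default_rates(k),
                            seq(0, 14 / k, length.out = 30))
  rep <- verify_propositions(traj, tol = 1e-5)
  expect_true(rep$free_subunits$pass)
  expect_true(rep$tagged_complex_total$pass)
  expect_identical(rep$equilibrium_ratio$status, "checked")
  expect_true(rep$equilibrium_ratio$pass)

  # truncated before 5/k_off: equilibrium reported not-yet-reached, not failed
  short <- simulate_exchange(equivalent_protocol(), default_rates(k),
                             seq(0, 0.5 / k, length.out = 10))
  rep_s <- verify_propositions(short)
  expect_identical(rep_s$equilibrium_ratio$status, "not_reached")
  expect_true(is.na(rep_s$equilibrium_ratio$pass))
})

test_that("unequal B totals break the constant-free-pool premise (negative control)", {
  proto <- mixing_protocol(lysate(1, 1, "unlabeled_tagged"),
                           lysate(1, 2, "labeled_untagged"))
  k <- 1e-3
  traj <- simulate_exchange(proto, default_rates(k),
                            seq(0, 14 / k, length.out = 30))
  rep <- verify_propositions(traj, tol = 1e-5)
  expect_false(rep$free_subunits$pass)
  expect_gt(rep$free_subunits$max_rel_dev, 0.01)
  # and the exchange no longer saturates at parity
  Rfin <- extract_R(traj)$R[30]
  expect_gt(abs(Rfin - 1), 0.01)
})

test_that("dilution of both lysates cancels out of the exchange curve", {
  k <- 1e-4
  base <- extract_R(simulate_exchange(equivalent_protocol(1, 1),
                                      default_rates(k), tg8h))$R
  half <- extract_R(simulate_exchange(equivalent_protocol(0.5, 0.5),
                                      default_rates(k), tg8h))$R
  expect_equal(half, base, tolerance = 1e-7)
})

test_that("the model is tag-symmetric: tracking tagged B gives the same curve", {
  # relabeling swaps the roles of A and B; with the tag on B the analog of
  # R is [A_L_B_U]/[A_TU_B_U] read from the same 8-species system with
  # subunit roles exchanged, which by symmetry equals the A-tagged curve
  k <- 1e-4
  traj <- simulate_exchange(equivalent_protocol(), default_rates(k), tg8h)
  R_tagA <- traj$conc[, "A_TU_B_L"] / traj$conc[, "A_TU_B_U"]
  R_tagB <- traj$conc[, "A_L_B_U"] / traj$conc[, "A_TU_B_U"]
  expect_equal(R_tagB, R_tagA, tolerance = 1e-8)
})

test_that("solution is invariant to a 10x tolerance tightening", {
  k <- 1e-4
  a <- simulate_exchange(equivalent_protocol(), default_rates(k), tg8h,
                         rtol = 1e-9, atol = 1e-12)
  b <- simulate_exchange(equivalent_protocol(), default_rates(k), tg8h,
                         rtol = 1e-10, atol = 1e-13)
  expect_equal(a$conc, b$conc, tolerance = 1e-8)
})

test_that("trajectory containers validate their contracts", {
  expect_error(simulate_exchange(equivalent_protocol(), default_rates(),
                                 c(100, 200)), "start at 0")
  expect_error(simulate_exchange(equivalent_protocol(), default_rates(),
                                 c(0, 100, 100)), "increase strictly")
  traj <- simulate_exchange(equivalent_protocol(), default_rates(1e-4),
                            c(0, 600, 1200))
  df <- as.data.frame(traj)
  expect_named(df, c("t_seconds", "species", "concentration"))
  expect_equal(nrow(df), 3 * 8)
  # R starts at exactly 0: no hybrid complex exists at mixing
  expect_identical(extract_R(traj)$R[1], 0)
})

test_that("unequilibrated lysates start fully bound and still exchange", {
  proto <- equivalent_protocol(equilibrate = FALSE)
  st <- simulate_exchange(proto, default_rates(1e-4), c(0, 3600))
  expect_equal(unname(st$conc[1, "A_TU_B_U"]), 0.5)
  expect_equal(unname(st$conc[1, "A_TU"]), 0)
  expect_gt(st$conc[2, "A_TU_B_L"], 0)
})
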