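# Adhesion law and conservative advection-deposition on the network.

test_that("formulation invariants hold", {
  f <- np_formulation(d = 600e-9, alpha_neo = 1e10)
  expect_equal(f$alpha_pre, 1e8)
  expect_equal(f$delta1, 0.45)
  expect_error(np_formulation(d = -1), "d must be")
  expect_error(np_formulation(alpha_neo = -5), "alpha_neo")
})

test_that("adhesion fraction matches an independent evaluation of the law", {
  seg <- data.frame(surface = 2 * pi * 1e-5 * 2e-5, shear = 300,
                    origin = "neovessel")
  f <- np_formulation(d = 1e-7, alpha_neo = 1e12, beta = 1e-4, gamma = 1e4)
  got <- as.numeric(adhesion_fraction(f, seg))
  # independent arrangement, computed in log space
  expected <- exp(log(seg$surface) + log(1e12) + 0.45 * log(1e-7)
                  - 1e-4 * (1 + 1e4 * exp(1.57 * log(1e-7))) * 300)
  expect_equal(got, expected, tolerance = 1e-12)
  # alpha = 0 -> 0; infinite shear -> 0; preexisting uses alpha/100
  expect_equal(as.numeric(adhesion_fraction(np_formulation(alpha_neo = 0), seg)), 0)
  seg_hi <- seg; seg_hi$shear <- 1e12
  expect_equal(as.numeric(adhesion_fraction(f, seg_hi)), 0)
  seg_pre <- seg; seg_pre$origin <- "preexisting"
  expect_equal(as.numeric(adhesion_fraction(f, seg_pre)) / got, 0.01,
               tolerance = 1e-9)
  # clamp to [0, 1] with counter
  f_big <- np_formulation(d = 1e-6, alpha_neo = 1e15)
  a <- adhesion_fraction(f_big, seg)
  expect_equal(as.numeric(a), 1)
  expect_equal(attr(a, "clamped"), 1L)
})

test_that("pure advection washes in to the inlet concentration", {
  net <- solve_flow(make_toy_network("single_segment"), 100, 0)
  f0 <- np_formulation(alpha_neo = 0)       # no adhesion
  st <- np_state(net)
  for (k in 1:200) st <- advect_deposit_step(st, net, f0, dt = 1, c_in = 1)
  expect_equal(st$C_p[2], 1, tolerance = 1e-6)
  expect_equal(max(st$C_pS), 0)
})

test_that("full capture on the first segment starves the chain downstream", {
  # 3-node chain with capture 1 on segment 1
  nodes <- data.frame(id = 1:3, x = c(0, 1, 2), y = 0,
                      is_inlet = c(TRUE, FALSE, FALSE),
                      is_outlet = c(FALSE, FALSE, TRUE))
  segs <- data.frame(id = 1:2, from = 1:2, to = 2:3, radius = 1e-5,
                     length = 1e-3, origin = c("neovessel", "neovessel"))
  net <- solve_flow(vessel_network(nodes, segs), 100, 0)
  cap <- c(1, 0.5)
  op <- nanovasc:::.np_operator(net, cap, dt = 1)
  st <- np_state(net)
  for (k in 1:50) st <- advect_deposit_step(st, net, NULL, dt = 1, c_in = 1, op = op)
  expect_equal(st$C_p[2], 0, tolerance = 1e-12)
  expect_equal(st$C_p[3], 0, tolerance = 1e-12)
  expect_gt(st$C_pS[1], 0)
  expect_equal(st$C_pS[2], 0, tolerance = 1e-15)
})

test_that("two-segment deposition matches the hand-iterated recurrence", {
  nodes <- data.frame(id = 1:3, x = c(0, 1, 2), y = 0,
                      is_inlet = c(TRUE, FALSE, FALSE),
                      is_outlet = c(FALSE, FALSE, TRUE))
  segs <- data.frame(id = 1:2, from = 1:2, to = 2:3, radius = 1e-5,
                     length = 1e-3, origin = "neovessel")
  net <- solve_flow(vessel_network(nodes, segs), 100, 0)
  q <- net$segments$flow[1]
  f <- 0.3
  dt <- 0.05
  op <- nanovasc:::.np_operator(net, c(f, f), dt = dt)
  st <- np_state(net)
  for (k in 1:600) st <- advect_deposit_step(st, net, NULL, dt, 1, op)
  M1 <- bound_count(st, net)                # past the washin transient
  for (k in 1:400) st <- advect_deposit_step(st, net, NULL, dt, 1, op)
  rate <- (bound_count(st, net) - M1) / (400 * dt)
  # hand recurrence (small-dt limit): steady node concentration after the
  # first segment is (1 - f); deposition rates q*c0*f and q*(1-f)*f
  expect_equal(rate[1], q * 1 * f, tolerance = 0.01)
  expect_equal(rate[2], q * (1 - f) * f, tolerance = 0.01)
})

test_that("global NP balance holds to 1e-6 on a looped network", {
  net <- solved_grid3x3()
  f <- np_formulation(d = 600e-9, alpha_neo = 5e9)
  st <- run_injection(net, f, duration_s = 400, dt = 20)
  expect_lt(attr(st, "max_balance_error"), 1e-6)
  expect_true(all(st$C_p >= 0) && all(st$C_pS >= 0))
  # injected mass = escaped + bound + residual free (washout complete)
  expect_equal(st$injected, st$escaped + sum(bound_count(st, net)),
               tolerance = 1e-6)
})

test_that("raising shear lowers adhesion and total bound count", {
  net <- solved_grid3x3()
  f <- np_formulation(d = 600e-9, alpha_neo = 5e9)
  net_hi <- net
  net_hi$segments$shear <- net$segments$shear * 10
  a_lo <- adhesion_fraction(f, net)
  a_hi <- adhesion_fraction(f, net_hi)
  expect_true(all(a_hi <= a_lo + 1e-15))
  b_lo <- sum(bound_count(run_injection(net, f, 400, 20), net))
  b_hi <- sum(bound_count(run_injection(net_hi, f, 400, 20), net_hi))
  expect_lt(b_hi, b_lo)
})

test_that("zero-duration injection binds nothing; low-capture response is linear", {
  net <- solved_grid3x3()
  f <- np_formulation(d = 100e-9, alpha_neo = 1e8)
  st0 <- run_injection(net, f, duration_s = 0)
  expect_equal(sum(st0$C_pS), 0)
  # doubling alpha doubles the bound count before saturation/depletion
  b1 <- sum(bound_count(run_injection(net, f, 400, 20), net))
  f2 <- np_formulation(d = 100e-9, alpha_neo = 2e8)
  b2 <- sum(bound_count(run_injection(net, f2, 400, 20), net))
  expect_equal(b2 / b1, 2, tolerance = 0.02)
})

test_that("high affinity shifts bound mass towards the inflow side", {
  net <- solved_grid3x3()
  hi <- np_summary(run_injection(net, np_formulation(d = 1000e-9, alpha_neo = 1e12),
                                 400, 20), net)
  lo <- np_summary(run_injection(net, np_formulation(d = 1000e-9, alpha_neo = 1e8),
                                 400, 20), net)
  expect_lt(hi$com_x, lo$com_x)
})
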