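# Payload, sqrt(d) release kinetics and drug reaction-diffusion.

test_that("full-release durations follow the sqrt(d) calibration", {
  dp <- drug_params()
  expect_equal(release_duration_h(100e-9, dp), 12)
  expect_equal(release_duration_h(1000e-9, dp), 12 * sqrt(10))  # ~37.9 h
  expect_equal(release_duration_h(600e-9, dp), 12 * sqrt(6))    # ~29.4 h
  # sqrt scaling holds across arbitrary diameter sets
  d <- c(50, 130, 420, 990) * 1e-9
  expect_equal(release_duration_h(d, dp) / release_duration_h(100e-9, dp),
               sqrt(d / 100e-9))
})

test_that("payload initializes proportional to diameter and releases linearly", {
  g <- test_grid(32)
  net <- solve_flow(make_toy_network("single_segment"), 100, 0)
  f <- np_formulation(d = 400e-9, alpha_neo = 1e10)
  np <- run_injection(net, f, duration_s = 400, dt = 20)
  dp <- drug_params()
  pl <- payload_state(np, net, f, dp, g)
  M <- bound_count(np, net)
  expect_equal(pl$df$initial, M * 4)                       # d / d_ref = 4
  tau_day <- release_duration_h(400e-9, dp) / 24
  expect_equal(pl$df$rate, pl$df$initial / tau_day)
  # constant rate until exhaustion, then exactly the remainder
  rs <- release_source(pl, dt = 0.01)
  expect_equal(rs$released, pl$df$rate * 0.01)
  pl2 <- pl; pl2$df$remaining <- pl$df$rate * 0.004        # less than one step
  rs2 <- release_source(pl2, dt = 0.01)
  expect_equal(rs2$released, pl2$df$remaining)
  pl3 <- consume_payload(pl2, rs2$released)
  expect_equal(pl3$df$remaining, 0 * pl3$df$remaining)
  expect_equal(sum(release_source(pl3, 0.01)$released), 0) # exhausted -> 0
})

test_that("drug halves every 6 h without release or diffusion", {
  g <- test_grid(16)
  dp <- drug_params(half_life_h = 6)
  dt <- 0.25 / 500                                         # fine step
  stepper <- make_diffusion_stepper(g, 0, dp$lambda_decay, dt)
  G <- matrix(1, g$n, g$n)
  zero <- matrix(0, g$n, g$n)
  for (k in 1:500) G <- stepper(G, zero)                   # 6 hours
  expect_equal(mean(G), 0.5, tolerance = 1e-3)
})

test_that("drug mass balance: change equals released minus decayed", {
  g <- test_grid(32)
  net <- solve_flow(make_toy_network("grid3x3"), 100, 0)
  f <- np_formulation(d = 600e-9, alpha_neo = 1e10)
  np <- run_injection(net, f, 400, 20)
  dp <- drug_params()
  # rescale toy coordinates (1 mm) onto the 2 mm grid: fine as-is
  pl <- payload_state(np, net, f, dp, g)
  G <- matrix(0, g$n, g$n)
  dt <- 0.02
  for (k in 1:50) {
    G_before <- sum(G)
    rel_before <- sum(pl$df$remaining)
    st <- step_drug(G, pl, dp, dt, g)
    released <- rel_before - sum(st$payload$df$remaining)
    decayed <- dp$lambda_decay * sum(st$G) * dt
    dG <- sum(st$G) - G_before
    expect_lt(abs(dG - (released / g$h^2 - decayed)),
              1e-6 * max(released / g$h^2, 1e-300))
    G <- st$G; pl <- st$payload
  }
  expect_true(all(G >= 0))
})

test_that("single-source exposure rises to a kink at exhaustion then decays", {
  g <- test_grid(32)
  # hand-built payload: one segment, one cell, no diffusion
  net <- solve_flow(make_toy_network("single_segment"), 100, 0)
  f <- np_formulation(d = 100e-9)
  np <- np_state(net)
  np$C_pS <- 1e-3
  dp <- drug_params(D_G = 1, D_ref = 0, half_life_h = 6)   # no diffusion
  pl <- payload_state(np, net, f, dp, g)
  tau_day <- 0.5                                           # 12 h
  tumor <- matrix(TRUE, g$n, g$n)
  dt <- 0.01
  tot <- numeric(100)
  for (k in 1:100) {
    st <- step_drug(if (k == 1) matrix(0, g$n, g$n) else st$G, pl, dp, dt, g)
    pl <- st$payload
    tot[k] <- tumor_drug_exposure(st$G, tumor, g)$total
  }
  peak <- which.max(tot)
  expect_equal(peak * dt, tau_day, tolerance = dt / tau_day + 0.04)
  expect_true(all(diff(tot[1:(peak - 1)]) > 0))            # monotone rise
  expect_true(all(diff(tot[(peak + 1):100]) < 0))          # decay after kink
  # closed-form check at the peak: s/l * (1 - e^{-l tau}) per unit area
  s_rate <- sum(pl$df$initial) / tau_day
  expect_equal(max(tot),
               s_rate / dp$lambda_decay * (1 - exp(-dp$lambda_decay * tau_day)),
               tolerance = 0.05)
  expect_error(tumor_drug_exposure(st$G, matrix(FALSE, g$n, g$n), g), "empty")
})

test_that("more diffusive drug lowers peak tumor exposure from interior sources", {
  g <- test_grid(48)
  net <- solve_flow(make_toy_network("single_segment"), 100, 0)
  f <- np_formulation(d = 100e-9)
  np <- np_state(net); np$C_pS <- 1e-3
  tumor <- matrix(FALSE, g$n, g$n)
  tumor[11:15, 1:5] <- TRUE                   # small tumor around the source cell
  peak_for <- function(dg) {
    dp <- drug_params(D_G = dg, D_ref = 4)
    pl <- payload_state(np, net, f, dp, g)
    G <- matrix(0, g$n, g$n)
    stepper <- make_diffusion_stepper(g, dp$D_G * dp$D_ref, dp$lambda_decay, 0.02)
    best <- 0
    for (k in 1:40) {
      st <- step_drug(G, pl, dp, 0.02, g, stepper)
      G <- st$G; pl <- st$payload
      best <- max(best, tumor_drug_exposure(G, tumor, g)$total)
    }
    best
  }
  expect_gt(peak_for(0.022), peak_for(1))
})
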