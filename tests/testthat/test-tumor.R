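# Region classification, net proliferation, Darcy pressure/velocity and
# level-set interface dynamics.

test_that("region classification follows the oxygen thresholds", {
  g <- test_grid(48)
  st <- make_toy_tumor(0.6, g)
  gp <- growth_params(sigma_H = 0.5, sigma_N = 0.3)
  st1 <- classify_regions(st, matrix(1, g$n, g$n), gp)
  expect_true(all(st1$masks$P == st1$masks$tumor))
  st0 <- classify_regions(st, matrix(0, g$n, g$n), gp)
  expect_true(all(st0$masks$N == st0$masks$tumor))
  expect_error(growth_params(sigma_H = 0.3, sigma_N = 0.5), "thresholds")
})

test_that("radially decaying oxygen yields concentric P/H/N annuli", {
  g <- grid_spec(96)
  st <- make_toy_tumor(0.9, g)
  xc <- cell_centers(g)
  r <- sqrt(outer((xc - 1)^2, rep(1, g$n)) + outer(rep(1, g$n), (xc - 1)^2))
  sigma <- pmin(pmax(1 - r, 0), 1)          # sigma = 1 - r (mm)
  gp <- growth_params(sigma_H = 0.5, sigma_N = 0.3)
  st <- classify_regions(st, sigma, gp)
  # crossing radii: sigma >= 0.5 at r <= 0.5; sigma < 0.3 at r > 0.7
  h2 <- g$h^2
  expect_equal(sum(st$masks$P) * h2, pi * 0.5^2, tolerance = 0.05)
  expect_equal(sum(st$masks$H) * h2, pi * (0.7^2 - 0.5^2), tolerance = 0.05)
  expect_equal(sum(st$masks$N) * h2, pi * (0.9^2 - 0.7^2), tolerance = 0.05)
  # partition invariant
  expect_true(all((st$masks$P | st$masks$H | st$masks$N) == st$masks$tumor))
  expect_equal(sum(st$masks$P & st$masks$H), 0)
})

test_that("net proliferation follows the piecewise drug-modulated law", {
  g <- test_grid(32)
  st <- make_toy_tumor(0.5, g)
  gp <- growth_params(lambda_M = 1.2, lambda_A = 0.3, lambda_N = 0.4,
                      lambda_effect = 2)
  st <- classify_regions(st, matrix(1, g$n, g$n), gp)     # all proliferating
  # no drug: lambda_M * sigma - lambda_A
  lp <- net_proliferation(st, 1, 0, gp)
  expect_equal(lp[st$masks$P], rep(1.2 - 0.3, sum(st$masks$P)))
  expect_equal(lp[!st$masks$tumor], rep(0, sum(!st$masks$tumor)))
  # lambda_effect * G = 1 suppresses proliferation entirely
  lp1 <- net_proliferation(st, 1, matrix(0.5, g$n, g$n), gp)
  expect_equal(unique(lp1[st$masks$P]), -0.3)
  # hypoxic cells ignore the drug; necrotic lose volume
  stn <- classify_regions(st, matrix(0.4, g$n, g$n), gp)  # all hypoxic
  expect_equal(unique(net_proliferation(stn, 0.4, 99, gp)[stn$masks$H]), 0)
  stn <- classify_regions(st, matrix(0.1, g$n, g$n), gp)  # all necrotic
  expect_equal(unique(net_proliferation(stn, 0.1, 99, gp)[stn$masks$N]), -0.4)
})

test_that("Darcy velocity of a uniformly proliferating disc is radial r*g/2", {
  g <- grid_spec(96)
  st <- make_toy_tumor(0.5, g)
  gp <- growth_params()
  gr <- 0.4
  lp <- matrix(0, g$n, g$n); lp[st$masks$tumor] <- gr
  st <- solve_pressure_velocity(st, lp, gp)
  xc <- cell_centers(g)
  sp <- sqrt(st$vx^2 + st$vy^2)
  for (r_test in c(0.15, 0.3, 0.45)) {
    i <- which.min(abs(xc - (1 + r_test)))
    j <- which.min(abs(xc - 1))
    expect_equal(sp[i, j], gr * r_test / 2, tolerance = 0.1)
  }
  # zero source -> zero velocity
  st0 <- solve_pressure_velocity(make_toy_tumor(0.5, g), matrix(0, g$n, g$n), gp)
  expect_lt(max(abs(st0$vx), abs(st0$vy)), 1e-10)
  # mirror symmetry: symmetric tumor and source give antisymmetric vx
  expect_equal(st$vx, -st$vx[g$n:1, ], tolerance = 1e-8)
})

test_that("interface advection conserves area at zero velocity", {
  g <- test_grid(64)
  st <- make_toy_tumor(0.4, g)
  gp <- growth_params()
  A0 <- tumor_area(st)
  lp0 <- matrix(0, g$n, g$n)
  for (k in 1:100) {
    st <- solve_pressure_velocity(st, lp0, gp)
    st <- advance_interface(st, 0.05)
  }
  expect_equal(tumor_area(st), A0, tolerance = 0.025)
})

test_that("uniform proliferation gives exponential area growth within 5%", {
  g <- grid_spec(96)
  st <- make_toy_tumor(0.3, g)
  gp <- growth_params()
  gr <- 0.3
  days <- log(2) / gr                       # one doubling
  dt <- 0.02
  A0 <- tumor_area(st)
  for (k in seq_len(round(days / dt))) {
    lp <- matrix(0, g$n, g$n); lp[st$masks$tumor] <- gr
    st$masks$P <- st$masks$tumor
    st <- solve_pressure_velocity(st, lp, gp)
    st <- advance_interface(st, dt, reinit = (k %% 5 == 0))
    st$masks$tumor <- st$phi < 0
  }
  expect_equal(tumor_area(st), A0 * exp(gr * days), tolerance = 0.05)
})

test_that("uniform volume loss shrinks the tumor monotonically to extinction", {
  g <- test_grid(64)
  st <- make_toy_tumor(0.2, g)
  gp <- growth_params()
  areas <- tumor_area(st)
  for (k in 1:300) {
    lp <- matrix(0, g$n, g$n); lp[st$masks$tumor] <- -1.5
    st <- solve_pressure_velocity(st, lp, gp)
    st <- advance_interface(st, 0.05)
    st$masks$tumor <- st$phi < 0
    areas <- c(areas, tumor_area(st))
    if (tail(areas, 1) < 1e-5) break
  }
  expect_true(all(diff(areas) < 1e-4))      # monotone shrinkage
  expect_lt(tail(areas, 1), 1e-4)           # vanishes in finite time
})

test_that("CFL guard rejects absurd velocities", {
  g <- test_grid(32)
  st <- make_toy_tumor(0.4, g)
  st$vx <- matrix(1e6, g$n, g$n); st$vy <- matrix(0, g$n, g$n)
  expect_error(advance_interface(st, 1), "CFL")
  expect_error(advance_interface(st, -1), "dt")
})
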