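# TAF dynamics, sprout-tip walk probabilities, anastomosis and perfusion.

test_that("TAF decays to zero without hypoxic tissue and stays bounded", {
  g <- test_grid(32)
  par <- angio_params()
  taf <- matrix(0.5, g$n, g$n)
  none <- matrix(FALSE, g$n, g$n)
  for (k in 1:60) taf <- update_taf(taf, none, par, 0.1, g)
  expect_lt(max(taf), 0.5 * exp(-par$lambda_taf * 3))
  # with a hypoxic disc, TAF is bounded by s/lambda and peaks inside it
  st <- make_toy_tumor(0.3, g)
  hyp <- st$masks$tumor
  taf <- matrix(0, g$n, g$n)
  for (k in 1:200) taf <- update_taf(taf, hyp, par, 0.05, g)
  expect_lte(max(taf), par$s_taf / par$lambda_taf + 1e-9)
  expect_true(which.max(taf) %in% which(hyp))
  # radially decreasing outside the disc (sample along the midline)
  mid <- g$n / 2
  prof <- taf[(mid + 6):g$n, mid]
  expect_true(all(diff(prof) < 1e-12))
})

test_that("steady TAF front decays with length sqrt(D/lambda)", {
  g <- grid_spec(128)
  par <- angio_params(D_taf = 0.8, lambda_taf = 20)   # ell = 0.2 mm
  hyp <- matrix(FALSE, g$n, g$n); hyp[1:32, ] <- TRUE # hypoxic half-plane
  taf <- matrix(0, g$n, g$n)
  for (k in 1:400) taf <- update_taf(taf, hyp, par, 0.05, g)
  prof <- rowMeans(taf)
  sel <- 45:90
  fit <- stats::lm(log(prof[sel]) ~ sel)
  ell <- -1 / stats::coef(fit)[2] * g$h
  expect_equal(unname(ell), sqrt(par$D_taf / par$lambda_taf), tolerance = 0.1)
})

test_that("tip move probabilities follow the discretized stencil weights", {
  par <- angio_params(D_tip = 1, chi_taf = 1, chi_ecm = 0)
  # no gradients: stay weight D, each neighbour D -> all equal
  expect_equal(sprout_move_probs(c(0, 0, 0, 0), params = par), rep(0.2, 5))
  # printed toy weights: chemotactic contributions +x: 2, -x: 0, +y/-y: 1
  # -> weights (stay, +x, -x, +y, -y) = (1, 3, 1, 2, 2), normalized by 9
  expect_equal(sprout_move_probs(c(2, 0, 1, 1), params = par),
               c(1, 3, 1, 2, 2) / 9)
  # strong +x gradient with vanishing motility: probability of +x -> 1
  par2 <- angio_params(D_tip = 1e-9, chi_taf = 1)
  p <- sprout_move_probs(c(5, -5, 0, 0), params = par2)
  expect_gt(p[2], 0.999)
  # all-zero weights: the tip stays
  par0 <- angio_params(D_tip = 0, chi_taf = 1)
  expect_equal(sprout_move_probs(c(-1, -1, -1, -1), params = par0),
               c(1, 0, 0, 0, 0))
})

test_that("sprouting is reproducible under a fixed seed", {
  run_once <- function(seed) {
    cfg <- default_config()
    cfg$grid$n_cells <- 64L
    cfg$tumor$seed_radius_mm <- 0.2
    cfg$seed <- seed
    sim <- sim_init(cfg)
    sim_grow(sim, 4)
    sim$net$segments[, c("from", "to", "origin")]
  }
  a <- run_once(11); b <- run_once(11)
  expect_identical(a, b)
})

test_that("dead-end sprouts carry no flow; anastomosed bridges do", {
  net <- make_toy_network("grid3x3")
  n0 <- nrow(net$nodes)
  # dangling chain off the middle horizontal line
  mid_node <- which(net$nodes$x == 0.25 & net$nodes$y == 0.5)
  net$nodes <- rbind(net$nodes,
    data.frame(id = n0 + 1:2, x = c(0.35, 0.55), y = c(0.65, 0.85),
               is_inlet = FALSE, is_outlet = FALSE, pressure = NA_real_))
  ns <- nrow(net$segments)
  tmpl <- net$segments[1, ]
  s1 <- tmpl; s1$id <- ns + 1; s1$from <- mid_node; s1$to <- n0 + 1
  s2 <- tmpl; s2$id <- ns + 2; s2$from <- n0 + 1; s2$to <- n0 + 2
  s1$origin <- s2$origin <- "neovessel"
  net$segments <- rbind(net$segments, s1, s2)
  solved <- perfuse_new_vessels(net, HD = 0.45)
  qmax <- max(abs(solved$segments$flow))
  dangling <- solved$segments$id %in% c(ns + 1, ns + 2)
  expect_lt(max(abs(solved$segments$flow[dangling])), 1e-10 * qmax)
  expect_lt(max(solved$segments$shear[dangling]),
            1e-10 * max(solved$segments$shear))
  # unperfused neovessels carry no hematocrit (no oxygen release)
  expect_equal(solved$segments$hematocrit[dangling], c(0, 0))
  # close the loop onto the top line at a different pressure station:
  # now it must carry flow
  n1 <- nrow(net$nodes)
  top_node <- which(net$nodes$x == 0.75 & net$nodes$y == 1)
  s3 <- tmpl; s3$id <- ns + 3; s3$from <- n1 - 0; s3$to <- top_node
  s3$origin <- "neovessel"
  net$segments <- rbind(net$segments, s3)
  solved2 <- perfuse_new_vessels(net, HD = 0.45)
  bridge <- solved2$segments$id %in% (ns + 1:3)
  expect_gt(min(abs(solved2$segments$flow[bridge])),
            1e-6 * max(abs(solved2$segments$flow)))
  expect_gt(min(solved2$segments$hematocrit[bridge]), 0)
  # the network remains flow-conservative after the anastomosis
  expect_lt(flow_conservation_residual(solved2), 1e-8)
})

test_that("neovessels only appear while hypoxic tissue exists", {
  cfg <- default_config()
  cfg$grid$n_cells <- 64L
  cfg$tumor$seed_radius_mm <- 0.05
  sim <- sim_init(cfg)
  sim_grow(sim, 2)      # far too small for hypoxia this early
  expect_equal(sum(sim$net$segments$origin == "neovessel"), 0)
})
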