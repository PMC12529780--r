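test_that("flat-bottom restraint energy has the stated piecewise form", {
  rp <- restraint_params(K = 100, dD_fb = 2, dD_h = 1)
  D0 <- 5
  expect_equal(restraint_energy(D0 + 1, D0, rp), 0)
  expect_equal(restraint_energy(D0 - 1.99, D0, rp), 0)
  # junction of harmonic and linear branches: 1/2 K dD_h^2
  expect_equal(restraint_energy(D0 + rp$dD_fb + rp$dD_h, D0, rp), 50)
  # linear branch slope K*dD_h
  expect_equal(restraint_energy(D0 + 10, D0, rp) - restraint_energy(D0 + 9, D0, rp),
               rp$K * rp$dD_h, tolerance = 1e-12)
  x <- seq(-8, 8, by = 0.37)
  expect_equal(restraint_energy(D0 + x, D0, rp), restraint_energy(D0 - x, D0, rp))
  expect_error(restraint_params(K = -1), "K")
})

test_that("restraint force is minus the energy derivative in all regimes", {
  rp <- restraint_params(K = 100, dD_fb = 2, dD_h = 1)
  D0 <- -3
  expect_equal(restraint_force_dD(D0 + 0.5, D0, rp), 0)
  expect_equal(restraint_force_dD(D0 + 100, D0, rp), -rp$K * rp$dD_h)
  expect_equal(restraint_force_dD(D0 - 100, D0, rp), rp$K * rp$dD_h)
  expect_equal(restraint_force_dD(D0 + 2.5, D0, rp), -100 * 0.5)
  # central finite differences, 100 points spread over all three regimes
  set.seed(1)
  x <- c(runif(40, -1.9, 1.9), runif(30, 2.05, 2.95), runif(30, 3.1, 20)) *
    sample(c(-1, 1), 100, replace = TRUE)
  eps <- 1e-5
  fd <- -(restraint_energy(D0 + x + eps, D0, rp) -
            restraint_energy(D0 + x - eps, D0, rp)) / (2 * eps)
  f <- restraint_force_dD(D0 + x, D0, rp)
  expect_equal(fd, f, tolerance = 1e-6)
  # continuity of energy and force at both junctions
  for (xj in c(2, 3, -2, -3)) {
    expect_equal(restraint_energy(D0 + xj - 1e-9, D0, rp),
                 restraint_energy(D0 + xj + 1e-9, D0, rp), tolerance = 1e-6)
    expect_equal(restraint_force_dD(D0 + xj - 1e-9, D0, rp),
                 restraint_force_dD(D0 + xj + 1e-9, D0, rp), tolerance = 1e-6)
  }
})

test_that("exponential-memory average: fixed point, long-memory limit, step response", {
  expect_equal(update_exp_average(0.3, 0.3, 0.002, 10), 0.3)
  # tau -> Inf: new samples get vanishing weight
  p <- 0.7
  for (i in 1:100) p <- update_exp_average(p, -0.5, 0.002, 1e12)
  expect_equal(p, 0.7, tolerance = 1e-9)
  # step signal 0 -> 1: Pbar_n = 1 - exp(-n dt / tau), the discretized
  # closed-form of the continuous exponential-memory integral
  dt <- 0.002; tau <- 0.1
  p <- 0
  for (n in 1:200) {
    p <- update_exp_average(p, 1, dt, tau)
    expect_equal(p, 1 - exp(-n * dt / tau), tolerance = 1e-12)
  }
  expect_error(update_exp_average(0, 0, 0.002, -1), "tau")
})

test_that("P2 gradient matches finite differences and is constraint-tangent", {
  set.seed(5)
  bond <- 0.153
  for (rep in 1:20) {
    u_rdc <- rnorm(3); u_rdc <- u_rdc / sqrt(sum(u_rdc^2))
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    r2 <- rnorm(3); r1 <- r2 + bond * d
    g <- p2_gradient(d, u_rdc, bond)
    p2_of <- function(r1v) {
      v <- r1v - r2
      legendre_p2(sum(v * u_rdc) / sqrt(sum(v * v)))
    }
    eps <- 1e-7
    fd <- sapply(1:3, function(i) {
      e <- rep(0, 3); e[i] <- eps
      (p2_of(r1 + e) - p2_of(r1 - e)) / (2 * eps)
    })
    expect_equal(g, fd, tolerance = 1e-6)
    expect_lt(abs(sum(g * d)), 1e-12)  # tangency to the rigid bond
  }
  # perpendicular orientation: zero gradient
  expect_equal(p2_gradient(c(0, 0, 1), c(1, 0, 0), bond), c(0, 0, 0))
})

test_that("mfv forces vanish in flat bottoms, balance, and stay in-plane", {
  h <- fixture_helix(8)
  st <- synth_targets(h, default_tensor(), classes = "N-HN")
  tg <- st$targets
  tg$restrained <- TRUE
  sim <- sim_params(n_steps = 1, n_runs = 1)
  set.seed(2)
  state <- init_mfv_state(sim)
  rp <- restraint_params()
  # averages exactly on target -> all in flat bottom -> zero force
  P_on_target <- tg$D0 / st$vectors$scale_Hz
  f0 <- mfv_force(state, st$vectors, tg, P_on_target, rp, sim$dt)
  expect_equal(f0$f1, c(0, 0, 0))
  # far-off averages: equal and opposite forces
  f <- mfv_force(state, st$vectors, tg, rep(0.8, nrow(tg)), rp, sim$dt)
  expect_equal(f$f1 + f$f2, c(0, 0, 0))
  expect_gt(sqrt(sum(f$f1^2)), 0)
  # single restraint: force in span(u_mfv, u_rdc)
  tg1 <- tg[1, , drop = FALSE]; v1 <- st$vectors[1, , drop = FALSE]
  class(tg1) <- class(tg); class(v1) <- class(st$vectors)
  fs <- mfv_force(state, v1, tg1, 0.8, rp, sim$dt)
  u_mfv <- (state$r1 - state$r2) / sqrt(sum((state$r1 - state$r2)^2))
  u_rdc <- as.numeric(v1[, c("ux", "uy", "uz")])
  nrm <- rdcalc:::pracma_cross(u_mfv, u_rdc)
  expect_lt(abs(sum(fs$f1 * nrm)) / sqrt(sum(fs$f1^2)), 1e-12)
})

test_that("compiled engine reproduces the R reference stepper", {
  h <- fixture_helix(8)
  st <- synth_targets(h, default_tensor(), classes = c("N-HN", "CA-HA"))
  tg <- select_restraint_set(st$targets, "NCAH160")
  for (renorm in c(TRUE, FALSE)) {
    sim <- sim_params(n_steps = 150, n_runs = 1, seed = 7)
    set.seed(sim$seed)
    ref <- rdcalc:::.hrs_run_r(st$vectors, tg, restraint_params(), sim,
                               n_steps = 150, renormalize = renorm)
    out <- run_hrs(st$vectors, tg, restraint_params(), sim,
                   traj_stride = 0, renormalize = renorm)
    expect_equal(out$P_mean, ref$P_mean, tolerance = 1e-12)
  }
})

test_that("seeded runs are exactly reproducible", {
  h <- fixture_helix(6)
  st <- synth_targets(h, default_tensor(), classes = "N-HN")
  tg <- select_restraint_set(st$targets, "NH101")
  sim <- sim_params(n_steps = 1000, n_runs = 2, seed = 99)
  a <- run_hrs(st$vectors, tg, restraint_params(), sim, traj_stride = 50)
  b <- run_hrs(st$vectors, tg, restraint_params(), sim, traj_stride = 50)
  expect_identical(a$D, b$D)
  expect_identical(a$traj, b$traj)
  # different seeds decorrelate the runs
  sim2 <- sim_params(n_steps = 1000, n_runs = 2, seed = 100)
  expect_false(identical(run_hrs(st$vectors, tg, restraint_params(), sim2,
                                 traj_stride = 0)$D, a$D))
})

test_that("force-free dynamics keep the bond rigid and equipartitioned", {
  kB <- rdc_constants()$kB
  set.seed(2)
  sd_v <- sqrt(kB * 308 / 15.035)
  d <- rdcalc:::mfv_free_diagnostics_cpp(0.002, 308, 2.4, 15.035, 0.153, 1e5,
                                         rnorm(3, 0, sd_v), rnorm(3, 0, sd_v))
  expect_lt(abs(d$min_bond - 0.153) / 0.153, 1e-4)
  expect_lt(abs(d$max_bond - 0.153) / 0.153, 1e-4)
  # 5 degrees of freedom (6 velocity components minus 1 bond constraint):
  # mean KE = 5/2 kBT; 3 sigma of the autocorrelation-corrected mean ~ 8%
  expect_lt(abs(d$mean_kinetic / (2.5 * kB * 308) - 1), 0.08)
})

test_that("force-free sampling is isotropic and averages stay bounded", {
  h <- fixture_helix(10)
  st <- synth_targets(h, default_tensor())
  tg <- select_restraint_set(st$targets, "NCAH160")
  out <- run_hrs(st$vectors, tg, restraint_params(K = 0),
                 sim_params(n_steps = 1e6, n_runs = 1, seed = 13),
                 traj_stride = 10)
  expect_lt(max(abs(out$P_mean)), 0.05)
  expect_true(all(out$P_mean >= -0.5 & out$P_mean <= 1))
  expect_true(all(abs(out$D) <= abs(out$vectors$scale_Hz)))
  # orientation histogram flat after 1/sin(theta) weighting (interior bins)
  td <- theta_distribution(out$traj, helix_axis_refs(h, list(c(2, 10))))
  inner <- td$mids > 10 & td$mids < 170
  expect_lt(max(td$density[inner, 1]) / min(td$density[inner, 1]), 1.5)
  expect_false(td$flag)
})

test_that("restraining pulls the reported averages toward the targets", {
  # scaled-down self-consistency: short memory, short runs; the full
  # study-parameter protocol is exercised in the acceptance tests
  h <- fixture_helix(10)
  st <- synth_targets(h, default_tensor(), classes = "N-HN")
  tg <- select_restraint_set(st$targets, "NH101")
  rp <- restraint_params(K = 100, tau_theta = 100)
  out <- run_hrs(st$vectors, tg, rp, sim_params(n_steps = 2e5, n_runs = 1, seed = 21),
                 traj_stride = 0)
  out0 <- run_hrs(st$vectors, tg, restraint_params(K = 0),
                  sim_params(n_steps = 2e5, n_runs = 1, seed = 21), traj_stride = 0)
  dev_r <- sqrt(mean((out$D - tg$D0)^2))
  dev_0 <- sqrt(mean((out0$D - tg$D0)^2))
  expect_lt(dev_r, dev_0 / 2)
})
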