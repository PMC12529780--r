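# HRS: magnetic-field rotational sampling. A rigid two-particle "magnetic-field
# vector" (mfv) is propagated by Langevin stochastic dynamics under flat-bottom
# RDC-restraining forces that act on exponentially-damped time averages of the
# orientation factor P2; reported couplings use the plain time average.

#' Flat-bottom RDC restraint parameters
#'
#' @param K Force constant, kJ mol^-1 Hz^-2 (default 100).
#' @param dD_fb Flat-bottom half-width, Hz (default 2): deviations
#'   `|Dbar - D0| <= dD_fb` are penalty-free.
#' @param dD_h Width of the harmonic band, Hz (default 1); beyond
#'   `dD_fb + dD_h` the restraint is linear (constant force `K * dD_h`).
#' @param tau_theta Memory relaxation time of the exponential average, ps
#'   (default 10000 ps = 10 ns).
#' @return List of class `restraint_params`.
#' @export
restraint_params <- function(K = 100, dD_fb = 2, dD_h = 1, tau_theta = 1e4) {
  stopifnot(K >= 0, dD_fb >= 0, dD_h > 0, tau_theta > 0)
  structure(list(K = K, dD_fb = dD_fb, dD_h = dD_h, tau_theta = tau_theta),
            class = "restraint_params")
}

#' Stochastic-dynamics parameters for the magnetic-field vector
#'
#' Defaults are the simulation conditions of the case study: 2 fs time step,
#' 308 K, friction 2.4 ps^-1 per particle, two united CH3 atoms of 15.035 u on
#' a rigid 0.153 nm bond, three runs of 5e6 steps (3 x 10 ns = 30 ns).
#'
#' @param dt Time step, ps. @param T Temperature, K.
#' @param gamma Friction coefficient, ps^-1.
#' @param n_steps Steps per run. @param n_runs Number of runs.
#' @param mass Particle mass, u. @param bond Rigid bond length, nm.
#' @param seed Base random seed; run j uses `seed + j - 1`.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(dt = 0.002, T = 308, gamma = 2.4, n_steps = 5e6,
                       n_runs = 3, mass = 15.035, bond = 0.153, seed = 1) {
  stopifnot(dt > 0, T > 0, gamma >= 0, n_steps >= 1, n_runs >= 1,
            mass > 0, bond > 0)
  structure(list(dt = dt, T = T, gamma = gamma, n_steps = as.integer(n_steps),
                 n_runs = as.integer(n_runs), mass = mass, bond = bond,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Flat-bottom restraint energy
#'
#' Zero inside the flat bottom, half-harmonic in a band of width `dD_h`,
#' linear beyond, continuous with continuous first derivative at both
#' junctions:
#' \deqn{V = 0,\; \tfrac12 K (|x| - \Delta^{fb})^2,\;
#'       K \Delta^h (|x| - \Delta^{fb} - \tfrac12\Delta^h)}
#' for `|x| = |Dbar - D0|` in the three regimes.
#'
#' @param D_bar Averaged coupling(s), Hz.
#' @param D0 Target coupling(s), Hz.
#' @param params A [restraint_params()] list.
#' @return Energy (kJ/mol), vectorized over the inputs.
#' @export
restraint_energy <- function(D_bar, D0, params) {
  x <- abs(D_bar - D0)
  fb <- params$dD_fb; h <- params$dD_h; K <- params$K
  ifelse(x <= fb, 0,
         ifelse(x <= fb + h, 0.5 * K * (x - fb)^2,
                K * h * (x - fb - 0.5 * h)))
}

#' Restraint force with respect to the averaged coupling
#'
#' Minus the derivative of [restraint_energy()] with respect to `Dbar`
#' (kJ mol^-1 Hz^-1): zero in the flat bottom, `-K (Dbar - D0 -/+ dD_fb)` in
#' the harmonic band, and constant magnitude `K * dD_h` beyond.
#'
#' @inheritParams restraint_energy
#' @return Force (kJ mol^-1 Hz^-1), vectorized.
#' @export
restraint_force_dD <- function(D_bar, D0, params) {
  x <- D_bar - D0
  fb <- params$dD_fb; h <- params$dD_h; K <- params$K
  ifelse(abs(x) <= fb, 0,
         ifelse(x > 0,
                ifelse(x <= fb + h, -K * (x - fb), -K * h),
                ifelse(x >= -fb - h, -K * (x + fb), K * h)))
}

#' One update of the exponentially damped running average
#'
#' Discrete exponential-memory recursion with decay `a = exp(-dt/tau)`:
#' `Pbar_n = P_n (1 - a) + a Pbar_{n-1}`, initialized at the first evaluated
#' value. A constant signal is a fixed point; for `tau -> Inf` new samples get
#' vanishing weight. The SD engine can renormalize the early average by the
#' accumulated weight `1 - a^(n+1)` (growing-window form); see [run_hrs()].
#'
#' @param P_bar_prev Previous average. @param P_now Current sample.
#' @param dt Time step, ps. @param tau Memory relaxation time, ps (> 0).
#' @return Updated average.
#' @export
update_exp_average <- function(P_bar_prev, P_now, dt, tau) {
  if (tau <= 0) stop("tau must be positive")
  a <- exp(-dt / tau)
  P_now * (1 - a) + a * P_bar_prev
}

#' Gradient of P2 with respect to the first mfv particle position
#'
#' For `P = P2(cos theta)` with `cos theta = u_mfv . u_rdc` and a rigid mfv
#' bond of length `bond`, the gradient with respect to the position of
#' particle h1 is `3 cos(theta) (u_rdc - cos(theta) u_mfv) / bond`; the
#' gradient on h2 is its negative, so the restraint exerts no net force.
#'
#' @param u_mfv Unit vector along the magnetic-field vector (h1 - h2).
#' @param u_rdc Unit internuclear vector.
#' @param bond mfv bond length, nm.
#' @return Numeric length-3 gradient (per nm) on particle h1.
#' @export
p2_gradient <- function(u_mfv, u_rdc, bond) {
  ct <- sum(u_mfv * u_rdc)
  3 * ct * (u_rdc - ct * u_mfv) / bond
}

#' Initial state of the magnetic-field vector
#'
#' The mfv starts along the +z axis (the initial orientation is arbitrary);
#' velocities are Maxwell-drawn at temperature `T` and projected onto the
#' bond constraint.
#'
#' @param sim A [sim_params()] list.
#' @return List of class `mfv_state`: positions `r1`, `r2` (nm), velocities
#'   `v1`, `v2` (nm/ps), `step` counter.
#' @export
init_mfv_state <- function(sim) {
  b2 <- sim$bond / 2
  r1 <- c(0, 0, b2); r2 <- c(0, 0, -b2)
  sd_v <- sqrt(rdc_constants()$kB * sim$T / sim$mass)
  v1 <- stats::rnorm(3, 0, sd_v); v2 <- stats::rnorm(3, 0, sd_v)
  st <- list(r1 = r1, r2 = r2, v1 = v1, v2 = v2, step = 0L)
  st[c("v1", "v2")] <- .rattle_v(st$r1, st$r2, st$v1, st$v2)
  structure(st, class = "mfv_state")
}

# iterative SHAKE for the single bond constraint; tolerance is the relative
# geometric precision on the bond length
.shake <- function(r1, r2, ref1, ref2, bond, mass, tol = 1e-4, maxit = 1000) {
  dref <- ref1 - ref2
  for (it in seq_len(maxit)) {
    d <- r1 - r2
    len <- sqrt(sum(d * d))
    if (abs(len - bond) / bond < tol) return(list(r1 = r1, r2 = r2))
    g <- (sum(d * d) - bond^2) / (2 * (2 / mass) * sum(d * dref))
    r1 <- r1 - (g / mass) * dref
    r2 <- r2 + (g / mass) * dref
  }
  stop("SHAKE failed to converge within ", maxit, " iterations")
}

.rattle_v <- function(r1, r2, v1, v2) {
  d <- (r1 - r2) / sqrt(sum((r1 - r2)^2))
  c_rad <- sum((v1 - v2) * d)
  list(v1 = v1 - 0.5 * c_rad * d, v2 = v2 + 0.5 * c_rad * d)
}

#' Restraining forces on the magnetic-field vector particles
#'
#' Sums, over the restrained couplings, the restraint force with respect to
#' the averaged coupling times the chain-rule factors: the effective prefactor
#' (Hz), the derivative `1 - exp(-dt/tau)` of the exponential average with
#' respect to the current sample (approximately `dt/tau`), and the P2
#' gradient. The force on h2 is minus the force on h1.
#'
#' @param state An `mfv_state`.
#' @param vectors An `rdc_vectors` table.
#' @param targets An `rdc_targets` table (index-aligned with `vectors`).
#' @param P_bar Current exponentially averaged P2 values (one per target),
#'   after any renormalization.
#' @param params A [restraint_params()] list.
#' @param dt Time step, ps.
#' @return List with `f1`, `f2` (kJ mol^-1 nm^-1).
#' @export
mfv_force <- function(state, vectors, targets, P_bar, params, dt) {
  u <- (state$r1 - state$r2)
  bond <- sqrt(sum(u * u)); u <- u / bond
  f1 <- c(0, 0, 0)
  w <- 1 - exp(-dt / params$tau_theta)
  for (k in which(targets$restrained)) {
    Dbar <- vectors$scale_Hz[k] * P_bar[k]
    fD <- restraint_force_dD(Dbar, targets$D0[k], params)
    if (fD != 0) {
      g <- p2_gradient(u, c(vectors$ux[k], vectors$uy[k], vectors$uz[k]), bond)
      f1 <- f1 + fD * vectors$scale_Hz[k] * w * g
    }
  }
  list(f1 = f1, f2 = -f1)
}

#' One constrained Langevin (BAOAB) step of the magnetic-field vector
#'
#' Splitting scheme: half kick (with the force at the current positions),
#' half drift + SHAKE, full Ornstein-Uhlenbeck velocity refresh, half drift +
#' SHAKE, then a half kick with the force recomputed at the new positions
#' (supplied by `force_fn`). Velocities are projected onto the constraint
#' after every kick and refresh. Force-free, the stationary velocity marginal
#' is exact (Maxwell at `T`) and orientations are isotropic.
#'
#' @param state An `mfv_state`; element `f` (list `f1`, `f2`) holds the force
#'   at the current positions (zero if absent).
#' @param sim A [sim_params()] list.
#' @param force_fn Function of the updated state returning `list(f1, f2)`, or
#'   `NULL` for force-free motion.
#' @return The updated `mfv_state` (with the new force stored in `$f`).
#' @export
langevin_step <- function(state, sim, force_fn = NULL) {
  m <- sim$mass; h <- sim$dt; kB <- rdc_constants()$kB
  f <- state$f
  if (is.null(f)) f <- list(f1 = c(0, 0, 0), f2 = c(0, 0, 0))
  v1 <- state$v1 + 0.5 * h * f$f1 / m
  v2 <- state$v2 + 0.5 * h * f$f2 / m
  vv <- .rattle_v(state$r1, state$r2, v1, v2); v1 <- vv$v1; v2 <- vv$v2
  # half drift + SHAKE
  r1 <- state$r1 + 0.5 * h * v1
  r2 <- state$r2 + 0.5 * h * v2
  rr <- .shake(r1, r2, state$r1, state$r2, sim$bond, m)
  v1 <- v1 + (rr$r1 - r1) / (0.5 * h); v2 <- v2 + (rr$r2 - r2) / (0.5 * h)
  r1 <- rr$r1; r2 <- rr$r2
  # Ornstein-Uhlenbeck refresh (exact)
  c1 <- exp(-sim$gamma * h)
  c2 <- sqrt((1 - c1^2) * kB * sim$T / m)
  v1 <- c1 * v1 + c2 * stats::rnorm(3)
  v2 <- c1 * v2 + c2 * stats::rnorm(3)
  vv <- .rattle_v(r1, r2, v1, v2); v1 <- vv$v1; v2 <- vv$v2
  # second half drift + SHAKE
  r1n <- r1 + 0.5 * h * v1
  r2n <- r2 + 0.5 * h * v2
  rr <- .shake(r1n, r2n, r1, r2, sim$bond, m)
  v1 <- v1 + (rr$r1 - r1n) / (0.5 * h); v2 <- v2 + (rr$r2 - r2n) / (0.5 * h)
  r1 <- rr$r1; r2 <- rr$r2
  new_state <- structure(list(r1 = r1, r2 = r2, v1 = v1, v2 = v2,
                              step = state$step + 1L), class = "mfv_state")
  fnew <- if (is.null(force_fn)) list(f1 = c(0, 0, 0), f2 = c(0, 0, 0)) else force_fn(new_state)
  v1 <- v1 + 0.5 * h * fnew$f1 / m
  v2 <- v2 + 0.5 * h * fnew$f2 / m
  vv <- .rattle_v(r1, r2, v1, v2)
  new_state$v1 <- vv$v1; new_state$v2 <- vv$v2
  new_state$f <- fnew
  new_state
}

# Pure-R reference implementation of one HRS run; mirrors the C++ engine
# step-for-step (same RNG draw order) and exists as its independent check.
.hrs_run_r <- function(vectors, targets, restraint, sim, n_steps,
                       renormalize = TRUE) {
  a <- exp(-sim$dt / restraint$tau_theta)
  state <- init_mfv_state(sim)
  u0 <- .unit(state$r1 - state$r2)
  uk <- cbind(vectors$ux, vectors$uy, vectors$uz)
  P <- legendre_p2(drop(uk %*% u0))
  acc <- (1 - a) * P
  bar <- P
  wsum <- 1 - a
  P_eff <- if (renormalize) acc / wsum else bar
  P_sum <- rep(0, nrow(vectors))
  force_fn <- function(st) {
    if (restraint$K == 0) return(list(f1 = c(0, 0, 0), f2 = c(0, 0, 0)))
    mfv_force(st, vectors, targets, P_eff, restraint, sim$dt)
  }
  state$f <- force_fn(state)
  for (n in seq_len(n_steps)) {
    # P_eff must reflect the average *before* this step's force recomputation:
    # langevin_step calls force_fn after moving, so refresh the average first
    # via the closure below. Order: move, sample P, update average, force.
    state <- langevin_step(state, sim, force_fn = function(st) {
      u <- .unit(st$r1 - st$r2)
      P <<- legendre_p2(drop(uk %*% u))
      acc <<- (1 - a) * P + a * acc
      bar <<- (1 - a) * P + a * bar
      wsum <<- 1 - a + a * wsum
      P_eff <<- if (renormalize) acc / wsum else bar
      P_sum <<- P_sum + P
      force_fn(st)
    })
  }
  list(P_mean = P_sum / n_steps, state = state)
}

#' Run the HRS magnetic-field rotational-sampling calculation
#'
#' Propagates the rigid two-particle magnetic-field vector by constrained
#' Langevin dynamics under flat-bottom RDC restraints acting on the
#' exponentially averaged couplings, for `sim$n_runs` independent runs
#' differing only in their random seed, and reports for every coupling the
#' plain arithmetic average over all sampled steps of all runs (the
#' exponentially damped average drives the forces but is never reported).
#'
#' @param vectors An `rdc_vectors` table (restrained and unrestrained bonds).
#' @param targets An `rdc_targets` table, index-aligned; the `restrained`
#'   flags select which couplings exert forces.
#' @param restraint A [restraint_params()] list.
#' @param sim A [sim_params()] list.
#' @param traj_stride Store the mfv unit vector every this many steps
#'   (0 = no trajectory).
#' @param trace_stride Store the running plain-average couplings every this
#'   many steps (0 = no trace).
#' @param renormalize If `TRUE` (default), the exponential average used in the
#'   forces is divided by its accumulated weight `1 - a^(n+1)` so that early in
#'   a run it is a plain growing-window average rather than being dominated by
#'   the starting orientation; `FALSE` gives the bare recursion.
#' @return List of class `hrs_result`: `D` (reported couplings, Hz), `P_mean`,
#'   `per_run` (couplings per run), `traj` (unit-vector samples, with run
#'   index), `trace` (list of running-average matrices), `targets`,
#'   `vectors`, `restraint`, `sim`, `seeds`.
#' @export
run_hrs <- function(vectors, targets, restraint = restraint_params(),
                    sim = sim_params(), traj_stride = 100L,
                    trace_stride = 0L, renormalize = TRUE) {
  if (nrow(vectors) != nrow(targets)) stop("vectors and targets must be index-aligned")
  uk <- cbind(vectors$ux, vectors$uy, vectors$uz)
  seeds <- sim$seed + seq_len(sim$n_runs) - 1L
  P_runs <- matrix(0, nrow(vectors), sim$n_runs)
  traj <- vector("list", sim$n_runs)
  trace <- vector("list", sim$n_runs)
  for (j in seq_len(sim$n_runs)) {
    set.seed(seeds[j])
    sd_v <- sqrt(rdc_constants()$kB * sim$T / sim$mass)
    v1 <- stats::rnorm(3, 0, sd_v); v2 <- stats::rnorm(3, 0, sd_v)
    out <- hrs_run_cpp(uk, vectors$scale_Hz, targets$D0, targets$restrained,
                       restraint$K, restraint$dD_fb, restraint$dD_h,
                       restraint$tau_theta, sim$dt, sim$T, sim$gamma,
                       sim$mass, sim$bond, sim$n_steps,
                       as.integer(traj_stride), as.integer(trace_stride),
                       renormalize, v1, v2)
    P_runs[, j] <- out$P_mean
    if (traj_stride > 0) traj[[j]] <- out$traj
    if (trace_stride > 0) trace[[j]] <- out$trace
  }
  P_mean <- rowMeans(P_runs)
  structure(list(
    D = vectors$scale_Hz * P_mean,
    P_mean = P_mean,
    per_run = vectors$scale_Hz * P_runs,
    traj = if (traj_stride > 0) do.call(rbind, traj) else NULL,
    traj_run = if (traj_stride > 0) rep(seq_len(sim$n_runs),
                                        vapply(traj, nrow, 1L)) else NULL,
    trace = if (trace_stride > 0) trace else NULL,
    targets = targets, vectors = vectors,
    restraint = restraint, sim = sim, seeds = seeds,
    renormalize = renormalize
  ), class = "hrs_result")
}

#' @export
print.hrs_result <- function(x, ...) {
  cat(sprintf("HRS result: %d couplings (%d restrained), %d x %g ns, K = %g kJ mol^-1 Hz^-2\n",
              nrow(x$targets), sum(x$targets$restrained), x$sim$n_runs,
              x$sim$n_steps * x$sim$dt / 1000, x$restraint$K))
  dev <- x$D - x$targets$D0
  cat(sprintf("  RMSD(D - D0) all: %.3g Hz; run-to-run sd (median): %.3g Hz\n",
              sqrt(mean(dev^2)), stats::median(apply(x$per_run, 1, stats::sd))))
  invisible(x)
}
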