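test_that("clearance_at_time obeys the sigmoid boundary identities", {
  pop <- test_pop(emax = -0.3)
  ind <- individual_parameters(pop, 60.8)
  expect_equal(clearance_at_time(ind, pop, 0), ind$cl_base)
  # degenerate sigmoid: emax = 0 keeps clearance flat
  pop0 <- test_pop(emax = 0)
  ind0 <- individual_parameters(pop0, 60.8)
  tt <- c(0, 10, 500, 5000)
  expect_equal(clearance_at_time(ind0, pop0, tt), rep(ind0$cl_base, 4))
  # midpoint identity at t = t50 with hill = 1
  pop1 <- test_pop(emax = -0.3, hill = 1)
  ind1 <- individual_parameters(pop1, 60.8)
  expect_equal(clearance_at_time(ind1, pop1, pop1$t50),
               ind1$cl_base * exp(-0.3 / 2))
  # monotone decreasing for emax < 0, bounded by the asymptote
  cl <- clearance_at_time(ind, pop, seq(0, 50000, by = 500))
  expect_true(all(diff(cl) <= 0))
  expect_true(all(cl <= ind$cl_base + 1e-12))
  expect_true(all(cl >= ind$cl_base * exp(-0.3) - 1e-12))
  expect_error(clearance_at_time(ind, pop, -1), "t must be")
})

test_that("solver matches the one-compartment closed form when q -> 0", {
  pop <- test_pop(q_typical = 1e-9, v2_typical = 1e-6)
  ind <- individual_parameters(pop, 60.8)
  doses <- dose_events(regimen(interval = 336, dose_per_kg = 10,
                               n_doses = 3), 60.8)
  times <- c(0.5, 1, 24, 168, 336, 400, 700, 1000)
  got <- solve_concentrations(ind, pop, doses, times)$values
  want <- onecpt_infusion_oracle(ind$cl_base, ind$v1, doses, times)
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("solver matches the bi-exponential two-compartment solution for constant clearance", {
  set.seed(42)
  for (rep in 1:100) {
    cl <- runif(1, 0.005, 0.05)
    v1 <- runif(1, 3, 8)
    v2 <- runif(1, 1, 6)
    q <- runif(1, 0.005, 0.08)
    pop <- pop_parameters(cl_typical = cl, v1_typical = v1, v2_typical = v2,
                          q_typical = q, wt_ref = 60.8)
    ind <- individual_parameters(pop, 60.8)
    doses <- data.frame(start = c(0, 336), amount = c(600, 600), duration = 1)
    times <- sort(runif(4, 0.5, 800))
    got <- solve_concentrations(ind, pop, doses, times)$values
    want <- twocpt_infusion_oracle(cl, v1, v2, q, doses, times)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("concentrations are zero before dosing and superpose across dose lists", {
  pop <- test_pop(emax = -0.25)
  ind <- individual_parameters(pop, 55)
  d1 <- data.frame(start = 0, amount = 550, duration = 1)
  d2 <- data.frame(start = 336, amount = 440, duration = 1)
  times <- c(0, 100, 336.5, 500, 900)
  c1 <- solve_concentrations(ind, pop, d1, times)$values
  c2 <- solve_concentrations(ind, pop, d2, times)$values
  c12 <- solve_concentrations(ind, pop, rbind(d1, d2), times)$values
  expect_equal(c12, c1 + c2, tolerance = 1e-6)
  # nothing on board before the first infusion starts
  expect_identical(solve_concentrations(ind, pop, d2, c(0, 100, 336))$values,
                   c(0, 0, 0))
})

test_that("Cmin,1 is evaluated at the scheduled second-dose time and is linear in dose", {
  pop <- test_pop(emax = -0.25)
  ind <- individual_parameters(pop, 60.8)
  reg <- regimen(interval = 336, dose_per_kg = 10, n_doses = 14)
  c1 <- trough_after_first_dose(ind, pop, reg)
  direct <- solve_concentrations(ind, pop, dose_events(reg, 60.8)[1, ],
                                 336)$values
  expect_equal(c1, direct)
  expect_gt(c1, 0)
  # linear kinetics: doubling dose per kg doubles the trough
  reg2 <- regimen(interval = 336, dose_per_kg = 20, n_doses = 14)
  expect_equal(trough_after_first_dose(ind, pop, reg2), 2 * c1,
               tolerance = 1e-6)
  reg0 <- regimen(interval = 336, dose_per_kg = 0, n_doses = 2)
  expect_warning(c0 <- trough_after_first_dose(ind, pop, reg0), "zero")
  expect_identical(c0, 0)
})

test_that("steady-state trough matches the repeated-infusion geometric series for one compartment", {
  pop <- test_pop(q_typical = 1e-9, v2_typical = 1e-6)
  ind <- individual_parameters(pop, 60.8)
  reg <- regimen(interval = 336, dose_per_kg = 10, n_doses = 14)
  got <- trough_at_steady_state(ind, pop, reg, rel_tol = 1e-5, max_doses = 60)
  want <- onecpt_ss_trough_oracle(ind$cl_base, ind$v1, 608, 1, 336)
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("accumulation makes Cmin,ss at least Cmin,1 when clearance does not increase", {
  pop <- test_pop(emax = -0.25)
  set.seed(7)
  etas <- sample_etas(test_pop(omega = diag(c(0.04, 0.04, 0.1, 0.005))), 5)
  for (i in 1:5) {
    ind <- individual_parameters(pop, 45 + 10 * i, etas[i, ])
    reg <- regimen(interval = 336, dose_per_kg = 10, n_doses = 14)
    expect_gte(trough_at_steady_state(ind, pop, reg),
               trough_after_first_dose(ind, pop, reg))
  }
})

test_that("steady-state trough is robust to tightening the solver tolerance", {
  pop <- test_pop(emax = -0.25)
  ind <- individual_parameters(pop, 60.8)
  reg <- regimen(interval = 336, dose_per_kg = 10, n_doses = 14)
  base <- trough_at_steady_state(ind, pop, reg)
  # re-solve the whole history at the recorded troughs with halved tolerance
  tight <- local({
    ev <- dose_events(reg, 60.8)
    last <- ev[nrow(ev), ]
    add <- data.frame(start = last$start + (1:30) * 336, amount = last$amount,
                      duration = 1, dose_per_kg = last$dose_per_kg)
    ev <- rbind(ev, add)
    n <- 40
    sol <- solve_concentrations(ind, pop, ev[seq_len(n), ],
                                ev$start[2:(n + 1)], rtol = 5e-9,
                                atol = 5e-11)
    prev <- sol$values[-length(sol$values)]
    cur <- sol$values[-1]
    cur[which(abs(cur - prev) / prev < 1e-3)[1]]
  })
  expect_equal(base, tight, tolerance = 1e-4)
})

test_that("MAP estimation recovers the prior mode and known random effects", {
  omega <- diag(c(0.09, 0.04, 0.16, 0.01))
  pop <- test_pop(emax = -0.25, omega = omega, sigma_prop = 1e-4,
                  sigma_add = 1e-6)
  reg <- regimen(interval = 336, dose_per_kg = 10, n_doses = 14)
  doses <- dose_events(reg, 60.8)
  # truth at the prior mode: noiseless observations generated with eta = 0
  ind0 <- individual_parameters(pop, 60.8)
  tt <- protocol_sampling_times(doses)$time
  obs0 <- solve_concentrations(ind0, pop, doses, tt)
  est0 <- map_estimate_etas(pop, 60.8, doses, obs0)
  expect_true(est0$converged)
  expect_lt(max(abs(est0$eta)), 1e-3)
  # rich sampling, tiny residual error: known eta recovered within 1%
  eta <- c(0.2, -0.1, 0.15, 0.05)
  ind <- individual_parameters(pop, 60.8, eta)
  rich_t <- seq(24, 4500, length.out = 24)
  obs <- solve_concentrations(ind, pop, doses, rich_t)
  est <- map_estimate_etas(pop, 60.8, doses, obs)
  expect_equal(est$eta, eta, tolerance = 0.01)
  # no post-dose observations: posterior collapses to the prior mode
  empty <- structure(list(times = numeric(), values = numeric(),
                          kind = "observation"),
                     class = "concentration_profile")
  est_e <- map_estimate_etas(pop, 60.8, doses, empty)
  expect_identical(est_e$eta, c(0, 0, 0, 0))
  expect_identical(est_e$flag, "no_observations")
  # all-zero concentrations despite dosing are implausible
  zero <- structure(list(times = c(336, 672), values = c(0, 0),
                         kind = "observation"),
                    class = "concentration_profile")
  expect_identical(map_estimate_etas(pop, 60.8, doses, zero)$flag,
                   "implausible_zero")
})

test_that("regimen comparison is reproducible and degenerates without variability", {
  pop <- test_pop(emax = -0.25)
  regs <- list(q2w = regimen(interval = 336, dose_per_kg = 10, n_doses = 4),
               q3w = regimen(interval = 504, dose_per_kg = 10, n_doses = 3))
  ws <- function(n) rep(60.8, n)
  a <- simulate_regimen_comparison(pop, regs, n_iter = 3,
                                   weight_sampler = function(n)
                                     runif(n, 45, 80), seed = 5)
  b <- simulate_regimen_comparison(pop, regs, n_iter = 3,
                                   weight_sampler = function(n)
                                     runif(n, 45, 80), seed = 5)
  expect_identical(a, b)
  # no IIV, fixed weight, single iteration: the three bands coincide
  d <- simulate_regimen_comparison(pop, regs["q2w"], n_iter = 1,
                                   weight_sampler = ws, seed = 1)
  expect_equal(d$q2w$bands["p5", ], d$q2w$bands["p95", ])
  expect_error(simulate_regimen_comparison(pop, list(), 1, 1, ws),
               "empty regimen")
})

test_that("dose events apply the reduction ladder and delay rules", {
  reg <- regimen(interval = 336, dose_per_kg = 10, n_doses = 5)
  ev <- dose_events(reg, 60)
  expect_equal(ev$start, c(0, 336, 672, 1008, 1344))
  expect_equal(ev$amount, rep(600, 5))
  reg_red <- regimen(interval = 336, dose_per_kg = 10, n_doses = 5,
                     modifications = list(list(dose = 3, dose_per_kg = 8)))
  expect_equal(dose_events(reg_red, 60)$amount, c(600, 600, 480, 480, 480))
  reg_del <- regimen(interval = 336, dose_per_kg = 10, n_doses = 4,
                     modifications = list(list(dose = 2, delay_h = 168)))
  expect_equal(dose_events(reg_del, 60)$start, c(0, 504, 840, 1176))
  expect_error(regimen(interval = 336, n_doses = 4,
                       modifications = list(list(dose = 2, delay_h = 1200))),
               "42 days")
  expect_error(regimen(interval = 336, n_doses = 4,
                       modifications = list(list(dose = 9, delay_h = 24))),
               "nonexistent dose")
  expect_error(regimen(interval = 336, n_doses = 4,
                       modifications = list(list(dose = 2, dose_per_kg = 7))),
               "8, 6, 5")
  # ladder cannot step back up
  reg_up <- regimen(interval = 336, dose_per_kg = 10, n_doses = 5,
                    modifications = list(list(dose = 2, dose_per_kg = 6),
                                         list(dose = 4, dose_per_kg = 8)))
  expect_error(dose_events(reg_up, 60), "ladder")
})

test_that("compiled RK45 agrees with an independent lsoda integration under time-varying clearance", {
  skip_if_not_installed("deSolve")
  pop <- test_pop(emax = -0.35)
  ind <- individual_parameters(pop, 55, c(0.1, -0.05, 0.2, -0.02))
  doses <- data.frame(start = c(0, 336, 672), amount = c(550, 440, 550),
                      duration = 1)
  times <- c(1, 100, 336, 500, 700, 1100)
  got <- solve_concentrations(ind, pop, doses, times)$values
  derivs <- function(t, y, p) {
    s <- if (t == 0) 0 else t^p$hill / (p$t50^p$hill + t^p$hill)
    cl <- p$cl_base * exp(p$emax * s)
    list(c(p$rate - (cl + p$q) / p$v1 * y[1] + p$q / p$v2 * y[2],
           p$q / p$v1 * y[1] - p$q / p$v2 * y[2]))
  }
  # piecewise lsoda with constant rate per switch-to-switch segment
  switches <- sort(unique(c(doses$start, doses$start + doses$duration,
                            max(times))))
  state <- c(0, 0)
  cur <- 0
  want <- numeric(length(times))
  for (b in switches) {
    mid <- (cur + b) / 2
    on <- doses$start <= mid & mid < doses$start + doses$duration
    tout <- sort(unique(c(times[times > cur & times <= b], b)))
    sol <- deSolve::lsoda(state, times = c(cur, tout), func = derivs,
                          parms = list(cl_base = ind$cl_base,
                                       emax = ind$emax, t50 = pop$t50,
                                       hill = pop$hill, v1 = ind$v1,
                                       v2 = ind$v2, q = ind$q,
                                       rate = sum(doses$amount[on] /
                                                    doses$duration[on])),
                          rtol = 1e-10, atol = 1e-12)
    state <- unname(sol[nrow(sol), 2:3])
    hit <- times > cur & times <= b
    if (any(hit))
      want[hit] <- sol[match(times[hit], sol[, 1]), 2] / ind$v1
    cur <- b
  }
  expect_equal(got, want, tolerance = 1e-5)
})
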