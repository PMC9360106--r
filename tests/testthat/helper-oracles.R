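# Closed-form oracles used to cross-check the ODE solver.  These are coded
# directly from textbook infusion solutions, independently of the solver.

# One-compartment constant-rate infusion superposition (CL constant, Q = 0).
onecpt_infusion_oracle <- function(cl, v, doses, times) {
  k <- cl / v
  sapply(times, function(t) {
    c_tot <- 0
    for (i in seq_len(nrow(doses))) {
      s <- doses$start[i]; Tdur <- doses$duration[i]
      R <- doses$amount[i] / Tdur
      if (t <= s) next
      if (t <= s + Tdur) {
        c_tot <- c_tot + (R / cl) * (1 - exp(-k * (t - s)))
      } else {
        c_tot <- c_tot + (R / cl) * (1 - exp(-k * Tdur)) *
          exp(-k * (t - s - Tdur))
      }
    }
    c_tot
  })
}

# One-compartment repeated-infusion steady-state trough (interval tau,
# infusion duration Tdur, trough evaluated tau after a dose start).
onecpt_ss_trough_oracle <- function(cl, v, rate, Tdur, tau) {
  k <- cl / v
  (rate / cl) * (1 - exp(-k * Tdur)) * exp(-k * (tau - Tdur)) /
    (1 - exp(-k * tau))
}

# Two-compartment constant-clearance infusion superposition via the
# bi-exponential solution with macro-constants.
twocpt_infusion_oracle <- function(cl, v1, v2, q, doses, times) {
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  p <- k10 * k21
  alpha <- (s + sqrt(s^2 - 4 * p)) / 2
  beta <- (s - sqrt(s^2 - 4 * p)) / 2
  A <- (alpha - k21) / (alpha - beta)
  B <- (k21 - beta) / (alpha - beta)
  sapply(times, function(t) {
    c_tot <- 0
    for (i in seq_len(nrow(doses))) {
      st <- doses$start[i]; Tdur <- doses$duration[i]
      R <- doses$amount[i] / Tdur
      if (t <= st) next
      te <- min(t - st, Tdur)
      rel <- max(t - st - Tdur, 0)
      c_tot <- c_tot + (R / v1) * (
        A * (1 - exp(-alpha * te)) * exp(-alpha * rel) / alpha +
        B * (1 - exp(-beta * te)) * exp(-beta * rel) / beta)
    }
    c_tot
  })
}

# A small deterministic population used across PK tests (constant clearance
# unless a test overrides emax).
test_pop <- function(emax = 0, omega = diag(0, 4), sigma_prop = 0,
                     sigma_add = 0, hill = 2, q_typical = 0.023,
                     v2_typical = 2.9) {
  pop_parameters(cl_typical = 0.018, v1_typical = 5.5,
                 v2_typical = v2_typical, q_typical = q_typical,
                 wt_ref = 60.8, emax_typical = emax, t50 = 720, hill = hill,
                 omega = omega, sigma_prop = sigma_prop,
                 sigma_add = sigma_add)
}

# Exhaustive-scan greedy caliper matching used to cross-check the
# package implementation on small instances.
naive_greedy <- function(cases, controls, factors, caliper_mult) {
  pooled <- rbind(cbind(cases[factors], case = 1L),
                  cbind(controls[factors], case = 0L))
  fit <- glm(case ~ ., data = pooled, family = binomial())
  lp <- predict(fit, type = "link")
  ca <- lp[seq_len(nrow(cases))]; co <- lp[-seq_len(nrow(cases))]
  cal <- caliper_mult * sd(lp)
  mm <- model.matrix(~ . - 1, pooled[factors])
  Sinv <- solve(cov(mm))
  Xc <- mm[seq_len(nrow(cases)), , drop = FALSE]
  Xo <- mm[-seq_len(nrow(cases)), , drop = FALSE]
  used <- rep(FALSE, nrow(controls))
  out <- cbind(case = integer(), control = integer())
  for (i in order(ca, decreasing = TRUE)) {
    best <- NA; bestd <- Inf
    for (j in seq_len(nrow(controls))) {   # exhaustive scan per case
      if (used[j] || abs(co[j] - ca[i]) > cal) next
      dv <- Xc[i, ] - Xo[j, ]
      dd <- drop(dv %*% Sinv %*% dv)
      if (dd < bestd) { bestd <- dd; best <- j }
    }
    if (!is.na(best)) { used[best] <- TRUE
      out <- rbind(out, cbind(case = i, control = best)) }
  }
  out
}
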