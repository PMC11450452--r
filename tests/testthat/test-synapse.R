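test_that("synapse parameter invariants are enforced", {
  expect_s3_class(synapse_params(), "bcpnn_synapse_params")
  expect_equal(synapse_params(f_max = 100, dt = 0.001)$mu_spk, 0.1)
  expect_error(synapse_params(tau_zi = 0.0005, dt = 0.001))  # tau_z < dt
  expect_error(synapse_params(tau_p = 0.001, tau_zi = 0.02)) # tau_p < tau_z
  expect_error(synapse_params(f_max = 2000, dt = 0.001))     # mu > 1
})

test_that("z-traces follow the closed-form exponential filter exactly", {
  prm <- synapse_params(tau_zi = 0.020, tau_zj = 0.010, f_max = 100,
                        dt = 0.001)
  # zero stays a fixed point
  st <- trace_state(1, 1, 2, 2)
  for (k in 1:50) st <- step_z_traces(st, 0, 0, prm)
  expect_identical(st$z_pre, 0)
  expect_identical(st$z_post, 0)

  # single spike then silence: jump to (dt/tau)/mu, geometric decay
  st <- trace_state(1, 1, 2, 2)
  st <- step_z_traces(st, 1, 1, prm)
  expect_equal(st$z_pre, (0.001 / 0.020) / 0.1)   # = 0.5
  z1 <- st$z_pre
  st <- step_z_traces(st, 0, 0, prm)
  expect_equal(st$z_pre, z1 * (1 - 0.05), tolerance = 1e-15)

  # arbitrary fixed spike train matches the iterated oracle to 1e-12
  set.seed(11)
  spikes <- as.numeric(runif(400) < 0.07)
  st <- trace_state(1, 1, 2, 2)
  trace <- numeric(length(spikes))
  for (t in seq_along(spikes)) {
    st <- step_z_traces(st, spikes[t], 0, prm)
    trace[t] <- st$z_pre
  }
  expect_equal(trace, z_filter_oracle(spikes, 0.020, 0.001, 0.1),
               tolerance = 1e-12)
})

test_that("long-run z-trace mean recovers the underlying probability", {
  # spikes at probability pi * mu_spk per step: time-averaged z -> pi
  for (f_max in c(100, 1000)) {
    for (pi_tgt in c(0.1, 0.5, 1.0)) {
      prm <- synapse_params(tau_zi = 0.020, tau_zj = 0.020, f_max = f_max,
                            dt = 0.001)
      n_units <- 40
      n_steps <- 4000
      set.seed(f_max + round(1000 * pi_tgt))
      st <- trace_state(n_units, 1, 2, 2)
      acc <- 0
      burn <- 200
      for (t in seq_len(n_steps)) {
        s <- as.numeric(runif(n_units) < pi_tgt * prm$mu_spk)
        st <- step_z_traces(st, s, 0, prm)
        if (t > burn) acc <- acc + mean(st$z_pre)
      }
      z_bar <- acc / (n_steps - burn)
      # SE of the pooled spike-rate estimate, conservative for the trace
      se <- sqrt(pi_tgt * prm$mu_spk / (n_units * n_steps)) / prm$mu_spk
      expect_lt(abs(z_bar - pi_tgt), max(3 * se, 0.02),
                label = sprintf("f_max=%g pi=%g: |%.4f - %g|",
                                f_max, pi_tgt, z_bar, pi_tgt))
    }
  }
})

test_that("p-traces decay and converge to products of constant z-drives", {
  prm <- synapse_params(tau_p = 0.5)
  st <- trace_state(1, 1, 2, 2)
  st$z_pre <- 0; st$z_post <- 0
  n <- 300
  st0 <- st
  for (k in seq_len(n)) st <- step_p_traces(st, prm)
  expect_equal(st$p_pre, p_const_oracle(0, st0$p_pre, 0.5, 0.001, n),
               tolerance = 1e-12)

  # constant z at (a, b): p_joint -> a*b along the closed-form path
  st <- trace_state(1, 1, 2, 2)
  st$z_pre <- 0.3; st$z_post <- 0.6
  for (k in seq_len(n)) st <- step_p_traces(st, prm)
  expect_equal(st$p_joint[1, 1],
               p_const_oracle(0.3 * 0.6, 0.25, 0.5, 0.001, n),
               tolerance = 1e-12)
})

test_that("uncorrelated spike trains give p_joint ~ p_pre * p_post", {
  prm <- synapse_params(tau_zi = 0.01, tau_zj = 0.01, tau_p = 0.2,
                        f_max = 1000, dt = 0.001)
  set.seed(21)
  st <- trace_state(1, 1, 2, 2)
  for (t in 1:6000) {
    st <- step_z_traces(st, as.numeric(runif(1) < 0.4),
                        as.numeric(runif(1) < 0.3), prm)
    st <- step_p_traces(st, prm)
  }
  expect_equal(st$p_joint[1, 1], st$p_pre * st$p_post, tolerance = 0.05)
})

test_that("bias/weight transform reproduces hand-computed values", {
  prm <- synapse_params(eps = 1e-4)
  st <- trace_state(1, 1, 2, 2)
  st$p_pre <- 0.5; st$p_post <- 0.5; st$p_joint[1, 1] <- 0.5
  bw <- compute_bias_weight(st, prm)
  expect_equal(bw$weight[1, 1], log(2))
  expect_equal(bw$bias, log(0.5))

  # independence => zero PMI
  st$p_joint[1, 1] <- 0.25
  expect_equal(compute_bias_weight(st, prm)$weight[1, 1], 0)

  # p_j = 1 => zero bias; p floored so everything stays finite
  st$p_post <- 1
  st$p_pre <- 0; st$p_joint[1, 1] <- 0
  bw <- compute_bias_weight(st, prm)
  expect_equal(bw$bias, 0)
  expect_true(all(is.finite(bw$weight)))
})

test_that("recurrent-style traces stay symmetric and independent weights -> 0", {
  prm <- synapse_params(tau_zi = 0.02, tau_zj = 0.02, tau_p = 0.2,
                        f_max = 1000)
  n <- 6
  st <- trace_state(n, n, 3, 3)
  set.seed(5)
  for (t in 1:2000) {
    s <- as.numeric(runif(n) < 0.3)
    st <- step_z_traces(st, s, s, prm)  # same population pre and post
    st <- step_p_traces(st, prm)
  }
  expect_identical(st$z_pre, st$z_post)
  expect_equal(st$p_joint, t(st$p_joint), tolerance = 1e-14)
  w <- compute_bias_weight(st, prm)$weight
  expect_equal(w, t(w), tolerance = 1e-12)
  # off-diagonal pairs are independent Bernoulli units -> small PMI
  expect_lt(max(abs(w[upper.tri(w)])), 0.25)
})

test_that("spike inputs are validated", {
  prm <- synapse_params()
  st <- trace_state(2, 2, 2, 2)
  expect_error(step_z_traces(st, c(0.5, 0), c(0, 0), prm), "binary")
  expect_error(step_z_traces(st, c(1, 0, 0), c(0, 0), prm), "length")
})
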