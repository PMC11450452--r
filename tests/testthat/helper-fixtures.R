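# Shared fixtures: tiny networks and datasets built in code.

tiny_config <- function(variant = "spspk_full", seed = 42, ...) {
  network_config(variant = variant, h_inp = 9, m_inp = 2,
                 h_hid = 3, m_hid = 4, n_conn_ff = 5, n_conn_rec = 3,
                 n_conn_fb = 2, n_intv = 10, n_flip = 5, seed = seed, ...)
}

tiny_dataset <- function(n_prototypes = 2, hw = c(3, 3), n_per_class = 6,
                         flip_noise = 0.05, seed = 7) {
  generate_synthetic_dataset(synthetic_spec(
    n_prototypes = n_prototypes, image_shape = hw, flip_noise = flip_noise,
    n_per_class = n_per_class, seed = seed))
}

# independent discrete-time oracle for the z-trace filter:
# z_{t+1} = z_t (1 - dt/tau) + (dt/tau) s_t / mu
z_filter_oracle <- function(spikes, tau, dt, mu, z0 = 0) {
  a <- dt / tau
  z <- numeric(length(spikes))
  prev <- z0
  for (t in seq_along(spikes)) {
    prev <- prev * (1 - a) + a * spikes[t] / mu
    z[t] <- prev
  }
  z
}

# independent oracle for the p-trace filter under a constant drive x:
# closed-form geometric decay toward the fixed point
p_const_oracle <- function(x, p0, tau_p, dt, n_steps) {
  x + (p0 - x) * (1 - dt / tau_p)^n_steps
}

# brute-force pair-enumeration oracle for the orthogonality ratio
s_ortho_oracle <- function(x, labels) {
  n <- nrow(x)
  num <- den <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cs <- sum(x[i, ] * x[j, ]) /
      (sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2)))
    den <- c(den, cs)
    if (labels[i] == labels[j]) num <- c(num, cs)
  }
  mean(num) / mean(den)
}
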