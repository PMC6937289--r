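# Independent numerical oracles used across the suite. These are
# deliberately brute-force implementations that share no code with the
# package internals.

# Second moment of area of an annulus by direct numerical integration
# of integral(y^2 dA) in polar coordinates (Simpson in r and theta).
annulus_I_numeric <- function(a, t, n_r = 201, n_th = 401) {
  r_in <- a - t
  simpson_w <- function(n) {
    w <- c(1, rep(c(4, 2), length.out = n - 2), 1)
    w[n] <- 1
    w
  }
  r <- seq(r_in, a, length.out = n_r)
  th <- seq(0, 2 * pi, length.out = n_th)
  wr <- simpson_w(n_r) * (r[2] - r[1]) / 3
  wt <- simpson_w(n_th) * (th[2] - th[1]) / 3
  # y = r sin(theta); dA = r dr dtheta
  integrand <- outer(r^3, sin(th)^2)
  sum(integrand * outer(wr, wt))
}

# Upper-tail hypergeometric probability by explicit combinatorial sum,
# independent of phyper().
hyper_tail_enum <- function(N, K, n, k) {
  j <- seq(max(k, 0), min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force split-plot sums of squares: every effect SS accumulated
# observation by observation from subgroup means.
split_plot_ss_brute <- function(y, R, A, B) {
  gm <- mean(y)
  mean_of <- function(keys) {
    key <- interaction(keys, drop = TRUE)
    ave(y, key)
  }
  ss_R <- sum((mean_of(list(R)) - gm)^2)
  ss_A <- sum((mean_of(list(A)) - gm)^2)
  ss_B <- sum((mean_of(list(B)) - gm)^2)
  ss_RA <- sum((mean_of(list(R, A)) - gm)^2) - ss_R - ss_A
  ss_AB <- sum((mean_of(list(A, B)) - gm)^2) - ss_A - ss_B
  ss_T <- sum((y - gm)^2)
  ss_E <- ss_T - ss_R - ss_A - ss_RA - ss_B - ss_AB
  c(replicate = ss_R, whole = ss_A, whole_error = ss_RA,
    sub = ss_B, interaction = ss_AB, residual = ss_E, total = ss_T)
}

# A balanced 2x2x4 plot table with configurable cell means.
make_plot_table <- function(mu = c(FFP.A = 0, OPT.A = 0, FFP.B = 0, OPT.B = 0),
                            sd = 1, n_reps = 4) {
  d <- expand.grid(replicate = seq_len(n_reps),
                   treatment = c("FFP", "OPT"),
                   variety = c("A", "B"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(d$treatment, d$variety, sep = ".")
  d$value <- mu[key] + rnorm(nrow(d), 0, sd)
  d
}

# Small lengths-only trial config (one variety) for fast simulations.
mini_trial_config <- function() {
  tibble::tibble(
    variety = "YJRZ",
    treatment = rep(c("FFP", "OPT"), each = 3),
    internode = rep(1:3, 2),
    mean_length_cm = c(3.4, 8.1, 16.9, 2.8, 6.8, 13.2),
    se_length_cm = c(0.1, 0.2, 0.4, 0.2, 0.5, 0.6),
    mean_diameter_mm = rep(5.5, 6), se_diameter_mm = rep(0.1, 6),
    mean_wall_mm = rep(0.7, 6), se_wall_mm = rep(0.02, 6)
  )
}
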