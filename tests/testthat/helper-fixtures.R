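# shared fixture builders; all data is generated in code at test time

# simple iid linear-model table: y = beta * x + e, one row per subject
make_linear_table <- function(n, beta = 0.5, sigma = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  data.frame(subject_id = seq_len(n), visit_index = 0L,
             age = runif(n, 40, 60), sex = rbinom(n, 1, 0.5),
             x = x, y = beta * x + rnorm(n, 0, sigma))
}

# balanced two-group table with group mean difference delta
make_two_group_table <- function(n, delta, sd0 = 1, sd1 = 1, seed = 1) {
  set.seed(seed)
  g <- rep(0:1, each = n / 2)
  data.frame(subject_id = seq_len(n), visit_index = 0L,
             age = 50, sex = g, g = g,
             y = delta * g + rnorm(n, 0, ifelse(g == 1, sd1, sd0)))
}

# default longitudinal fixture used across modules
make_longitudinal_fixture <- function(n = 300, visits = 3, bb = 0.5,
                                      bw = 0.5, u_sd = 1, seed = 1) {
  simulate_longitudinal_study(sim_config(
    n_subjects = n, visits_per_subject = visits,
    beta_between = bb, beta_within = bw,
    subject_intercept_sd = u_sd, seed = seed))
}

expect_snapshot_equal_tables <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
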