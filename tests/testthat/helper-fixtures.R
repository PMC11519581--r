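# shared fixtures, built in code at load time (cheap ones only)

lv_fix <- lotka_volterra_model()
rep_fix <- repressilator_model()
vir_fix <- viral_model()

rep_grid <- seq(3, 72, by = 3)
rep_cands <- enumerate_candidates(rep_grid, c("B", "C"))

# PARSEC-PSI matrix of the repressilator candidate universe (~0.5 s);
# memoised so several test files can share it
rep_psi <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- compute_parsec_psi(rep_fix, rep_cands)
    val
  }
})

# noiseless LV dataset at ground truth over the default hourly grid
lv_data <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      des <- new_design(enumerate_candidates(seq(1, 16), c("prey", "predator")))
      val <<- generate_dataset(lv_fix, design = des)
    }
    val
  }
})

# single-state toy whose solution is y(t) = theta1 * t: the chi-squared
# surface against a one-point dataset is an exact quadratic in theta1
linear_toy <- ode_model(
  "linear_toy", "y", c("t1", "t2"),
  function(t, y, th) th[1] + 0 * th[2],
  c(t1 = 1, t2 = 1), c(y = 0))

# trajectory object from raw pieces (for direct chi-squared arithmetic)
manual_trajectory <- function(times, states) {
  structure(list(times = times, states = states), class = "trajectory")
}

manual_dataset <- function(time, variable, value, sd) {
  structure(data.frame(time = time, variable = variable, value = value,
                       sd = sd, stringsAsFactors = FALSE),
            class = c("parsec_dataset", "data.frame"))
}
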