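# Shared fixtures: small hand-checkable tables and the two working models.

ph_pars <- function(beta_sex = -1) cgd_ph_params(beta_sex)
nph_pars <- function() cgd_nph_params()

# Three subjects per arm, no censoring, event times 1, 2, 3 in each arm:
# the product-limit curve steps 2/3, 1/3, 0 and the restricted mean at
# t* = 3 is 1 + 2/3 + 1/3 = 2 in each arm.
toy_table <- function() {
  as_subject_table(data.frame(
    time = c(1, 2, 3, 1, 2, 3),
    event = 1,
    treatment = rep(c(1, 0), each = 3),
    inherit = 0, sex = 0))
}

# A quickly simulated midsize table for cross-implementation checks.
sim_table <- function(n = 50, params = ph_pars(), seed = 2024)
  simulate_trial(params, n, seed = seed)

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
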