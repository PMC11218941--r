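# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

ref_params <- function() fixture("ref", make_reference_case())

# deterministic operating model (no recruitment deviates) with exact
# observations: the self-consistency workhorse
det_sim <- function() fixture("det_sim", {
  p <- make_reference_case(sigma_r = 0)
  simulate_assessment_data(p, seed = 1, exact = TRUE)
})

det_params <- function() fixture("det_params", make_reference_case(sigma_r = 0))

det_fit <- function() fixture("det_fit", {
  fit_assessment(det_sim()$data, matching_config(det_params()))
})

# one noisy reference-case replicate and its matching-config fit
noisy_sim <- function() fixture("noisy_sim",
  simulate_assessment_data(ref_params(), seed = 1))

noisy_fit <- function() fixture("noisy_fit",
  fit_assessment(noisy_sim()$data, matching_config(ref_params())))

ref_refpts <- function() fixture("ref_refpts", compute_refpts(ref_params()))

# small canonical grid factors (all seven factor names, few cells)
toy_factors <- function(m_levels = c("0.3", "0.4"),
                        e_levels = "50") {
  list(M = m_levels, h = "0.7", sR = "0.4", E = e_levels, CV = "0.3",
       q = "0", sel = "Log")
}
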