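# Shared fixtures for the test suite. Everything is generated in code;
# seeds are fixed so runs are reproducible.

trapz <- huxmtc:::trapz

# A mid-range parameter set used by most unit tests.
test_pars <- function() {
  mtc_parameters(
    elastic = elastic_parameters(f_max_ce = 16e-3, l_ce_opt = 6e-3,
                                 see_slack = 2.5e-3, pee_shape = 1.0),
    activation = activation_parameters(tau_act = 0.03, tau_deact = 0.07,
                                       kappa = 0.35),
    rates = rate_parameters(f1 = 700, g1 = 100, g2 = 1.2e4, g3 = 500),
    scale = scale_parameters(),
    energetic = energetic_parameters(c1 = 0.16, c2 = 0.06, c3 = 100)
  )
}

# MTC length at which the CE sits near its optimum under tetanus.
test_opt_length <- function(pars) {
  el <- pars$elastic
  el$l_ce_opt + el$see_slack * (1 + el$see_strain_at_fmax)
}
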