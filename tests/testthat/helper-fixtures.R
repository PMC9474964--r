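# Shared fixtures, built in code at test time.

fix_input <- function() feng_input(feng_params())

fix_schedule <- function() frame_schedule_66()

# mid-prior kinetic parameters for a named tissue class
fix_params <- function(tissue = "cortex") {
  r <- tissue_priors()
  r <- r[r$tissue == tissue, ]
  kinetic_params((r$K1_lo + r$K1_hi) / 2, (r$k2_lo + r$k2_hi) / 2,
                 (r$k3_lo + r$k3_hi) / 2, (r$Vb_lo + r$Vb_hi) / 2)
}

# noise-free forward-model TAC for a tissue class
fix_tac <- function(tissue = "cortex", sampling = "average") {
  model_tac(fix_input(), fix_params(tissue), fix_schedule(), sampling = sampling)
}

# small toy input: triangular bolus then plateau, piecewise linear
fix_toy_input <- function() {
  input_function(c(0, 1, 2, 60), c(0, 10, 2, 1))
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
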