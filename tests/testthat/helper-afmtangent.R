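# Shared fixtures: everything is generated in code, no data files.

rel_err <- function(x, ref) abs(x / ref - 1)

# The worked-example scale used throughout: soft gel, ~1 um sphere,
# sub-micrometre indentation.
example_params <- function(E = 132.5e3, v = 0.5, R = 0.921e-6) {
  contact_params(E = E, v = v, R = R)
}

# Printed cubic fit of the worked example (SI units) and its tangent inputs.
EXAMPLE_ABC <- c(281, -23340, -1.019e10)
EXAMPLE_HMAX <- 4.32e-7
EXAMPLE_S <- 0.2505
EXAMPLE_B <- -3.363e-8
EXAMPLE_HCOM <- 1.342e-7
EXAMPLE_R <- 0.921e-6
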