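# Shared helpers for the test suite.

# A flat (identically zero) pulsatile shape on a 100-point cycle.
flat_shape <- function(period = 1, n = 100) {
  tt <- seq(0, period - period / n, length.out = n)
  waveform(tt, rep(0, n), period = period, units = "normalized")
}

# A deterministic cardiac-like shape shared across tests.
demo_shape <- function(seed = 101) generate_waveform(seed = seed)

# Purely elastic material (no Prony branches) with a given shear modulus.
elastic_material <- function(shear = 216.44) {
  material_model(elastic_modulus = 2 * (1 + 0.35) * shear,
                 prony_g = numeric(0), prony_tau = numeric(0))
}
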