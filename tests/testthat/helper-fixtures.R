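# Reference fixtures used across tests: a 20 um square channel of 5 mm
# length, a water-like aqueous phase against light oil (gamma = 5 mN/m,
# hydrophobic 120 degree walls), and the rotor of the worked design case
# (5000 rpm, R1 = 18 mm, R2 = 6 mm, a = 6579.7 m/s^2).

ref_channel <- function(w = 20e-6, h = 20e-6, l = 5e-3) {
  channel_geometry(w, h, l)
}

ref_fluids <- function(theta_deg = 120, gamma = 5e-3) {
  fluid_system(1000, 1e-3, gamma, deg_to_rad(theta_deg))
}

ref_rotor <- function(omega = 523.599, r1 = 18e-3, r2 = 6e-3) {
  rotor_config(omega, r1, r2)
}

ref_condition <- function(...) {
  emul_condition(ref_channel(), ref_fluids(), ref_rotor(...))
}

# Noise-free resistance factors on the truth law, for fit-recovery tests
law_rf <- function(D, alpha, beta) alpha * exp(-beta * D)
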