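# Shared fixtures: the published figure-2 parameter set and a generic frame.

fig2_frame <- function() wave_frame(xi = 1, zeta = 4, Lambda1 = 1)
fig2_phis  <- function() reduced_coefficients(Phi1 = 1, Phi2 = 1, Lambda1 = 1)
fig2_aux   <- function() aux_params(sigma = 1, mu = 1, rho = 0.01,
                                    branch_signs = 1L)

generic_frame <- function() wave_frame(xi = 1, zeta = 2, Lambda1 = 1)

unit_params <- function(b0 = 1)
  physical_params(a0 = 1, h = 1, omega = 1, g = 1, Z = 1,
                  Gamma = 1, Delta = 1, b0 = b0)

# all catalogued chi entries of the given cases
chi_entries <- function(cases) {
  reg <- chi_registry()
  reg[reg$case_id %in% cases, , drop = FALSE]
}
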