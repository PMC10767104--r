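# random-but-valid inputs for property tests; callers set the seed

rand_params <- function() {
  flow_params(
    beta_F = runif(1, 0, 1.5),
    M = runif(1, 0, 2.5),
    beta_e = runif(1, 0, 3),
    beta_i = runif(1, 0, 3),
    G_R = runif(1, 0, 1),
    G_C = runif(1, 0, 1),
    Pr = runif(1, 0.5, 25),
    N_T = runif(1, 0, 2),
    N_B = runif(1, 0.2, 2),
    E_C = runif(1, 0, 0.3),
    Sc = runif(1, 0, 1),
    K_R = runif(1, 0, 1),
    Ra = runif(1, 0.1, 2),
    Fr = runif(1, 0.2, 2),
    Lambda = runif(1, 0, pi / 2))
}

rand_geometry <- function() {
  channel_geometry(
    a = runif(1, 0, 0.4),
    b = runif(1, 0, 0.4),
    m = runif(1, -0.2, 0.3),
    omega = runif(1, 0, pi),
    Theta = runif(1, 0.5, 2))
}

# parameters with every coupling off: the cascade's higher orders vanish and
# the zeroth-order cubic/ramp closed forms solve the full system exactly
decoupled_params <- function(Pr = 1) {
  flow_params(beta_F = 0, M = 0, beta_e = 0, beta_i = 0, G_R = 0, G_C = 0,
              Pr = Pr, N_T = 0, N_B = 0, E_C = 0, Sc = 0, K_R = 0)
}

flat_section <- function(F = 2) {
  cross_section(0, 0, channel_geometry(a = 0, b = 0, m = 0, omega = 0,
                                       Theta = F))
}
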