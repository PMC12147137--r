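# Shared fixtures: the shipped 14-member library and the default protocol.
test_lib <- default_library()
test_protocol <- build_default_protocol(library_offsets(test_lib))

# A random small sample for property-style simulator tests.  Offsets are
# kept within +-1.5 ppm so the independent ODE oracle can resolve the
# transverse oscillation at reasonable cost; all couplings (relaxation,
# exchange, RF, off-resonance) are still exercised.
random_small_sample <- function(npool, cfg = spectrometer_config()) {
  pools <- lapply(seq_len(npool), function(i) {
    t2f <- runif(1, 0.2, 1)
    t1f <- t2f + runif(1, 0.5, 2)
    lanthanide_pool(paste0("P", i),
                    delta_omega_ppm = runif(1, -1.5, 1.5),
                    f = runif(1, 1e-4, 0.01),
                    k_ex = runif(1, 100, 2000),
                    t1_free = t1f, t2_free = t2f,
                    t1_bound = t1f, t2_bound = runif(1, 0.005, 0.05))
  })
  t2f <- runif(1, 0.2, 1)
  ln_sample(pools, runif(max(npool, 1), 0.5, 2)[seq_len(npool)], cfg,
            t1_free = t2f + runif(1, 0.5, 2.5), t2_free = t2f)
}

# Independent oracle: adaptive ODE integration of dM/dt = A M.
ode_propagate <- function(state, A, t) {
  ode <- deSolve::lsoda(state, c(0, t),
                        function(tt, y, p) list(A %*% y),
                        rtol = 1e-11, atol = 1e-12, maxsteps = 1e6)
  as.numeric(ode[2, -1])
}

# Depth of the z-spectrum dip at one offset: 1 - z(offset).
dip_depth <- function(sample, offset_ppm, b1_uT = 2.87, t_sat = 4) {
  1 - simulate_zspectrum(sample, offset_ppm, b1_uT, t_sat)$z
}
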