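# paragest

Simulation and fingerprint-based identification of lanthanides sensed by
19F saturation-transfer NMR.

## The problem

A fluorinated guest molecule exchanges between free solution and the
cavities of lanthanide-chelating cyclodextrin hosts (Ln-α-CD).  Each
lanthanide's pseudocontact shift places the bound guest's 19F resonance at
a characteristic offset Δω, so saturating at Δω depletes the free-guest
signal through guest exchange (GEST, the supramolecular analog of CEST).
Reading the lanthanide content of a mixture off a densely sampled
z-spectrum is slow and subjective; the fingerprinting approach instead
acquires a fixed 40-point saturation schedule and matches the resulting
normalized signal trajectory against a dictionary of trajectories simulated
from the Bloch-McConnell equations for every candidate mixture.  The
package is aimed at magnetic-resonance and chemical-sensing researchers who
want to prototype such pipelines end to end without spectrometer data.

At its core are the coupled Bloch-McConnell equations for one free pool and
N bound pools in star topology.  Per pool p, with Δ_p = δ_p − ω_rf and
nutation frequency ω₁ = γB₁:

    dMx/dt = −Mx/T2p + Δp·My
    dMy/dt = −Δp·Mx − My/T2p + ω₁·Mz
    dMz/dt = −ω₁·My − (Mz − M0p)/T1p

with exchange at forward rate f_i·c_i·k_ex,i (free → bound i) and reverse
rate k_ex,i on all components.  The system is linear, so each saturation or
recovery segment is a matrix exponential, computed in compiled
(RcppArmadillo) code.  Matching uses cosine similarity (dot products of
L2-normalized trajectories) with R² = 1 − SS_res/SS_tot as data-model
fidelity, and per-pair parameters (T1, T2, Δω, f, k_ex) are extracted from
multi-power z-spectra by bounded multi-start Levenberg-Marquardt fitting.

The package provides:

* `build_default_protocol()` — the three-block 40-point acquisition scheme
  (1.75 µT and 2.87 µT blocks, 1–11 ppm sweep, 9.57 s recoveries);
* `simulate_zspectrum()` / `simulate_fingerprint()` — the forward model;
* `build_dictionary()` / `match_fingerprint()` / `fidelity_r2()` —
  combinatorial dictionary generation and pattern matching;
* `fit_zspectrum()` — stage-1 exchange-parameter extraction;
* `default_library()` / `generate_sample()` / `generate_noisy_fingerprint()`
  — a 14-lanthanide synthetic fixture library and noise model making every
  stage testable.

A thin command-line front end (`gen`, `build-dict`, `match`, `fit` —
`inst/cli/paragest.R`) wraps the same functions for shell use.

## Worked example

Identify a synthetic two-lanthanide "unknown" from a noisy fingerprint:

```r
library(paragest)
lib <- default_library()
protocol <- build_default_protocol(library_offsets(lib))

# a synthetic unknown: Dy + Nd at equal concentration, with noise
unknown <- generate_sample(c("Dy", "Nd"), c(1, 1), lib)
fp <- generate_noisy_fingerprint(unknown, protocol,
                                 noise_model(sigma = 0.005, seed = 7))

dict <- build_dictionary(lib, sizes = c(1, 2), grid = c(0.5, 1, 2),
                         protocol = protocol)
match_fingerprint(fp, dict, top_k = 3)
```

```
<match_result> best: Dy+Nd|1,1 (score 0.999980, R2 = 0.9997)
          key subset  conc     score
1   Dy+Nd|1,1  Dy+Nd   1,1 0.9999797
2 Dy+Nd|1,0.5  Dy+Nd 1,0.5 0.9993768
3   Dy+Nd|1,2  Dy+Nd   1,2 0.9992337
```

The generating hypothesis — the subset {Dy, Nd} at concentration factors
(1, 1) — ranks first with cosine score 0.99998; the runner-up entries are
the same subset at neighboring concentrations.  The fidelity R² = 0.9997 is
the coefficient of determination of the matched simulated trajectory
against the noisy input.  The fingerprint itself is a 40-vector of
normalized intensities in [0, 1] (plus noise), with depleted points where
the protocol saturates at the offsets of Dy (−28.6 ppm) and Nd (−1.2 ppm).

## Scientific background

The methods vignette (`vignettes/paragest-methods.Rmd`) documents the spin
model and its assumptions, the protocol and fixture-library design choices,
the numerical decisions in the simulator and the fitter, and the known
limitations of the synthetic noise model.
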