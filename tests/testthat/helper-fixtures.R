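# Shared miniature fixtures, generated in code at test time.

small_acq <- function(noise_sigma = 0, ...) {
  acquisition_config(noise_sigma = noise_sigma, ...)
}

small_truth <- function(dim = c(16, 16, 6), seed = 11, ...) {
  tissue_truth(dim = dim, seed = seed, lesion_radius_mm = 12, ...)
}

# concentration series built from a chosen 4D concentration array by passing
# the exact exponential signal through the converter (an exact inverse)
conc_from_curves <- function(conc4d, acq = small_acq()) {
  s <- acq$s0 * exp(-acq$te * conc4d)
  series <- list(signal = s, te = acq$te, dt = acq$dt,
                 baseline_frames = acq$baseline_frames)
  signal_to_concentration(series)
}

# a reference-like bolus curve on the acquisition time axis
bolus_curve <- function(acq = small_acq(), mtt = 4) {
  tt <- (seq_len(acq$n_frames) - 1) * acq$dt
  arrival <- acq$baseline_frames * acq$dt + 2
  aif <- aif_curve(tt, arrival = arrival)
  n <- length(tt)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, 1:i] <- aif[i:1]
  drop(acq$dt * (A %*% exp(-tt / mtt)))
}
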