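#' Convert DSC signal to concentration (ΔR2*) curves
#'
#' Per voxel, the baseline signal S0 is the mean of the pre-bolus frames and
#' `ΔR2*(t) = -log(S(t)/S0) / TE`. Voxels whose signal ever drops to zero or
#' below (or whose S0 is non-positive) cannot be log-transformed; they are
#' flagged invalid rather than raising an error, and all downstream fits
#' exclude them.
#'
#' @param series a `dsc_series` (see [simulate_dsc_signal()]), or any list
#'   with `signal` (4D array), `te`, `dt`, `baseline_frames`.
#' @param brain_mask logical 3D array; voxels outside are marked invalid.
#' @return a `concentration_series`: list with `conc` (4D ΔR2* array, 1/s),
#'   `time` (s), `dt`, `baseline_frames`, and `valid` (3D logical).
#' @export
signal_to_concentration <- function(series, brain_mask = NULL) {
  S <- series$signal
  stopifnot(length(dim(S)) == 4)
  d3 <- dim(S)[1:3]; nt <- dim(S)[4]
  if (is.null(brain_mask)) brain_mask <- array(TRUE, d3)
  if (!any(brain_mask)) stop("empty brain mask", call. = FALSE)
  if (nt < series$baseline_frames + 10)
    stop("time axis too short for baseline window", call. = FALSE)

  m <- matrix(S, nrow = prod(d3))                 # voxels x time
  bl <- seq_len(series$baseline_frames)
  s0 <- rowMeans(m[, bl, drop = FALSE])
  bad <- s0 <= 0 | apply(m <= 0, 1, any)
  valid <- array(as.vector(brain_mask) & !bad, d3)

  conc <- matrix(0, nrow = nrow(m), ncol = nt)
  ok <- which(as.vector(valid))
  conc[ok, ] <- -log(m[ok, , drop = FALSE] / s0[ok]) / series$te
  structure(list(conc = array(conc, c(d3, nt)),
                 time = (seq_len(nt) - 1) * series$dt,
                 dt = series$dt, baseline_frames = series$baseline_frames,
                 valid = valid),
            class = "concentration_series")
}

#' Reference concentration curve from the contralateral ROI
#'
#' Arithmetic mean ΔR2*(t) over the valid voxels of a reference mask placed
#' in normal-appearing contralateral white matter.
#'
#' @param conc a `concentration_series`.
#' @param reference_mask logical 3D array.
#' @return numeric vector, one value per frame.
#' @export
reference_curve <- function(conc, reference_mask) {
  stopifnot(inherits(conc, "concentration_series"))
  use <- reference_mask & conc$valid
  if (!any(use)) stop("no valid reference voxels", call. = FALSE)
  d <- dim(conc$conc)
  m <- matrix(conc$conc, nrow = prod(d[1:3]))
  colMeans(m[which(as.vector(use)), , drop = FALSE])
}

#' Voxelwise two-regressor leakage (K2) fit
#'
#' In tissue with a disrupted blood-brain barrier the voxel's concentration
#' curve returns toward baseline faster than normal tissue as gadolinium
#' extravasates. That relative change is captured by ordinary least squares
#' of each voxel curve on two regressors over the post-baseline frames: the
#' reference curve itself (coefficient K1, a dimensionless scaling) and the
#' negative running integral of the reference normalized by its total
#' integral (coefficient K2). The normalization makes K2 a dimensionless
#' decimal fraction. Negative K2 (T1-dominant leakage) is retained.
#'
#' Ischemic tissue receives the bolus late, and the two-regressor model is
#' only exact for arrival-aligned curves, so by default each voxel is fitted
#' against regressors shifted over a delay grid (`0` to `max_delay` s in
#' `delay_step` steps, linear interpolation between frames) and the shift
#' with the smallest residual sum of squares is kept (ties: smallest
#' delay). `align = FALSE` fits the unshifted regressors only.
#'
#' An intercept nuisance column (default on) absorbs residual baseline
#' offset — the small positive ΔR2* floor left by estimating S0 from finitely
#' many noisy baseline frames and by the curvature of the log transform —
#' which would otherwise couple into the ramp-shaped leakage regressor and
#' bias K2 downward at realistic SNR. It is reported as `b0` and subtracted
#' (with the leakage term) before CBV integration; on noiseless input it is
#' exactly zero.
#'
#' @param conc a `concentration_series`.
#' @param ref reference curve from [reference_curve()].
#' @param mask logical 3D array of voxels to fit (default: all valid).
#' @param align compensate per-voxel bolus arrival delay (default `TRUE`).
#' @param max_delay largest delay searched (s).
#' @param delay_step delay grid spacing (s).
#' @param intercept include the baseline-offset nuisance column.
#' @return a `leakage_fit`: list with `k1`, `k2`, `b0`, `rms`, `delay_s`
#'   (3D maps, `NA` outside the fitted set), `ref`, `leak_regressor` (full
#'   time axis, unshifted), `window` (post-baseline frame indices), `valid`
#'   (fitted-voxel mask), `dt`.
#' @export
fit_leakage <- function(conc, ref, mask = NULL, align = TRUE, max_delay = 12,
                        delay_step = 0.25, intercept = TRUE) {
  stopifnot(inherits(conc, "concentration_series"))
  if (all(ref == 0)) stop("reference curve is identically zero", call. = FALSE)
  d <- dim(conc$conc); d3 <- d[1:3]; nt <- d[4]
  if (is.null(mask)) mask <- array(TRUE, d3)
  w <- (conc$baseline_frames + 1):nt
  tot <- trapz(ref, conc$dt)
  leak <- -cumtrapz(ref, conc$dt) / tot
  shifts <- if (align) seq(0, max_delay, by = delay_step) else 0

  use <- mask & conc$valid
  idx <- which(as.vector(use))
  m <- matrix(conc$conc, nrow = prod(d3))
  Y <- t(m[idx, w, drop = FALSE])                 # frames x voxels
  yy <- colSums(Y^2)
  nv <- length(idx)
  best_rss <- rep(Inf, nv)
  b1 <- b2 <- bb0 <- rep(NA_real_, nv)
  del <- rep(NA_real_, nv)
  for (s in shifts) {
    refs <- drop(shift_curves(matrix(ref, ncol = 1), conc$dt, s))
    leaks <- drop(shift_curves(matrix(leak, ncol = 1), conc$dt, s))
    X <- cbind(refs[w], leaks[w])
    if (intercept) X <- cbind(X, 1)
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-12) {
      if (s == 0)
        stop("singular leakage design (reference proportional to its integral)",
             call. = FALSE)
      next
    }
    B <- solve(XtX, crossprod(X, Y))              # coefs x voxels
    rss <- yy - colSums((X %*% B) * Y)
    upd <- rss < best_rss - 1e-12 * pmax(yy, 1)   # strict: ties keep smaller s
    if (any(upd)) {
      best_rss[upd] <- rss[upd]
      b1[upd] <- B[1, upd]; b2[upd] <- B[2, upd]
      bb0[upd] <- if (intercept) B[3, upd] else 0
      del[upd] <- s
    }
  }
  k1 <- k2 <- b0 <- rms <- delay_s <- array(NA_real_, d3)
  k1[idx] <- b1; k2[idx] <- b2; b0[idx] <- bb0; delay_s[idx] <- del
  rms[idx] <- sqrt(pmax(best_rss, 0) / length(w))
  structure(list(k1 = k1, k2 = k2, b0 = b0, rms = rms, delay_s = delay_s,
                 ref = ref, leak_regressor = leak, window = w, valid = use,
                 dt = conc$dt),
            class = "leakage_fit")
}

#' Leakage-corrected, contralateral-normalized CBV ratio map
#'
#' Voxel CBV is the trapezoidal integral over the post-baseline frames of the
#' leakage-corrected curve (ΔR2* minus the fitted K2 leakage term); the map
#' is normalized by the mean corrected CBV over the reference mask, so the
#' contralateral ROI averages exactly 1. Negative corrected integrals are
#' retained (flagged in the QC count), not clipped.
#'
#' @param conc a `concentration_series`.
#' @param fit a `leakage_fit`.
#' @param reference_mask logical 3D array (the normalization ROI).
#' @param mask voxels to map (default: fitted voxels).
#' @return 3D `cbv_ratio` map (`NA` outside), with attributes
#'   `reference_cbv` (mean reference integral, pre-normalization) and
#'   `n_negative` (QC count of negative corrected integrals).
#' @export
compute_cbv_ratio <- function(conc, fit, reference_mask, mask = NULL) {
  stopifnot(inherits(conc, "concentration_series"), inherits(fit, "leakage_fit"))
  d <- dim(conc$conc); d3 <- d[1:3]
  if (is.null(mask)) mask <- fit$valid
  use <- mask & fit$valid
  idx <- which(as.vector(use))
  w <- fit$window
  m <- matrix(conc$conc, nrow = prod(d3))
  # corrected curve = conc - K2 * leak_regressor - b0, with the regressor
  # shifted by the voxel's fitted arrival delay
  corr <- t(m[idx, w, drop = FALSE]) -
    matrix(fit$b0[idx], nrow = length(w), ncol = length(idx), byrow = TRUE)
  for (s in unique(fit$delay_s[idx])) {
    leaks <- drop(shift_curves(matrix(fit$leak_regressor, ncol = 1),
                               fit$dt, s))
    cols <- fit$delay_s[idx] == s
    corr[, cols] <- corr[, cols, drop = FALSE] -
      outer(leaks[w], fit$k2[idx][cols])
  }
  cbv <- trapz(corr, conc$dt)
  cbv_map <- array(NA_real_, d3)
  cbv_map[idx] <- cbv

  ref_idx <- which(as.vector(reference_mask & fit$valid))
  if (length(ref_idx) == 0) stop("no valid reference voxels", call. = FALSE)
  ref_cbv <- mean(cbv_map[ref_idx])
  if (!is.finite(ref_cbv) || ref_cbv <= 0)
    stop("non-positive reference CBV; cannot normalize", call. = FALSE)
  out <- cbv_map / ref_cbv
  attr(out, "reference_cbv") <- ref_cbv
  attr(out, "n_negative") <- sum(cbv < 0)
  out
}

#' Tmax map by truncated-SVD deconvolution
#'
#' Each voxel curve is deconvolved by the arterial input function using the
#' Toeplitz formulation; singular values below `lambda` times the largest are
#' discarded. Tmax is the time of the maximum of the recovered residue
#' function, quantized to the frame interval.
#'
#' @param conc a `concentration_series`.
#' @param aif arterial input function sampled on the same time axis.
#' @param mask voxels to map (default: valid voxels).
#' @param lambda relative singular-value cutoff (default 0.15).
#' @return 3D map of Tmax in seconds (`NA` outside the mask).
#' @export
compute_tmax <- function(conc, aif, mask = NULL, lambda = 0.15) {
  stopifnot(inherits(conc, "concentration_series"))
  if (max(aif) <= 0 || diff(range(aif)) < 1e-12 * max(abs(aif)))
    stop("flat or non-positive AIF", call. = FALSE)
  d <- dim(conc$conc); d3 <- d[1:3]; nt <- d[4]
  if (is.null(mask)) mask <- conc$valid
  use <- mask & conc$valid
  idx <- which(as.vector(use))

  n <- nt
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, 1:i] <- aif[i:1]
  A <- A * conc$dt
  sv <- svd(A)
  keep <- sv$d >= lambda * max(sv$d)
  Ainv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])

  m <- matrix(conc$conc, nrow = prod(d3))
  Rhat <- Ainv %*% t(m[idx, , drop = FALSE])      # frames x voxels
  tmax <- array(NA_real_, d3)
  tmax[idx] <- (max.col(t(Rhat), ties.method = "first") - 1) * conc$dt
  tmax
}

#' Bundle voxelwise parameter maps on a shared grid
#'
#' @param cbv_ratio,k2,tmax,adc 3D maps (ADC passed through from diffusion).
#' @param valid logical 3D mask of voxels with trustworthy fits.
#' @return a `parameter_maps` list.
#' @export
parameter_maps <- function(cbv_ratio, k2, tmax, adc, valid) {
  stopifnot(identical(dim(cbv_ratio), dim(k2)),
            identical(dim(cbv_ratio), dim(tmax)),
            identical(dim(cbv_ratio), dim(adc)))
  structure(list(cbv_ratio = cbv_ratio, k2 = k2, tmax = tmax, adc = adc,
                 valid = valid),
            class = "parameter_maps")
}
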