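#' DSC acquisition settings for the synthetic scanner
#'
#' Describes the dynamic susceptibility contrast (DSC) acquisition the
#' generator emulates: a T2*-weighted EPI series of `n_frames` volumes every
#' `dt` seconds with echo time `te`, the first `baseline_frames` volumes
#' acquired before contrast arrival. The acquisition must span at least 45 s
#' (first-pass bolus, recirculation and return toward baseline).
#'
#' @param te echo time in seconds.
#' @param dt frame interval in seconds.
#' @param n_frames number of dynamic frames.
#' @param baseline_frames pre-bolus frames used to estimate S0 (>= 3).
#' @param noise_sigma SD of additive Gaussian noise, in signal units
#'   (baseline signal is `s0`; SNR = s0/noise_sigma).
#' @param s0 baseline signal level.
#' @param cref_peak peak concentration (ΔR2*, 1/s) of the normal-tissue
#'   reference curve; sets the contrast dose / signal-drop depth.
#' @return an `acquisition_config` list.
#' @export
acquisition_config <- function(te = 0.045, dt = 1.5, n_frames = 40,
                               baseline_frames = 8, noise_sigma = 0,
                               s0 = 100, cref_peak = 8) {
  if (te <= 0 || dt <= 0) stop_config("te and dt must be positive")
  if (n_frames * dt < 45)
    stop_config("acquisition must cover at least 45 s (got %.1f s)", n_frames * dt)
  if (baseline_frames < 3) stop_config("baseline_frames must be >= 3")
  if (n_frames < baseline_frames + 10)
    stop_config("need at least 10 post-baseline frames")
  if (noise_sigma < 0) stop_config("noise_sigma must be >= 0")
  structure(list(te = te, dt = dt, n_frames = n_frames,
                 baseline_frames = baseline_frames,
                 noise_sigma = noise_sigma, s0 = s0, cref_peak = cref_peak),
            class = "acquisition_config")
}

#' Gamma-variate arterial input function with recirculation
#'
#' First-pass bolus as a unit-peak gamma variate arriving at `arrival`,
#' plus a scaled, delayed copy standing in for recirculation; the sum decays
#' back toward baseline over the rest of the acquisition.
#'
#' @param t sample times (s).
#' @param arrival bolus arrival time (s).
#' @param shape,scale gamma-variate shape and scale (peak at
#'   `arrival + shape*scale`).
#' @param recirc_amp amplitude of the recirculation pass relative to the
#'   first pass (default 0.3).
#' @param recirc_delay delay of the recirculation pass (default 12 s).
#' @return numeric vector of AIF samples (unit first-pass peak).
#' @export
aif_curve <- function(t, arrival = 14, shape = 3, scale = 1.5,
                      recirc_amp = 0.3, recirc_delay = 12) {
  g <- function(tt) {
    u <- pmax(tt - arrival, 0) / (shape * scale)
    ifelse(tt > arrival, u^shape * exp(shape * (1 - u)), 0)
  }
  g(t) + recirc_amp * g(t - recirc_delay)
}

#' Ground-truth tissue parameter maps for one synthetic patient
#'
#' Builds the voxelwise "truth" the DSC simulator and all downstream recovery
#' tests refer to: an ellipsoidal brain, a spherical ischemic lesion in the
#' left hemisphere and a mirrored contralateral normal-appearing
#' white-matter reference region. Within the lesion, CBV, ADC and K2 are
#' drawn so that the lesion's 10th/10th/90th percentiles match the requested
#' per-patient targets (`cbv10`, `adc10`, `k2_90`); contralateral CBV is
#' recentred to mean exactly 1 (it is the normalization reference).
#'
#' @param dim grid size in voxels (default 64 x 64 x 16).
#' @param voxmm voxel size in mm (default 2 x 2 x 5, i.e. 0.02 mL/voxel).
#' @param cbv10,adc10,k2_90 per-patient generating feature targets: lesion
#'   10th percentile CBV ratio, 10th percentile ADC (1e-6 mm^2/s) and 90th
#'   percentile K2 (decimal).
#' @param lesion_delay bolus arrival delay inside the lesion (s).
#' @param lesion_radius_mm lesion sphere radius (mm).
#' @param sd_vox within-lesion voxel SDs, list with `cbv`, `adc`, `k2`.
#' @param mtt0 reference-tissue mean transit time (s).
#' @param seed optional RNG seed (otherwise inherits the caller's stream).
#' @return a `tissue_truth` list: `adc_map`, `cbf_map`, `cbv_true`,
#'   `k2_true`, `delay_map`, `dwi` (b=1000-like image), `lesion_mask`,
#'   `contralateral_mask`, `brain_mask`, `voxmm`, `mtt0`.
#' @export
tissue_truth <- function(dim = c(64, 64, 16), voxmm = c(2, 2, 5),
                         cbv10 = 0.40, adc10 = 320, k2_90 = 0.32,
                         lesion_delay = 8, lesion_radius_mm = 16,
                         sd_vox = list(cbv = 0.15, adc = 120, k2 = 0.08),
                         mtt0 = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(dim) == 3, all(dim >= 5), all(voxmm > 0))
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  xs <- (seq_len(nx) - 0.5) * voxmm[1]
  ys <- (seq_len(ny) - 0.5) * voxmm[2]
  zs <- (seq_len(nz) - 0.5) * voxmm[3]
  ctr <- c(nx, ny, nz) * voxmm / 2
  ax <- 0.46 * c(nx, ny, nz) * voxmm
  X <- array(rep(xs, times = ny * nz), dim)
  Y <- array(rep(rep(ys, each = nx), times = nz), dim)
  Z <- array(rep(zs, each = nx * ny), dim)
  brain <- ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
    ((Z - ctr[3]) / ax[3])^2 <= 1

  sphere <- function(cx) {
    (X - cx[1])^2 + (Y - cx[2])^2 + (Z - cx[3])^2 <= lesion_radius_mm^2
  }
  les_ctr <- c(ctr[1] * 0.5, ctr[2], ctr[3])
  lesion <- sphere(les_ctr) & brain
  # contralateral normal white matter: mirrored centre, fixed 10 mm radius
  ref_ctr <- c(2 * ctr[1] - les_ctr[1], ctr[2], ctr[3])
  contra <- ((X - ref_ctr[1])^2 + (Y - ref_ctr[2])^2 +
               (Z - ref_ctr[3])^2 <= 10^2) & brain & !lesion
  stopifnot(sum(lesion) > 0, sum(contra) > 0, !any(lesion & contra))

  z90 <- stats::qnorm(0.9)            # maps a percentile target to the mean
  nvox <- prod(dim)
  nles <- sum(lesion); ncon <- sum(contra)

  cbv <- array(0, dim)
  cbv[brain] <- stats::rnorm(sum(brain), 1, 0.05)
  cbv[lesion] <- pmax(stats::rnorm(nles, cbv10 + z90 * sd_vox$cbv, sd_vox$cbv),
                      0.02)
  cbv[contra] <- cbv[contra] - mean(cbv[contra]) + 1   # exact unit mean

  adc <- array(0, dim)
  adc[brain] <- stats::rnorm(sum(brain), 750, 60)
  adc[lesion] <- pmax(stats::rnorm(nles, adc10 + z90 * sd_vox$adc, sd_vox$adc),
                      50)

  k2 <- array(0, dim)
  k2[lesion] <- stats::rnorm(nles, k2_90 - z90 * sd_vox$k2, sd_vox$k2)

  # CBF in contralateral-normalized units. CBF tracks CBV everywhere so the
  # mean transit time is uniformly mtt0: every voxel's bolus passage is then
  # a scaled, delayed copy of the reference — the regime in which the
  # two-regressor leakage model is exactly specified (see vignette).
  cbf <- array(0, dim)
  cbf[brain] <- cbv[brain]

  delay <- array(0, dim)
  delay[lesion] <- lesion_delay

  dwi <- array(0, dim)
  dwi[brain] <- stats::rnorm(sum(brain), 100, 5)
  dwi[lesion] <- dwi[lesion] + 40     # diffusion hyperintensity

  structure(list(adc_map = adc, cbf_map = cbf, cbv_true = cbv, k2_true = k2,
                 delay_map = delay, dwi = dwi,
                 lesion_mask = lesion, contralateral_mask = contra,
                 brain_mask = brain, voxmm = voxmm, mtt0 = mtt0),
            class = "tissue_truth")
}

#' Simulate a DSC signal series from ground-truth tissue maps
#'
#' Per voxel, the concentration (ΔR2*) curve is
#' `cbf * (AIF ⊛ R)(t - delay) + k2_true * L(t)` where `R(t) = exp(-t/MTT)`
#' with `MTT = mtt0 * cbv_true / cbf` (so the curve integral is proportional
#' to `cbv_true`), the AIF is a gamma variate with a delayed 0.3-amplitude
#' recirculation pass, and `L(t) = -cumint(ref)/totint(ref)` is the same
#' normalized leakage regressor the K2 fit uses — ground-truth K2 is thereby
#' defined in the fitted units. Signal follows the T2* relation
#' `S = s0 * exp(-te * c)` plus additive Gaussian noise.
#'
#' @param truth a [tissue_truth()] object.
#' @param acq an [acquisition_config()].
#' @param seed optional RNG seed for the noise draw.
#' @return a `dsc_series`: list with 4D `signal`, `te`, `dt`,
#'   `baseline_frames`, plus the generating `aif` and noiseless reference
#'   curve `cref` as attributes (used by Tmax deconvolution and QC).
#' @export
simulate_dsc_signal <- function(truth, acq, seed = NULL) {
  stopifnot(inherits(truth, "tissue_truth"), inherits(acq, "acquisition_config"))
  if (!is.null(seed)) set.seed(seed)
  tt <- (seq_len(acq$n_frames) - 1) * acq$dt
  arrival <- acq$baseline_frames * acq$dt + 2
  aif_raw <- aif_curve(tt, arrival = arrival)

  conv_mat <- function(a) {          # lower-triangular Toeplitz, c = A %*% r
    n <- length(a)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) A[i, 1:i] <- a[i:1]
    acq$dt * A
  }
  A_raw <- conv_mat(aif_raw)
  cref_raw <- as.vector(A_raw %*% exp(-tt / truth$mtt0))  # unit cbv/cbf reference
  sc <- acq$cref_peak / max(cref_raw)
  aif <- aif_raw * sc
  A <- A_raw * sc
  cref <- cref_raw * sc
  leak <- -cumtrapz(cref, acq$dt) / trapz(cref, acq$dt)

  dims <- dim(truth$cbv_true)
  idx <- which(truth$brain_mask & truth$cbf_map > 0)
  mtt <- truth$mtt0 * truth$cbv_true[idx] / truth$cbf_map[idx]
  R <- exp(-outer(tt, mtt, "/"))                       # T x V residue matrix
  C <- (A %*% R) * rep(truth$cbf_map[idx], each = acq$n_frames)
  C <- C + outer(leak, truth$k2_true[idx])
  # the bolus delay shifts the whole tracer curve, leakage included
  for (d in setdiff(unique(truth$delay_map[idx]), 0)) {
    cols <- truth$delay_map[idx] == d
    C[, cols] <- shift_curves(C[, cols, drop = FALSE], acq$dt, d)
  }

  S <- array(acq$s0, dim = c(dims, acq$n_frames))
  sig <- acq$s0 * exp(-acq$te * C)
  frame_stride <- prod(dims)
  for (f in seq_len(acq$n_frames)) {
    S[idx + (f - 1) * frame_stride] <- sig[f, ]
  }
  if (acq$noise_sigma > 0) {
    S <- S + array(stats::rnorm(length(S), 0, acq$noise_sigma), dim = dim(S))
  }
  structure(list(signal = S, te = acq$te, dt = acq$dt,
                 baseline_frames = acq$baseline_frames),
            class = "dsc_series", aif = aif, cref = cref)
}

#' Cohort-level configuration for the synthetic trial
#'
#' Defaults reproduce the analysed trial cohort: 83 patients of whom 20
#' develop parenchymal hemorrhage (24% prevalence). Group feature
#' distributions (generating CBV10 / ADC10 / K2_90 per arm) default to values
#' derived a priori from the published single-classifier operating points
#' (threshold, sensitivity, specificity) under a normal model — see the
#' methods vignette for the inversion. Clinical covariates are drawn
#' independently of the PH label (no clinical variable predicted PH).
#'
#' @param n_patients cohort size (default 83).
#' @param n_ph number of PH-positive patients (default 20).
#' @param feat_ph,feat_noph per-group generating distributions: named list
#'   with `cbv10`, `adc10`, `k2_90`, each `c(mean, sd)`.
#' @param label_mode `"group"` (labels drawn first, exactly `n_ph` positive,
#'   features from the per-group distributions) or `"published_logistic"`
#'   (features from the prevalence-weighted mixture; label = published
#'   logistic decision rule on the generating features — used for pipeline
#'   fidelity checks, where `n_ph` only sets the mixture weight).
#' @param grid_dim,voxmm imaging grid passed to [tissue_truth()] when
#'   volumes are simulated.
#' @param lesion_radius_range per-patient lesion radius range (mm), drawn
#'   uniformly.
#' @param seed RNG seed recorded in the config.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 83, n_ph = 20,
                          feat_ph = list(cbv10 = c(0.2526, 0.12),
                                         adc10 = c(244.3, 90),
                                         k2_90 = c(0.4338, 0.12)),
                          feat_noph = list(cbv10 = c(0.5797, 0.25),
                                           adc10 = c(344.2, 110),
                                           k2_90 = c(0.2487, 0.12)),
                          label_mode = c("group", "published_logistic"),
                          grid_dim = c(64, 64, 16), voxmm = c(2, 2, 5),
                          lesion_radius_range = c(12, 20), seed = 20170222) {
  label_mode <- match.arg(label_mode)
  if (n_ph <= 0 || n_ph >= n_patients)
    stop_config("need 0 < n_ph < n_patients")
  for (g in list(feat_ph, feat_noph)) {
    stopifnot(all(c("cbv10", "adc10", "k2_90") %in% names(g)))
    if (any(vapply(g, function(p) p[2] < 0, logical(1))))
      stop_config("negative SD in feature distribution")
  }
  structure(list(n_patients = n_patients, n_ph = n_ph,
                 feat_ph = feat_ph, feat_noph = feat_noph,
                 label_mode = label_mode, grid_dim = grid_dim, voxmm = voxmm,
                 lesion_radius_range = lesion_radius_range, seed = seed),
            class = "cohort_config")
}

#' Fixed column order of the cohort table
#' @keywords internal
cohort_columns <- function() {
  c("patient_id", "age", "sex_male", "hypertension", "diabetes", "sbp",
    "nihss", "iv_tpa", "thrombectomy", "penumbral_pattern",
    "cbv_p10", "adc_p10", "k2_p90", "core_volume_ml", "tmax6_volume_ml",
    "global_reperfusion", "ph_label")
}

#' Generate a synthetic cohort table (and optional imaging truths)
#'
#' Draws per-patient generating features and clinical covariates. In the
#' returned table the feature columns hold the generating (ground-truth)
#' targets; when the imaging pipeline is run they are re-measured from
#' simulated volumes. Clinical covariate distributions follow the trial's
#' reported demographics (age 66 ± 15.2 y, 45/83 men, NIHSS median 17,
#' IV tPA 31/83, thrombectomy 41/83).
#'
#' @param cfg a [cohort_config()].
#' @param truths if `TRUE`, also return a list of [tissue_truth()] objects,
#'   one per patient (memory scales with `n_patients * prod(grid_dim)`).
#' @return a data.frame in [cohort_columns()] order, with the `tissue_truth`
#'   list attached as attribute `"truths"` when requested and the seed as
#'   attribute `"seed"`.
#' @export
generate_cohort <- function(cfg, truths = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients

  draw_feats <- function(g, m) {
    data.frame(
      cbv_p10 = pmax(stats::rnorm(m, g$cbv10[1], g$cbv10[2]), 0.05),
      adc_p10 = pmax(stats::rnorm(m, g$adc10[1], g$adc10[2]), 50),
      k2_p90  = pmax(stats::rnorm(m, g$k2_90[1], g$k2_90[2]), 0))
  }

  if (cfg$label_mode == "group") {
    ph <- integer(n)
    ph[sample.int(n, cfg$n_ph)] <- 1L
    feats <- draw_feats(cfg$feat_noph, n)
    if (any(ph == 1L)) feats[ph == 1L, ] <- draw_feats(cfg$feat_ph, sum(ph))
  } else {
    from_ph <- stats::rbinom(n, 1, cfg$n_ph / n)
    feats <- draw_feats(cfg$feat_noph, n)
    if (any(from_ph == 1L))
      feats[from_ph == 1L, ] <- draw_feats(cfg$feat_ph, sum(from_ph))
    sc <- logistic_score_value(feats$cbv_p10, feats$k2_p90)
    ph <- as.integer(sc >= published_logistic()$threshold)
  }

  tab <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(pmin(pmax(stats::rnorm(n, 66, 15.2), 18), 85)),
    sex_male = stats::rbinom(n, 1, 45 / 83),
    hypertension = stats::rbinom(n, 1, 0.60),
    diabetes = stats::rbinom(n, 1, 0.25),
    sbp = round(stats::rnorm(n, 145, 20)),
    nihss = pmin(pmax(round(stats::rnorm(n, 17, 5)), 6), 29),
    iv_tpa = stats::rbinom(n, 1, 31 / 83),
    thrombectomy = stats::rbinom(n, 1, 41 / 83),
    penumbral_pattern = stats::rbinom(n, 1, 0.58),
    feats,
    core_volume_ml = NA_real_,
    tmax6_volume_ml = NA_real_,
    global_reperfusion = NA_integer_,
    ph_label = ph)
  tab <- tab[, cohort_columns()]

  if (truths) {
    radius <- stats::runif(n, cfg$lesion_radius_range[1],
                           cfg$lesion_radius_range[2])
    tl <- lapply(seq_len(n), function(i) {
      tissue_truth(dim = cfg$grid_dim, voxmm = cfg$voxmm,
                   cbv10 = tab$cbv_p10[i], adc10 = tab$adc_p10[i],
                   k2_90 = tab$k2_p90[i], lesion_radius_mm = radius[i])
    })
    attr(tab, "truths") <- tl
  }
  attr(tab, "seed") <- cfg$seed
  tab
}
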