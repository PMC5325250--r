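#' Label connected components of a binary 3D mask
#'
#' Breadth-first labelling with 26- or 6-connectivity. Used for the
#' largest-component rule and hole filling of the lesion VOI.
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @return integer array of component labels (0 = background).
#' @keywords internal
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  todo <- which(mask)
  if (length(todo) == 0) return(lab)
  cur <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier) > 0) {
      co <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
        sweep(co, 2, offs[k, ], "+")
      }))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * d[1] +
                      (nb[, 3] - 1L) * d[1] * d[2])
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- cur
      frontier <- lin
    }
  }
  lab
}

# fill cavities: 6-connected background components not touching the border
fill_holes <- function(mask) {
  d <- dim(mask)
  lab <- label_components(!mask, connectivity = 6)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  mask | (lab != 0L & !(lab %in% border))
}

# translate a 3D volume by an integer voxel shift: out[i] = vol[i + s]
translate_volume <- function(vol, s) {
  d <- dim(vol)
  out <- array(NA_real_, d)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) + s[a]
    i[i < 1 | i > d[a]] <- NA
    i
  })
  okx <- !is.na(src[[1]]); oky <- !is.na(src[[2]]); okz <- !is.na(src[[3]])
  out[okx, oky, okz] <- vol[src[[1]][okx], src[[2]][oky], src[[3]][okz]]
  out
}

mutual_information <- function(a, b, nbins, breaks_a, breaks_b) {
  ia <- findInterval(a, breaks_a, all.inside = TRUE)
  ib <- findInterval(b, breaks_b, all.inside = TRUE)
  joint <- tabulate(ia + (ib - 1L) * nbins, nbins * nbins) / length(a)
  jm <- matrix(joint, nbins, nbins)
  px <- rowSums(jm); py <- colSums(jm)
  nz <- jm > 0
  sum(jm[nz] * log(jm[nz] / (px[row(jm)[nz]] * py[col(jm)[nz]])))
}

#' Translation-only mutual-information registration
#'
#' Exhaustive search over integer voxel shifts within `±search_radius` per
#' axis, scoring each candidate by the mutual information of a 32-bin joint
#' intensity histogram over the overlap region. Ties are broken toward the
#' smaller shift magnitude, then lexicographic axis order. If the MI surface
#' has no clear peak (score of the best shift less than 4 SD above the mean
#' over all candidates, as happens for unrelated images), the result is
#' flagged low-confidence.
#'
#' @param moving,fixed 3D arrays on the same grid spacing.
#' @param search_radius maximum shift per axis, voxels.
#' @param nbins histogram bins per image (default 32).
#' @return list with `shift` (integer 3-vector such that
#'   `aligned[i] = moving[i + shift]` matches `fixed`), `aligned` volume
#'   (`NA` where the shift leaves no data), `mi` of the chosen shift, and
#'   `low_confidence` flag.
#' @export
register_translation <- function(moving, fixed, search_radius = 3, nbins = 32) {
  stopifnot(identical(dim(moving), dim(fixed)))
  r <- search_radius
  breaks_f <- seq(min(fixed), max(fixed), length.out = nbins + 1)
  breaks_m <- seq(min(moving), max(moving), length.out = nbins + 1)
  d <- dim(fixed)
  shifts <- as.matrix(expand.grid(sx = -r:r, sy = -r:r, sz = -r:r))
  score <- rep(NA_real_, nrow(shifts))
  for (k in seq_len(nrow(shifts))) {
    s <- shifts[k, ]
    rng <- lapply(1:3, function(a) max(1, 1 - s[a]):min(d[a], d[a] - s[a]))
    if (any(vapply(rng, length, 1L) == 0)) next    # empty overlap: invalid
    fsub <- fixed[rng[[1]], rng[[2]], rng[[3]]]
    msub <- moving[rng[[1]] + s[1], rng[[2]] + s[2], rng[[3]] + s[3]]
    score[k] <- mutual_information(fsub, msub, nbins, breaks_f, breaks_m)
  }
  ok <- which(is.finite(score))
  best_mi <- max(score[ok])
  cand <- ok[score[ok] == best_mi]
  if (length(cand) > 1) {                          # tie-break
    mag <- rowSums(abs(shifts[cand, , drop = FALSE]))
    cand <- cand[mag == min(mag)]
    cand <- cand[order(shifts[cand, 1], shifts[cand, 2], shifts[cand, 3])][1]
  }
  s <- unname(shifts[cand[1], ])
  mu <- mean(score[ok]); sd_ <- stats::sd(score[ok])
  low_conf <- !is.finite(sd_) || sd_ == 0 || (best_mi - mu) / sd_ < 4
  list(shift = s, aligned = translate_volume(moving, s), mi = best_mi,
       low_confidence = low_conf)
}

#' Extract the diffusion-hyperintense lesion VOI
#'
#' Voxels whose DWI intensity exceeds `z_thr` standard deviations above the
#' contralateral reference mean are candidates; the largest 26-connected
#' component is retained and interior holes are filled, subsuming the entire
#' diffusion-hyperintense region. No voxel above threshold yields an empty
#' VOI (downstream feature extraction refuses it, but no error is raised
#' here).
#'
#' @param dwi 3D diffusion-weighted image.
#' @param brain_mask,contralateral_mask logical 3D arrays.
#' @param z_thr z-score threshold (default 2.0).
#' @param connectivity component connectivity (default 26).
#' @return a `lesion_voi`: list with `lesion_mask`, `contralateral_mask`,
#'   `provenance` (method + all parameters).
#' @export
extract_voi <- function(dwi, brain_mask, contralateral_mask, z_thr = 2,
                        connectivity = 26) {
  mu <- mean(dwi[contralateral_mask]); sd_ <- stats::sd(dwi[contralateral_mask])
  if (!is.finite(mu) || !is.finite(sd_))
    stop("degenerate reference region", call. = FALSE)
  # a perfectly uniform image has no hyperintensity: empty VOI, not an error
  cand <- if (sd_ == 0) array(FALSE, dim(dwi)) else
    brain_mask & (dwi - mu) / sd_ > z_thr
  if (any(cand)) {
    lab <- label_components(cand, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    lesion <- fill_holes(lab == which.max(sizes))
  } else {
    lesion <- array(FALSE, dim(dwi))
  }
  lesion <- lesion & !contralateral_mask          # masks stay disjoint
  structure(list(lesion_mask = lesion,
                 contralateral_mask = contralateral_mask,
                 provenance = list(method = "dwi_zscore", z_thr = z_thr,
                                   connectivity = connectivity,
                                   ref_mean = mu, ref_sd = sd_,
                                   n_voxels = sum(lesion))),
            class = "lesion_voi")
}

#' Percentile features of the lesion VOI
#'
#' The per-patient summary the predictive models consume: the 10th
#' percentile of CBV ratio and ADC (the lowest representation of each) and
#' the 90th percentile of K2 (the highest), computed over the lesion VOI
#' with linear interpolation between order statistics.
#'
#' @param maps a [parameter_maps()] object.
#' @param voi a `lesion_voi`.
#' @return named numeric vector `c(cbv_p10, adc_p10, k2_p90)`.
#' @export
percentile_features <- function(maps, voi) {
  stopifnot(inherits(maps, "parameter_maps"), inherits(voi, "lesion_voi"))
  if (!any(voi$lesion_mask)) stop("empty lesion VOI", call. = FALSE)
  use <- voi$lesion_mask & maps$valid
  if (!any(use)) stop("all VOI voxels flagged invalid", call. = FALSE)
  q <- function(x, p) unname(stats::quantile(x[use], p, type = 7, names = FALSE))
  c(cbv_p10 = q(maps$cbv_ratio, 0.10),
    adc_p10 = q(maps$adc, 0.10),
    k2_p90 = q(maps$k2, 0.90))
}

#' Infarct core volume from the ADC map
#'
#' Counts in-mask voxels with ADC strictly below 600 x 1e-6 mm^2/s and
#' multiplies by the voxel volume. Warns if the in-mask median ADC falls
#' outside 200-2000, which usually indicates a unit mismatch.
#'
#' @param adc 3D ADC map in 1e-6 mm^2/s.
#' @param brain_mask logical 3D array.
#' @param voxel_volume_ml volume of one voxel in mL.
#' @param threshold core threshold (default 600).
#' @return core volume in mL.
#' @export
core_volume <- function(adc, brain_mask, voxel_volume_ml, threshold = 600) {
  med <- stats::median(adc[brain_mask])
  if (!is.finite(med) || med < 200 || med > 2000)
    warning("median brain ADC ", round(med),
            " outside 200-2000; check units (expect 1e-6 mm^2/s)")
  sum(adc < threshold & brain_mask, na.rm = TRUE) * voxel_volume_ml
}

#' Perfusion-lesion volume and the global-reperfusion flag
#'
#' The perfusion lesion is Tmax >= 6 s (inclusive). Successful global
#' reperfusion is a reduction of at least 90% in that volume from baseline
#' to follow-up (follow-up exactly 10% of baseline counts as reperfused).
#' Without a follow-up map the flag is absent (`NA`).
#'
#' @param tmax_baseline 3D Tmax map (s).
#' @param tmax_followup optional follow-up Tmax map.
#' @param voxel_volume_ml volume of one voxel in mL.
#' @param mask optional logical mask restricting the count.
#' @param threshold Tmax cut in seconds (default 6, inclusive).
#' @return list with `tmax6_volume_ml`, `global_reperfusion` (logical or
#'   `NA`), and `flag` (`"undefined_baseline"` when baseline volume is zero
#'   but follow-up was supplied).
#' @export
tmax_volume_and_reperfusion <- function(tmax_baseline, tmax_followup = NULL,
                                        voxel_volume_ml, mask = NULL,
                                        threshold = 6) {
  if (is.null(mask)) mask <- array(TRUE, dim(tmax_baseline))
  vol <- function(m) sum(m >= threshold & mask, na.rm = TRUE) * voxel_volume_ml
  v0 <- vol(tmax_baseline)
  if (is.null(tmax_followup))
    return(list(tmax6_volume_ml = v0, global_reperfusion = NA, flag = NULL))
  if (v0 == 0)
    return(list(tmax6_volume_ml = v0, global_reperfusion = NA,
                flag = "undefined_baseline"))
  v1 <- vol(tmax_followup)
  list(tmax6_volume_ml = v0,
       global_reperfusion = v1 <= 0.10 * v0 + 1e-12, flag = NULL)
}
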