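#' Organ physiology for the digital phantom
#'
#' Physiological ground truth attached to one organ: fractional blood
#' volume (FBV) and accumulated extravascular gold. FBV is stored per scan
#' day because it is a measured quantity that can differ slightly between
#' the day-1 (gold-based) and day-3 (iodine-based) estimates of the same
#' organ; for most organs the two are equal. Accumulated gold on day 1 is
#' identically zero (the gold is injected at scan time and is still
#' entirely intravascular).
#'
#' @param fbv fractional blood volume in `[0, 1]`; used for both days
#'   unless overridden.
#' @param c_au_accum_day3 accumulated (extravascular) gold on day 3, mg/mL.
#' @param fbv_day1,fbv_day3 optional per-day overrides of `fbv`.
#' @return An `organ_physiology` list.
#' @export
organ_physiology <- function(fbv, c_au_accum_day3 = 0,
                             fbv_day1 = fbv, fbv_day3 = fbv) {
  stopifnot(fbv_day1 >= 0, fbv_day1 <= 1, fbv_day3 >= 0, fbv_day3 <= 1,
            c_au_accum_day3 >= 0)
  structure(list(fbv_day1 = fbv_day1, fbv_day3 = fbv_day3,
                 c_au_accum_day1 = 0, c_au_accum_day3 = c_au_accum_day3),
            class = "organ_physiology")
}

#' Ellipsoidal organ primitive
#'
#' @param label organ name (string). Two primitives may share a label
#'   (e.g. left/right kidney) and then share one physiology entry.
#' @param center ellipsoid center in voxel units (length 3, 1-based).
#' @param semi_axes ellipsoid semi-axes in voxel units (length 3).
#' @param baseline pre-contrast attenuation `c(hu40, hu80)` in HU.
#' @param physiology an [organ_physiology()], or `NULL` for inert tissue.
#' @param priority overlap resolution: higher priority wins. Defaults to
#'   listing order (later organs on top).
#' @return An `organ_spec` list.
#' @export
organ <- function(label, center, semi_axes, baseline,
                  physiology = NULL, priority = NA_real_) {
  stopifnot(length(center) == 3, length(semi_axes) == 3, all(semi_axes > 0),
            length(baseline) == 2)
  structure(list(label = label, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 baseline = as.numeric(baseline),
                 physiology = physiology, priority = priority),
            class = "organ_spec")
}

#' Digital phantom specification
#'
#' The complete stated world for one synthetic mouse: grid geometry, organ
#' primitives with baseline attenuation and physiology, blood-pool
#' contrast concentrations at the three scan timepoints, per-energy noise,
#' and optional misregistration / bias-field perturbations.
#'
#' @param dim voxel counts `c(nx, ny, nz)`, each >= 8.
#' @param voxel_mm isotropic voxel size, mm.
#' @param organs list of [organ()] primitives.
#' @param blood blood-pool concentrations (mg/mL):
#'   `c_au_day1` gold immediately after injection (day 1), `c_au_day3`
#'   gold remaining on day 3, `c_i_day3` iodine immediately after
#'   injection on day 3.
#' @param noise_sd additive Gaussian HU noise sd; scalar or `c(sd40, sd80)`.
#' @param seed RNG seed recorded in provenance and used for all noise.
#' @param background_hu attenuation of unlabelled voxels (air).
#' @param misregistration optional sub-voxel translation (voxels, length 3)
#'   applied to the 80 kVp channel by trilinear resampling; `NULL` = off.
#' @param bias_amplitude amplitude of a smooth multiplicative field
#'   `1 + a * cos(2 pi x/nx) cos(2 pi y/ny) cos(2 pi z/nz)` applied to the
#'   contrast term only (beam-hardening-like shading); 0 = off.
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(dim, voxel_mm, organs,
                         blood = list(c_au_day1 = 9.1, c_au_day3 = 5.3,
                                      c_i_day3 = 16.6),
                         noise_sd = 20, seed = 1,
                         background_hu = c(-1000, -1000),
                         misregistration = NULL, bias_amplitude = 0) {
  dim <- as.integer(dim)
  if (length(dim) != 3 || any(dim < 8))
    stop("phantom grid must be 3D with at least 8 voxels per axis",
         call. = FALSE)
  if (voxel_mm <= 0) stop("voxel size must be positive", call. = FALSE)
  noise_sd <- rep_len(as.numeric(noise_sd), 2)
  if (any(noise_sd < 0)) stop("noise sd must be >= 0", call. = FALSE)
  stopifnot(all(c("c_au_day1", "c_au_day3", "c_i_day3") %in% names(blood)))
  if (any(unlist(blood[c("c_au_day1", "c_au_day3", "c_i_day3")]) < 0))
    stop("blood concentrations must be >= 0", call. = FALSE)
  if (!is.null(misregistration)) stopifnot(length(misregistration) == 3)
  # default priority = listing order; physiology must be consistent within
  # a shared label
  labs <- vapply(organs, `[[`, "", "label")
  for (i in seq_along(organs))
    if (is.na(organs[[i]]$priority)) organs[[i]]$priority <- i
  phys <- list()
  for (o in organs) {
    if (o$label %in% names(phys)) {
      if (!identical(unclass(phys[[o$label]]), unclass(o$physiology)))
        stop(sprintf("organ label '%s' appears twice with different physiology",
                     o$label), call. = FALSE)
    } else phys[[o$label]] <- o$physiology
  }
  structure(list(dim = dim, voxel_mm = voxel_mm, organs = organs,
                 labels = unique(labs), physiology = phys, blood = blood,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 background_hu = as.numeric(background_hu),
                 misregistration = misregistration,
                 bias_amplitude = bias_amplitude),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom spec> %s voxels @ %.3f mm, %d organ primitives, seed %d\n",
              paste(x$dim, collapse = "x"), x$voxel_mm,
              length(x$organs), x$seed))
  cat(sprintf("  blood (mg/mL): Au day1 %.2f, Au day3 %.2f, I day3 %.2f\n",
              x$blood$c_au_day1, x$blood$c_au_day3, x$blood$c_i_day3))
  cat(sprintf("  noise sd (HU): %.1f / %.1f; misregistration %s; bias %.3g\n",
              x$noise_sd[1], x$noise_sd[2],
              if (is.null(x$misregistration)) "off"
              else paste(x$misregistration, collapse = ","),
              x$bias_amplitude))
  invisible(x)
}

#' Default digital mouse phantom
#'
#' A reduced-scale mouse thorax/abdomen: soft-tissue body, two air-filled
#' lungs, a blood pool (heart + great vessels, FBV = 1), liver, spleen,
#' two kidneys, and four spherical lung tumors spanning roughly
#' 0.2-1.5 mm^3 at the default geometry. Baselines (HU, both energies):
#' air -1000, lung -500, soft tissue/blood 50, liver/spleen/kidney 55.
#' Physiology defaults: tumor FBV 0.14 (day 1) / 0.13 (day 3) with
#' 0.7 mg/mL accumulated gold; spleen 0.44 / 3.5; liver 0.29 / 1.3;
#' kidney 0.29 / 0.8; blood-pool gold 9.1 (day 1) and 5.3 (day 3) mg/mL,
#' blood iodine 16.6 mg/mL.
#'
#' @param n grid size per axis (default 128; full scale is 512).
#' @param voxel_mm voxel size (default 0.088 mm).
#' @param noise_sd,seed,misregistration,bias_amplitude see [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
mouse_phantom_spec <- function(n = 128, voxel_mm = 0.088, noise_sd = 20,
                               seed = 1, misregistration = NULL,
                               bias_amplitude = 0) {
  ctr <- function(f) 1 + f * (n - 1)          # fraction -> voxel coordinate
  ax <- function(f) f * n                      # fraction -> semi-axis voxels
  soft <- c(50, 50); organhu <- c(55, 55); lunghu <- c(-500, -500)
  tumor_phys <- organ_physiology(0.14, 0.7, fbv_day1 = 0.14, fbv_day3 = 0.13)
  organs <- list(
    organ("body", ctr(c(0.50, 0.50, 0.50)), ax(c(0.45, 0.42, 0.47)), soft,
          organ_physiology(0.03, 0.05)),
    organ("lung_l", ctr(c(0.32, 0.45, 0.62)), ax(c(0.155, 0.16, 0.21)), lunghu,
          organ_physiology(0.10, 0)),
    organ("lung_r", ctr(c(0.68, 0.45, 0.62)), ax(c(0.155, 0.16, 0.21)), lunghu,
          organ_physiology(0.10, 0)),
    organ("blood", ctr(c(0.50, 0.49, 0.58)), ax(c(0.095, 0.095, 0.12)), soft,
          organ_physiology(1, 0)),
    organ("liver", ctr(c(0.52, 0.50, 0.29)), ax(c(0.24, 0.20, 0.115)), organhu,
          organ_physiology(0.29, 1.3)),
    organ("spleen", ctr(c(0.20, 0.56, 0.28)), ax(c(0.07, 0.10, 0.09)), organhu,
          organ_physiology(0.44, 3.5)),
    organ("kidney", ctr(c(0.35, 0.45, 0.135)), ax(c(0.06, 0.06, 0.08)), organhu,
          organ_physiology(0.29, 0.8)),
    organ("kidney", ctr(c(0.65, 0.45, 0.135)), ax(c(0.06, 0.06, 0.08)), organhu,
          organ_physiology(0.29, 0.8)),
    # spherical tumors inside the lung fields; ~0.2-1.5 mm^3 at n = 128
    organ("tumor", ctr(c(0.29, 0.41, 0.56)), rep(ax(0.033), 3), soft, tumor_phys),
    organ("tumor", ctr(c(0.35, 0.50, 0.70)), rep(ax(0.047), 3), soft, tumor_phys),
    organ("tumor", ctr(c(0.66, 0.42, 0.60)), rep(ax(0.039), 3), soft, tumor_phys),
    organ("tumor", ctr(c(0.70, 0.51, 0.69)), rep(ax(0.0625), 3), soft, tumor_phys)
  )
  phantom_spec(dim = rep(n, 3), voxel_mm = voxel_mm, organs = organs,
               noise_sd = noise_sd, seed = seed,
               misregistration = misregistration,
               bias_amplitude = bias_amplitude)
}

#' Rasterize the organ label volume
#'
#' Assigns every voxel exactly one integer label by voxel-center inclusion
#' in the organ ellipsoids, resolving overlaps by priority (higher wins).
#' Label 0 is background (air); organ codes follow the order of first
#' appearance in `spec$labels`.
#'
#' @param spec a [phantom_spec()].
#' @return Integer 3D array with attribute `label_table`, a named integer
#'   vector mapping organ names to codes.
#' @export
build_label_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  lab <- array(0L, d)
  codes <- stats::setNames(seq_along(spec$labels), spec$labels)
  ord <- order(vapply(spec$organs, `[[`, 0, "priority"))
  for (o in spec$organs[ord]) {
    lo <- o$center - o$semi_axes
    hi <- o$center + o$semi_axes
    if (any(lo < 1) || any(hi > d))
      stop(sprintf("organ '%s' extends outside the grid", o$label),
           call. = FALSE)
    ix <- seq.int(max(1L, floor(lo[1])), min(d[1], ceiling(hi[1])))
    iy <- seq.int(max(1L, floor(lo[2])), min(d[2], ceiling(hi[2])))
    iz <- seq.int(max(1L, floor(lo[3])), min(d[3], ceiling(hi[3])))
    ex <- ((ix - o$center[1]) / o$semi_axes[1])^2
    ey <- ((iy - o$center[2]) / o$semi_axes[2])^2
    ez <- ((iz - o$center[3]) / o$semi_axes[3])^2
    inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
    sub <- lab[ix, iy, iz]
    sub[inside] <- codes[[o$label]]
    lab[ix, iy, iz] <- sub
  }
  attr(lab, "label_table") <- codes
  attr(lab, "voxel_mm") <- spec$voxel_mm
  lab
}

timepoints <- c("day1", "day3_pre", "day3_post")

# per-label lookup of (c_i, c_au) at a timepoint; background = 0
label_concentrations <- function(spec, timepoint) {
  timepoint <- match.arg(timepoint, timepoints)
  b <- spec$blood
  ci <- cau <- numeric(length(spec$labels))
  for (k in seq_along(spec$labels)) {
    p <- spec$physiology[[spec$labels[k]]]
    if (is.null(p))
      stop(sprintf("organ '%s' has no physiology", spec$labels[k]),
           call. = FALSE)
    cau[k] <- switch(timepoint,
      day1 = p$fbv_day1 * b$c_au_day1,
      p$fbv_day3 * b$c_au_day3 + p$c_au_accum_day3)
    ci[k] <- if (timepoint == "day3_post") p$fbv_day3 * b$c_i_day3 else 0
  }
  list(c_i = ci, c_au = cau)
}

#' Ground-truth concentration maps from physiology
#'
#' Converts organ physiology into per-voxel material concentrations under
#' the conservation identity `C_Au,tot = FBV * C_Au,blood + C_Au,accum`
#' (iodine analogous, with zero accumulation). On day 1 only gold is
#' present; on day 3 pre-iodine the gold includes extravascular
#' accumulation; on day 3 post-iodine the iodine blood pool is added.
#'
#' @param labels label volume from [build_label_volume()].
#' @param spec the generating [phantom_spec()].
#' @param timepoint `"day1"`, `"day3_pre"` or `"day3_post"`.
#' @return List of two [concentration_volume()]s: `iodine`, `gold`.
#' @export
physiology_to_concentrations <- function(labels, spec,
                                         timepoint = timepoints) {
  timepoint <- match.arg(timepoint)
  lc <- label_concentrations(spec, timepoint)
  idx <- as.vector(labels) + 1L       # 1 = background
  ci <- c(0, lc$c_i)[idx]
  cau <- c(0, lc$c_au)[idx]
  dim(ci) <- dim(cau) <- dim(labels)
  list(iodine = concentration_volume(ci, spec$voxel_mm, "iodine"),
       gold = concentration_volume(cau, spec$voxel_mm, "gold"))
}

# smooth multiplicative shading field on [1-a, 1+a]
bias_field <- function(d, amplitude) {
  gx <- cos(2 * pi * (seq_len(d[1]) - 1) / d[1])
  gy <- cos(2 * pi * (seq_len(d[2]) - 1) / d[2])
  gz <- cos(2 * pi * (seq_len(d[3]) - 1) / d[3])
  1 + amplitude * outer(outer(gx, gy), gz)
}

# trilinear resampling of `a` at source positions shifted by `shift`
# (voxels), edge-clamped
trilinear_shift <- function(a, shift) {
  d <- dim(a)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  sx <- cl(seq_len(d[1]) + shift[1], d[1])
  sy <- cl(seq_len(d[2]) + shift[2], d[2])
  sz <- cl(seq_len(d[3]) + shift[3], d[3])
  x0 <- cl(floor(sx), d[1]); x1 <- cl(x0 + 1, d[1]); fx <- sx - x0
  y0 <- cl(floor(sy), d[2]); y1 <- cl(y0 + 1, d[2]); fy <- sy - y0
  z0 <- cl(floor(sz), d[3]); z1 <- cl(z0 + 1, d[3]); fz <- sz - z0
  out <- array(0, d)
  WX <- list(1 - fx, fx); WY <- list(1 - fy, fy); WZ <- list(1 - fz, fz)
  IX <- list(x0, x1); IY <- list(y0, y1); IZ <- list(z0, z1)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    w <- outer(outer(WX[[i]], WY[[j]]), WZ[[k]])
    out <- out + w * a[IX[[i]], IY[[j]], IZ[[k]]]
  }
  out
}

#' Simulate the paired-energy acquisition
#'
#' Forward model: per voxel,
#' `HU_E = baseline_E(label) + CT_I,E * C_I + CT_Au,E * C_Au + noise_E`,
#' with independent zero-mean Gaussian noise per voxel and energy. The
#' optional bias field multiplies the contrast term only; the optional
#' misregistration shifts the noiseless 80 kVp signal by trilinear
#' resampling before noise is added. Reproducible under `spec$seed`
#' (the timepoint offsets the stream so scans get independent noise).
#'
#' @param iodine,gold [concentration_volume()]s (or bare arrays).
#' @param labels label volume from [build_label_volume()].
#' @param spec the [phantom_spec()].
#' @param m the [sensitivity_matrix()] acting as the scanner physics.
#' @param timepoint scan timepoint (selects an independent noise stream).
#' @return List of two [energy_volume()]s: `v40`, `v80`.
#' @export
forward_model <- function(iodine, gold, labels, spec,
                          m = reference_sensitivity_matrix(),
                          timepoint = timepoints) {
  timepoint <- match.arg(timepoint)
  check_same_grid(iodine, gold)
  check_same_grid(iodine, labels)
  d <- spec$dim
  base40 <- c(spec$background_hu[1],
              vapply(spec$labels, function(l) {
                for (o in spec$organs) if (o$label == l) return(o$baseline[1])
              }, 0))
  base80 <- c(spec$background_hu[2],
              vapply(spec$labels, function(l) {
                for (o in spec$organs) if (o$label == l) return(o$baseline[2])
              }, 0))
  idx <- as.vector(labels) + 1L
  ci <- as.vector(iodine); cau <- as.vector(gold)
  con40 <- m$ct_i_40 * ci + m$ct_au_40 * cau
  con80 <- m$ct_i_80 * ci + m$ct_au_80 * cau
  if (spec$bias_amplitude != 0) {
    bf <- as.vector(bias_field(d, spec$bias_amplitude))
    con40 <- con40 * bf
    con80 <- con80 * bf
  }
  v40 <- base40[idx] + con40
  v80 <- base80[idx] + con80
  dim(v40) <- dim(v80) <- d
  if (!is.null(spec$misregistration))
    v80 <- trilinear_shift(v80, spec$misregistration)
  if (any(spec$noise_sd > 0)) {
    sub_seed <- spec$seed + match(timepoint, timepoints) - 1L
    with_seed(sub_seed, {
      n <- prod(d)
      if (spec$noise_sd[1] > 0)
        v40 <- v40 + array(rnorm(n, 0, spec$noise_sd[1]), d)
      if (spec$noise_sd[2] > 0)
        v80 <- v80 + array(rnorm(n, 0, spec$noise_sd[2]), d)
    })
  }
  list(v40 = energy_volume(v40, spec$voxel_mm, 40),
       v80 = energy_volume(v80, spec$voxel_mm, 80))
}

#' Synthetic calibration vials
#'
#' Generates per-vial mean HU at 40 and 80 kVp from known concentration
#' pairs under the linear sensitivity model, with zero baseline inside the
#' vials (water-equivalent background) and optional measurement noise.
#'
#' @param conc_pairs list of `c(C_I, C_Au)` pairs (mg/mL).
#' @param m generating [sensitivity_matrix()].
#' @param noise_sd HU noise sd on the vial means (0 = noiseless).
#' @param seed seed for the noise.
#' @return Data frame with columns `c_i`, `c_au`, `hu40`, `hu80`.
#' @export
make_calibration_phantom <- function(conc_pairs,
                                     m = reference_sensitivity_matrix(),
                                     noise_sd = 0, seed = 1) {
  if (length(conc_pairs) == 0)
    return(data.frame(c_i = numeric(), c_au = numeric(),
                      hu40 = numeric(), hu80 = numeric()))
  ci <- vapply(conc_pairs, `[`, 0, 1)
  cau <- vapply(conc_pairs, `[`, 0, 2)
  hu40 <- m$ct_i_40 * ci + m$ct_au_40 * cau
  hu80 <- m$ct_i_80 * ci + m$ct_au_80 * cau
  if (noise_sd > 0) with_seed(seed, {
    hu40 <- hu40 + rnorm(length(ci), 0, noise_sd)
    hu80 <- hu80 + rnorm(length(ci), 0, noise_sd)
  })
  data.frame(c_i = ci, c_au = cau, hu40 = hu40, hu80 = hu80)
}

#' Generate a complete phantom study
#'
#' Convenience wrapper producing, for each requested timepoint, the
#' ground-truth concentration maps and the simulated paired-energy
#' volumes, plus the label volume and a per-organ ground-truth biomarker
#' table.
#'
#' @param spec a [phantom_spec()].
#' @param times timepoints to simulate.
#' @param m scanner physics [sensitivity_matrix()].
#' @return List with `labels`, `scans` (per timepoint: `v40`, `v80`,
#'   `truth$iodine`, `truth$gold`), and `truth_biomarkers` (data frame).
#' @export
build_phantom <- function(spec, times = timepoints,
                          m = reference_sensitivity_matrix()) {
  times <- match.arg(times, several.ok = TRUE)
  labels <- build_label_volume(spec)
  scans <- list()
  for (tp in times) {
    conc <- physiology_to_concentrations(labels, spec, tp)
    vols <- forward_model(conc$iodine, conc$gold, labels, spec, m, tp)
    scans[[tp]] <- list(v40 = vols$v40, v80 = vols$v80, truth = conc)
  }
  tb <- do.call(rbind, lapply(spec$labels, function(l) {
    p <- spec$physiology[[l]]
    data.frame(roi = l,
               fbv_day1 = p$fbv_day1, fbv_day3 = p$fbv_day3,
               c_au_accum = p$c_au_accum_day3,
               c_au_tot_day3 = p$fbv_day3 * spec$blood$c_au_day3 +
                 p$c_au_accum_day3)
  }))
  list(labels = labels, scans = scans, truth_biomarkers = tb, spec = spec,
       seed = spec$seed)
}
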