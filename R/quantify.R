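#' Gold-threshold tumor segmentation
#'
#' Selects voxels within a search region whose gold concentration lies in
#' `[lo, hi]` mg/mL, splits them into 26-connected components, and
#' discards components smaller than `min_voxels`. The default band
#' (0.25-3 mg/mL) excludes normal lung parenchyma below and large blood
#' vessels / bone above.
#'
#' @param gold a gold [concentration_volume()].
#' @param search logical array (same shape): the region to search.
#' @param lo,hi concentration band, mg/mL (`lo < hi`).
#' @param min_voxels minimum component size retained.
#' @return List of logical ROI masks, one per tumor, each with attributes
#'   `label` (`"tumor_k"`), `n_voxels`, and `origin = "gold-threshold"`,
#'   ordered by decreasing size.
#' @export
segment_tumors <- function(gold, search, lo = 0.25, hi = 3, min_voxels = 4) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  check_same_grid(gold, search)
  if (!any(search)) stop("empty search region", call. = FALSE)
  inband <- search & gold >= lo & gold <= hi
  comp <- label_components_cpp(as.vector(inband), dim(gold))
  k <- max(comp)
  if (k == 0) return(list())
  sizes <- tabulate(comp[comp > 0], nbins = k)
  keep <- which(sizes >= min_voxels)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  out <- lapply(seq_along(keep), function(i) {
    m <- comp == keep[i]
    structure(m, label = sprintf("tumor_%d", i),
              n_voxels = sizes[keep[i]], origin = "gold-threshold")
  })
  out
}

#' Mean concentration over a region of interest
#'
#' @param map a [concentration_volume()] (or numeric array).
#' @param roi logical array of the same shape; must select >= 1 voxel.
#' @return Arithmetic mean over the ROI, mg/mL.
#' @export
roi_mean <- function(map, roi) {
  check_same_grid(map, roi)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  mean(map[roi])
}

#' Fractional blood volume
#'
#' FBV of a tissue is its concentration of a purely intravascular tracer
#' divided by the blood-pool concentration of the same tracer measured on
#' the same scan, immediately after injection.
#'
#' @param c_tissue mean tissue concentration, mg/mL.
#' @param c_blood mean blood-pool concentration, mg/mL (> 0).
#' @return FBV fraction; values > 1 are permitted but raise a warning.
#' @export
fractional_blood_volume <- function(c_tissue, c_blood) {
  if (!is.finite(c_blood) || c_blood <= 0)
    stop("blood concentration must be positive", call. = FALSE)
  fbv <- c_tissue / c_blood
  if (any(fbv > 1))
    warning("FBV > 1: tissue concentration exceeds blood concentration")
  fbv
}

#' Accumulated (extravascular) gold
#'
#' Subtracts the intravascular component from the total tissue gold:
#' `C_Au,accum = C_Au,tot - FBV * C_Au,blood`. Negative results (possible
#' under noise) are clamped to zero by default, with a warning.
#'
#' @param c_tot total tissue gold from the day-3 gold map, mg/mL.
#' @param fbv tissue fractional blood volume (>= 0).
#' @param c_blood blood-pool gold on day 3, mg/mL.
#' @param clamp clamp negative results to 0 (default `TRUE`).
#' @return Accumulated gold, mg/mL.
#' @export
accumulated_gold <- function(c_tot, fbv, c_blood, clamp = TRUE) {
  stopifnot(all(is.finite(c(c_tot, fbv, c_blood))), all(fbv >= 0))
  acc <- c_tot - fbv * c_blood
  if (clamp && any(acc < 0)) {
    warning(sprintf("%d negative accumulated-gold value(s) clamped to 0",
                    sum(acc < 0)))
    acc[acc < 0] <- 0
  }
  acc
}

#' Blood half-life under exponential clearance
#'
#' @param delta_t elapsed time, hours (> 0).
#' @param ratio_remaining fraction of the initial blood concentration
#'   remaining after `delta_t` (strictly between 0 and 1).
#' @return Half-life in hours: `delta_t * log(2) / log(1 / ratio)`.
#' @examples
#' blood_half_life(48, 0.54)   # ~54 h
#' @export
blood_half_life <- function(delta_t, ratio_remaining) {
  if (delta_t <= 0) stop("delta_t must be positive", call. = FALSE)
  if (ratio_remaining <= 0 || ratio_remaining >= 1)
    stop("ratio_remaining must be strictly between 0 and 1", call. = FALSE)
  delta_t * log(2) / log(1 / ratio_remaining)
}

#' Otsu threshold of a numeric image
#'
#' Histogram-based threshold maximizing between-class variance.
#'
#' @param x numeric vector/array.
#' @param n_bins histogram resolution.
#' @return Threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.vector(x)
  r <- range(x)
  if (r[1] == r[2]) stop("constant image has no Otsu threshold", call. = FALSE)
  br <- seq(r[1], r[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Microvascular density of a stained section
#'
#' Fraction of the field of view positive for the endothelial stain after
#' automatic (Otsu) thresholding. Multiple fields of one tumor are
#' averaged by passing a list.
#'
#' @param image 2D numeric intensity grid, or a list of them.
#' @return Positive-area fraction in `[0, 1]`.
#' @export
microvascular_density <- function(image) {
  if (is.list(image))
    return(mean(vapply(image, microvascular_density, 0)))
  if (length(unique(as.vector(image))) == 1) {
    warning("constant image: microvascular density reported as 0")
    return(0)
  }
  thr <- otsu_threshold(image)
  mean(image > thr)
}

# masks for every organ label (kidneys merged under their shared label)
label_masks <- function(labels) {
  tab <- attr(labels, "label_table")
  lapply(tab, function(code) labels == code)
}

# one biomarker row
biomarker_row <- function(roi_label, method, n_voxels, fbv,
                          c_au_tot, c_au_blood, c_fbv_tracer_blood,
                          clamp = TRUE) {
  c_au_iv <- fbv * c_au_blood
  acc_raw <- c_au_tot - c_au_iv
  clamped <- clamp && acc_raw < 0
  data.frame(roi = roi_label, method = method, n_voxels = n_voxels,
             fbv = fbv, c_au_tot = c_au_tot, c_au_iv = c_au_iv,
             c_au_accum = if (clamped) 0 else acc_raw,
             c_au_accum_raw = acc_raw, clamped = clamped,
             c_blood_fbv_ref = c_fbv_tracer_blood,
             c_au_blood = c_au_blood)
}

#' Per-ROI vascular biomarkers from decomposed maps
#'
#' Computes, for every organ ROI and every segmented tumor, the fractional
#' blood volume, total / intravascular / accumulated gold, under one or
#' both quantification variants:
#' \describe{
#'   \item{single-material}{FBV from the day-1 gold map (scan 1); total and
#'     blood gold from the day-3 pre-iodine gold map (scan 2).}
#'   \item{two-material}{FBV from the day-3 post-iodine iodine map and all
#'     gold quantities from the same single scan (scan 3).}
#' }
#' Blood reference concentrations are ROI means over the blood-pool label
#' on the same scan as the numerator.
#'
#' @param labels label volume from [build_label_volume()].
#' @param day1,day3_pre,day3_post decomposed map pairs
#'   (`list(iodine =, gold =)`) for the three scans; only the scans a
#'   variant needs must be present.
#' @param method `"both"`, `"single"` or `"two"`.
#' @param blood_label name of the blood-pool label.
#' @param organ_labels organ labels to quantify (default: all labels
#'   except the blood pool, body and lungs).
#' @param tumor_source `"segment"` (gold-threshold segmentation of the
#'   scan supplying the gold totals, searched over `search_labels`) or
#'   `"labels"` (use the ground-truth tumor label).
#' @param search_labels labels forming the tumor search region.
#' @param lo,hi,min_voxels segmentation parameters, see [segment_tumors()].
#' @param clamp clamp negative accumulated gold, see [accumulated_gold()].
#' @return Data frame of biomarker records (one row per ROI x method).
#' @export
quantify_biomarkers <- function(labels, day1 = NULL, day3_pre = NULL,
                                day3_post = NULL,
                                method = c("both", "single", "two"),
                                blood_label = "blood",
                                organ_labels = NULL,
                                tumor_source = c("segment", "labels"),
                                search_labels = c("lung_l", "lung_r", "tumor"),
                                lo = 0.25, hi = 3, min_voxels = 4,
                                clamp = TRUE) {
  method <- match.arg(method)
  tumor_source <- match.arg(tumor_source)
  tab <- attr(labels, "label_table")
  if (is.null(tab)) stop("labels must carry a label_table attribute",
                         call. = FALSE)
  if (!blood_label %in% names(tab))
    stop(sprintf("blood label '%s' not present", blood_label), call. = FALSE)
  if (is.null(organ_labels))
    organ_labels <- setdiff(names(tab),
                            c(blood_label, "body", "lung_l", "lung_r", "tumor"))
  blood_mask <- labels == tab[[blood_label]]
  search_mask <- array(FALSE, dim(labels))
  for (l in intersect(search_labels, names(tab)))
    search_mask <- search_mask | labels == tab[[l]]

  variants <- if (method == "both") c("single", "two") else method
  rows <- list()
  for (v in variants) {
    if (v == "single") {
      if (is.null(day1) || is.null(day3_pre))
        stop("single-material method needs day1 and day3_pre maps",
             call. = FALSE)
      fbv_map <- day1$gold
      fbv_blood <- roi_mean(day1$gold, blood_mask)
      gold_map <- day3_pre$gold
    } else {
      if (is.null(day3_post))
        stop("two-material method needs day3_post maps", call. = FALSE)
      fbv_map <- day3_post$iodine
      fbv_blood <- roi_mean(day3_post$iodine, blood_mask)
      gold_map <- day3_post$gold
    }
    c_au_blood <- roi_mean(gold_map, blood_mask)
    method_name <- paste0(v, "-material")

    rois <- list()
    for (l in organ_labels)
      rois[[l]] <- structure(labels == tab[[l]], label = l)
    if (tumor_source == "segment") {
      if (any(search_mask))
        for (tm in segment_tumors(gold_map, search_mask, lo, hi, min_voxels))
          rois[[attr(tm, "label")]] <- tm
    } else if ("tumor" %in% names(tab)) {
      rois[["tumor"]] <- structure(labels == tab[["tumor"]], label = "tumor")
    }
    rois[[blood_label]] <- structure(blood_mask, label = blood_label)

    for (r in rois) {
      fbv <- suppressWarnings(
        fractional_blood_volume(roi_mean(fbv_map, r), fbv_blood))
      rows[[length(rows) + 1L]] <- biomarker_row(
        attr(r, "label"), method_name, sum(r), fbv,
        roi_mean(gold_map, r), c_au_blood, fbv_blood, clamp = clamp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
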