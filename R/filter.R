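#' Joint bilateral filter parameters
#'
#' @param sigma_s spatial Gaussian sd, voxels.
#' @param sigma_r range Gaussian sd per energy channel, HU; scalar or
#'   `c(sd40, sd80)`.
#' @param radius window half-width, voxels (window is `(2r+1)^3`).
#' @param passes number of filter passes.
#' @return A `filter_params` list.
#' @export
filter_params <- function(sigma_s = 2, sigma_r = 60, radius = 3, passes = 1) {
  sigma_r <- rep_len(as.numeric(sigma_r), 2)
  if (sigma_s <= 0 || any(sigma_r <= 0))
    stop("filter sigmas must be positive", call. = FALSE)
  if (radius < 1 || passes < 1)
    stop("radius and passes must be >= 1", call. = FALSE)
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r,
                 radius = as.integer(radius), passes = as.integer(passes)),
            class = "filter_params")
}

#' Joint bilateral filtration of a paired-energy acquisition
#'
#' Edge-preserving denoising applied to both energy channels with a single
#' shared weight field. Each output voxel is the normalized weighted mean
#' over its window; the weight is the product of a spatial Gaussian and a
#' joint range Gaussian whose distance is the Euclidean norm of the
#' two-channel HU difference vector, each channel scaled by its own range
#' sigma. Because the weights are identical for both channels, structure
#' present in either channel protects edges in both. Boundaries use mirror
#' padding with weight renormalization.
#'
#' @param v40,v80 co-registered [energy_volume()]s.
#' @param params a [filter_params()].
#' @return List of the two filtered [energy_volume()]s, `v40` and `v80`.
#' @export
joint_bilateral_filter <- function(v40, v80, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  check_same_grid(v40, v80)
  out <- joint_bf_cpp(as.vector(v40), as.vector(v80), dim(v40),
                      params$sigma_s, params$sigma_r[1], params$sigma_r[2],
                      params$radius, params$passes)
  voxel_mm <- attr(v40, "voxel_mm") %||% 1
  list(v40 = energy_volume(out$a, voxel_mm, attr(v40, "kvp") %||% 40),
       v80 = energy_volume(out$b, voxel_mm, attr(v80, "kvp") %||% 80))
}
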