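#' Volume containers
#'
#' A `demict` volume is a plain 3D numeric array carrying grid metadata as
#' attributes: the isotropic voxel size in mm and either the tube voltage
#' (`energy_volume`, values in HU) or the material tag
#' (`concentration_volume`, values in mg/mL). All pipeline operations accept
#' and return these; most also accept bare arrays where metadata is not
#' needed.
#'
#' @param data 3D numeric array.
#' @param voxel_mm isotropic voxel size in mm (> 0).
#' @param kvp tube peak voltage in kVp (e.g. 40 or 80).
#' @return The array with class and metadata attributes attached.
#' @export
energy_volume <- function(data, voxel_mm, kvp) {
  stopifnot(is.array(data), length(dim(data)) == 3, voxel_mm > 0)
  structure(data,
            voxel_mm = voxel_mm, kvp = kvp,
            class = c("energy_volume", "demict_volume", class(data)))
}

#' @param material `"iodine"` or `"gold"`.
#' @rdname energy_volume
#' @export
concentration_volume <- function(data, voxel_mm, material) {
  stopifnot(is.array(data), length(dim(data)) == 3, voxel_mm > 0)
  material <- match.arg(material, c("iodine", "gold"))
  structure(data,
            voxel_mm = voxel_mm, material = material,
            class = c("concentration_volume", "demict_volume", class(data)))
}

#' @export
print.demict_volume <- function(x, ...) {
  d <- dim(x)
  kind <- if (inherits(x, "energy_volume"))
    sprintf("energy volume (%s kVp, HU)", attr(x, "kvp"))
  else
    sprintf("concentration volume (%s, mg/mL)", attr(x, "material"))
  cat(sprintf("<%s> %d x %d x %d voxels @ %.3f mm\n",
              kind, d[1], d[2], d[3], attr(x, "voxel_mm")))
  cat(sprintf("  range [%.2f, %.2f], mean %.3f\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

# strip demict classes/attrs, keep dim
vol_array <- function(x) {
  a <- as.vector(x)
  dim(a) <- dim(x)
  a
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s have mismatched shapes: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}
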