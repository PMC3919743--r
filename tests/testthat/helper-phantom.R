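# shared fixtures, built in code

ref_m <- reference_sensitivity_matrix()

# single-sphere spec on a small grid
sphere_spec <- function(n = 32, r = 4, baseline = c(50, 50), noise_sd = 0,
                        fbv = 0.1, accum = 0, seed = 1) {
  c0 <- (n + 1) / 2
  phantom_spec(rep(n, 3), 0.088,
               list(organ("s", rep(c0, 3), rep(r, 3), baseline,
                          organ_physiology(fbv, accum))),
               noise_sd = noise_sd, seed = seed)
}

# zero-baseline variant of the mouse phantom: exact decomposition limit
zero_baseline_mouse <- function(n = 64, noise_sd = 0, seed = 1,
                                equal_fbv = TRUE) {
  spec <- mouse_phantom_spec(n = n, noise_sd = noise_sd, seed = seed)
  spec$background_hu <- c(0, 0)
  for (i in seq_along(spec$organs)) {
    spec$organs[[i]]$baseline <- c(0, 0)
    if (equal_fbv) {
      p <- spec$organs[[i]]$physiology
      p$fbv_day1 <- p$fbv_day3 <- (p$fbv_day1 + p$fbv_day3) / 2
      spec$organs[[i]]$physiology <- p
      spec$physiology[[spec$organs[[i]]$label]] <- p
    }
  }
  spec
}

# mask helpers
label_mask <- function(labels, name) {
  labels == attr(labels, "label_table")[[name]]
}

lung_search_mask <- function(labels) {
  label_mask(labels, "lung_l") | label_mask(labels, "lung_r") |
    label_mask(labels, "tumor")
}
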