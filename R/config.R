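#' Default analysis configuration
#'
#' The package-wide defaults in one nested list, matching the YAML config
#' schema: `lga$bands` (E/C class boundaries, mm^2), `body` (preset name,
#' mass/extent fractions, half-widths), `bed` (stiffness bounds and
#' baseline uniform stiffnesses, N/mm; trunk-bending coupling), `stats`
#' (significance levels) and `cohort` (simulation settings).
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  contour <- body_contour_defaults()
  list(
    lga = list(bands = list(soft_min = 2000, firm_max = 1000)),
    body = list(
      preset = "HTM",
      fractions = as.list(contour$mass_fractions),
      extent_fractions = as.list(contour$extent_fractions),
      half_widths_mm = as.list(contour$half_widths_mm),
      pelvis_spine_fraction = contour$pelvis_spine_fraction
    ),
    bed = list(bounds = c(0.5, 20), soft = 2, firm = 100,
               coupling = 0.1, block_length_mm = 100,
               block_height_mm = 200),
    stats = list(alpha = 0.05, alpha_strict = 0.001),
    cohort = list(n_subjects = 25, jitter_sd = 0.05, marker_noise_sd = 2,
                  n_repeats = 2, seed = 1)
  )
}

#' Load a YAML configuration, merged over the defaults
#'
#' Reads a YAML file and recursively overlays it on [default_config()], so
#' partial configs are valid.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge_rec(cfg, user)
}
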