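#' Assign cortical layers from depth below the pial surface
#'
#' Depth bands (um): 50-100 layer I, 150-300 layer II/III, 320-500 layer IV;
#' depth 0 is the cortical surface. Depths falling in the gaps between bands
#' (0-50 exclusive, 100-150, 300-320, > 500) are `"unassigned"`. Band
#' boundaries are closed on both ends; a depth on a shared boundary resolves
#' to the shallower layer.
#'
#' @param depth_um Depth(s) below the surface, um (>= 0).
#' @return Character vector with levels `surface`, `I`, `II/III`, `IV`,
#'   `unassigned`.
#' @export
#' @examples
#' assign_layer(c(0, 75, 200, 310, 400))
assign_layer <- function(depth_um) {
  if (any(depth_um < 0, na.rm = TRUE)) {
    abort("`depth_um` must be >= 0.", class = "odaciti_invalid_parameter")
  }
  dplyr::case_when(
    depth_um == 0 ~ "surface",
    depth_um >= 50 & depth_um <= 100 ~ "I",
    depth_um >= 150 & depth_um <= 300 ~ "II/III",
    depth_um >= 320 & depth_um <= 500 ~ "IV",
    TRUE ~ "unassigned"
  )
}

#' Means of the lower and upper tails of a pO2 distribution
#'
#' The bottom tail (values at or below the `fraction` quantile) probes
#' inter-capillary tissue oxygenation; the top tail (values at or above the
#' `1 - fraction` quantile) the periarteriolar pool. Quantiles are
#' linear-interpolation quantiles; ties at a threshold are included.
#'
#' @param values Numeric pO2 values (>= 3 of them).
#' @param fraction Tail fraction in (0, 0.5]; default 0.35.
#' @return A `tail_summary` tibble: `mean_bottom`, `mean_top`, `fraction`,
#'   `n`.
#' @export
#' @examples
#' distribution_tails(1:100)  # bottom mean 18, top mean 83
distribution_tails <- function(values, fraction = 0.35) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    abort("Need at least 3 values.", class = "odaciti_insufficient_data")
  }
  if (fraction <= 0 || fraction > 0.5) {
    abort("`fraction` must be in (0, 0.5].", class = "odaciti_invalid_parameter")
  }
  qlo <- unname(quantile(values, fraction, type = 7))
  qhi <- unname(quantile(values, 1 - fraction, type = 7))
  tibble(mean_bottom = mean(values[values <= qlo]),
         mean_top = mean(values[values >= qhi]),
         fraction = fraction, n = length(values))
}

#' Per-layer summary of CMRO2 estimates
#'
#' Grouped mean and standard error of the estimates by cortical layer, with
#' optional per-subject means to expose the clustering structure (repeated
#' planes within an animal are not independent; a mixed-effects model fitted
#' outside this package is the appropriate inferential tool).
#'
#' @param estimates Tibble with `cmro2` and either a `layer` column or
#'   `depth_um` (from which layers are assigned).
#' @param by_subject Also return per-subject, per-layer means?
#' @return Tibble `layer`, `n`, `mean_cmro2`, `se_cmro2` (`NA` for n = 1);
#'   with `by_subject`, attribute `subject_means`.
#' @export
layer_summary <- function(estimates, by_subject = FALSE) {
  stopifnot(is.data.frame(estimates))
  if (!"layer" %in% names(estimates)) {
    if (!"depth_um" %in% names(estimates)) {
      abort("Estimates need a `layer` or `depth_um` column.",
            class = "odaciti_schema_error")
    }
    estimates$layer <- assign_layer(estimates$depth_um)
  }
  out <- estimates |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cmro2 = mean(.data$cmro2),
      se_cmro2 = ifelse(dplyr::n() > 1, sd(.data$cmro2) / sqrt(dplyr::n()),
                        NA_real_),
      .groups = "drop")
  if (by_subject && "subject_id" %in% names(estimates)) {
    sm <- estimates |>
      dplyr::group_by(.data$subject_id, .data$layer) |>
      dplyr::summarise(mean_cmro2 = mean(.data$cmro2), n = dplyr::n(),
                       .groups = "drop")
    attr(out, "subject_means") <- sm
  }
  out
}

#' Mean pO2 versus cortical depth
#'
#' Averages all measured points at each depth, per arteriole. Because every
#' measurement grid is centered on a penetrating arteriole, these means are
#' biased towards the highly oxygenated periarteriolar space and do not
#' represent mean tissue pO2; the returned table carries a `bias` note
#' recording this.
#'
#' @param grids A list of `po2_grid` objects, or a single one.
#' @return Tibble `arteriole_id`, `subject_id`, `depth_um`, `mean_po2`, `n`,
#'   `bias`.
#' @export
depth_profile <- function(grids) {
  if (is.data.frame(grids)) grids <- list(grids)
  purrr::map_dfr(grids, function(g) {
    tibble(arteriole_id = attr(g, "arteriole_id") %||% NA_character_,
           subject_id = attr(g, "subject_id") %||% NA_character_,
           depth_um = attr(g, "depth_um") %||% NA_real_,
           mean_po2 = mean(g$po2_mmhg), n = nrow(g),
           bias = "periarteriolar")
  })
}
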