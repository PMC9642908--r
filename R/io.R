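# Plain-text persistence. Tabular payloads are comma-separated UTF-8 with a
# header line; plane metadata travels in leading '# key: value' comment
# lines so that a file round-trips losslessly through read -> write.

write_meta_csv <- function(df, path, meta) {
  meta <- meta[!vapply(meta, function(v) is.null(v) || all(is.na(v)), logical(1))]
  lines <- purrr::imap_chr(meta, function(v, k) {
    paste0("# ", k, ": ", paste(v, collapse = " "))
  })
  df <- as_tibble(as.data.frame(df))
  # fixed 15-significant-digit rendering so that write -> read -> write is
  # byte-stable (shortest-roundtrip printing wobbles in the last ulp)
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.15g", x))))
  body <- readr::format_csv(df)
  writeLines(c(unname(lines), sub("\n$", "", body)), path)
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  if (!length(lines)) return(list())
  kv <- sub("^# ", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  setNames(as.list(vals), keys)
}

#' Read and write pO2 measurement grids
#'
#' Grids are stored as CSV with required columns `x_um`, `y_um`, `po2_mmhg`
#' and optional `n_cycles`; the arteriole center, vessel radius and plane
#' identifiers are stored in `# key: value` header lines. A missing required
#' column raises a schema error naming the column.
#'
#' @param path File path.
#' @return `read_po2_grid()`: a `po2_grid` tibble; `write_po2_grid()`: the
#'   path, invisibly.
#' @export
read_po2_grid <- function(path) {
  meta <- read_meta(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  needed <- c("x_um", "y_um", "po2_mmhg")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(paste0("Grid file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "odaciti_schema_error")
  }
  num <- function(k) if (is.null(meta[[k]])) NA_real_ else as.numeric(meta[[k]])
  chr <- function(k) if (is.null(meta[[k]])) NA_character_ else meta[[k]]
  center <- if (is.null(meta$center)) c(NA_real_, NA_real_)
            else as.numeric(strsplit(meta$center, " +")[[1]])
  as_po2_grid(df, center = center, r_ves_um = num("r_ves_um"),
              depth_um = num("depth_um"), arteriole_id = chr("arteriole_id"),
              subject_id = chr("subject_id"))
}

#' @rdname read_po2_grid
#' @param grid A `po2_grid`.
#' @export
write_po2_grid <- function(grid, path) {
  stopifnot(is.data.frame(grid))
  write_meta_csv(grid, path, list(
    center = attr(grid, "center"),
    r_ves_um = attr(grid, "r_ves_um"),
    depth_um = attr(grid, "depth_um"),
    arteriole_id = attr(grid, "arteriole_id"),
    subject_id = attr(grid, "subject_id")))
}

#' Read and write radial pO2 profiles
#'
#' Native profiles are CSV with columns `r_um`, `po2_mmhg`. For profiles
#' exported from spreadsheet supplements the reader falls back to positional
#' mapping -- first column distance in um, second column pO2 in mmHg -- and
#' accepts a `col_map` override naming which input columns hold which
#' quantity.
#'
#' @param path File path.
#' @param col_map Optional named character vector, e.g.
#'   `c(r_um = "Distance", po2_mmhg = "pO2")`.
#' @return A `radial_profile` tibble.
#' @export
read_radial_profile <- function(path, col_map = NULL) {
  meta <- read_meta(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!is.null(col_map)) {
    df <- dplyr::rename(df, dplyr::all_of(col_map))
  }
  if (!all(c("r_um", "po2_mmhg") %in% names(df))) {
    if (ncol(df) < 2) {
      abort("Profile file needs at least two columns (distance, pO2).",
            class = "odaciti_schema_error")
    }
    df <- setNames(df[, 1:2], c("r_um", "po2_mmhg"))
  }
  num <- function(k) if (is.null(meta[[k]])) NA_real_ else as.numeric(meta[[k]])
  as_radial_profile(df[, c("r_um", "po2_mmhg")],
                    r_ves_um = num("r_ves_um"), r_t_um = num("r_t_um"))
}

#' @rdname read_radial_profile
#' @param profile A `radial_profile`.
#' @export
write_radial_profile <- function(profile, path) {
  write_meta_csv(profile, path, list(
    r_ves_um = attr(profile, "r_ves_um"),
    r_t_um = attr(profile, "r_t_um")))
}

#' Read and write lifetime calibrations
#'
#' Flat key-value config (YAML) with keys `a1`, `t1_us`, `a2`, `t2_us`,
#' `y0`.
#'
#' @param path File path.
#' @return A [lifetime_calibration()].
#' @export
read_calibration <- function(path) {
  v <- yaml::read_yaml(path)
  needed <- c("a1", "t1_us", "a2", "t2_us", "y0")
  missing_keys <- setdiff(needed, names(v))
  if (length(missing_keys)) {
    abort(paste0("Calibration file is missing key(s): ",
                 paste(missing_keys, collapse = ", ")),
          class = "odaciti_schema_error")
  }
  lifetime_calibration(v$a1, v$t1_us, v$a2, v$t2_us, v$y0)
}

#' @rdname read_calibration
#' @param cal A [lifetime_calibration()].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "lifetime_calibration"))
  yaml::write_yaml(unclass(cal), path)
  invisible(path)
}

#' Read and write vascular geometry specifications
#'
#' YAML config with a `sources` list (each with `cx`, `cy`, `radius`, `po2`,
#' `label`), `domain`, `mesh_um` and optionally `shape`, `disk_radius`,
#' `disk_center`.
#'
#' @param path File path.
#' @return A [geometry_spec()].
#' @export
read_geometry <- function(path) {
  v <- yaml::read_yaml(path)
  sources <- purrr::map_dfr(v$sources, function(s) {
    vessel_source(s$cx, s$cy, s$radius, s$po2, s$label %||% "capillary")
  })
  geometry_spec(sources, domain = as.numeric(v$domain),
                mesh_um = v$mesh_um %||% 1, shape = v$shape %||% "rect",
                disk_radius = v$disk_radius,
                disk_center = as.numeric(v$disk_center %||% c(0, 0)))
}

#' @rdname read_geometry
#' @param geom A [geometry_spec()].
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "geometry_spec"))
  v <- list(
    sources = purrr::pmap(geom$sources, function(cx, cy, radius, po2, label) {
      list(cx = cx, cy = cy, radius = radius, po2 = po2, label = label)
    }),
    domain = geom$domain, mesh_um = geom$mesh_um, shape = geom$shape)
  if (geom$shape == "disk") {
    v$disk_radius <- geom$disk_radius
    v$disk_center <- geom$disk_center
  }
  yaml::write_yaml(v, path)
  invisible(path)
}
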