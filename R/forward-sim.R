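#' Circular vascular O2 source
#'
#' @param cx,cy Center coordinates, um.
#' @param radius Vessel radius, um (> 0).
#' @param po2 Fixed intravascular pO2, mmHg (>= 0).
#' @param label `"arteriole"` or `"capillary"`.
#' @return One-row tibble describing the source.
#' @export
vessel_source <- function(cx, cy, radius, po2, label = c("arteriole", "capillary")) {
  label <- match.arg(label)
  if (radius <= 0) abort("`radius` must be > 0.", class = "odaciti_invalid_parameter")
  if (po2 < 0) abort("`po2` must be >= 0.", class = "odaciti_invalid_parameter")
  tibble(cx = cx, cy = cy, radius = radius, po2 = po2, label = label)
}

#' Vascular geometry for the 2-D forward simulation
#'
#' Describes the computational domain and its circular vessel sources. The
#' domain is a rectangle `[xmin, xmax] x [ymin, ymax]` (um) discretised at
#' `mesh_um`; with `shape = "disk"` the solve is restricted to the inscribed
#' disk of radius `disk_radius` around `disk_center` (zero-flux outer rim),
#' which is the natural domain for comparing against the cylinder solutions.
#'
#' @param sources Tibble of [vessel_source()] rows.
#' @param domain Numeric length-4: `c(xmin, xmax, ymin, ymax)`, um.
#' @param mesh_um Grid spacing, um.
#' @param shape `"rect"` (default) or `"disk"`.
#' @param disk_radius,disk_center Disk mask parameters (um), used when
#'   `shape = "disk"`.
#' @return Object of class `geometry_spec`.
#' @export
geometry_spec <- function(sources, domain = c(-150, 150, -150, 150),
                          mesh_um = 1, shape = c("rect", "disk"),
                          disk_radius = NULL, disk_center = c(0, 0)) {
  shape <- match.arg(shape)
  stopifnot(is.data.frame(sources), nrow(sources) >= 0, length(domain) == 4)
  if (mesh_um <= 0) abort("`mesh_um` must be > 0.", class = "odaciti_invalid_parameter")
  if (nrow(sources)) {
    inside <- sources$cx - sources$radius >= domain[1] &
      sources$cx + sources$radius <= domain[2] &
      sources$cy - sources$radius >= domain[3] &
      sources$cy + sources$radius <= domain[4]
    if (!all(inside)) abort("All sources must lie inside the domain.",
                            class = "odaciti_invalid_parameter")
    if (nrow(sources) > 1) {
      d <- as.matrix(stats::dist(sources[, c("cx", "cy")]))
      rsum <- outer(sources$radius, sources$radius, "+")
      diag(d) <- Inf
      if (any(d <= rsum)) abort("Sources must not overlap.",
                                class = "odaciti_invalid_parameter")
    }
  }
  if (shape == "disk" && is.null(disk_radius)) {
    abort("`disk_radius` is required for shape = \"disk\".",
          class = "odaciti_invalid_parameter")
  }
  structure(
    list(sources = as_tibble(sources), domain = domain, mesh_um = mesh_um,
         shape = shape, disk_radius = disk_radius, disk_center = disk_center),
    class = "geometry_spec"
  )
}

#' Reference microvascular geometry for validation
#'
#' A 15-um-diameter central arteriole held at 70 mmHg, surrounded by seven
#' 5-um-diameter capillaries at 35 mmHg placed 80-130 um from the center
#' (radii 80, 88, 97, 105, 113, 122, 130 um at evenly spaced angles offset by
#' half a sector so none collides with the extra vessel), plus one additional
#' arteriole at 60 mmHg located 110 um away on the +x axis, emulating the
#' occasional highly oxygenated vessel inside a measurement grid.
#'
#' The default computational domain is a disk whose zero-flux rim sits at the
#' outer edge of the capillary shell (radius 133 um): the sources represent
#' only the periarteriolar region out to the first capillaries, and the
#' reflective rim stands for the symmetric continuation of the capillary bed
#' beyond them (delivery balancing consumption). With `shape = "rect"` the
#' same sources are solved on a 300 x 300 um box instead; tissue beyond the
#' capillary shell then has no O2 source at all and the field decays
#' unphysically towards the corners.
#'
#' @param mesh_um Grid spacing, um.
#' @param shape `"disk"` (default) or `"rect"` domain.
#' @return A [geometry_spec()].
#' @export
fig2d_geometry <- function(mesh_um = 1, shape = c("disk", "rect")) {
  shape <- match.arg(shape)
  cap_r <- c(80, 88, 97, 105, 113, 122, 130)
  cap_theta <- (seq_along(cap_r) - 0.5) * 2 * pi / length(cap_r)
  caps <- purrr::pmap_dfr(
    list(cap_r, cap_theta),
    function(r, th) vessel_source(r * cos(th), r * sin(th), radius = 2.5,
                                  po2 = 35, label = "capillary"))
  sources <- dplyr::bind_rows(
    vessel_source(0, 0, radius = 7.5, po2 = 70, label = "arteriole"),
    caps,
    vessel_source(110, 0, radius = 7.5, po2 = 60, label = "arteriole")
  )
  if (shape == "disk") {
    geometry_spec(sources, domain = c(-135, 135, -135, 135),
                  mesh_um = mesh_um, shape = "disk", disk_radius = 133)
  } else {
    geometry_spec(sources, domain = c(-150, 150, -150, 150), mesh_um = mesh_um)
  }
}

#' Solve the steady-state 2-D oxygen diffusion (Poisson) equation
#'
#' Finite-difference solution of `laplacian(P) = cmro2 / (D alpha)` on the
#' geometry's mesh: 5-point stencil with Shortley-Weller corrected spacings
#' where a stencil arm crosses a vessel wall (so the Dirichlet condition is
#' imposed on the true circle, second-order accurate), fixed intravascular
#' pO2 inside each source, and a reflective (zero-flux) outer boundary.
#' Consumption is uniform outside the vessels.
#'
#' @param geom A [geometry_spec()].
#' @param cmro2 O2 consumption rate, umol cm^-3 min^-1.
#' @param constants A [tissue_constants()] bundle.
#' @return A `po2_field` object: list with `values` (matrix, `values[i, j]`
#'   is pO2 at `(x_um[i], y_um[j])`, `NA` outside a disk domain), `x_um`,
#'   `y_um`, `source_id` matrix, the geometry, and the relative residual of
#'   the discrete linear system.
#' @export
solve_poisson_2d <- function(geom, cmro2, constants = tissue_constants()) {
  stopifnot(inherits(geom, "geometry_spec"))
  src <- geom$sources
  if (nrow(src) == 0) {
    abort("Geometry has no sources; the Neumann problem is singular.",
          class = "odaciti_no_source")
  }
  h <- geom$mesh_um
  if (h > min(src$radius) / 2) {
    abort(sprintf(
      "mesh_um = %g does not resolve the smallest vessel (radius %g um needs mesh <= %g).",
      h, min(src$radius), min(src$radius) / 2), class = "odaciti_resolution_error")
  }
  x <- seq(geom$domain[1], geom$domain[2], by = h)
  y <- seq(geom$domain[3], geom$domain[4], by = h)
  nx <- length(x); ny <- length(y)
  X <- rep(x, times = ny); Y <- rep(y, each = nx)

  in_domain <- rep(TRUE, nx * ny)
  if (geom$shape == "disk") {
    in_domain <- (X - geom$disk_center[1])^2 + (Y - geom$disk_center[2])^2 <=
      geom$disk_radius^2
  }
  source_id <- integer(nx * ny)
  for (s in seq_len(nrow(src))) {
    hit <- (X - src$cx[s])^2 + (Y - src$cy[s])^2 <= src$radius[s]^2
    source_id[hit] <- s
  }
  dirichlet <- in_domain & source_id > 0L
  free <- in_domain & source_id == 0L
  if (!any(dirichlet)) {
    abort("No mesh node falls inside a source; refine the mesh.",
          class = "odaciti_resolution_error")
  }

  eq <- integer(nx * ny)
  eq[free] <- seq_len(sum(free))
  n_free <- sum(free)
  fidx <- which(free)
  fx <- ((fidx - 1L) %% nx) + 1L
  fy <- ((fidx - 1L) %/% nx) + 1L

  # per direction: neighbour classification
  dir_dx <- c(-1L, 1L, 0L, 0L)
  dir_dy <- c(0L, 0L, -1L, 1L)
  side <- vector("list", 4)
  for (d in 1:4) {
    nxi <- fx + dir_dx[d]
    nyi <- fy + dir_dy[d]
    ok <- nxi >= 1L & nxi <= nx & nyi >= 1L & nyi <= ny
    nidx <- ifelse(ok, (nyi - 1L) * nx + nxi, NA_integer_)
    type <- rep(2L, n_free)                       # 2 = neumann (reflect)
    type[ok & free[pmax(nidx, 1L)]] <- 0L         # 0 = free coupling
    type[ok & dirichlet[pmax(nidx, 1L)]] <- 1L    # 1 = dirichlet arm
    spacing <- rep(h, n_free)
    gval <- rep(NA_real_, n_free)
    di <- which(type == 1L)
    if (length(di)) {
      sid <- source_id[nidx[di]]
      px <- x[fx[di]]; py <- y[fy[di]]
      cxs <- src$cx[sid]; cys <- src$cy[sid]; rad <- src$radius[sid]
      wx <- px - cxs; wy <- py - cys
      b <- wx * dir_dx[d] + wy * dir_dy[d]
      cc <- wx^2 + wy^2 - rad^2
      disc <- pmax(b^2 - cc, 0)
      t1 <- (-b - sqrt(disc)) / h
      t2 <- (-b + sqrt(disc)) / h
      theta <- ifelse(t1 > 1e-9, t1, t2)
      theta <- pmin(pmax(theta, 1e-3), 1)
      spacing[di] <- theta * h
      gval[di] <- src$po2[sid]
    }
    side[[d]] <- list(type = type, nidx = nidx, spacing = spacing, gval = gval)
  }

  k4 <- quarter_coef(cmro2, constants)        # mmHg / um^2
  rhs <- rep(4 * k4, n_free)
  diag_acc <- numeric(n_free)
  trip_i <- vector("list", 8); trip_j <- vector("list", 8); trip_x <- vector("list", 8)
  tcount <- 0L

  for (axis in 1:2) {
    l <- side[[2 * axis - 1]]; r <- side[[2 * axis]]
    hl <- l$spacing; hr <- r$spacing
    # zero-flux sides: drop the missing face (finite-volume view -- the
    # reflective boundary sits half a cell beyond the last node)
    both_n <- l$type == 2L & r$type == 2L
    l_only_n <- l$type == 2L & r$type != 2L
    r_only_n <- r$type == 2L & l$type != 2L
    a_l <- 2 / (hl * (hl + hr))
    a_r <- 2 / (hr * (hl + hr))
    a_l[l_only_n] <- 0
    a_r[l_only_n] <- 1 / hr[l_only_n]^2
    a_r[r_only_n] <- 0
    a_l[r_only_n] <- 1 / hl[r_only_n]^2
    a_l[both_n] <- 0; a_r[both_n] <- 0

    for (sd in list(list(s = l, a = a_l), list(s = r, a = a_r))) {
      cpl <- sd$s$type == 0L & sd$a > 0
      if (any(cpl)) {
        tcount <- tcount + 1L
        trip_i[[tcount]] <- eq[fidx][cpl]
        trip_j[[tcount]] <- eq[sd$s$nidx[cpl]]
        trip_x[[tcount]] <- sd$a[cpl]
      }
      dir <- sd$s$type == 1L & sd$a > 0
      rhs[dir] <- rhs[dir] - sd$a[dir] * sd$s$gval[dir]
      diag_acc <- diag_acc - sd$a
    }
  }

  # isolated staircase pixels (all four arms reflective) would make the
  # system singular; give them an identity row and blank them afterwards
  isolated <- diag_acc == 0
  diag_acc[isolated] <- -1
  rhs[isolated] <- 0

  tcount <- tcount + 1L
  trip_i[[tcount]] <- eq[fidx]
  trip_j[[tcount]] <- eq[fidx]
  trip_x[[tcount]] <- diag_acc

  A <- Matrix::sparseMatrix(
    i = unlist(trip_i[seq_len(tcount)]),
    j = unlist(trip_j[seq_len(tcount)]),
    x = unlist(trip_x[seq_len(tcount)]),
    dims = c(n_free, n_free)
  )
  u <- as.numeric(Matrix::solve(A, rhs))
  resid <- sqrt(sum((as.numeric(A %*% u) - rhs)^2)) / sqrt(sum(rhs^2))

  u[isolated] <- NA_real_
  vals <- rep(NA_real_, nx * ny)
  vals[free] <- u
  vals[dirichlet] <- src$po2[source_id[dirichlet]]
  values <- matrix(vals, nrow = nx, ncol = ny)
  if (min(vals, na.rm = TRUE) < 0) {
    warn("Solved field contains negative pO2 values (over-consumption geometry).")
  }
  structure(
    list(values = values, x_um = x, y_um = y,
         source_id = matrix(source_id, nrow = nx, ncol = ny),
         geometry = geom, cmro2 = cmro2, constants = constants,
         residual = resid),
    class = "po2_field"
  )
}

#' @export
print.po2_field <- function(x, ...) {
  cat(sprintf("pO2 field: %d x %d nodes (%g um mesh), %d sources, cmro2 = %g\n",
              length(x$x_um), length(x$y_um), x$geometry$mesh_um,
              nrow(x$geometry$sources), x$cmro2))
  cat(sprintf("  range %.2f - %.2f mmHg, linear-system residual %.2e\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              x$residual))
  invisible(x)
}

#' Square measurement grid layout
#'
#' `n x n` points spanning a square field of view, mimicking the serial
#' point-measurement grids of the experiments (default 20 x 20 = 400 points
#' over 300 x 300 um).
#'
#' @param n Points per side.
#' @param fov_um Field-of-view side length, um.
#' @param center Grid center, um.
#' @return Tibble with `x_um`, `y_um`.
#' @export
square_grid <- function(n = 20, fov_um = 300, center = c(0, 0)) {
  g <- seq(-fov_um / 2, fov_um / 2, length.out = n)
  tidyr::expand_grid(x_um = g + center[1], y_um = g + center[2])
}

#' Sample a solved pO2 field at measurement-grid points
#'
#' Bilinear interpolation of the field at each point; points falling inside a
#' vessel take that vessel's intravascular pO2. Points outside the solved
#' domain raise a domain error.
#'
#' @param field A `po2_field` from [solve_poisson_2d()].
#' @param points Data frame with `x_um`, `y_um` (e.g. [square_grid()]).
#' @param n_cycles Cycle count recorded per point.
#' @param depth_um,arteriole_id,subject_id Metadata carried on the grid.
#' @param center Arteriole center; defaults to the first source labelled
#'   `"arteriole"`.
#' @param r_ves_um Arteriole radius; defaults to that source's radius.
#' @return A `po2_grid` tibble: `x_um`, `y_um`, `po2_mmhg`, `n_cycles`, with
#'   attributes `center`, `r_ves_um`, `depth_um`, `arteriole_id`,
#'   `subject_id`.
#' @export
sample_field_to_grid <- function(field, points, n_cycles = 1000,
                                 depth_um = NA_real_, arteriole_id = "sim",
                                 subject_id = "sim", center = NULL,
                                 r_ves_um = NULL) {
  stopifnot(inherits(field, "po2_field"), is.data.frame(points))
  src <- field$geometry$sources
  if (is.null(center) || is.null(r_ves_um)) {
    a <- which(src$label == "arteriole")[1]
    if (is.na(a)) a <- 1L
    if (is.null(center)) center <- c(src$cx[a], src$cy[a])
    if (is.null(r_ves_um)) r_ves_um <- src$radius[a]
  }
  px <- points$x_um; py <- points$y_um
  x <- field$x_um; y <- field$y_um
  if (any(px < min(x) | px > max(x) | py < min(y) | py > max(y))) {
    abort("Grid point outside the solved domain.", class = "odaciti_domain_error")
  }
  po2 <- rep(NA_real_, length(px))
  for (s in seq_len(nrow(src))) {
    hit <- (px - src$cx[s])^2 + (py - src$cy[s])^2 <= src$radius[s]^2
    po2[hit] <- src$po2[s]
  }
  todo <- which(is.na(po2))
  if (length(todo)) {
    h <- field$geometry$mesh_um
    ix <- pmin(pmax(findInterval(px[todo], x), 1L), length(x) - 1L)
    iy <- pmin(pmax(findInterval(py[todo], y), 1L), length(y) - 1L)
    tx <- (px[todo] - x[ix]) / (x[ix + 1L] - x[ix])
    ty <- (py[todo] - y[iy]) / (y[iy + 1L] - y[iy])
    v00 <- field$values[cbind(ix, iy)]
    v10 <- field$values[cbind(ix + 1L, iy)]
    v01 <- field$values[cbind(ix, iy + 1L)]
    v11 <- field$values[cbind(ix + 1L, iy + 1L)]
    po2[todo] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
      (1 - tx) * ty * v01 + tx * ty * v11
  }
  if (any(is.na(po2))) {
    abort("Grid point outside the solved domain (masked region).",
          class = "odaciti_domain_error")
  }
  as_po2_grid(tibble(x_um = px, y_um = py, po2_mmhg = po2,
                     n_cycles = n_cycles),
              center = center, r_ves_um = r_ves_um, depth_um = depth_um,
              arteriole_id = arteriole_id, subject_id = subject_id)
}

#' Construct a pO2 measurement grid
#'
#' @param df Data frame with at least `x_um`, `y_um`, `po2_mmhg`.
#' @param center Length-2 arteriole center, um.
#' @param r_ves_um Arteriole radius, um.
#' @param depth_um,arteriole_id,subject_id Plane metadata.
#' @return A `po2_grid` tibble.
#' @export
as_po2_grid <- function(df, center, r_ves_um, depth_um = NA_real_,
                        arteriole_id = NA_character_,
                        subject_id = NA_character_) {
  needed <- c("x_um", "y_um", "po2_mmhg")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "odaciti_schema_error")
  }
  if (!"n_cycles" %in% names(df)) df$n_cycles <- NA_real_
  out <- as_tibble(df)
  structure(out, center = as.numeric(center), r_ves_um = r_ves_um,
            depth_um = depth_um, arteriole_id = arteriole_id,
            subject_id = subject_id,
            class = c("po2_grid", class(out)))
}

#' Add measurement noise to pO2 values
#'
#' `mode = "sampled"` (default) replaces each pO2 value by a draw from
#' `Normal(pO2, sigma)`. `mode = "literal_mu_plus_sigma"` instead adds
#' exactly `sigma` to every value -- the deterministic upward shift obtained
#' by replacing each value by (mu + sigma); kept for comparison with that
#' construction.
#'
#' @param grid Any data frame with a `po2_mmhg` column (grid or profile).
#' @param sigma Noise SD, mmHg (>= 0); default 2.
#' @param seed Optional seed for reproducible draws.
#' @param mode `"sampled"` or `"literal_mu_plus_sigma"`.
#' @return The input with `po2_mmhg` perturbed; class and attributes kept.
#' @export
add_gaussian_noise <- function(grid, sigma = 2, seed = NULL,
                               mode = c("sampled", "literal_mu_plus_sigma")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(grid))
  if (!"po2_mmhg" %in% names(grid)) {
    abort("`grid` must have a `po2_mmhg` column.", class = "odaciti_schema_error")
  }
  if (!is.numeric(sigma) || sigma < 0) {
    abort("`sigma` must be >= 0.", class = "odaciti_invalid_parameter")
  }
  if (mode == "literal_mu_plus_sigma") {
    grid$po2_mmhg <- grid$po2_mmhg + sigma
  } else if (sigma > 0) {
    if (!is.null(seed)) {
      old <- get_seed_state()
      on.exit(restore_seed_state(old), add = TRUE)
      set.seed(seed)
    }
    grid$po2_mmhg <- rnorm(nrow(grid), mean = grid$po2_mmhg, sd = sigma)
  }
  grid
}

#' Generate a Krogh-with-plateau synthetic radial profile
#'
#' The standard synthetic validation dataset: `p_ves` inside the vessel
#' (`r < r_ves`), the Krogh-Erlang solution on `[r_ves, r_t]`, and (when
#' `plateau = TRUE`) a constant capillary-bed level equal to `pO2(r_t)` for
#' `r > r_t`. Continuous at both joins by construction.
#'
#' @param p A [krogh_params()] object (the generating ground truth).
#' @param radii Sampling radii, um; default 0-100 um in 2-um steps, the
#'   radial extent and bin width of the experimental profiles.
#' @param plateau Keep the constant level beyond `r_t`? If `FALSE`, radii
#'   beyond `r_t` are dropped.
#' @return A `radial_profile` tibble (`r_um`, `po2_mmhg`) with attributes
#'   `r_ves_um`, `r_t_um` and `true_params`.
#' @export
generate_krogh_synthetic <- function(p, radii = seq(0, 100, by = 2),
                                     plateau = TRUE) {
  stopifnot(inherits(p, "krogh_params"))
  if (!plateau) radii <- radii[radii <= p$r_t]
  po2 <- ifelse(
    radii < p$r_ves, p$p_ves,
    ifelse(radii <= p$r_t, krogh_po2(pmin(pmax(radii, p$r_ves), p$r_t), p),
           krogh_po2(p$r_t, p)))
  as_radial_profile(tibble(r_um = radii, po2_mmhg = po2),
                    r_ves_um = p$r_ves, r_t_um = p$r_t, true_params = p)
}

#' @rdname generate_krogh_synthetic
#' @param n,fov_um Measurement-grid layout for the grid variant: `n x n`
#'   points over a square field of view of side `fov_um`, centered on the
#'   vessel.
#' @export
generate_krogh_synthetic_grid <- function(p, n = 20, fov_um = 300,
                                          plateau = TRUE) {
  stopifnot(inherits(p, "krogh_params"))
  g <- square_grid(n, fov_um)
  r <- sqrt(g$x_um^2 + g$y_um^2)
  if (!plateau) g <- g[r <= p$r_t, , drop = FALSE]
  r <- sqrt(g$x_um^2 + g$y_um^2)
  po2 <- ifelse(
    r < p$r_ves, p$p_ves,
    ifelse(r <= p$r_t, krogh_po2(pmin(pmax(r, p$r_ves), p$r_t), p),
           krogh_po2(p$r_t, p)))
  as_po2_grid(tibble(x_um = g$x_um, y_um = g$y_um, po2_mmhg = po2),
              center = c(0, 0), r_ves_um = p$r_ves)
}

#' @rdname generate_krogh_synthetic
#' @param df Data frame with `r_um`, `po2_mmhg`.
#' @param r_ves_um,r_t_um,true_params Metadata attributes.
#' @export
as_radial_profile <- function(df, r_ves_um = NA_real_, r_t_um = NA_real_,
                              true_params = NULL) {
  needed <- c("r_um", "po2_mmhg")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "odaciti_schema_error")
  }
  if (nrow(df) == 0) abort("Radial profile is empty.", class = "odaciti_empty_roi")
  out <- as_tibble(df)
  structure(out, r_ves_um = r_ves_um, r_t_um = r_t_um,
            true_params = true_params,
            class = c("radial_profile", class(out)))
}
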