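# Spatial ligand densities. The local density at a site conditional on its
# occupancy, rho(R | n_j), is estimated by a Gaussian kernel density over
# the pose centroids observed at that occupancy level and normalized so that
# its integral over the site volume equals n_j. The unconditional site
# density follows by occupancy-weighting, rho_j(R) = sum_n rho(n_j) *
# rho(R | n_j), integrating to <n_j>; z-projections add the homogeneous
# reservoir term rho_bar * A(z) outside the sites.

#' Regular scalar density grid
#'
#' @param origin Length-3 numeric: position of the first grid node (A).
#' @param spacing Isotropic node spacing (A, > 0).
#' @param values 3D numeric array of number densities (A^-3), dimensions
#'   `(nx, ny, nz)`.
#' @return Object of class `density_grid`.
#' @export
density_grid <- function(origin, spacing, values) {
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 vector", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (A)", call. = FALSE)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("grid values must be finite and >= 0", call. = FALSE)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dim = dim(values), values = values),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d nodes, spacing %.3g A, integral %.6g\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, grid_integral(x)))
  invisible(x)
}

#' Integral of a density grid
#'
#' Voxel sum times `spacing^3`; for a conditional density this equals the
#' occupancy level `n_j`, for a site density the mean occupancy `<n_j>`.
#'
#' @param grid A [density_grid()].
#' @return The integral (number of molecules).
#' @export
grid_integral <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  sum(grid$values) * grid$spacing^3
}

.grid_axis <- function(grid, d) {
  grid$origin[d] + (seq_len(grid$dim[d]) - 1L) * grid$spacing
}

.same_grid <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) < tol) && abs(a$spacing - b$spacing) < tol &&
    all(a$dim == b$dim)
}

# Scott-style bandwidth on 3D points, floored.
.kernel_bandwidth <- function(points, floor = 0.8) {
  m <- nrow(points)
  if (m < 2L) return(floor)
  s <- sqrt(mean(apply(points, 2, stats::var)))
  if (!is.finite(s) || s <= 0) return(floor)
  max(floor, s * m^(-1 / 7))
}

#' Conditional ligand density at a site
#'
#' Gaussian kernel density over the ligand centroids observed with the site
#' at occupancy level `n` (for `n = 2`, both centroids of each two-ligand
#' configuration contribute), normalized so the grid integral equals `n`.
#'
#' @param points Numeric matrix (m x 3) of ligand centroids (A).
#' @param n Occupancy level the ensemble represents (integer >= 1).
#' @param spacing Grid spacing in A (default 0.5).
#' @param bandwidth Gaussian kernel sigma in A; default is a Scott-style
#'   rule on the centroid spread, floored at 0.8 A.
#' @param padding Grid padding beyond the extreme centroids (default
#'   `3 * bandwidth`).
#' @return A [density_grid()] whose integral is exactly `n`.
#' @export
conditional_density <- function(points, n, spacing = 0.5, bandwidth = NULL,
                                padding = NULL) {
  points <- as.matrix(points)
  if (nrow(points) == 0L)
    stop("no poses at this occupancy level; use a zero density instead",
         call. = FALSE)
  if (ncol(points) != 3L || any(!is.finite(points)))
    stop("`points` must be a finite m x 3 matrix", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- .kernel_bandwidth(points)
  if (bandwidth <= 0) stop("`bandwidth` must be > 0", call. = FALSE)
  if (is.null(padding)) padding <- 3 * bandwidth
  lo <- apply(points, 2, min) - padding
  hi <- apply(points, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  axes <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 1L) * spacing)
  values <- array(0, dims)
  for (i in seq_len(nrow(points))) {
    gx <- stats::dnorm(axes[[1]], points[i, 1], bandwidth)
    gy <- stats::dnorm(axes[[2]], points[i, 2], bandwidth)
    gz <- stats::dnorm(axes[[3]], points[i, 3], bandwidth)
    values <- values + outer(outer(gx, gy), gz)
  }
  tot <- sum(values) * spacing^3
  if (tot <= 0) stop("kernel mass vanished on the grid", call. = FALSE)
  density_grid(lo, spacing, values * (n / tot))
}

#' Occupancy-weighted site density
#'
#' `rho_j(R) = sum_n rho(n_j) * rho(R | n_j)`; the grid integral equals the
#' mean site occupancy `<n_j> = sum_n n * rho(n_j)`.
#'
#' @param conditionals Named list of [density_grid()]s, one per occupancy
#'   level (names "1", "2", ...), all on an identical grid.
#' @param marginal Numeric probability vector `rho(n_j)` over levels
#'   `0..n_max` (must sum to 1); levels with positive probability must have
#'   a conditional density (level 0 contributes nothing).
#' @return A [density_grid()].
#' @export
site_density <- function(conditionals, marginal) {
  if (abs(sum(marginal) - 1) > 1e-6)
    stop("`marginal` must sum to 1", call. = FALSE)
  nmax <- length(marginal) - 1L
  ref <- NULL
  values <- NULL
  for (n in seq_len(nmax)) {
    p <- marginal[n + 1L]
    g <- conditionals[[as.character(n)]]
    if (is.null(g)) {
      if (p > 1e-12)
        stop("marginal has weight at level ", n,
             " but no conditional density was given", call. = FALSE)
      next
    }
    stopifnot(inherits(g, "density_grid"))
    if (is.null(ref)) {
      ref <- g
      values <- p * g$values
    } else {
      if (!.same_grid(ref, g))
        stop("conditional densities are on mismatched grids", call. = FALSE)
      values <- values + p * g$values
    }
  }
  if (is.null(ref)) {
    # all occupied-level weight is zero: an empty site
    g0 <- conditionals[[1L]]
    if (is.null(g0)) stop("no conditional densities given", call. = FALSE)
    return(density_grid(g0$origin, g0$spacing, array(0, g0$dim)))
  }
  density_grid(ref$origin, ref$spacing, values)
}

#' Project a density grid onto the z axis
#'
#' @param grid A [density_grid()].
#' @return Data frame with node coordinate `z` (A) and linear density
#'   `density` (A^-1, voxel sums times `spacing^2`); its integral
#'   (`sum * spacing`) equals the grid integral.
#' @export
z_profile <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  data.frame(z = .grid_axis(grid, 3L),
             density = apply(grid$values, 3L, sum) * grid$spacing^2)
}

#' Transmembrane density profile with reservoir baseline
#'
#' Combines per-site z-projections with the homogeneous reservoir term:
#' `rho(z) = rho_bar * A(z) + sum_j rho_j(z)`, where `A(z)` is the membrane-
#' aqueous cross-section area. Site grids are resampled mass-conservingly
#' onto a common z axis.
#'
#' @param site_grids Named list of [density_grid()]s (one per site), all with
#'   the same spacing.
#' @param area Cross-section area `A(z)` in A^2 (a single constant
#'   `dx * dy`).
#' @param reservoir A [ligand_reservoir()] supplying the bulk number density
#'   (or `NULL` for no baseline).
#' @param z_range Optional length-2 numeric extending the profile beyond the
#'   site grids.
#' @return Data frame with columns `z`, one linear-density column per site,
#'   `reservoir` and `total` (all A^-1).
#' @export
z_projection <- function(site_grids, area, reservoir = NULL, z_range = NULL) {
  if (length(site_grids) == 0L && is.null(z_range))
    stop("need site grids or an explicit z_range", call. = FALSE)
  sp <- if (length(site_grids)) site_grids[[1L]]$spacing else 0.5
  for (g in site_grids) {
    stopifnot(inherits(g, "density_grid"))
    if (abs(g$spacing - sp) > 1e-9)
      stop("all site grids must share one spacing", call. = FALSE)
  }
  zlo <- min(c(vapply(site_grids, function(g) .grid_axis(g, 3L)[1L], numeric(1)),
               z_range[1L]))
  zhi <- max(c(vapply(site_grids, function(g) utils::tail(.grid_axis(g, 3L), 1L),
                      numeric(1)), z_range[2L]))
  z <- seq(zlo, zhi, by = sp)
  out <- data.frame(z = z)
  total <- numeric(length(z))
  nm <- names(site_grids)
  if (is.null(nm)) nm <- sprintf("site%d", seq_along(site_grids))
  for (i in seq_along(site_grids)) {
    prof <- z_profile(site_grids[[i]])
    idx <- pmin(length(z), pmax(1L, round((prof$z - zlo) / sp) + 1L))
    col <- numeric(length(z))
    for (k in seq_along(idx)) col[idx[k]] <- col[idx[k]] + prof$density[k]
    out[[nm[i]]] <- col
    total <- total + col
  }
  base <- if (is.null(reservoir)) 0 else .as_reservoir(reservoir)$number_density * area
  out$reservoir <- rep(base, length(z))
  out$total <- total + out$reservoir
  out
}

#' Write a density grid as an OpenDX scalar field
#'
#' Plain-text OpenDX format (gridpositions / gridconnections / array), the
#' volumetric format read by common molecular viewers. [read_dx()] is the
#' matching reader; a write-read round trip reproduces the grid to float
#' precision.
#'
#' @param grid A [density_grid()].
#' @param path Output file path.
#' @param name Field name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path, name = "density") {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid$dim
  writeLines(c(
    "# OpenDX scalar field written by multibind",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  vals <- as.vector(aperm(grid$values, c(3L, 2L, 1L))) # z fastest
  pad <- (-length(vals)) %% 3L
  if (pad) vals <- c(vals, rep(NA_real_, pad))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  lines <- apply(m, 1L, function(r) {
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " ")
  })
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               sprintf('object "%s" class field', name),
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' @rdname write_dx
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1L]
  if (is.na(gp)) stop(path, ": not an OpenDX gridpositions file", call. = FALSE)
  counts <- as.integer(utils::tail(strsplit(trimws(gp), "\\s+")[[1L]], 3L))
  og <- grep("^origin", lines, value = TRUE)[1L]
  origin <- as.numeric(strsplit(trimws(og), "\\s+")[[1L]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]][2:4])
  }, numeric(3)))
  spacing <- dmat[1L, 1L]
  if (abs(dmat[2L, 2L] - spacing) > 1e-9 || abs(dmat[3L, 3L] - spacing) > 1e-9)
    stop(path, ": only isotropic axis-aligned grids are supported",
         call. = FALSE)
  start <- grep("data follows", lines)[1L]
  items <- prod(counts)
  vals <- numeric(0)
  i <- start + 1L
  while (length(vals) < items && i <= length(lines)) {
    if (grepl("^(attribute|object|component)", lines[i])) break
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    i <- i + 1L
  }
  if (length(vals) != items)
    stop(path, ": expected ", items, " data values, found ", length(vals),
         call. = FALSE)
  arr <- array(vals, dim = rev(counts))
  density_grid(origin, spacing, aperm(arr, c(3L, 2L, 1L)))
}
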