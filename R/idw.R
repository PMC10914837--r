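## Inverse-distance-weighted interpolation -----------------------------------

#' Inverse-distance-weighted interpolation onto a regular grid
#'
#' Interpolates a per-site scalar (a village WQI, a fluoride concentration,
#' a factor score) onto a regular grid. At grid point g the value is the
#' weighted mean of site values with weights \eqn{w_i = 1/d(g, s_i)^p}; a
#' grid point coinciding with a site takes that site's value exactly. The
#' result is a convex combination, so every grid value lies between the
#' site minimum and maximum. Coordinates are treated as planar (Euclidean);
#' geographic lon/lat must be projected beforehand.
#'
#' @param sites Data frame with columns `x`, `y`, `value` (and optionally
#'   `site`). Duplicate coordinates with conflicting values are an error.
#' @param grid Either a list `list(x =, y =)` of axis tick vectors, or an
#'   integer: the number of ticks per axis over the bounding box of the
#'   sites (default 50).
#' @param power IDW exponent p > 0 (default 2).
#' @param neighborhood `"all"` (default) or an integer k: use only the k
#'   nearest sites per grid point.
#' @return An `idw_surface`: list with axis vectors `x`, `y`, matrix
#'   `values` (`length(x)` rows by `length(y)` columns), `power`,
#'   `neighborhood`.
#' @examples
#' sites <- data.frame(x = c(0, 1), y = c(0, 0), value = c(100, 200))
#' idw_interpolate(sites, grid = list(x = 0.5, y = 0))$values  # 150
#' @export
idw_interpolate <- function(sites, grid = 50, power = 2,
                            neighborhood = "all") {
  if (!is.data.frame(sites) || !all(c("x", "y", "value") %in% names(sites)))
    stop("sites must be a data frame with x, y, value", call. = FALSE)
  if (nrow(sites) < 1) stop("empty site list", call. = FALSE)
  if (!all(is.finite(sites$x)) || !all(is.finite(sites$y)))
    stop("site coordinates must be finite", call. = FALSE)
  if (power <= 0) stop("power must be > 0", call. = FALSE)
  key <- paste(sites$x, sites$y)
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)]))
      if (length(unique(sites$value[key == k])) > 1)
        stop("duplicate coordinates with conflicting values", call. = FALSE)
    sites <- sites[!duplicated(key), ]
  }
  if (is.numeric(grid) && length(grid) == 1) {
    pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
    rx <- pad(range(sites$x)); ry <- pad(range(sites$y))
    grid <- list(x = seq(rx[1], rx[2], length.out = grid),
                 y = seq(ry[1], ry[2], length.out = grid))
  }
  gx <- grid$x; gy <- grid$y
  k_nn <- if (identical(neighborhood, "all")) nrow(sites)
          else min(as.integer(neighborhood), nrow(sites))
  vals <- matrix(NA_real_, length(gx), length(gy))
  for (iy in seq_along(gy)) {
    d2 <- outer(gx, sites$x, "-")^2 +
      matrix((gy[iy] - sites$y)^2, length(gx), nrow(sites), byrow = TRUE)
    d <- sqrt(d2)
    for (ix in seq_along(gx)) {
      di <- d[ix, ]
      use <- if (k_nn < nrow(sites)) order(di)[seq_len(k_nn)]
             else seq_len(nrow(sites))
      if (any(di[use] == 0)) {
        vals[ix, iy] <- sites$value[use[di[use] == 0][1]]
      } else {
        w <- 1 / di[use]^power
        vals[ix, iy] <- sum(w * sites$value[use]) / sum(w)
      }
    }
  }
  structure(list(x = gx, y = gy, values = vals, power = power,
                 neighborhood = neighborhood, sites = sites),
            class = "idw_surface")
}

#' Classify an interpolated surface into quality bands
#'
#' Maps every grid cell of an interpolated WQI surface through
#' [categorize_wqi()], yielding the categorical surface behind a
#' spatial-distribution map.
#'
#' @param surface An `idw_surface` from [idw_interpolate()].
#' @return List with `bands` (character matrix, same shape as the values)
#'   and `counts` (table of cells per band).
#' @export
classify_surface <- function(surface) {
  stopifnot(inherits(surface, "idw_surface"))
  b <- matrix(as.character(categorize_wqi(as.vector(surface$values))),
              nrow(surface$values), ncol(surface$values))
  list(bands = b, counts = table(factor(b, levels = levels(categorize_wqi(0)))))
}

#' @export
print.idw_surface <- function(x, ...) {
  cat("IDW surface: ", length(x$x), " x ", length(x$y), " grid from ",
      nrow(x$sites), " sites (p = ", x$power, ", neighborhood = ",
      if (identical(x$neighborhood, "all")) "all" else x$neighborhood,
      ")\n", sep = "")
  cat("value range:", format(range(x$values), digits = 5), "\n")
  invisible(x)
}

#' @describeIn idw_interpolate Image plot of the surface with site
#'   locations overlaid.
#' @param x An `idw_surface`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.idw_surface <- function(x, ...) {
  graphics::image(x$x, x$y, x$values, xlab = "x", ylab = "y",
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE), ...)
  graphics::points(x$sites$x, x$sites$y, pch = 21, bg = "white")
  invisible(x)
}

#' Write an IDW surface as an ESRI ASCII raster
#'
#' Plain-text raster dialect importable by common GIS tools. Requires a
#' uniformly spaced square-celled grid.
#'
#' @param surface An `idw_surface`.
#' @param path Output file path.
#' @export
write_ascii_grid <- function(surface, path) {
  stopifnot(inherits(surface, "idw_surface"))
  dx <- diff(surface$x); dy <- diff(surface$y)
  if (length(dx) && (max(abs(dx - dx[1])) > 1e-9 * abs(dx[1]) ||
                     max(abs(dy - dy[1])) > 1e-9 * abs(dy[1]) ||
                     abs(dx[1] - dy[1]) > 1e-9 * abs(dx[1])))
    stop("ASCII grid export needs a uniform square-celled grid", call. = FALSE)
  cell <- if (length(dx)) dx[1] else 1
  hdr <- c(paste("ncols", length(surface$x)),
           paste("nrows", length(surface$y)),
           paste("xllcorner", surface$x[1] - cell / 2),
           paste("yllcorner", surface$y[1] - cell / 2),
           paste("cellsize", cell),
           "NODATA_value -9999")
  # rows top-to-bottom per the ESRI convention
  body <- apply(t(surface$values)[rev(seq_along(surface$y)), , drop = FALSE],
                1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
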