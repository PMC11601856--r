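#' Build a rectangular modeling grid
#'
#' Creates the spatial lattice shared by all gridded objects: `n_x * n_y`
#' square cells with 0-based, row-major (x fastest) cell ids, cell-center
#' coordinates in planar lattice units, an area per cell, and a region
#' label assigned from a set of rectangles that must tile the lattice.
#'
#' @param n_x,n_y number of columns and rows (both >= 2).
#' @param region_spec named list of rectangles, each
#'   `c(x0, x1, y0, y1)` in cell units (1-based, inclusive).  The
#'   rectangles must cover every cell exactly once.  Default: one region
#'   named `"all"` covering the lattice.
#' @param cell_area_km2 area of one cell in km^2.
#' @param seed integer seed (kept for interface symmetry; the lattice is
#'   deterministic).
#' @return an object of class `grid_domain`: a data.frame with columns
#'   `cell_id` (0-based), `ix`, `iy` (1-based lattice indices), `x`, `y`
#'   (cell centers), `region`, `area`, and attributes `n_x`, `n_y`.
#' @export
make_domain <- function(n_x, n_y, region_spec = NULL, cell_area_km2 = 1, seed = 0L) {
  stopifnot(n_x >= 2, n_y >= 2)
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (is.null(region_spec)) {
    region_spec <- list(all = c(1, n_x, 1, n_y))
  }
  ix <- rep(seq_len(n_x), times = n_y)
  iy <- rep(seq_len(n_y), each = n_x)
  region <- rep(NA_character_, n_x * n_y)
  hits <- integer(n_x * n_y)
  for (nm in names(region_spec)) {
    r <- region_spec[[nm]]
    stopifnot(length(r) == 4)
    sel <- ix >= r[1] & ix <= r[2] & iy >= r[3] & iy <= r[4]
    region[sel] <- nm
    hits[sel] <- hits[sel] + 1L
  }
  if (any(hits != 1L)) {
    stop("region_spec rectangles must tile the lattice exactly (found ",
         sum(hits == 0L), " uncovered and ", sum(hits > 1L), " overlapping cells)")
  }
  dom <- data.frame(
    cell_id = seq_len(n_x * n_y) - 1L,
    ix = ix, iy = iy,
    x = ix - 0.5, y = iy - 0.5,
    region = region,
    area = cell_area_km2
  )
  attr(dom, "n_x") <- n_x
  attr(dom, "n_y") <- n_y
  class(dom) <- c("grid_domain", "data.frame")
  dom
}

n_cells <- function(domain) nrow(domain)

#' @export
print.grid_domain <- function(x, ...) {
  cat("grid_domain:", attr(x, "n_x"), "x", attr(x, "n_y"), "cells;",
      length(unique(x$region)), "region(s):",
      paste(unique(x$region), collapse = ", "), "\n")
  invisible(x)
}
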