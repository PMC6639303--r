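#' Region-of-interest set for one cell
#'
#' Bundles the hand-drawn regions a single-cell injury assay needs: the cell
#' outline, the injury point, and optionally a background region and a FRAP
#' bleach region. Polygons are n x 2 (row, col) vertex matrices; all
#' coordinates are 1-based pixel centres.
#'
#' Validation enforces the documented contract: polygons must be simple
#' (non-self-intersecting), the background region must be disjoint from the
#' cell, and the injury point must lie on or inside the cell outline.
#'
#' @param cell_polygon n x 2 matrix of cell outline vertices.
#' @param injury_point (row, col) coordinate of the injury site.
#' @param background_polygon Optional background region, disjoint from the
#'   cell polygon.
#' @param bleach_region Optional photobleached region polygon.
#' @return Object of class `roi_set`.
#' @export
roi_set <- function(cell_polygon, injury_point = NULL,
                    background_polygon = NULL, bleach_region = NULL) {
  cell_polygon <- as_polygon(cell_polygon, "cell_polygon")
  ok <- polygon_is_simple(cell_polygon)
  if (!isTRUE(ok))
    stop(sprintf("cell_polygon is self-intersecting (edges %s)",
                 paste(attr(ok, "edges"), collapse = " and ")))
  if (!is.null(injury_point)) {
    injury_point <- as.numeric(injury_point)
    stopifnot(length(injury_point) == 2)
    inside <- point_in_polygon(matrix(injury_point, 1), cell_polygon) ||
      polygon_boundary_dist(injury_point, cell_polygon) <= 1
    if (!inside)
      stop("injury_point lies outside the cell polygon")
  }
  if (!is.null(background_polygon)) {
    background_polygon <- as_polygon(background_polygon, "background_polygon")
    ok <- polygon_is_simple(background_polygon)
    if (!isTRUE(ok))
      stop(sprintf("background_polygon is self-intersecting (edges %s)",
                   paste(attr(ok, "edges"), collapse = " and ")))
    if (polygons_overlap(cell_polygon, background_polygon))
      stop("background_polygon overlaps the cell polygon")
  }
  if (!is.null(bleach_region)) {
    bleach_region <- as_polygon(bleach_region, "bleach_region")
    ok <- polygon_is_simple(bleach_region)
    if (!isTRUE(ok))
      stop(sprintf("bleach_region is self-intersecting (edges %s)",
                   paste(attr(ok, "edges"), collapse = " and ")))
  }
  structure(list(cell_polygon = cell_polygon, injury_point = injury_point,
                 background_polygon = background_polygon,
                 bleach_region = bleach_region),
            class = "roi_set")
}

as_polygon <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 2 || nrow(x) < 3)
    stop(sprintf("%s must be an n x 2 vertex matrix with n >= 3", what))
  storage.mode(x) <- "double"
  unname(x)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> cell outline with %d vertices", nrow(x$cell_polygon)))
  if (!is.null(x$injury_point))
    cat(sprintf(", injury at (%.1f, %.1f)", x$injury_point[1], x$injury_point[2]))
  if (!is.null(x$background_polygon)) cat(", background region")
  if (!is.null(x$bleach_region)) cat(", bleach region")
  cat("\n")
  invisible(x)
}
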