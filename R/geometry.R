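#' Sphere radius from volume
#'
#' Each brain region is modeled as a sphere of the region's measured volume,
#' so the radius is the inverse of the sphere volume formula.
#'
#' @param volume Numeric vector of volumes in mm^3; all entries must be
#'   positive and finite.
#' @return Numeric vector of radii in mm: `(3 * volume / (4 * pi))^(1/3)`.
#' @examples
#' radius_from_volume(4 * pi / 3) # unit sphere
#' @export
radius_from_volume <- function(volume) {
  if (!is.numeric(volume) || length(volume) == 0L) {
    stop("`volume` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    bad <- which(!is.finite(volume) | volume <= 0)[1L]
    stop(sprintf("volumes must be positive and finite (entry %d is %s)",
                 bad, format(volume[bad])), call. = FALSE)
  }
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Construct a packing of spherical regions
#'
#' A packing is an ordered set of named spheres in a common mm coordinate
#' frame. The row order is the canonical index that all adjacency matrices
#' must follow. Radii are derived from volumes and stored alongside.
#'
#' @param regions A data.frame with columns `id`, `acronym`, `x_mm`, `y_mm`,
#'   `z_mm`, `volume_mm3`. Acronyms must be unique, coordinates finite and
#'   volumes positive.
#' @param frame_note Free-text provenance for the coordinate frame.
#' @return An object of class `packing`: the validated data.frame with an
#'   added `radius_mm` column and a `frame_note` attribute.
#' @export
packing <- function(regions, frame_note = "arbitrary right-handed mm frame") {
  required <- c("id", "acronym", "x_mm", "y_mm", "z_mm", "volume_mm3")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0L) {
    stop("region table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  regions <- as.data.frame(regions)[, union(required, names(regions)), drop = FALSE]
  for (col in c("x_mm", "y_mm", "z_mm", "volume_mm3")) {
    if (!is.numeric(regions[[col]])) {
      stop(sprintf("column `%s` must be numeric", col), call. = FALSE)
    }
    if (any(!is.finite(regions[[col]]))) {
      stop(sprintf("column `%s` has a non-finite value in row %d", col,
                   which(!is.finite(regions[[col]]))[1L]), call. = FALSE)
    }
  }
  regions$acronym <- as.character(regions$acronym)
  regions$id <- as.character(regions$id)
  dup <- regions$acronym[duplicated(regions$acronym)]
  if (length(dup) > 0L) {
    stop("duplicate region acronym(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(regions$volume_mm3 <= 0)) {
    stop(sprintf("volume must be > 0 (row %d, acronym %s)",
                 which(regions$volume_mm3 <= 0)[1L],
                 regions$acronym[which(regions$volume_mm3 <= 0)[1L]]),
         call. = FALSE)
  }
  regions$radius_mm <- radius_from_volume(regions$volume_mm3)
  rownames(regions) <- NULL
  structure(regions, frame_note = frame_note,
            class = c("packing", "data.frame"))
}

#' @export
print.packing <- function(x, ...) {
  cat(sprintf("Packing of %d spherical regions (%s)\n", nrow(x),
              attr(x, "frame_note")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more regions\n", nrow(x) - 10L))
  invisible(x)
}

# Internal: n x 3 matrix of centers.
centers_of <- function(packing) {
  as.matrix(as.data.frame(packing)[, c("x_mm", "y_mm", "z_mm")])
}

#' Replace the centers of a packing
#'
#' @param packing A [packing()].
#' @param centers An n x 3 numeric matrix of new coordinates (mm).
#' @return The packing with updated coordinates; radii and order unchanged.
#' @export
set_centers <- function(packing, centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) != nrow(packing) || ncol(centers) != 3L) {
    stop("`centers` must be an n x 3 matrix matching the packing", call. = FALSE)
  }
  if (any(!is.finite(centers))) stop("centers must be finite", call. = FALSE)
  packing$x_mm <- centers[, 1L]
  packing$y_mm <- centers[, 2L]
  packing$z_mm <- centers[, 3L]
  packing
}

#' Pairwise center-to-center distances
#'
#' @param packing A [packing()] with at least two regions.
#' @return A symmetric n x n matrix of Euclidean distances (mm) with zero
#'   diagonal, dimnames set to the region acronyms.
#' @export
pairwise_distances <- function(packing) {
  if (nrow(packing) < 2L) stop("need at least 2 regions", call. = FALSE)
  d <- as.matrix(stats::dist(centers_of(packing)))
  dimnames(d) <- list(packing$acronym, packing$acronym)
  d
}

#' Signed separations between sphere surfaces
#'
#' The signed separation of a pair is the center-to-center distance minus
#' the sum of the two radii: negative values are overlaps, positive values
#' are gaps, zero means the spheres touch.
#'
#' @inheritParams pairwise_distances
#' @return A symmetric n x n matrix (mm); the diagonal is `-2 * radius`
#'   by the formula but is never used and is set to 0.
#' @export
signed_separation <- function(packing) {
  d <- pairwise_distances(packing)
  r <- packing$radius_mm
  sep <- d - outer(r, r, "+")
  diag(sep) <- 0
  sep
}

#' The six overlap/gap statistics of a packing
#'
#' Over all unordered region pairs, an overlap is minus the signed
#' separation where that is negative and a gap is the signed separation
#' where positive; touching pairs count in neither subset. Means are taken
#' over the respective subsets and defined as 0 when a subset is empty,
#' as are the maxima.
#'
#' @inheritParams pairwise_distances
#' @return An object of class `packing_stats`: a list with `total_overlap`,
#'   `mean_overlap`, `max_overlap`, `total_gap`, `mean_gap`, `max_gap` (mm),
#'   `n_overlapping_pairs` and `n_pairs`.
#' @export
packing_stats <- function(packing) {
  sep <- signed_separation(packing)
  v <- sep[upper.tri(sep)]
  overlaps <- -v[v < 0]
  gaps <- v[v > 0]
  structure(list(
    total_overlap = sum(overlaps),
    mean_overlap = if (length(overlaps)) mean(overlaps) else 0,
    max_overlap = if (length(overlaps)) max(overlaps) else 0,
    total_gap = sum(gaps),
    mean_gap = if (length(gaps)) mean(gaps) else 0,
    max_gap = if (length(gaps)) max(gaps) else 0,
    n_overlapping_pairs = length(overlaps),
    n_pairs = length(v)
  ), class = "packing_stats")
}

#' @export
print.packing_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Packing statistics over %d pairs (%d overlapping):\n",
           "  overlap mm: total %.4g, mean %.4g, max %.4g\n",
           "  gap mm:     total %.4g, mean %.4g, max %.4g\n"),
    x$n_pairs, x$n_overlapping_pairs,
    x$total_overlap, x$mean_overlap, x$max_overlap,
    x$total_gap, x$mean_gap, x$max_gap))
  invisible(x)
}

#' Axis-aligned bounding box of a packing
#'
#' The smallest axis-aligned box containing every sphere surface: per axis
#' from `min(center - radius)` to `max(center + radius)`.
#'
#' @param packing A [packing()] with at least one region.
#' @return A list with `origin` (3-vector, mm), `sides` (3-vector, mm) and
#'   `upper` (`origin + sides`).
#' @export
bounding_box <- function(packing) {
  if (nrow(packing) < 1L) stop("need at least 1 region", call. = FALSE)
  x <- centers_of(packing)
  r <- packing$radius_mm
  lo <- apply(x - r, 2L, min)
  hi <- apply(x + r, 2L, max)
  list(origin = unname(lo), sides = unname(hi - lo), upper = unname(hi))
}
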