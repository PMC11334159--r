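#' Validate a weighted adjacency matrix against a packing
#'
#' Directed projection-volume matrices must be square, non-negative, and
#' labeled in the packing's canonical region order. The diagonal is forced
#' to zero at validation (self-projections are excluded from all metrics);
#' a warning is raised if nonzero diagonal entries were present.
#'
#' @param adjacency A square numeric matrix with row and column names equal
#'   to the packing acronyms, or unnamed with matching dimension.
#' @param packing The [packing()] defining the canonical order. Matrices
#'   labeled in a different order are reindexed to it.
#' @return The validated matrix with dimnames set to the acronyms.
#' @export
as_weighted_adjacency <- function(adjacency, packing) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(packing)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency matrix must be square", call. = FALSE)
  }
  if (nrow(adjacency) != n) {
    stop(sprintf("adjacency is %d x %d but the packing has %d regions",
                 nrow(adjacency), ncol(adjacency), n), call. = FALSE)
  }
  if (!is.numeric(adjacency) || any(!is.finite(adjacency))) {
    stop("adjacency entries must be finite numbers", call. = FALSE)
  }
  if (any(adjacency < 0)) {
    idx <- which(adjacency < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative projection volume at (%d, %d)", idx[1L], idx[2L]),
         call. = FALSE)
  }
  if (!is.null(rownames(adjacency))) {
    if (!setequal(rownames(adjacency), packing$acronym) ||
        !identical(rownames(adjacency), colnames(adjacency))) {
      stop("adjacency labels do not match the region acronyms", call. = FALSE)
    }
    adjacency <- adjacency[packing$acronym, packing$acronym]
  } else {
    dimnames(adjacency) <- list(packing$acronym, packing$acronym)
  }
  if (any(diag(adjacency) != 0)) {
    warning("nonzero diagonal entries set to 0 (self-projections excluded)",
            call. = FALSE)
    diag(adjacency) <- 0
  }
  adjacency
}

#' Read a region table
#'
#' Expects a comma-separated UTF-8 file with header columns `id`, `acronym`,
#' `x_mm`, `y_mm`, `z_mm`, `volume_mm3` ('.' decimal separator). Row order
#' becomes the canonical region order.
#'
#' @param path Path to the CSV file.
#' @return A [packing()].
#' @export
read_regions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "acronym", "x_mm", "y_mm", "z_mm", "volume_mm3")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("x_mm", "y_mm", "z_mm", "volume_mm3")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop(sprintf("%s: non-numeric value in column `%s`, row %d",
                   path, col, bad), call. = FALSE)
    }
  }
  packing(df, frame_note = paste("read from", basename(path)))
}

#' Write a region table
#'
#' @param packing A [packing()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(packing, path) {
  df <- as.data.frame(packing)[, c("id", "acronym", "x_mm", "y_mm", "z_mm",
                                   "volume_mm3")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled adjacency matrix
#'
#' Expects a CSV whose first row and first column carry region acronyms
#' (row label = source, column label = target) and whose cells are
#' non-negative projection volumes in mm^3.
#'
#' @param path Path to the CSV file.
#' @param packing Optional [packing()]; when given, labels are checked and
#'   the matrix is reindexed to the packing order.
#' @return A numeric matrix with dimnames.
#' @export
read_adjacency <- function(path, packing = NULL) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE,
                        stringsAsFactors = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop(sprintf("%s: non-numeric cell", path), call. = FALSE)
  if (nrow(mat) != ncol(mat) || !identical(rownames(mat), colnames(mat))) {
    stop(sprintf("%s: adjacency must be square with matching row/column labels",
                 path), call. = FALSE)
  }
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: negative entry at row %s, column %s", path,
                 rownames(mat)[idx[1L]], colnames(mat)[idx[2L]]), call. = FALSE)
  }
  if (!is.null(packing)) mat <- as_weighted_adjacency(mat, packing)
  mat
}

#' Write a labeled adjacency matrix
#'
#' @param adjacency Matrix with dimnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adjacency, path) {
  utils::write.csv(as.data.frame(adjacency), path, row.names = TRUE,
                   quote = FALSE)
  invisible(path)
}

#' Read a raw viral-tracing experiment table
#'
#' Long-format CSV with columns `experiment_id`, `source_acronym`, `x_mm`,
#' `y_mm`, `z_mm` (injection position), `target_acronym`,
#' `projection_volume_mm3`. Atlas-style data carry several replicate
#' injection experiments per source region.
#'
#' @param path Path to the CSV file.
#' @return A data.frame of experiment records.
#' @export
read_experiments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("experiment_id", "source_acronym", "x_mm", "y_mm", "z_mm",
                "target_acronym", "projection_volume_mm3")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(df$projection_volume_mm3 < 0)) {
    stop(sprintf("%s: negative projection volume in row %d", path,
                 which(df$projection_volume_mm3 < 0)[1L]), call. = FALSE)
  }
  df
}

#' Pick the maximum-intensity experiment for a source region
#'
#' Replicate injection experiments for the same source region are reduced
#' to the one with the greatest intensity, operationalized as the greatest
#' total projection volume summed over targets; ties break toward the
#' lexicographically smallest experiment id for determinism.
#'
#' @param experiments A data.frame from [read_experiments()].
#' @param source Source region acronym.
#' @return A list with `experiment_id`, `source_acronym`,
#'   `injection_position` (3-vector, mm) and `projections` (named numeric
#'   vector of target projection volumes, mm^3).
#' @export
select_max_intensity_experiment <- function(experiments, source) {
  rec <- experiments[experiments$source_acronym == source, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop(sprintf("no experiment records for source region %s", source),
         call. = FALSE)
  }
  totals <- tapply(rec$projection_volume_mm3, rec$experiment_id, sum)
  ids <- sort(names(totals))
  totals <- totals[ids]
  best <- ids[which.max(totals)]  # which.max takes the first = smallest id
  sub <- rec[rec$experiment_id == best, , drop = FALSE]
  list(
    experiment_id = best,
    source_acronym = source,
    injection_position = unname(as.numeric(sub[1L, c("x_mm", "y_mm", "z_mm")])),
    projections = stats::setNames(sub$projection_volume_mm3,
                                  sub$target_acronym)
  )
}

#' Average injection position for a source region
#'
#' Replicate experiments inject at slightly different coordinates; the
#' region's model position is the geometric center of the injections, i.e.
#' the per-axis arithmetic centroid over distinct experiments. (A per-axis
#' geometric mean is undefined for non-positive coordinates and is not
#' used.)
#'
#' @inheritParams select_max_intensity_experiment
#' @return A 3-vector (mm).
#' @export
average_injection_position <- function(experiments, source) {
  rec <- experiments[experiments$source_acronym == source, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop(sprintf("no experiment records for source region %s", source),
         call. = FALSE)
  }
  one <- rec[!duplicated(rec$experiment_id), , drop = FALSE]
  colMeans(as.matrix(one[, c("x_mm", "y_mm", "z_mm")]))
}

#' Remove regions and slice the adjacency accordingly
#'
#' Drops the listed regions (e.g. outlier regions outside the tightly
#' packed bulk) and reduces the adjacency to the aligned submatrix of the
#' survivors, preserving their order.
#'
#' @param packing A [packing()].
#' @param adjacency Aligned weighted adjacency matrix.
#' @param acronyms Character vector of acronyms to remove (may be empty).
#' @return A list with elements `packing` and `adjacency`.
#' @export
remove_regions <- function(packing, adjacency, acronyms) {
  adjacency <- as_weighted_adjacency(adjacency, packing)
  unknown <- setdiff(acronyms, packing$acronym)
  if (length(unknown) > 0L) {
    stop("unknown acronym(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- !(packing$acronym %in% acronyms)
  sub <- packing(as.data.frame(packing)[keep, , drop = FALSE],
                 frame_note = attr(packing, "frame_note"))
  list(packing = sub,
       adjacency = adjacency[packing$acronym[keep], packing$acronym[keep],
                             drop = FALSE])
}

#' Export a wired packing as a graph file
#'
#' Nodes carry coordinates and radius; edges carry projection-volume
#' weights. GraphML export goes through igraph; the edge-csv format writes
#' columns `source,target,weight_mm3` (one row per directed edge).
#'
#' @param packing A [packing()].
#' @param adjacency Aligned weighted adjacency matrix.
#' @param path Output file path.
#' @param format `"graphml"` or `"edge-csv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(packing, adjacency, path,
                         format = c("graphml", "edge-csv")) {
  format <- match.arg(format)
  adjacency <- as_weighted_adjacency(adjacency, packing)
  if (format == "edge-csv") {
    idx <- which(adjacency > 0, arr.ind = TRUE)
    edges <- data.frame(
      source = rownames(adjacency)[idx[, 1L]],
      target = colnames(adjacency)[idx[, 2L]],
      weight_mm3 = adjacency[idx]
    )
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "directed",
                                             weighted = TRUE)
    igraph::V(g)$x <- packing$x_mm
    igraph::V(g)$y <- packing$y_mm
    igraph::V(g)$z <- packing$z_mm
    igraph::V(g)$radius <- packing$radius_mm
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
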