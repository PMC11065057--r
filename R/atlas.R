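#' Construct a region atlas
#'
#' A region atlas fixes the node set of every connectivity matrix in a run:
#' region ids (1..N), short unique labels, centroid coordinates in mm, and a
#' network assignment per region.  Rows are sorted by `region_id`, and that
#' order defines the row/column order of every matrix.
#'
#' @param region_id integer vector of unique ids, 1..N after sorting
#' @param label character vector of unique short labels
#' @param x_mm,y_mm,z_mm numeric centroid coordinates (mm)
#' @param network character network assignment per region
#' @return a `region_atlas` data frame with columns
#'   `region_id, label, x_mm, y_mm, z_mm, network`
#' @export
region_atlas <- function(region_id, label, x_mm, y_mm, z_mm, network) {
  atlas <- data.frame(
    region_id = as.integer(region_id),
    label = as.character(label),
    x_mm = as.numeric(x_mm),
    y_mm = as.numeric(y_mm),
    z_mm = as.numeric(z_mm),
    network = as.character(network),
    stringsAsFactors = FALSE
  )
  atlas <- atlas[order(atlas$region_id), , drop = FALSE]
  rownames(atlas) <- NULL
  class(atlas) <- c("region_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

#' Validate a region atlas
#'
#' @param atlas a `region_atlas`
#' @return the atlas, invisibly; errors on violation
#' @export
validate_atlas <- function(atlas) {
  req <- c("region_id", "label", "x_mm", "y_mm", "z_mm", "network")
  missing_cols <- setdiff(req, names(atlas))
  if (length(missing_cols)) {
    stop("atlas is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(atlas)
  if (n < 2L) stop("atlas must contain at least 2 regions", call. = FALSE)
  if (anyDuplicated(atlas$region_id)) {
    stop("duplicate region_id values in atlas", call. = FALSE)
  }
  if (anyDuplicated(atlas$label)) {
    stop("duplicate region labels in atlas", call. = FALSE)
  }
  coords <- as.matrix(atlas[, c("x_mm", "y_mm", "z_mm")])
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    stop("atlas centroids must be finite numeric coordinates", call. = FALSE)
  }
  if (is.unsorted(atlas$region_id)) {
    stop("atlas rows must be sorted by region_id", call. = FALSE)
  }
  invisible(atlas)
}

#' Region labels in atlas order
#' @param atlas a `region_atlas`
#' @return character vector of labels
#' @export
atlas_labels <- function(atlas) as.character(atlas$label)

#' Centroid coordinate matrix (N x 3, mm) in atlas order
#' @param atlas a `region_atlas`
#' @return numeric matrix with rownames = labels
#' @export
atlas_centroids <- function(atlas) {
  m <- as.matrix(atlas[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- atlas$label
  m
}

#' Read a region atlas from CSV
#'
#' Expects columns `region_id,label,x_mm,y_mm,z_mm,network`.  Rows are sorted
#' by `region_id`; duplicate ids or labels and non-numeric coordinates are
#' rejected.
#'
#' @param path path to the atlas CSV
#' @return a `region_atlas`
#' @export
read_atlas <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("region_id", "label", "x_mm", "y_mm", "z_mm", "network")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("atlas file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in c("x_mm", "y_mm", "z_mm")) {
    val <- suppressWarnings(as.numeric(tab[[cc]]))
    if (any(is.na(val))) {
      stop("non-numeric coordinate in column ", cc, " of ", path,
           call. = FALSE)
    }
    tab[[cc]] <- val
  }
  region_atlas(tab$region_id, tab$label, tab$x_mm, tab$y_mm, tab$z_mm,
               tab$network)
}

#' Write a region atlas to CSV
#' @param atlas a `region_atlas`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  write.csv(as.data.frame(atlas), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
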