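#' Validate a connectivity matrix for a declared kind
#'
#' Every matrix in a run is square, symmetric (absolute tolerance 1e-9),
#' zero-diagonal and ordered like the atlas.  Kind-specific range rules:
#' \describe{
#'   \item{SC}{entries >= 0 (FA-weighted structural strength)}
#'   \item{FC}{entries in \[-1, 1\] (Pearson correlations)}
#'   \item{USFC}{entries >= 0 (accumulated absolute functional load)}
#'   \item{DIST}{off-diagonal entries > 0 (Euclidean mm)}
#' }
#'
#' @param values numeric N x N matrix
#' @param kind one of `"SC"`, `"FC"`, `"USFC"`, `"DIST"`
#' @param atlas optional `region_atlas`; when given, dimnames must equal the
#'   atlas labels in order
#' @param tol symmetry tolerance (absolute)
#' @return `values`, invisibly; errors on violation
#' @export
validate_conn_matrix <- function(values, kind = c("SC", "FC", "USFC", "DIST"),
                                 atlas = NULL, tol = 1e-9) {
  kind <- match.arg(kind)
  check_symmetric(values, tol = tol, what = paste0(kind, " matrix"))
  if (max(abs(diag(values))) > tol) {
    stop(kind, " matrix must have a zero diagonal", call. = FALSE)
  }
  off <- values[row(values) != col(values)]
  switch(kind,
    SC = if (any(off < 0)) {
      stop("SC matrix contains negative entries", call. = FALSE)
    },
    FC = if (any(off < -1 - tol) || any(off > 1 + tol)) {
      stop("FC matrix contains entries outside [-1, 1]", call. = FALSE)
    },
    USFC = if (any(off < 0)) {
      stop("USFC matrix contains negative entries", call. = FALSE)
    },
    DIST = if (any(off <= 0)) {
      stop("DIST matrix must have strictly positive off-diagonal entries",
           call. = FALSE)
    }
  )
  if (!is.null(atlas)) {
    labs <- atlas_labels(atlas)
    if (is.null(rownames(values)) ||
        !identical(rownames(values), labs) ||
        !identical(colnames(values), labs)) {
      stop(kind, " matrix dimnames do not match the atlas label order",
           call. = FALSE)
    }
  }
  invisible(values)
}

#' Read a connectivity matrix from TSV
#'
#' The file is a tab-separated (N+1) x (N+1) table with region labels on both
#' axes.  Labels must be exactly the atlas label set (any order); the matrix
#' is reordered to atlas order and validated for the declared kind.
#'
#' @param path path to the TSV file
#' @param atlas a `region_atlas` defining labels and order
#' @inheritParams validate_conn_matrix
#' @return numeric matrix in atlas order with label dimnames
#' @export
read_conn_matrix <- function(path, atlas,
                             kind = c("SC", "FC", "USFC", "DIST"),
                             tol = 1e-9) {
  kind <- match.arg(kind)
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    stop("matrix file ", path, " contains non-numeric entries", call. = FALSE)
  }
  labs <- atlas_labels(atlas)
  file_rows <- rownames(m)
  file_cols <- colnames(m)
  if (!setequal(file_rows, labs) || !setequal(file_cols, labs) ||
      anyDuplicated(file_rows) || anyDuplicated(file_cols)) {
    missing_l <- setdiff(labs, file_rows)
    extra_l <- setdiff(file_rows, labs)
    stop("label mismatch between ", path, " and atlas",
         if (length(missing_l)) paste0("; missing: ",
                                       paste(head(missing_l, 5), collapse = ", ")),
         if (length(extra_l)) paste0("; extra: ",
                                     paste(head(extra_l, 5), collapse = ", ")),
         call. = FALSE)
  }
  m <- m[labs, labs, drop = FALSE]
  validate_conn_matrix(m, kind, atlas = atlas, tol = tol)
  m
}

#' Write a connectivity matrix to TSV
#'
#' Tab-separated with region labels on both axes (the header row starts with
#' an empty cell), the dialect [read_conn_matrix()] parses back.
#'
#' @param values numeric matrix with label dimnames
#' @param path output path
#' @return `path`, invisibly
#' @export
write_conn_matrix <- function(values, path) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("matrix must carry label dimnames to be written", call. = FALSE)
  }
  write.table(format(values, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
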