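`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical key for an unordered region pair
#' @param i,j integer region indices (vectorised)
#' @return character key "min:max"
#' @keywords internal
#' @noRd
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = ":")
}

pair_from_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  t(vapply(parts, function(p) as.integer(p), integer(2)))
}

#' Check that a matrix is square and symmetric within tolerance
#' @noRd
check_symmetric <- function(m, tol = 1e-9, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop(what, " must be square, got ", nrow(m), "x", ncol(m), call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop(what, " contains non-finite entries", call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(what, " is asymmetric beyond tolerance ", format(tol),
         " (max |m - t(m)| = ", format(asym), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Lexicographic comparison of two equal-length integer sequences
#' @return TRUE if a < b lexicographically
#' @noRd
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

#' All permutations of 1..n as an n! x n matrix (row-major enumeration)
#' @noRd
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * m + 1L):(k * m)
    rest <- seq_len(n)[-k]
    out[rows, 1L] <- k
    out[rows, -1L] <- matrix(rest[sub], m, n - 1L)
  }
  out
}
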