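#' Construct a route (efficient pathway) between two regions
#'
#' @param nodes integer vector of region indices from source to target
#'   (atlas row positions); must be a simple path
#' @param total_cost summed per-step cost (distance / SC) along the route
#' @return a `usfc_route` list with fields `pair`, `nodes`, `n_steps`,
#'   `total_cost`
#' @export
usfc_route <- function(nodes, total_cost) {
  nodes <- as.integer(nodes)
  if (length(nodes) < 2L) stop("a route needs at least 2 nodes", call. = FALSE)
  if (anyDuplicated(nodes)) {
    stop("route nodes must be distinct (simple path)", call. = FALSE)
  }
  if (!is.finite(total_cost) || total_cost <= 0) {
    stop("route total_cost must be a positive finite number", call. = FALSE)
  }
  structure(
    list(pair = c(nodes[1L], nodes[length(nodes)]),
         nodes = nodes,
         n_steps = length(nodes) - 1L,
         total_cost = as.numeric(total_cost)),
    class = "usfc_route"
  )
}

#' Construct a per-subject route table
#'
#' @param subject_id subject identifier
#' @param routes named list of `usfc_route`, keyed by "i:j" with i < j
#' @param unroutable integer matrix (2 columns) of pairs with no admissible
#'   route within the step limit
#' @return a `route_table`
#' @export
route_table <- function(subject_id, routes = list(),
                        unroutable = matrix(integer(0), ncol = 2)) {
  keys <- names(routes)
  bad <- intersect(keys, if (nrow(unroutable)) {
    pair_key(unroutable[, 1], unroutable[, 2])
  } else character(0))
  if (length(bad)) {
    stop("pairs cannot be both routed and unroutable: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id),
         routes = routes,
         unroutable = unroutable),
    class = "route_table"
  )
}

#' @export
print.route_table <- function(x, ...) {
  cat("<route_table> subject", x$subject_id, "-", length(x$routes),
      "routes,", nrow(x$unroutable), "unroutable pairs\n")
  invisible(x)
}

#' Serialize a subject's routes to CSV
#'
#' One row per routed pair with columns
#' `subject,source,target,route,steps,cost,fc`; the route is the
#' hyphen-joined label sequence.  An empty table writes a header-only file.
#'
#' @param rt a `route_table`
#' @param atlas the `region_atlas` supplying labels
#' @param fc the subject's FC matrix (atlas order)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_route_table <- function(rt, atlas, fc, path) {
  labs <- atlas_labels(atlas)
  rows <- lapply(rt$routes, function(r) {
    nodes <- r$nodes
    if (nodes[1L] != r$pair[1L] || nodes[length(nodes)] != r$pair[2L]) {
      stop("route sequence does not start/end at its pair", call. = FALSE)
    }
    data.frame(
      subject = rt$subject_id,
      source = labs[r$pair[1L]],
      target = labs[r$pair[2L]],
      route = paste(labs[nodes], collapse = "-"),
      steps = r$n_steps,
      cost = r$total_cost,
      fc = fc[r$pair[1L], r$pair[2L]],
      stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), source = character(0),
               target = character(0), route = character(0),
               steps = integer(0), cost = numeric(0), fc = numeric(0))
  rownames(tab) <- NULL
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a route table CSV written by [write_route_table()]
#'
#' @param path CSV path
#' @param atlas the `region_atlas` used when writing
#' @return a data frame with columns
#'   `subject,source,target,route,steps,cost,fc`
#' @export
read_route_table <- function(path, atlas) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "source", "target", "route", "steps", "cost", "fc")
  if (!all(req %in% names(tab))) {
    stop("route table ", path, " lacks required columns", call. = FALSE)
  }
  labs <- atlas_labels(atlas)
  if (nrow(tab)) {
    seqs <- strsplit(tab$route, "-", fixed = TRUE)
    ok <- vapply(seqs, function(s) all(s %in% labs), logical(1))
    if (!all(ok)) {
      stop("route table contains labels absent from the atlas", call. = FALSE)
    }
  }
  tab
}

#' Rebuild a `route_table` object from a serialized route data frame
#'
#' @param tab data frame as returned by [read_route_table()]
#' @param atlas the `region_atlas`
#' @return a `route_table` (unroutable pairs are not serialized and come back
#'   empty)
#' @export
routes_from_table <- function(tab, atlas) {
  labs <- atlas_labels(atlas)
  routes <- list()
  for (k in seq_len(nrow(tab))) {
    nodes <- match(strsplit(tab$route[k], "-", fixed = TRUE)[[1L]], labs)
    r <- usfc_route(nodes, tab$cost[k])
    routes[[pair_key(r$pair[1L], r$pair[2L])]] <- r
  }
  subject <- if (nrow(tab)) tab$subject[1L] else ""
  route_table(subject, routes)
}
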