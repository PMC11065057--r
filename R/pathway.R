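#' Euclidean distance matrix between region centroids
#'
#' Straight-line distances (mm) between centre-of-mass coordinates define the
#' template distance map used by the routing cost.
#'
#' @param atlas a `region_atlas`
#' @return symmetric N x N matrix (mm) with zero diagonal and label dimnames
#' @export
euclidean_distances <- function(atlas) {
  coords <- atlas_centroids(atlas)
  D <- as.matrix(stats::dist(coords, method = "euclidean"))
  dimnames(D) <- list(rownames(coords), rownames(coords))
  off <- D[row(D) != col(D)]
  if (any(off == 0)) {
    stop("coincident centroids for distinct regions (zero distance)",
         call. = FALSE)
  }
  D
}

#' Per-step routing cost: distance over structural strength
#'
#' The economical assumption: a step is cheap when it is short and runs over a
#' strong structural connection.  Absent edges (SC = 0) get infinite cost.
#'
#' @param dist Euclidean distance in mm (> 0), vectorised
#' @param sc_weight structural connectivity strength (>= 0), vectorised
#' @return `dist / sc_weight`, `Inf` where `sc_weight == 0`
#' @export
edge_cost <- function(dist, sc_weight) {
  if (any(dist <= 0)) stop("dist must be > 0", call. = FALSE)
  if (any(sc_weight < 0)) stop("sc_weight must be >= 0", call. = FALSE)
  ifelse(sc_weight == 0, Inf, dist / sc_weight)
}

#' Full cost matrix D / SC with infinite cost on absent edges and the diagonal
#' @noRd
cost_matrix <- function(D, SC) {
  C <- matrix(Inf, nrow(D), ncol(D), dimnames = dimnames(D))
  pos <- SC > 0 & row(SC) != col(SC)
  C[pos] <- D[pos] / SC[pos]
  C
}

resolve_node <- function(x, labs, what = "node") {
  if (is.character(x)) {
    idx <- match(x, labs)
    if (is.na(idx)) stop("unknown ", what, " label: ", x, call. = FALSE)
    return(idx)
  }
  idx <- as.integer(x)
  if (is.na(idx) || idx < 1L || idx > length(labs)) {
    stop("invalid ", what, " index: ", x, call. = FALSE)
  }
  idx
}

#' Hop-bounded single-source search over the cost matrix
#'
#' Bellman-Ford-style relaxation layered by hop count.  Because every edge
#' cost is strictly positive, the minimum over walks of <= max_steps edges is
#' attained by a simple path, so per-(node, hops) relaxation is exact; the
#' hop-layered states are essential because optimal substructure holds only
#' within a fixed hop budget.  Ties (cost within `tol`) are broken by fewer
#' steps, then by the lexicographically smallest node-index sequence.
#'
#' @param C cost matrix (Inf = absent edge)
#' @param source source node index
#' @param max_steps maximum number of edges
#' @param tol cost tie tolerance
#' @return list with `paths` (list of node sequences or NULL), `costs`,
#'   `steps` per target
#' @noRd
single_source_paths <- function(C, source, max_steps, tol = 1e-9) {
  n <- nrow(C)
  costs <- matrix(Inf, max_steps, n)
  paths <- vector("list", max_steps)

  p1 <- vector("list", n)
  reach <- which(is.finite(C[source, ]))
  costs[1L, reach] <- C[source, reach]
  for (v in reach) p1[[v]] <- c(source, v)
  paths[[1L]] <- p1

  if (max_steps >= 2L) {
    for (h in 2:max_steps) {
      ph <- vector("list", n)
      prev_cost <- costs[h - 1L, ]
      prev_paths <- paths[[h - 1L]]
      if (all(!is.finite(prev_cost))) {
        paths[[h]] <- ph
        next
      }
      for (v in seq_len(n)) {
        cand <- prev_cost + C[, v]
        cand[v] <- Inf
        m <- min(cand)
        if (!is.finite(m)) next
        tied <- which(cand <= m + tol)
        best_path <- NULL
        best_cost <- Inf
        for (u in tied) {
          pu <- prev_paths[[u]]
          if (v %in% pu) next  # would close a cycle at v
          cp <- c(pu, v)
          if (is.null(best_path) || lex_less(cp, best_path)) {
            best_path <- cp
            best_cost <- cand[u]
          }
        }
        if (!is.null(best_path)) {
          costs[h, v] <- best_cost
          ph[[v]] <- best_path
        }
      }
      paths[[h]] <- ph
    }
  }
  list(costs = costs, paths = paths)
}

#' Select the winning route for one target from layered search state
#' @noRd
pick_route <- function(state, target, tol = 1e-9) {
  cc <- state$costs[, target]
  finite <- which(is.finite(cc))
  if (!length(finite)) return(NULL)
  best <- min(cc[finite])
  cands <- finite[cc[finite] <= best + tol]
  for (h in cands) {  # increasing hop count: fewer steps wins ties
    p <- state$paths[[h]][[target]]
    if (!is.null(p) && !anyDuplicated(p)) {
      return(usfc_route(p, cc[h]))
    }
  }
  NULL
}

#' Most efficient pathway between two regions
#'
#' Finds the simple path of at most `max_steps` edges minimising the summed
#' cost (Euclidean distance / SC) over its steps.  Edges with SC = 0 are
#' inadmissible.  Ties in cost (within 1e-9) are broken by fewer steps, then
#' by the lexicographically smallest node-index sequence.
#'
#' @param D distance matrix (mm), symmetric, zero diagonal
#' @param SC structural connectivity matrix, symmetric, nonnegative
#' @param source,target region label or index; must differ
#' @param max_steps maximum route length in edges (default 4)
#' @return a [usfc_route()] or `NULL` when no admissible route exists
#' @examples
#' atlas <- region_atlas(1:4, c("R1", "R2", "R3", "R4"),
#'                       c(0, 10, 20, 30), 0, 0, "net1")
#' D <- euclidean_distances(atlas)
#' SC <- matrix(0, 4, 4, dimnames = dimnames(D))
#' SC[1, 2] <- SC[2, 1] <- SC[2, 3] <- SC[3, 2] <- SC[3, 4] <- SC[4, 3] <- 0.5
#' SC[1, 4] <- SC[4, 1] <- 0.1
#' find_efficient_pathway(D, SC, "R1", "R4")  # 3-step chain, cost 60
#' @export
find_efficient_pathway <- function(D, SC, source, target, max_steps = 4L) {
  if (max_steps < 1L) stop("max_steps must be >= 1", call. = FALSE)
  labs <- rownames(D) %||% as.character(seq_len(nrow(D)))
  s <- resolve_node(source, labs, "source")
  t <- resolve_node(target, labs, "target")
  if (s == t) stop("source and target must differ", call. = FALSE)
  C <- cost_matrix(D, SC)
  state <- single_source_paths(C, s, max_steps)
  pick_route(state, t)
}

#' Exhaustive pathway oracle
#'
#' Enumerates every simple path of at most `max_steps` edges between source
#' and target and returns the minimum-cost one under the same tie-break rule
#' as [find_efficient_pathway()] (fewer steps, then lexicographically smallest
#' sequence).  Intended as an independent test oracle for small graphs.
#'
#' @inheritParams find_efficient_pathway
#' @param tol cost tie tolerance
#' @return a [usfc_route()] or `NULL`
#' @export
brute_force_pathway <- function(D, SC, source, target, max_steps = 4L,
                                tol = 1e-9) {
  n <- nrow(D)
  if (n > 14L) {
    stop("brute_force_pathway guards at N <= 14 (got ", n, ")", call. = FALSE)
  }
  labs <- rownames(D) %||% as.character(seq_len(n))
  s <- resolve_node(source, labs, "source")
  t <- resolve_node(target, labs, "target")
  if (s == t) stop("source and target must differ", call. = FALSE)
  C <- cost_matrix(D, SC)

  best <- new.env(parent = emptyenv())
  best$cost <- Inf
  best$path <- NULL

  consider <- function(path, cost) {
    if (cost < best$cost - tol) {
      best$cost <- cost
      best$path <- path
    } else if (cost <= best$cost + tol) {
      if (length(path) < length(best$path) ||
          (length(path) == length(best$path) && lex_less(path, best$path))) {
        # keep the smaller recorded cost for reporting stability
        best$cost <- min(best$cost, cost)
        best$path <- path
      }
    }
  }

  dfs <- function(path, cost) {
    v <- path[length(path)]
    if (v == t) {
      consider(path, cost)
      return(invisible(NULL))
    }
    if (length(path) - 1L >= max_steps) return(invisible(NULL))
    for (w in which(is.finite(C[v, ]))) {
      if (w %in% path) next
      dfs(c(path, w), cost + C[v, w])
    }
    invisible(NULL)
  }
  dfs(s, 0)
  if (is.null(best$path)) return(NULL)
  usfc_route(best$path, best$cost)
}

#' Route every selected functional connection of one subject
#'
#' Selects unordered region pairs according to `fc_policy` and finds each
#' pair's most efficient structural route.  Pairs with no admissible route of
#' at most `max_steps` edges are recorded as unroutable.
#'
#' @param subject a [subject_connectome()]
#' @param D distance matrix in atlas order
#' @param max_steps maximum route length in edges (default 4)
#' @param fc_policy `"auto"` (masked when a significance mask is present,
#'   otherwise all nonzero FC pairs), `"masked"`, or `"all_nonzero"`
#' @param verbose emit a one-line summary via [message()]
#' @return a [route_table()]
#' @export
route_all_pairs <- function(subject, D, max_steps = 4L,
                            fc_policy = c("auto", "masked", "all_nonzero"),
                            verbose = FALSE) {
  fc_policy <- match.arg(fc_policy)
  fc <- subject$fc
  n <- nrow(fc)
  if (fc_policy == "auto") {
    fc_policy <- if (!is.null(subject$fc_mask)) "masked" else "all_nonzero"
  }
  if (fc_policy == "masked") {
    if (is.null(subject$fc_mask)) {
      stop("fc_policy = 'masked' but subject ", subject$subject_id,
           " carries no fc_mask", call. = FALSE)
    }
    sel <- subject$fc_mask & upper.tri(fc)
  } else {
    sel <- (fc != 0) & upper.tri(fc)
  }
  idx <- which(sel, arr.ind = TRUE)
  routes <- list()
  unroutable <- matrix(integer(0), ncol = 2)
  if (nrow(idx)) {
    C <- cost_matrix(D, subject$sc)
    for (s in sort(unique(idx[, 1L]))) {
      targets <- idx[idx[, 1L] == s, 2L]
      state <- single_source_paths(C, s, max_steps)
      for (t in targets) {
        r <- pick_route(state, t)
        if (is.null(r)) {
          unroutable <- rbind(unroutable, c(s, t))
        } else {
          routes[[pair_key(s, t)]] <- r
        }
      }
    }
  }
  if (verbose) {
    message("subject ", subject$subject_id, ": routed ", length(routes),
            " of ", nrow(idx), " pairs (", nrow(unroutable), " unroutable)")
  }
  route_table(subject$subject_id, routes, unroutable)
}

#' Bundle one subject's connectivity matrices
#'
#' @param subject_id subject identifier
#' @param sc structural connectivity matrix (symmetric, nonnegative)
#' @param fc functional connectivity matrix (symmetric, in \[-1, 1\])
#' @param fc_mask optional logical matrix of significant FC pairs (symmetric,
#'   FALSE diagonal)
#' @return a `subject_connectome`
#' @export
subject_connectome <- function(subject_id, sc, fc, fc_mask = NULL) {
  validate_conn_matrix(sc, "SC")
  validate_conn_matrix(fc, "FC")
  if (!identical(dim(sc), dim(fc))) {
    stop("sc and fc dimensions differ for subject ", subject_id,
         call. = FALSE)
  }
  if (!is.null(fc_mask)) {
    if (!is.logical(fc_mask) || !identical(dim(fc_mask), dim(fc))) {
      stop("fc_mask must be a logical matrix matching fc", call. = FALSE)
    }
    if (any(fc_mask != t(fc_mask)) || any(diag(fc_mask))) {
      stop("fc_mask must be symmetric with a FALSE diagonal", call. = FALSE)
    }
  }
  structure(
    list(subject_id = as.character(subject_id), sc = sc, fc = fc,
         fc_mask = fc_mask),
    class = "subject_connectome"
  )
}

#' Significance mask for Pearson FC values
#'
#' Converts correlations to t statistics given the time-series length,
#' derives two-sided p values and applies Benjamini-Hochberg FDR across the
#' upper triangle, mirroring the per-subject edge screening used for
#' resting-state FC matrices.
#'
#' @param fc FC matrix of Pearson correlations
#' @param n_timepoints number of time points behind each correlation (> 3)
#' @param alpha FDR level (default 0.05)
#' @return symmetric logical mask with FALSE diagonal
#' @export
fc_significance_mask <- function(fc, n_timepoints, alpha = 0.05) {
  if (n_timepoints <= 3) stop("n_timepoints must exceed 3", call. = FALSE)
  validate_conn_matrix(fc, "FC")
  ut <- upper.tri(fc)
  r <- fc[ut]
  r <- pmax(pmin(r, 1 - 1e-15), -1 + 1e-15)
  tt <- r * sqrt((n_timepoints - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), df = n_timepoints - 2)
  q <- p.adjust(p, method = "BH")
  mask <- matrix(FALSE, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  mask[ut] <- q <= alpha
  mask | t(mask)
}
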