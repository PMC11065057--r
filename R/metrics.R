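#' Convert a weight matrix to an edge-length graph
#'
#' Weighted shortest-path metrics need a weight-to-distance convention:
#' an edge is present iff its weight is positive and its length is the
#' reciprocal weight, so stronger connections are shorter.  Negative entries
#' are a domain error -- callers pass `|FC|` for functional matrices.
#'
#' @param m symmetric nonnegative matrix with zero diagonal
#' @return an igraph undirected graph with edge attributes `weight` and
#'   `length = 1/weight`
#' @export
to_length_graph <- function(m) {
  check_symmetric(m, what = "weight matrix")
  if (any(m < 0)) {
    stop("negative entries: take absolute values before building the length",
         " graph", call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

length_distances <- function(m) {
  g <- to_length_graph(m)
  igraph::distances(g, weights = igraph::E(g)$length)
}

#' Global efficiency of a weighted network
#'
#' Mean over ordered node pairs of the inverse weighted shortest-path length
#' (edge length = 1/weight); unreachable pairs contribute 0.
#'
#' @param m symmetric nonnegative matrix
#' @return scalar global efficiency
#' @export
global_efficiency <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("global_efficiency needs at least 2 nodes", call. = FALSE)
  d <- length_distances(m)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' For each node, the mean inverse shortest-path length to every other node.
#'
#' @param m symmetric nonnegative matrix
#' @return named numeric vector
#' @export
nodal_efficiency <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("nodal_efficiency needs at least 2 nodes", call. = FALSE)
  d <- length_distances(m)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  setNames(rowSums(inv) / (n - 1), rownames(m))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbours (0 for nodes with fewer than 2 neighbours).
#'
#' @param m symmetric nonnegative matrix
#' @return named numeric vector
#' @export
local_efficiency <- function(m) {
  n <- nrow(m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(m[i, ] > 0)
    nb <- setdiff(nb, i)
    if (length(nb) >= 2L) {
      out[i] <- global_efficiency(m[nb, nb, drop = FALSE])
    }
  }
  setNames(out, rownames(m))
}

#' Weighted betweenness centrality
#'
#' Shortest-path betweenness on the length graph (length = 1/weight), with
#' shortest-path multiplicity shared fractionally.  Normalisation divides by
#' `(N-1)(N-2)/2`, the number of node pairs a node could lie between.
#'
#' @param m symmetric nonnegative matrix
#' @param normalized divide by `(N-1)(N-2)/2` (default TRUE)
#' @return list with `nodal` (named vector) and `mean`
#' @export
betweenness_centrality <- function(m, normalized = TRUE) {
  g <- to_length_graph(m)
  b <- igraph::betweenness(g, weights = igraph::E(g)$length,
                           normalized = normalized)
  names(b) <- rownames(m)
  list(nodal = b, mean = mean(b))
}

#' Community partition and modularity with nodal decomposition
#'
#' Deterministic greedy agglomerative modularity maximisation (fast-greedy),
#' reporting \eqn{Q = \sum_c [W_c/W - (S_c/2W)^2]} and each node's additive
#' contribution \eqn{q_i = \sum_{j \in c(i)} (w_{ij} - s_i s_j / 2W) / (2W)},
#' which sums exactly to Q.
#'
#' @param m symmetric nonnegative matrix with at least one positive edge
#' @return list with `partition` (named integer membership), `Q`,
#'   `nodal_contribution` (named vector summing to Q).  The returned
#'   partition is never worse than the trivial single-community one, so
#'   `Q >= 0` always.
#' @export
modularity_partition <- function(m) {
  check_symmetric(m, what = "weight matrix")
  if (all(m <= 0)) {
    stop("modularity is undefined for an edgeless graph", call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cm)
  Q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  if (Q < 0) {
    # never return a partition worse than the single-community one (Q = 0),
    # which greedy merging can do on near-tie graphs
    memb[] <- 1L
    Q <- 0
  }

  s <- rowSums(m)
  W2 <- sum(m)  # 2W: total weight counted over ordered pairs
  same <- outer(memb, memb, `==`)
  contrib <- rowSums((m - outer(s, s) / W2) * same) / W2
  names(contrib) <- rownames(m)
  part <- as.integer(memb)
  names(part) <- rownames(m)
  list(partition = part, Q = Q, nodal_contribution = contrib)
}

metric_types <- c("SC", "FC", "USFC")

# one-sample t-test p-value on paired differences, NA when degenerate
# (fewer than 2 finite values, or numerically constant with nonzero mean)
paired_p_value <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 2L) return(NA_real_)
  if (all(d == 0)) return(1)
  if (sd(d) == 0) return(NA_real_)
  tryCatch(t.test(d)$p.value, error = function(e) NA_real_)
}

normalize_matrix <- function(m, normalize) {
  switch(normalize,
    none = m,
    max = if (max(m) > 0) m / max(m) else m,
    sum = if (sum(m) > 0) m / sum(m) else m
  )
}

subject_metrics <- function(m) {
  bt <- betweenness_centrality(m)
  has_edge <- any(m > 0)
  mod <- if (has_edge) modularity_partition(m) else
    list(partition = NULL, Q = NA_real_,
         nodal_contribution = setNames(rep(NA_real_, nrow(m)), rownames(m)))
  list(
    global_efficiency = global_efficiency(m),
    mean_betweenness = bt$mean,
    modularity_Q = mod$Q,
    nodal_efficiency = nodal_efficiency(m),
    local_efficiency = local_efficiency(m),
    betweenness = bt$nodal,
    nodal_modularity = mod$nodal_contribution,
    partition = mod$partition
  )
}

#' Compare graph metrics across SC, FC and USFC connectomes
#'
#' For every subject and connectivity type the matrix is optionally
#' normalised (`max` by default, so cross-type comparisons reflect topology
#' rather than scale; FC is passed as `|FC|` because shortest-path metrics
#' need nonnegative weights), then global efficiency, mean betweenness
#' centrality and modularity Q are computed together with the nodal vectors
#' (nodal/local efficiency, betweenness, nodal modularity contribution).
#' Connectivity types are compared with paired two-sided t-tests, globally
#' per metric and per node with BH correction across nodes.
#'
#' @param cohort list of [subject_connectome()]s (>= 2)
#' @param usfc_list per-subject USFC matrices, same order as `cohort`
#' @param normalize `"max"` (default), `"sum"`, or `"none"`
#' @param alpha significance level for BH-corrected nodal tests
#' @return a `metrics_comparison`: `global` (subject x type data frame),
#'   `global_tests`, `nodal` (arrays node x subject x type per metric),
#'   `nodal_tests` (per metric, per type pair: t, q vectors)
#' @export
compare_metrics <- function(cohort, usfc_list,
                            normalize = c("max", "sum", "none"),
                            alpha = 0.05) {
  normalize <- match.arg(normalize)
  ns <- length(cohort)
  if (ns < 2L) stop("compare_metrics needs at least 2 subjects",
                    call. = FALSE)
  if (length(usfc_list) != ns) {
    stop("cohort and usfc_list lengths differ", call. = FALSE)
  }
  n <- nrow(cohort[[1L]]$sc)
  labs <- rownames(cohort[[1L]]$sc) %||% as.character(seq_len(n))

  global_metrics <- c("global_efficiency", "mean_betweenness", "modularity_Q")
  nodal_metrics <- c("nodal_efficiency", "local_efficiency", "betweenness",
                     "nodal_modularity")
  global_rows <- list()
  nodal <- lapply(nodal_metrics, function(mm) {
    array(NA_real_, dim = c(n, ns, 3L),
          dimnames = list(labs, NULL, metric_types))
  })
  names(nodal) <- nodal_metrics

  for (si in seq_len(ns)) {
    mats <- list(
      SC = cohort[[si]]$sc,
      FC = abs(cohort[[si]]$fc),
      USFC = usfc_list[[si]]
    )
    for (ty in metric_types) {
      m <- normalize_matrix(mats[[ty]], normalize)
      res <- subject_metrics(m)
      global_rows[[paste(si, ty)]] <- data.frame(
        subject = cohort[[si]]$subject_id, type = ty,
        global_efficiency = res$global_efficiency,
        mean_betweenness = res$mean_betweenness,
        modularity_Q = res$modularity_Q,
        stringsAsFactors = FALSE
      )
      for (mm in nodal_metrics) nodal[[mm]][, si, ty] <- res[[mm]]
    }
  }
  global <- do.call(rbind, global_rows)
  rownames(global) <- NULL

  type_pairs <- list(c("SC", "FC"), c("SC", "USFC"), c("FC", "USFC"))
  gt_rows <- list()
  for (gm in global_metrics) {
    wide <- matrix(NA_real_, ns, 3L, dimnames = list(NULL, metric_types))
    for (ty in metric_types) {
      wide[, ty] <- global[global$type == ty, gm]
    }
    for (tp in type_pairs) {
      d <- wide[, tp[1L]] - wide[, tp[2L]]
      d <- d[is.finite(d)]
      p <- paired_p_value(d)
      gt_rows[[paste(gm, tp[1L], tp[2L])]] <- data.frame(
        metric = gm, type_a = tp[1L], type_b = tp[2L],
        mean_diff = if (length(d)) mean(d) else NA_real_, p_value = p,
        stringsAsFactors = FALSE
      )
    }
  }
  global_tests <- do.call(rbind, gt_rows)
  rownames(global_tests) <- NULL

  nodal_tests <- list()
  for (mm in nodal_metrics) {
    nodal_tests[[mm]] <- list()
    for (tp in type_pairs) {
      dmat <- nodal[[mm]][, , tp[1L]] - nodal[[mm]][, , tp[2L]]
      tvec <- pvec <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        d <- dmat[i, ]
        d <- d[is.finite(d)]
        pvec[i] <- paired_p_value(d)
        if (length(d) >= 2L && sd(d) > 0 && !is.na(pvec[i])) {
          tvec[i] <- mean(d) / (sd(d) / sqrt(length(d)))
        } else if (length(d) >= 2L && all(d == 0)) {
          tvec[i] <- 0
        }
      }
      qvec <- p.adjust(pvec, method = "BH")
      nodal_tests[[mm]][[paste(tp, collapse = "_vs_")]] <-
        data.frame(region = labs, t = tvec, q = qvec,
                   sig = !is.na(qvec) & qvec <= alpha,
                   stringsAsFactors = FALSE)
    }
  }
  structure(
    list(global = global, global_tests = global_tests, nodal = nodal,
         nodal_tests = nodal_tests, normalize = normalize, alpha = alpha),
    class = "metrics_comparison"
  )
}

#' @export
print.metrics_comparison <- function(x, ...) {
  cat("<metrics_comparison> normalize =", x$normalize, "\n")
  agg <- aggregate(cbind(global_efficiency, mean_betweenness, modularity_Q)
                   ~ type, data = x$global, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
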