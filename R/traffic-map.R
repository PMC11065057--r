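#' Accumulate functional load onto structural segments (USFC)
#'
#' For every routed pair, the pair's FC value is added to each structural
#' edge ("road segment") its route traverses, so each segment's total is the
#' sum of all FC values travelling over it -- weighted by both the number and
#' the magnitude of the traffic.  In `absolute` mode (default) the magnitude
#' `|FC|` is accumulated; `signed` mode sums raw FC values and lets
#' opposite-sign flows cancel.
#'
#' @param rt a [route_table()]
#' @param fc the subject's FC matrix (atlas order)
#' @param mode `"absolute"` (default) or `"signed"`
#' @return N x N symmetric USFC matrix with attributes `subject_id`, `mode`
#' @export
accumulate_usfc <- function(rt, fc, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  n <- nrow(fc)
  U <- matrix(0, n, n, dimnames = dimnames(fc))
  for (r in rt$routes) {
    v <- fc[r$pair[1L], r$pair[2L]]
    if (v == 0) {
      stop("route for pair (", r$pair[1L], ",", r$pair[2L],
           ") references an FC value of 0", call. = FALSE)
    }
    load <- if (mode == "absolute") abs(v) else v
    nodes <- r$nodes
    for (k in seq_len(length(nodes) - 1L)) {
      i <- nodes[k]; j <- nodes[k + 1L]
      U[i, j] <- U[i, j] + load
      U[j, i] <- U[j, i] + load
    }
  }
  attr(U, "subject_id") <- rt$subject_id
  attr(U, "mode") <- mode
  U
}

#' Group-level USFC statistics
#'
#' Averages USFC edge loads across subjects and tests every edge that is
#' nonzero in at least one subject with a one-sample t-test against zero,
#' followed by Benjamini-Hochberg FDR across the tested edges.  Edges with
#' zero variance but a nonzero mean (a constant positive load) are assigned
#' p = 0: a constant nonzero load is maximal evidence against the zero null.
#'
#' @param usfc_list list of per-subject USFC matrices (identical dimensions)
#' @param alpha FDR significance level (default 0.05)
#' @return a `group_usfc` list: `mean`, `t_stat`, `q_value`, `sig_mask`,
#'   `mean_sig` (mean masked to significant edges), `n_subjects`
#' @export
group_usfc <- function(usfc_list, alpha = 0.05) {
  ns <- length(usfc_list)
  if (ns < 2L) {
    stop("group_usfc needs at least 2 subjects", call. = FALSE)
  }
  dims <- lapply(usfc_list, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("USFC matrices have mismatched dimensions", call. = FALSE)
  }
  n <- nrow(usfc_list[[1L]])
  dn <- dimnames(usfc_list[[1L]])
  arr <- array(unlist(usfc_list), dim = c(n, n, ns))
  mean_m <- apply(arr, c(1, 2), mean)

  ut <- which(upper.tri(mean_m))
  vals <- matrix(0, length(ut), ns)
  for (s in seq_len(ns)) vals[, s] <- usfc_list[[s]][ut]
  tested <- rowSums(vals != 0) > 0

  t_stat <- matrix(NA_real_, n, n)
  q_value <- matrix(NA_real_, n, n)
  sig <- matrix(FALSE, n, n)
  if (any(tested)) {
    mu <- rowMeans(vals[tested, , drop = FALSE])
    sdev <- apply(vals[tested, , drop = FALSE], 1L, sd)
    tt <- ifelse(sdev == 0, Inf * sign(mu), mu / (sdev / sqrt(ns)))
    p <- ifelse(sdev == 0, 0, 2 * pt(-abs(tt), df = ns - 1L))
    q <- p.adjust(p, method = "BH")
    t_stat[ut[tested]] <- tt
    q_value[ut[tested]] <- q
    sig[ut[tested]] <- q <= alpha
  }
  t_stat[lower.tri(t_stat)] <- t(t_stat)[lower.tri(t_stat)]
  q_value[lower.tri(q_value)] <- t(q_value)[lower.tri(q_value)]
  sig <- sig | t(sig)
  dimnames(mean_m) <- dimnames(t_stat) <- dimnames(q_value) <-
    dimnames(sig) <- dn

  structure(
    list(mean = mean_m, t_stat = t_stat, q_value = q_value, sig_mask = sig,
         mean_sig = mean_m * sig, n_subjects = ns, alpha = alpha),
    class = "group_usfc"
  )
}

#' @export
print.group_usfc <- function(x, ...) {
  cat("<group_usfc>", x$n_subjects, "subjects,",
      sum(x$sig_mask[upper.tri(x$sig_mask)]), "significant edges at q <=",
      x$alpha, "\n")
  invisible(x)
}

#' Overall regional load of a connectivity matrix
#'
#' The load of a region is the sum of its incident edge weights (row sum of
#' the symmetric matrix).
#'
#' @param m symmetric N x N matrix
#' @return named numeric vector of per-region loads
#' @export
regional_load <- function(m) {
  check_symmetric(m, what = "load matrix")
  rowSums(m)
}

#' IQR-fence outlier detection on regional loads
#'
#' Quartiles use linear interpolation between order statistics (R type 7);
#' the upper fence is `q3 + k * IQR` and regions whose load exceeds it are
#' flagged, sorted descending by load.  Only the upper side is screened: the
#' interest is in regions carrying exceptionally heavy traffic.
#'
#' @param loads named numeric vector of regional loads (>= 4 values)
#' @param k fence multiplier (default 1.5)
#' @return an `outlier_report`: `regional_load`, `q1`, `q3`, `iqr`,
#'   `upper_fence`, `outlier_regions` (labels, descending by load)
#' @export
iqr_outliers <- function(loads, k = 1.5) {
  if (length(loads) < 4L) {
    stop("iqr_outliers needs at least 4 regional loads", call. = FALSE)
  }
  qs <- quantile(loads, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2L] - qs[1L]
  fence <- qs[2L] + k * iqr
  out <- loads[loads > fence]
  out <- out[order(-out)]
  structure(
    list(regional_load = loads, q1 = qs[1L], q3 = qs[2L], iqr = iqr,
         upper_fence = fence,
         outlier_regions = names(out) %||% character(0),
         outlier_loads = unname(out)),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> fence =", format(x$upper_fence), "->",
      length(x$outlier_regions), "outlier regions\n")
  if (length(x$outlier_regions)) {
    cat(" ", paste(x$outlier_regions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Network-level load summary and comparisons
#'
#' Aggregates regional loads to networks and compares networks.  With
#' `scope = "subjects"` (default) each subject contributes one value per
#' network (the mean regional load over that network's regions) and networks
#' are compared with pairwise paired t-tests across subjects,
#' BH-corrected.  With `scope = "regions"` the group-mean matrix's regional
#' loads are grouped by network and compared with Welch t-tests across
#' regions.
#'
#' @param x list of per-subject symmetric matrices (or a single matrix, in
#'   which case comparisons are skipped with a warning)
#' @param atlas a [region_atlas()] supplying network labels
#' @param scope `"subjects"` or `"regions"`
#' @param alpha significance level after BH correction (default 0.05)
#' @return a `network_summary`: per-network `mean`, `sd`, `ranking`
#'   (descending by mean), significance matrix `sig` with q-values `q`
#' @export
network_summary <- function(x, atlas, scope = c("subjects", "regions"),
                            alpha = 0.05) {
  scope <- match.arg(scope)
  validate_atlas(atlas)
  nets <- sort(unique(atlas$network))
  members <- lapply(nets, function(nw) which(atlas$network == nw))
  names(members) <- nets
  if (any(vapply(members, length, integer(1)) == 0L)) {
    stop("every network needs at least one region", call. = FALSE)
  }
  if (is.matrix(x)) x <- list(x)

  if (scope == "subjects") {
    vals <- t(vapply(x, function(m) {
      loads <- regional_load(m)
      vapply(members, function(idx) mean(loads[idx]), numeric(1))
    }, numeric(length(nets))))
    colnames(vals) <- nets
    means <- colMeans(vals)
    sds <- apply(vals, 2L, sd)
    q <- sig <- matrix(NA_real_, length(nets), length(nets),
                       dimnames = list(nets, nets))
    if (nrow(vals) >= 2L) {
      pairs <- which(upper.tri(q), arr.ind = TRUE)
      pv <- apply(pairs, 1L, function(ij) {
        d <- vals[, ij[1L]] - vals[, ij[2L]]
        if (all(d == 0)) return(1)
        if (sd(d) == 0) return(0)  # constant nonzero difference
        tryCatch(t.test(d)$p.value, error = function(e) NA_real_)
      })
      qv <- p.adjust(pv, method = "BH")
      q[pairs] <- qv
      q[pairs[, c(2, 1), drop = FALSE]] <- qv
      sig <- q <= alpha
    } else {
      warning("single subject: network comparisons skipped", call. = FALSE)
      sig <- matrix(NA, length(nets), length(nets),
                    dimnames = list(nets, nets))
    }
  } else {
    mean_m <- Reduce(`+`, x) / length(x)
    loads <- regional_load(mean_m)
    by_net <- lapply(members, function(idx) loads[idx])
    means <- vapply(by_net, mean, numeric(1))
    sds <- vapply(by_net, sd, numeric(1))
    vals <- NULL
    q <- matrix(NA_real_, length(nets), length(nets),
                dimnames = list(nets, nets))
    pairs <- which(upper.tri(q), arr.ind = TRUE)
    pv <- apply(pairs, 1L, function(ij) {
      a <- by_net[[ij[1L]]]; b <- by_net[[ij[2L]]]
      if (length(a) < 2L || length(b) < 2L || (sd(a) == 0 && sd(b) == 0)) {
        return(NA_real_)
      }
      t.test(a, b)$p.value
    })
    qv <- p.adjust(pv, method = "BH")
    q[pairs] <- qv
    q[pairs[, c(2, 1), drop = FALSE]] <- qv
    sig <- q <= alpha
  }
  structure(
    list(networks = nets, mean = means, sd = sds,
         ranking = nets[order(-means)], q = q, sig = sig,
         per_subject = vals, scope = scope, alpha = alpha),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary> scope =", x$scope, "\n ranking:",
      paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Top-k most heavily used structural pathways
#'
#' Ranks the significant group edges by mean USFC, descending; ties are
#' broken lexicographically by label pair.  When fewer than `k` significant
#' edges exist, all are returned with a warning.
#'
#' @param group a [group_usfc()] result
#' @param k number of edges to return (default 10)
#' @return data frame `region_a, region_b, mean_usfc, q_value`
#' @export
top_k_edges <- function(group, k = 10L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  sel <- which(group$sig_mask & upper.tri(group$sig_mask), arr.ind = TRUE)
  labs <- rownames(group$mean) %||% as.character(seq_len(nrow(group$mean)))
  tab <- data.frame(
    region_a = labs[sel[, 1L]],
    region_b = labs[sel[, 2L]],
    mean_usfc = group$mean[sel],
    q_value = group$q_value[sel],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$mean_usfc, tab$region_a, tab$region_b), , drop = FALSE]
  if (nrow(tab) < k) {
    warning("only ", nrow(tab), " significant edges available (k = ", k, ")",
            call. = FALSE)
  }
  tab <- head(tab, k)
  rownames(tab) <- NULL
  tab
}
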