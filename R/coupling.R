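#' Mean structural strength along a route
#'
#' Arithmetic mean of the SC values over the route's consecutive-node edges.
#'
#' @param nodes route node sequence (indices or labels)
#' @param sc SC matrix
#' @return mean SC over the route's steps
#' @export
route_mean_sc <- function(nodes, sc) {
  labs <- rownames(sc) %||% as.character(seq_len(nrow(sc)))
  if (is.character(nodes)) nodes <- match(nodes, labs)
  if (any(is.na(nodes)) || length(nodes) < 2L) {
    stop("invalid route node sequence", call. = FALSE)
  }
  vals <- sc[cbind(nodes[-length(nodes)], nodes[-1L])]
  if (any(vals <= 0)) {
    stop("route traverses an absent SC edge", call. = FALSE)
  }
  mean(vals)
}

#' Routes consistent across the cohort
#'
#' For each routed pair, finds the modal exact node sequence across subjects
#' and keeps it iff its frequency exceeds `threshold` of the cohort (strict
#' inequality: "over 50%" at the default).  Pairs whose modal sequence is
#' tied are dropped with a warning.  Each consistent route carries the
#' group-mean FC of its pair and the route-mean SC evaluated on the
#' subject-averaged SC matrix.
#'
#' @param route_tables list of per-subject [route_table()]s (>= 2 subjects)
#' @param subjects list of [subject_connectome()]s in the same order
#' @param threshold consistency threshold as a fraction of subjects
#'   (default 0.5)
#' @param match route identity: `"sequence"` (exact node sequence, default)
#'   or `"steps"` (step count only; the modal sequence within the modal step
#'   count is reported)
#' @return data frame with one row per consistent route: `pair_key`,
#'   `source`, `target`, `route` (hyphen-joined labels), `n_steps`,
#'   `support`, `group_fc`, `group_mean_sc`
#' @export
modal_routes <- function(route_tables, subjects, threshold = 0.5,
                         match = c("sequence", "steps")) {
  match <- match.arg(match)
  ns <- length(route_tables)
  if (ns < 2L) stop("modal_routes needs at least 2 subjects", call. = FALSE)
  if (length(subjects) != ns) {
    stop("route_tables and subjects lengths differ", call. = FALSE)
  }
  n <- nrow(subjects[[1L]]$fc)
  labs <- rownames(subjects[[1L]]$fc) %||% as.character(seq_len(n))

  seqs_by_pair <- list()
  for (rt in route_tables) {
    for (key in names(rt$routes)) {
      r <- rt$routes[[key]]
      id <- if (match == "sequence") {
        paste(r$nodes, collapse = "-")
      } else {
        as.character(r$n_steps)
      }
      seqs_by_pair[[key]] <- c(seqs_by_pair[[key]], id)
    }
  }
  sc_mean <- Reduce(`+`, lapply(subjects, `[[`, "sc")) / ns
  fc_mean <- Reduce(`+`, lapply(subjects, `[[`, "fc")) / ns

  rows <- list()
  n_tied <- 0L
  for (key in names(seqs_by_pair)) {
    counts <- table(seqs_by_pair[[key]])
    top <- max(counts)
    if (top / ns <= threshold) next
    winners <- names(counts)[counts == top]
    if (length(winners) > 1L) {
      n_tied <- n_tied + 1L
      next
    }
    modal_id <- winners[1L]
    if (match == "steps") {
      # report the modal sequence among routes with the modal step count
      seq_counts <- table(unlist(lapply(route_tables, function(rt) {
        r <- rt$routes[[key]]
        if (!is.null(r) && r$n_steps == as.integer(modal_id)) {
          paste(r$nodes, collapse = "-")
        }
      })))
      modal_seq <- names(seq_counts)[which.max(seq_counts)]
    } else {
      modal_seq <- modal_id
    }
    nodes <- as.integer(strsplit(modal_seq, "-", fixed = TRUE)[[1L]])
    ij <- pair_from_key(key)
    rows[[key]] <- data.frame(
      pair_key = key,
      source = labs[ij[1L]],
      target = labs[ij[2L]],
      route = paste(labs[nodes], collapse = "-"),
      n_steps = length(nodes) - 1L,
      support = top / ns,
      group_fc = fc_mean[ij[1L], ij[2L]],
      group_mean_sc = route_mean_sc(nodes, sc_mean),
      stringsAsFactors = FALSE
    )
  }
  if (n_tied > 0L) {
    warning(n_tied, " pair(s) dropped due to tied modal routes",
            call. = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_key = character(0), source = character(0),
               target = character(0), route = character(0),
               n_steps = integer(0), support = numeric(0),
               group_fc = numeric(0), group_mean_sc = numeric(0))
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Rho uses average ranks for ties.  The two-sided p-value is computed by
#' full permutation enumeration for n < 10 and by the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` for n >= 10, so small step groups
#' are tested exactly.
#'
#' @param x,y numeric vectors of equal length (n >= 3)
#' @return list with `rho`, `p_value`, `n`
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) {
    stop("spearman_test needs two vectors of equal length >= 3",
         call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- cor(rx, ry)
  if (n < 10L) {
    perms <- permutations_of(n)
    ry_c <- ry - mean(ry)
    rx_c <- rx - mean(rx)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    sums <- matrix(ry_c[perms], nrow(perms), n) %*% rx_c
    rho_all <- as.numeric(sums) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p <- 2 * pt(-abs(tt), df = n - 2)
    p <- min(p, 1)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Step-stratified SC-FC coupling
#'
#' Splits consistent routes by the sign of their group-mean FC (exact zeros
#' are excluded), groups them by step count, and computes the Spearman
#' correlation between route-mean SC and group FC within every group holding
#' at least 3 routes.  Groups with fewer routes keep their count but carry no
#' correlation.
#'
#' @param consistent data frame from [modal_routes()]
#' @param max_steps largest step count tabulated (default 4)
#' @return a `coupling_result`: data frame `table` with columns
#'   `step, sign, n, rho, p_value`, and `counts` (step x sign route counts)
#' @export
coupling_by_step <- function(consistent, max_steps = 4L) {
  zeros <- consistent$group_fc == 0
  if (any(zeros)) {
    message(sum(zeros), " route(s) with exactly zero group FC excluded")
    consistent <- consistent[!zeros, , drop = FALSE]
  }
  signs <- c("positive", "negative")
  rows <- list()
  counts <- matrix(0L, max_steps, 2L,
                   dimnames = list(paste0("step", seq_len(max_steps)), signs))
  for (st in seq_len(max_steps)) {
    for (sg in signs) {
      sel <- consistent$n_steps == st &
        (if (sg == "positive") consistent$group_fc > 0 else
           consistent$group_fc < 0)
      nn <- sum(sel)
      counts[st, sg] <- nn
      rho <- p <- NA_real_
      if (nn >= 3L) {
        res <- spearman_test(consistent$group_mean_sc[sel],
                             consistent$group_fc[sel])
        rho <- res$rho
        p <- res$p_value
      }
      rows[[paste(st, sg)]] <- data.frame(
        step = st, sign = sg, n = nn, rho = rho, p_value = p,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, counts = counts), class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("<coupling_result>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
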