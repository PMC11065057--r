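#' Configuration for a synthetic connectome cohort
#'
#' The generator emulates the statistical structure the traffic-map analysis
#' assumes: an AAL-like 90-region atlas whose networks are spatially
#' contiguous clusters inside a head-sized ellipsoid, sparse modular
#' FA-weighted SC, a planted high-strength midline "backbone" chain running
#' anterior to posterior, and signed FC tied to the cost and strength of the
#' cheapest structural route (negative FC blocks get magnitudes that grow
#' with route-mean SC).
#'
#' @param n_regions number of regions (default 90)
#' @param n_networks number of networks / spatial clusters (default 8)
#' @param n_subjects cohort size (default 20)
#' @param sc_density fraction of region pairs with a structural edge
#'   (default 0.15)
#' @param backbone integer vector of region ids forming the planted chain;
#'   default: the first `min(12, size of network 1)` ids, which all belong to
#'   the midline network
#' @param backbone_strength SC weight planted on chain edges (default 0.9)
#' @param noise_sd per-subject Gaussian perturbation SD (default 0.05)
#' @param negfc_block_pairs list of 2-vectors of network labels whose
#'   between-network pairs receive negative FC; default: all pairs (i, j),
#'   2 <= i < j <= n_networks, with i + j odd
#' @param seed integer RNG seed
#' @return a `synth_config` list
#' @export
synth_config <- function(n_regions = 90L, n_networks = 8L, n_subjects = 20L,
                         sc_density = 0.15, backbone = NULL,
                         backbone_strength = 0.9, noise_sd = 0.05,
                         negfc_block_pairs = NULL, seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_networks <- as.integer(n_networks)
  if (n_regions < 4L) stop("n_regions must be >= 4", call. = FALSE)
  if (n_networks < 1L || n_networks > n_regions) {
    stop("n_networks must be in 1..n_regions", call. = FALSE)
  }
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (sc_density <= 0 || sc_density > 1) {
    stop("sc_density must be in (0, 1]", call. = FALSE)
  }
  if (backbone_strength <= 0 || backbone_strength > 1) {
    stop("backbone_strength must be in (0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)

  sizes <- network_sizes(n_regions, n_networks)
  if (is.null(backbone)) {
    backbone <- seq_len(min(12L, sizes[1L]))
  }
  backbone <- as.integer(backbone)
  if (anyDuplicated(backbone) || any(backbone < 1L) ||
      any(backbone > n_regions) || length(backbone) < 2L) {
    stop("backbone must be a simple path of distinct region ids within 1..N",
         call. = FALSE)
  }
  if (is.null(negfc_block_pairs)) {
    negfc_block_pairs <- list()
    if (n_networks >= 3L) {
      for (i in 2:(n_networks - 1L)) {
        for (j in (i + 1L):n_networks) {
          if ((i + j) %% 2L == 1L) {
            negfc_block_pairs[[length(negfc_block_pairs) + 1L]] <-
              c(paste0("net", i), paste0("net", j))
          }
        }
      }
    }
  }
  structure(
    list(n_regions = n_regions, n_networks = n_networks,
         n_subjects = as.integer(n_subjects), sc_density = sc_density,
         backbone = backbone, backbone_strength = backbone_strength,
         noise_sd = noise_sd, negfc_block_pairs = negfc_block_pairs,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# near-equal contiguous blocks; earlier networks absorb the remainder
network_sizes <- function(n_regions, n_networks) {
  base <- n_regions %/% n_networks
  rem <- n_regions %% n_networks
  base + as.integer(seq_len(n_networks) <= rem)
}

# semi-axes of the head-sized ellipsoid (mm): x left-right, y
# anterior-posterior, z inferior-superior
ELLIPSOID <- c(70, 90, 60)

inside_ellipsoid <- function(p, scale = 1) {
  sum((p / (ELLIPSOID * scale))^2) <= 1
}

sample_in_ellipsoid <- function(scale = 1) {
  repeat {
    p <- runif(3, -ELLIPSOID * scale, ELLIPSOID * scale)
    if (inside_ellipsoid(p, scale)) return(p)
  }
}

#' Generate a synthetic region atlas
#'
#' Centroids are drawn inside a 140 x 180 x 120 mm ellipsoid.  Each network
#' is a spatially contiguous cluster around a random centre; network 1 is
#' centred on the midline and the planted backbone regions are laid out as an
#' anterior-to-posterior chain along the midline (x ~ 0, z ~ 0), emulating
#' the corridor geometry the traffic map is expected to recover.
#' Deterministic given `config$seed`.
#'
#' @param config a [synth_config()]
#' @return a [region_atlas()]
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_regions
  nets <- config$n_networks
  sizes <- network_sizes(n, nets)
  network_of <- rep(seq_len(nets), times = sizes)

  # network centres: network 1 sits on the midline and hosts the backbone
  # corridor; the remaining networks tile the anterior-posterior axis in
  # stratified bands (as cortical systems do), with lateral positions drawn
  # under a minimum mutual separation so clusters do not overlap
  centers <- matrix(0, nets, 3)
  if (nets >= 2L) {
    bands <- if (nets == 2L) 0 else seq(65, -65, length.out = nets - 1L)
    bands <- sample(bands)
    for (k in 2:nets) {
      sep <- 45
      tries <- 0L
      repeat {
        p <- c(runif(1, -70 * 0.75, 70 * 0.75), bands[k - 1L],
               runif(1, -60 * 0.75, 60 * 0.75))
        ok <- inside_ellipsoid(p, 0.8) &&
          min(sqrt(rowSums((centers[seq_len(k - 1L), , drop = FALSE] -
                              matrix(p, k - 1L, 3, byrow = TRUE))^2))) >= sep
        if (ok) break
        tries <- tries + 1L
        if (tries %% 500L == 0L) sep <- sep * 0.9  # guarantee termination
      }
      centers[k, ] <- p
    }
  }

  # backbone chain first: an anterior-to-posterior midline corridor
  bb <- config$backbone
  k <- length(bb)
  coords <- matrix(NA_real_, n, 3)
  coords[bb, 1] <- rnorm(k, 0, 2)
  coords[bb, 2] <- seq(80, -80, length.out = k)
  coords[bb, 3] <- rnorm(k, 0, 2)

  # remaining regions: cluster scatter with a minimum centroid separation, as
  # in real parcellations where centres of mass never coincide
  placed <- coords[bb, , drop = FALSE]
  for (r in setdiff(seq_len(n), bb)) {
    sep <- 12
    tries <- 0L
    repeat {
      p <- centers[network_of[r], ] + rnorm(3, 0, 12)
      if (inside_ellipsoid(p) &&
          min(sqrt(rowSums((placed - matrix(p, nrow(placed), 3,
                                            byrow = TRUE))^2))) >= sep) {
        break
      }
      tries <- tries + 1L
      if (tries %% 500L == 0L) sep <- sep * 0.9
    }
    coords[r, ] <- p
    placed <- rbind(placed, p)
  }

  region_atlas(
    region_id = seq_len(n),
    label = sprintf("R%03d", seq_len(n)),
    x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3],
    network = paste0("net", network_of)
  )
}

upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds a group-mean SC (distance-decaying random support densified within
#' networks, guaranteed "ramp" edges from every region to its two nearest
#' backbone nodes, a few direct links inside every negative block, weaker
#' long-range tracts between ordinary networks, chain edges at
#' `backbone_strength`), derives group-mean FC from the cheapest route of
#' every pair on the mean SC (positive pairs: `0.85 * exp(-cost / 60)`;
#' negative-block pairs: `-(0.05 + 0.7 * route-mean SC) * exp(-cost / 150)`,
#' so stronger routes carry stronger negative FC), then perturbs
#' both per subject with Gaussian noise (SC on supported edges, FC on all
#' off-diagonal entries), re-symmetrises, clips SC to \[0, 1\] and FC to
#' \[-1, 1\], and zeroes the diagonals.  Deterministic given `config$seed`:
#' a single RNG stream is seeded once, drawing support scores, edge weights,
#' then per-subject SC and FC noise in subject order.
#'
#' @param config a [synth_config()]
#' @param atlas atlas from [generate_atlas()] (or compatible)
#' @param max_steps hop limit used when planting routes (default 4)
#' @return list with `subjects` (list of [subject_connectome()]),
#'   `ground_truth` (backbone edges, planted routes, FC sign map, group-mean
#'   SC/FC), and `atlas`
#' @export
generate_cohort <- function(config, atlas, max_steps = 4L) {
  stopifnot(inherits(config, "synth_config"))
  validate_atlas(atlas)
  n <- config$n_regions
  if (nrow(atlas) != n) {
    stop("atlas size does not match config$n_regions", call. = FALSE)
  }
  if (any(config$backbone > nrow(atlas))) {
    stop("backbone nodes outside the atlas", call. = FALSE)
  }
  labs <- atlas_labels(atlas)
  network <- atlas$network
  set.seed(config$seed + 1L)

  D <- euclidean_distances(atlas)
  pairs <- upper_pairs(n)
  d <- D[pairs]
  same_net <- network[pairs[, 1L]] == network[pairs[, 2L]]
  bb <- config$backbone
  is_bb_node <- seq_len(n) %in% bb
  feeder <- xor(is_bb_node[pairs[, 1L]], is_bb_node[pairs[, 2L]])

  # support: distance-decayed random scores, boosted within networks and on
  # feeders into the backbone, truncated at the target density
  mult <- ifelse(same_net, 3, ifelse(feeder, 1.2, 0.6))
  score <- exp(-d / 60) * mult * runif(nrow(pairs))
  m_target <- max(1L, round(config$sc_density * nrow(pairs)))

  bb_edge_keys <- pair_key(bb[-length(bb)], bb[-1L])
  all_keys <- pair_key(pairs[, 1L], pairs[, 2L])
  forced <- all_keys %in% bb_edge_keys

  # every region gets ramps to its two nearest backbone nodes, so corridor
  # traffic enters locally (split by travel direction) instead of funnelling
  # through a few mega-gateways
  non_bb <- setdiff(seq_len(n), bb)
  if (length(non_bb)) {
    n_ramps <- min(2L, length(bb))
    for (kk in seq_len(n_ramps)) {
      kth_bb <- bb[apply(D[non_bb, bb, drop = FALSE], 1L, function(dd) {
        order(dd)[kk]
      })]
      forced <- forced | all_keys %in% pair_key(non_bb, kth_bb)
    }
  }

  # each negative block keeps its few shortest direct links, so 1-step
  # routes underneath negative FC exist
  net_key_of <- paste(pmin(network[pairs[, 1L]], network[pairs[, 2L]]),
                      pmax(network[pairs[, 1L]], network[pairs[, 2L]]),
                      sep = "|")
  neg_keys <- vapply(config$negfc_block_pairs, function(p) {
    paste(sort(p), collapse = "|")
  }, character(1))
  neg_direct <- logical(nrow(pairs))
  for (nk in neg_keys) {
    block <- which(net_key_of == nk)
    if (length(block)) {
      neg_direct[block[order(d[block])[seq_len(min(10L, length(block)))]]] <-
        TRUE
    }
  }
  forced <- forced | neg_direct
  # forced edges count towards the density target; the rest of the support
  # is the highest-scoring remainder
  n_free <- max(0L, m_target - sum(forced))
  keep <- forced
  if (n_free > 0L) {
    score[forced] <- -Inf
    keep[order(-score)[seq_len(n_free)]] <- TRUE
  }

  w <- numeric(nrow(pairs))
  u <- runif(nrow(pairs))  # one draw per candidate pair keeps order stable
  w[keep] <- pmin(0.8, 0.2 + 0.4 * u[keep] + 0.2 * exp(-d[keep] / 60))
  # long-range tracts between two ordinary networks are weaker than
  # within-network or corridor (ramp/backbone) connections, as FA-weighted
  # connectomes show for inter-lobe association fibres
  cross_plain <- keep & !same_net & !feeder
  w[cross_plain] <- 0.12 + 0.28 * u[cross_plain] +
    0.1 * exp(-d[cross_plain] / 60)
  # negative-block direct links span the full strength range so the planted
  # SC-FC anti-correlation is identifiable against distance variation
  w[neg_direct] <- 0.25 + 0.55 * u[neg_direct]
  w[all_keys %in% bb_edge_keys] <- config$backbone_strength

  sc_bar <- matrix(0, n, n, dimnames = list(labs, labs))
  sc_bar[pairs] <- w
  sc_bar <- sc_bar + t(sc_bar)

  # plant FC from the cheapest route on the group-mean SC
  C <- cost_matrix(D, sc_bar)
  neg_set <- vapply(config$negfc_block_pairs, function(p) {
    paste(sort(p), collapse = "|")
  }, character(1))
  fc_bar <- matrix(0, n, n, dimnames = list(labs, labs))
  planted_routes <- list()
  for (s in seq_len(n - 1L)) {
    state <- single_source_paths(C, s, max_steps)
    for (t in (s + 1L):n) {
      r <- pick_route(state, t)
      if (is.null(r)) next
      key <- pair_key(s, t)
      planted_routes[[key]] <- r$nodes
      net_key <- paste(sort(c(network[s], network[t])), collapse = "|")
      if (net_key %in% neg_set) {
        msc <- route_mean_sc(r$nodes, sc_bar)
        fc_bar[s, t] <- -(0.05 + 0.7 * msc) * exp(-r$total_cost / 150)
      } else {
        fc_bar[s, t] <- 0.85 * exp(-r$total_cost / 60)
      }
      fc_bar[t, s] <- fc_bar[s, t]
    }
  }

  support_ut <- which(upper.tri(sc_bar) & sc_bar > 0)
  ut <- which(upper.tri(sc_bar))
  subjects <- vector("list", config$n_subjects)
  for (si in seq_len(config$n_subjects)) {
    sc_s <- sc_bar
    if (config$noise_sd > 0) {
      sc_s[support_ut] <- sc_s[support_ut] +
        rnorm(length(support_ut), 0, config$noise_sd)
      sc_s[lower.tri(sc_s)] <- 0
      sc_s <- sc_s + t(sc_s)
      sc_s <- pmin(pmax(sc_s, 0), 1)
    }
    fc_s <- fc_bar
    if (config$noise_sd > 0) {
      fc_s[ut] <- fc_s[ut] + rnorm(length(ut), 0, config$noise_sd)
      fc_s[lower.tri(fc_s)] <- 0
      fc_s <- fc_s + t(fc_s)
      fc_s <- pmin(pmax(fc_s, -1), 1)
    }
    diag(sc_s) <- 0
    diag(fc_s) <- 0
    dim(sc_s) <- c(n, n); dimnames(sc_s) <- list(labs, labs)
    dim(fc_s) <- c(n, n); dimnames(fc_s) <- list(labs, labs)
    subjects[[si]] <- subject_connectome(sprintf("sub%03d", si), sc_s, fc_s)
  }

  backbone_edges <- cbind(bb[-length(bb)], bb[-1L])
  ground_truth <- list(
    backbone = bb,
    backbone_edges = backbone_edges,
    backbone_edge_keys = bb_edge_keys,
    backbone_network = names(which.max(table(network[bb]))),
    planted_routes = planted_routes,
    fc_sign_map = sign(fc_bar),
    sc_mean = sc_bar,
    fc_mean = fc_bar
  )
  list(subjects = subjects, ground_truth = ground_truth, atlas = atlas)
}

#' Write a simulated cohort to disk
#'
#' Writes `atlas.csv`, per-subject `sc/<id>.tsv` and `fc/<id>.tsv` matrices,
#' and `ground_truth.json` (backbone chain, planted routes as label
#' sequences, FC sign map counts) into `dir`.
#'
#' @param config a [synth_config()]
#' @param dir output directory (created if needed)
#' @return the cohort list from [generate_cohort()], invisibly
#' @export
simulate_cohort_dir <- function(config, dir) {
  atlas <- generate_atlas(config)
  cohort <- generate_cohort(config, atlas)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sc"), showWarnings = FALSE)
  dir.create(file.path(dir, "fc"), showWarnings = FALSE)
  write_atlas(atlas, file.path(dir, "atlas.csv"))
  for (subj in cohort$subjects) {
    write_conn_matrix(subj$sc, file.path(dir, "sc",
                                         paste0(subj$subject_id, ".tsv")))
    write_conn_matrix(subj$fc, file.path(dir, "fc",
                                         paste0(subj$subject_id, ".tsv")))
  }
  labs <- atlas_labels(atlas)
  gt <- cohort$ground_truth
  gt_json <- list(
    seed = config$seed,
    backbone = labs[gt$backbone],
    backbone_network = gt$backbone_network,
    backbone_edges = apply(gt$backbone_edges, 1L, function(e) {
      paste(labs[e], collapse = "-")
    }),
    planted_routes = lapply(gt$planted_routes, function(nodes) {
      paste(labs[nodes], collapse = "-")
    }),
    n_negative_fc_pairs = sum(gt$fc_mean[upper.tri(gt$fc_mean)] < 0),
    n_positive_fc_pairs = sum(gt$fc_mean[upper.tri(gt$fc_mean)] > 0)
  )
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}
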