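# Shared fixtures, built in code.

# Four collinear regions 10 mm apart; a weak direct link R1-R4 competes with
# a strong 3-step chain.  EP(R1,R4) = R1-R2-R3-R4 with cost 3 * (10/0.5) = 60
# against the direct 30/0.1 = 300.
line_fixture <- function() {
  atlas <- region_atlas(1:4, c("R1", "R2", "R3", "R4"),
                        c(0, 10, 20, 30), 0, 0, "net1")
  D <- euclidean_distances(atlas)
  SC <- matrix(0, 4, 4, dimnames = dimnames(D))
  SC[1, 2] <- SC[2, 1] <- SC[2, 3] <- SC[3, 2] <- SC[3, 4] <- SC[4, 3] <- 0.5
  SC[1, 4] <- SC[4, 1] <- 0.1
  list(atlas = atlas, D = D, SC = SC)
}

# Six collinear regions with a cheap 5-edge chain: the unconstrained optimum
# R1-..-R6 uses 5 edges, so a 4-edge search must fall back to the planted
# alternative entering at R3.
hoplimit_fixture <- function() {
  atlas <- region_atlas(1:6, paste0("H", 1:6),
                        seq(0, 50, by = 10), 0, 0, "net1")
  D <- euclidean_distances(atlas)
  SC <- matrix(0, 6, 6, dimnames = dimnames(D))
  link <- function(i, j, w) SC[i, j] <<- SC[j, i] <<- w
  for (i in 1:5) link(i, i + 1, 0.9)
  link(1, 3, 0.25)
  link(1, 6, 0.3)
  list(atlas = atlas, D = D, SC = SC)
}

# Random spatial graph: distances from uniform 3D coordinates, Bernoulli
# support with Unif(0.05, 1) SC weights.  Uses the caller's RNG stream.
random_graph <- function(n, density = 0.4) {
  coords <- matrix(runif(n * 3, 0, 100), n, 3)
  atlas <- region_atlas(seq_len(n), sprintf("G%02d", seq_len(n)),
                        coords[, 1], coords[, 2], coords[, 3], "net1")
  D <- euclidean_distances(atlas)
  SC <- matrix(0, n, n, dimnames = dimnames(D))
  ut <- which(upper.tri(SC))
  on <- runif(length(ut)) < density
  SC[ut[on]] <- runif(sum(on), 0.05, 1)
  SC <- SC + t(SC)
  list(atlas = atlas, D = D, SC = SC)
}

# Random subject connectome on a random graph; FC nonzero on a subset of
# pairs, both signs.
random_subject <- function(id, n, density = 0.4, fc_density = 0.5) {
  g <- random_graph(n, density)
  fc <- matrix(0, n, n, dimnames = dimnames(g$D))
  ut <- which(upper.tri(fc))
  on <- runif(length(ut)) < fc_density
  fc[ut[on]] <- runif(sum(on), -0.9, 0.9)
  fc <- fc + t(fc)
  list(subject = subject_connectome(id, g$SC, fc), D = g$D, atlas = g$atlas)
}

# Small cohort for pipeline-level tests.
tiny_config <- function(seed = 7L, n_subjects = 3L) {
  synth_config(n_regions = 24L, n_networks = 4L, n_subjects = n_subjects,
               sc_density = 0.2, noise_sd = 0.05, seed = seed)
}

# Brute-force Benjamini-Hochberg step-up: largest k with p_(k) <= k*alpha/m.
bh_stepup_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  k <- which(p[ord] <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(k)) rej[ord[seq_len(max(k))]] <- TRUE
  rej
}

# Exhaustive weighted betweenness oracle: enumerates all simple paths per
# pair, keeps those within 1e-10 of the minimum length (length = 1/weight),
# and shares multiplicity fractionally.
betweenness_oracle <- function(m, normalized = TRUE) {
  n <- nrow(m)
  len <- ifelse(m > 0, 1 / m, Inf)
  score <- numeric(n)
  all_paths <- function(s, t) {
    out <- list()
    rec <- function(path, cost) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1L]] <<- list(path = path, cost = cost)
        return()
      }
      for (w in which(is.finite(len[v, ]))) {
        if (!(w %in% path)) rec(c(path, w), cost + len[v, w])
      }
    }
    rec(s, 0)
    out
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      ps <- all_paths(s, t)
      if (!length(ps)) next
      costs <- vapply(ps, `[[`, numeric(1), "cost")
      best <- min(costs)
      short <- ps[costs <= best + 1e-10]
      sigma <- length(short)
      for (p in short) {
        inner <- setdiff(p$path, c(s, t))
        score[inner] <- score[inner] + 1 / sigma
      }
    }
  }
  if (normalized) score <- score / ((n - 1) * (n - 2) / 2)
  score
}
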