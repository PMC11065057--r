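test_that("euclidean distances: 3-4-5 triangle, symmetry, equivariance", {
  a2 <- region_atlas(1:2, c("A", "B"), c(0, 3), c(0, 4), c(0, 0), "net1")
  expect_equal(euclidean_distances(a2)["A", "B"], 5)

  cfg <- synth_config(n_regions = 90L, seed = 3L)
  atlas <- generate_atlas(cfg)
  D <- euclidean_distances(atlas)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D[upper.tri(D)] > 0))

  # permuting atlas rows permutes D identically
  perm <- sample(nrow(atlas))
  ap <- region_atlas(seq_len(nrow(atlas)), atlas$label[perm],
                     atlas$x_mm[perm], atlas$y_mm[perm], atlas$z_mm[perm],
                     atlas$network[perm])
  Dp <- euclidean_distances(ap)
  expect_equal(unname(Dp), unname(D[perm, perm]))

  coincident <- region_atlas(1:2, c("A", "B"), c(1, 1), c(2, 2), c(3, 3),
                             "net1")
  expect_error(euclidean_distances(coincident), "coincident")
})

test_that("edge cost is distance over strength, infinite on absent edges", {
  expect_equal(edge_cost(10, 0.5), 20)
  expect_identical(edge_cost(10, 0), Inf)
  expect_error(edge_cost(-1, 0.5), "dist")
  expect_error(edge_cost(10, -0.1), "sc_weight")
  # strictly decreasing in SC at fixed distance
  w <- sort(runif(50, 0.01, 1))
  expect_true(all(diff(edge_cost(rep(7, 50), w)) < 0))
})

test_that("line fixture: the strong 3-step chain beats the weak direct link", {
  fx <- line_fixture()
  r <- find_efficient_pathway(fx$D, fx$SC, "R1", "R4")
  expect_equal(r$nodes, 1:4)
  expect_equal(r$n_steps, 3L)
  expect_equal(r$total_cost, 60)
  expect_equal(fx$D["R1", "R4"] / fx$SC["R1", "R4"], 300)

  # reverse direction gives the reversed sequence at identical cost
  rev_r <- find_efficient_pathway(fx$D, fx$SC, "R4", "R1")
  expect_equal(rev_r$nodes, 4:1)
  expect_equal(rev_r$total_cost, r$total_cost)
})

test_that("two-node graph routes over its only edge", {
  atlas <- region_atlas(1:2, c("A", "B"), c(0, 10), 0, 0, "net1")
  D <- euclidean_distances(atlas)
  SC <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = dimnames(D))
  r <- find_efficient_pathway(D, SC, "A", "B")
  expect_equal(r$nodes, 1:2)
  expect_equal(r$n_steps, 1L)
  expect_equal(r$total_cost, 25)
})

test_that("hop-limited search returns the best <=4-edge route when the
           unconstrained optimum needs 5 edges", {
  fx <- hoplimit_fixture()
  free <- brute_force_pathway(fx$D, fx$SC, 1, 6, max_steps = 5)
  expect_equal(free$nodes, 1:6)   # 5-edge chain is the unconstrained optimum
  expect_equal(free$n_steps, 5L)

  r4 <- find_efficient_pathway(fx$D, fx$SC, 1, 6, max_steps = 4)
  b4 <- brute_force_pathway(fx$D, fx$SC, 1, 6, max_steps = 4)
  expect_equal(r4$nodes, c(1L, 3L, 4L, 5L, 6L))
  expect_equal(r4$n_steps, 4L)
  expect_equal(r4$total_cost, 80 + 100 / 3, tolerance = 1e-12)
  expect_identical(r4$nodes, b4$nodes)
  expect_gt(r4$total_cost, free$total_cost)
})

test_that("layered search matches the exhaustive oracle on random graphs", {
  set.seed(101)
  for (trial in 1:40) {
    n <- sample(5:10, 1)
    g <- random_graph(n, density = runif(1, 0.25, 0.6))
    ms <- ((trial - 1) %% 4) + 1
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        a <- find_efficient_pathway(g$D, g$SC, i, j, max_steps = ms)
        b <- brute_force_pathway(g$D, g$SC, i, j, max_steps = ms)
        expect_identical(is.null(a), is.null(b))
        if (!is.null(a)) {
          expect_identical(a$nodes, b$nodes)
          expect_equal(a$total_cost, b$total_cost, tolerance = 1e-9)
          # direct-edge bound
          if (g$SC[i, j] > 0) {
            expect_lte(a$total_cost,
                       g$D[i, j] / g$SC[i, j] + 1e-9)
          }
        }
      }
    }
  }
})

test_that("route_all_pairs honours the FC policy and records unroutable
           pairs", {
  fx <- line_fixture()
  zero_fc <- matrix(0, 4, 4, dimnames = dimnames(fx$D))
  subj0 <- subject_connectome("s0", fx$SC, zero_fc)
  rt0 <- route_all_pairs(subj0, fx$D)
  expect_length(rt0$routes, 0L)
  expect_equal(nrow(rt0$unroutable), 0L)

  fc <- zero_fc; fc[1, 4] <- fc[4, 1] <- 0.4
  subj <- subject_connectome("s1", fx$SC, fc)
  rt <- route_all_pairs(subj, fx$D)
  expect_length(rt$routes, 1L)
  expect_equal(rt$routes[["1:4"]]$nodes, 1:4)

  expect_error(route_all_pairs(subj, fx$D, fc_policy = "masked"),
               "no fc_mask")

  mask <- zero_fc > 0  # all FALSE
  mask[1, 2] <- mask[2, 1] <- TRUE
  subj_m <- subject_connectome("s2", fx$SC, fc, fc_mask = mask)
  rt_m <- route_all_pairs(subj_m, fx$D)  # auto -> masked
  expect_setequal(names(rt_m$routes), "1:2")

  # disconnect R4 entirely: the selected pair becomes unroutable
  sc_cut <- fx$SC; sc_cut[4, ] <- 0; sc_cut[, 4] <- 0
  subj_cut <- subject_connectome("s3", sc_cut, fc)
  rt_cut <- route_all_pairs(subj_cut, fx$D)
  expect_length(rt_cut$routes, 0L)
  expect_equal(nrow(rt_cut$unroutable), 1L)
  expect_equal(unname(rt_cut$unroutable[1, ]), c(1L, 4L))
})

test_that("brute-force oracle guards its size and handles isolation", {
  fx <- line_fixture()
  sc_cut <- fx$SC; sc_cut[4, ] <- 0; sc_cut[, 4] <- 0
  expect_null(brute_force_pathway(fx$D, sc_cut, 1, 4))

  big <- random_graph(15, 0.5)
  expect_error(brute_force_pathway(big$D, big$SC, 1, 2), "N <= 14")
})

test_that("FC significance mask is symmetric and keeps strong correlations", {
  set.seed(9)
  n <- 10
  labs <- sprintf("m%02d", 1:n)
  fc <- matrix(0, n, n, dimnames = list(labs, labs))
  ut <- which(upper.tri(fc))
  fc[ut] <- runif(length(ut), -0.2, 0.2)
  fc[1, 2] <- 0.95
  fc[lower.tri(fc)] <- 0
  fc <- fc + t(fc)
  mask <- fc_significance_mask(fc, n_timepoints = 120)
  expect_true(isSymmetric(mask))
  expect_false(any(diag(mask)))
  expect_true(mask[1, 2])
  expect_lt(sum(mask), sum(fc != 0))
})
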