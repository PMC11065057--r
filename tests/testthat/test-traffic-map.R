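make_line_routes <- function() {
  # routes {(R1,R4): R1-R2-R3-R4, FC 0.4; (R2,R4): R2-R3-R4, FC -0.3}
  fx <- line_fixture()
  fc <- matrix(0, 4, 4, dimnames = dimnames(fx$D))
  fc[1, 4] <- fc[4, 1] <- 0.4
  fc[2, 4] <- fc[4, 2] <- -0.3
  rt <- route_table("s1", list(
    "1:4" = usfc_route(c(1, 2, 3, 4), 60),
    "2:4" = usfc_route(c(2, 3, 4), 40)
  ))
  list(fx = fx, fc = fc, rt = rt)
}

test_that("USFC accumulation sums absolute functional load per segment", {
  lr <- make_line_routes()
  u <- accumulate_usfc(lr$rt, lr$fc)
  expect_equal(u[1, 2], 0.4)
  expect_equal(u[2, 3], 0.7)
  expect_equal(u[3, 4], 0.7)
  expect_equal(u[1, 3], 0)
  expect_equal(u, t(u))
  # conservation: total = sum |FC| * steps = 0.4*3 + 0.3*2
  expect_equal(sum(u) / 2, 1.8, tolerance = 1e-12)

  s <- accumulate_usfc(lr$rt, lr$fc, mode = "signed")
  expect_equal(s[2, 3], 0.4 - 0.3)
  expect_equal(s[3, 4], 0.1)

  empty <- accumulate_usfc(route_table("s0"), lr$fc)
  expect_true(all(empty == 0))

  fc0 <- lr$fc; fc0[1, 4] <- fc0[4, 1] <- 0
  expect_error(accumulate_usfc(lr$rt, fc0), "FC value of 0")
})

test_that("conservation and FC-scaling hold on random subjects", {
  set.seed(33)
  for (trial in 1:5) {
    rs <- random_subject(paste0("s", trial), 12, density = 0.5,
                         fc_density = 0.7)
    rt <- route_all_pairs(rs$subject, rs$D)
    u <- accumulate_usfc(rt, rs$subject$fc)
    expected <- sum(vapply(rt$routes, function(r) {
      abs(rs$subject$fc[r$pair[1], r$pair[2]]) * r$n_steps
    }, numeric(1)))
    expect_equal(sum(u) / 2, expected, tolerance = 1e-9)
    # support of USFC is inside the SC support
    expect_true(all(rs$subject$sc[u > 0] > 0))
    # scaling FC by c scales USFC by c (routes ignore FC)
    fc2 <- rs$subject$fc * 0.5
    u2 <- accumulate_usfc(rt, fc2)
    expect_equal(u2, u * 0.5, tolerance = 1e-12)
  }
})

test_that("group USFC tests edges against zero with BH control", {
  n <- 4
  labs <- paste0("R", 1:n)
  zero <- matrix(0, n, n, dimnames = list(labs, labs))
  g0 <- group_usfc(rep(list(zero), 10))
  expect_false(any(g0$sig_mask))
  expect_true(all(is.na(g0$q_value[upper.tri(g0$q_value)])))

  # constant nonzero edge: zero variance, flagged by the decision rule
  m <- zero; m[1, 2] <- m[2, 1] <- 5
  gc <- group_usfc(rep(list(m), 10))
  expect_true(gc$sig_mask[1, 2])
  expect_equal(gc$q_value[1, 2], 0)
  expect_equal(gc$mean[1, 2], 5)
  expect_identical(gc$t_stat[1, 2], Inf)

  expect_error(group_usfc(list(m)), "at least 2")

  # group mean of identical subjects equals any single subject
  lr <- make_line_routes()
  u <- accumulate_usfc(lr$rt, lr$fc)
  gi <- group_usfc(list(u, u, u))
  expect_equal(gi$mean, u, ignore_attr = TRUE)
  expect_identical(dimnames(gi$mean), dimnames(u))
})

test_that("regional load sums incident edges and satisfies the handshake
           identity", {
  lr <- make_line_routes()
  u <- accumulate_usfc(lr$rt, lr$fc)
  loads <- regional_load(u)
  expect_equal(unname(loads), c(0.4, 1.1, 1.4, 0.7))
  expect_equal(sum(loads), sum(u))
  expect_true(all(regional_load(u * 0) == 0))
})

test_that("IQR fence flags the extreme region and respects translation", {
  loads <- setNames(c(1:10, 100), c(paste0("r", 1:10), "big"))
  rep1 <- iqr_outliers(loads)
  expect_equal(rep1$q1, 3.5)
  expect_equal(rep1$q3, 8.5)
  expect_equal(rep1$iqr, 5)
  expect_equal(rep1$upper_fence, 16)
  expect_identical(rep1$outlier_regions, "big")

  same <- setNames(rep(2, 8), paste0("r", 1:8))
  expect_length(iqr_outliers(same)$outlier_regions, 0L)

  shifted <- iqr_outliers(loads + 7)
  expect_equal(shifted$upper_fence, rep1$upper_fence + 7)
  expect_identical(shifted$outlier_regions, rep1$outlier_regions)

  expect_error(iqr_outliers(c(a = 1, b = 2, c = 3)), "at least 4")
})

test_that("network summary ranks, tests, and handles degenerate input", {
  atlas <- region_atlas(1:4, paste0("R", 1:4), c(0, 10, 20, 30), 0, 0,
                        c("netA", "netA", "netB", "netB"))
  labs <- atlas_labels(atlas)
  base <- matrix(0, 4, 4, dimnames = list(labs, labs))
  base[1, 2] <- base[2, 1] <- 1
  base[3, 4] <- base[4, 3] <- 1
  # identical network values per subject -> no significant differences
  ns <- network_summary(rep(list(base), 5), atlas)
  expect_false(any(ns$sig[upper.tri(ns$sig)]))

  heavy <- base; heavy[1, 2] <- heavy[2, 1] <- 3
  subj_list <- lapply(1:5, function(i) {
    m <- heavy
    m[1, 2] <- m[2, 1] <- 3 + 0.01 * i
    m
  })
  ns2 <- network_summary(subj_list, atlas)
  expect_identical(ns2$ranking[1], "netA")
  expect_true(ns2$sig["netA", "netB"])

  expect_warning(network_summary(base, atlas), "single subject")

  # across-regions scope still ranks netA first on the heavier cohort
  ns3 <- network_summary(subj_list, atlas, scope = "regions")
  expect_identical(ns3$ranking[1], "netA")
})

test_that("top-k edge ranking orders by mean with lexicographic ties", {
  labs <- c("A", "B", "C", "D")
  mean_m <- matrix(0, 4, 4, dimnames = list(labs, labs))
  mean_m["A", "B"] <- mean_m["B", "A"] <- 3
  mean_m["B", "C"] <- mean_m["C", "B"] <- 2
  mean_m["C", "D"] <- mean_m["D", "C"] <- 1
  sig <- mean_m > 0
  qv <- ifelse(sig, 0.01, NA_real_)
  grp <- structure(list(mean = mean_m, sig_mask = sig, q_value = qv,
                        n_subjects = 5L, alpha = 0.05),
                   class = "group_usfc")
  top2 <- top_k_edges(grp, 2)
  expect_equal(top2$region_a, c("A", "B"))
  expect_equal(top2$region_b, c("B", "C"))
  expect_warning(all3 <- top_k_edges(grp, 10), "only 3")
  expect_equal(nrow(all3), 3L)
})
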