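test_that("route-mean SC averages the traversed edges only", {
  labs <- c("A", "B", "C", "D")
  sc <- matrix(0, 4, 4, dimnames = list(labs, labs))
  sc[1, 2] <- sc[2, 1] <- 0.6
  sc[2, 3] <- sc[3, 2] <- 0.2
  sc[3, 4] <- sc[4, 3] <- 0.9
  expect_equal(route_mean_sc(c("A", "B", "C"), sc), 0.4)
  expect_equal(route_mean_sc(c(3, 4), sc), 0.9)  # 1-step: the edge itself
  # changing entries off the route leaves the result unchanged
  sc2 <- sc; sc2[1, 4] <- sc2[4, 1] <- 0.5
  expect_equal(route_mean_sc(c("A", "B", "C"), sc2), 0.4)
  expect_error(route_mean_sc(c("A", "D"), sc), "absent SC edge")
})

fabricate_cohort <- function(route_sets, fc_val = 0.5) {
  # build subjects over 3 regions A,B,C with fixed SC and given routes
  labs <- c("A", "B", "C")
  sc <- matrix(0, 3, 3, dimnames = list(labs, labs))
  sc[1, 2] <- sc[2, 1] <- 0.6
  sc[2, 3] <- sc[3, 2] <- 0.4
  sc[1, 3] <- sc[3, 1] <- 0.2
  fc <- matrix(0, 3, 3, dimnames = list(labs, labs))
  fc[1, 3] <- fc[3, 1] <- fc_val
  subjects <- lapply(seq_along(route_sets), function(i) {
    subject_connectome(paste0("s", i), sc, fc)
  })
  tables <- lapply(seq_along(route_sets), function(i) {
    nodes <- route_sets[[i]]
    cost <- sum(vapply(seq_len(length(nodes) - 1), function(k) {
      10 / sc[nodes[k], nodes[k + 1]]
    }, numeric(1)))
    route_table(paste0("s", i),
                setNames(list(usfc_route(nodes, cost)), "1:3"))
  })
  list(tables = tables, subjects = subjects)
}

test_that("modal routes require a strict majority of identical sequences", {
  fc3 <- fabricate_cohort(list(c(1, 2, 3), c(1, 2, 3), c(1, 3)))
  cons <- modal_routes(fc3$tables, fc3$subjects)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$route, "A-B-C")
  expect_equal(cons$n_steps, 2L)
  expect_equal(cons$support, 2 / 3)
  expect_equal(cons$group_fc, 0.5)
  expect_equal(cons$group_mean_sc, 0.5)  # mean of 0.6 and 0.4

  # all different -> no majority
  fc_diff <- fabricate_cohort(list(c(1, 2, 3), c(1, 3), c(1, 2, 3)))
  fc_diff$tables[[3]] <- route_table("s3",
                                     list("1:3" = usfc_route(c(1, 3), 50)))
  # now sequences: ABC, AC, AC -> modal AC with support 2/3
  cons2 <- modal_routes(fc_diff$tables, fc_diff$subjects)
  expect_equal(cons2$route, "A-C")

  # support exactly at the threshold is dropped (strict inequality)
  fc4 <- fabricate_cohort(list(c(1, 2, 3), c(1, 2, 3), c(1, 3), c(1, 3)))
  cons3 <- modal_routes(fc4$tables, fc4$subjects)
  expect_equal(nrow(cons3), 0L)

  # a genuine modal tie above the threshold is dropped with a warning
  fc_tie <- fabricate_cohort(list(c(1, 2, 3), c(1, 2, 3), c(1, 3),
                                  c(1, 3), c(1, 3)))
  fc_tie$tables[[5]] <- route_table("s5",
                                    list("1:3" = usfc_route(c(1, 2, 3), 42)))
  # sequences ABC x3, AC x2 at threshold 0.4: unique winner -> kept
  cons_ok <- modal_routes(fc_tie$tables, fc_tie$subjects, threshold = 0.4)
  expect_equal(cons_ok$route, "A-B-C")
  # drop one ABC to tie 2-2 above threshold 0.3 -> warned and dropped
  fc_tie$tables[[5]] <- route_table("s5", list())
  expect_warning(cons_tie <- modal_routes(fc_tie$tables, fc_tie$subjects,
                                          threshold = 0.3),
                 "tied modal")
  expect_equal(nrow(cons_tie), 0L)

  # a subject with the pair unrouted still counts in the denominator
  fc5 <- fabricate_cohort(list(c(1, 2, 3), c(1, 3), c(1, 3), c(1, 3),
                               c(1, 3)))
  fc5$tables[[5]] <- route_table("s5", list())  # pair unrouted in subject 5
  cons4 <- modal_routes(fc5$tables, fc5$subjects)
  # AC appears 3/5 = 0.6 > 0.5 -> kept; ABC at 1/5 loses
  expect_equal(cons4$route, "A-C")
  expect_equal(cons4$support, 0.6)
})

test_that("spearman rho matches the rank definition and the exact reference
           distribution", {
  set.seed(77)
  for (trial in 1:10) {
    n <- sample(4:8, 1)
    x <- runif(n)
    y <- runif(n)
    res <- spearman_test(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = TRUE))
    expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
  }
  # ties fall back to average ranks for rho
  x <- c(1, 1, 2, 3, 4, 5)
  y <- c(2, 1, 1, 3, 5, 4)
  expect_equal(spearman_test(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  # rank invariance under strictly monotone transforms
  a <- runif(12); b <- runif(12)
  expect_equal(spearman_test(exp(a), b^3)$rho, spearman_test(a, b)$rho,
               tolerance = 1e-12)
  expect_true(is.na(spearman_test(rep(1, 5), runif(5))$rho))
})

test_that("step-stratified coupling splits by sign and respects minimum
           group size", {
  consistent <- data.frame(
    pair_key = sprintf("p%d", 1:9),
    source = "A", target = "B",
    route = "A-B",
    n_steps = c(1, 1, 1, 1, 2, 2, 3, 3, 1),
    support = 1,
    group_fc = c(-0.8, -0.6, -0.4, -0.2, 0.3, 0.4, 0.2, 0.5, 0),
    group_mean_sc = c(0.9, 0.7, 0.5, 0.3, 0.5, 0.6, 0.4, 0.2, 0.5),
    stringsAsFactors = FALSE
  )
  expect_message(cp <- coupling_by_step(consistent), "zero group FC")
  tab <- cp$table
  neg1 <- tab[tab$step == 1 & tab$sign == "negative", ]
  expect_equal(neg1$n, 4L)
  expect_equal(neg1$rho, -1)   # perfectly anti-ranked
  pos2 <- tab[tab$step == 2 & tab$sign == "positive", ]
  expect_equal(pos2$n, 2L)
  expect_true(is.na(pos2$rho))  # below the minimum group size
  expect_equal(sum(cp$counts), 8L)  # zero-FC route excluded from counts
  expect_equal(unname(cp$counts["step3", "positive"]), 2L)
})
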