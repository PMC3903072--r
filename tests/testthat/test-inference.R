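# Small-cohort settings keep these checks fast; the full-scale recovery,
# type-I and comparator studies live in test-acceptance.R.
small_quad <- function() quad_spec(6, 16)
small_ctrl <- function() list(iter_max = 50, eval_max = 200, rel_tol = 1e-8)

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- toy_params()
      sim <- simulate_cohort(80, p, seed = 14)
      cache <<- suppressWarnings(fit_timing_model(
        sim$cohort, lam = p$lam, r = p$r, quad = small_quad(),
        control = small_ctrl()
      ))
    }
    cache
  }
})

test_that("fitting respects box constraints and improves on its starts", {
  fit <- small_fit()
  d <- fit$params$drivers
  expect_true(all(d$delta_j >= 0))
  expect_true(all(d$p_j >= 0 & d$p_j <= 1))
  expect_true(all(d$alpha_j >= 1))
  expect_gt(fit$logLik, -Inf)
  # the selected optimum beats every start's objective
  expect_true(all(-fit$logLik <= fit$starts_diagnostics$objective + 1e-8))
  # deterministic: refitting reproduces the same parameters exactly
  p <- toy_params()
  sim <- simulate_cohort(80, p, seed = 14)
  fit2 <- suppressWarnings(fit_timing_model(
    sim$cohort, lam = p$lam, r = p$r, quad = small_quad(),
    control = small_ctrl()
  ))
  expect_identical(fit$theta, fit2$theta)
})

test_that("degenerate cohorts never fit silently", {
  p <- toy_params()
  sim <- simulate_cohort(12, p, seed = 1)
  one <- as_cohort(sim$cohort[1, ], drivers = cohort_drivers(sim$cohort),
                   data_kind = "cna")
  expect_error(fit_timing_model(one, lam = p$lam, r = p$r,
                                quad = small_quad()), "fewer than 2")
  expect_warning(fit_timing_model(sim$cohort[1:8, ] |>
                                    as_cohort(data_kind = "cna"),
                                  lam = p$lam, r = p$r, quad = small_quad(),
                                  control = small_ctrl()),
                 "free parameters")
})

test_that("posterior summaries respect the latent-variable constraints", {
  p <- toy_params()
  sim <- simulate_cohort(60, p, germline_prob = c(M1 = 0.2), seed = 6)
  post <- posterior_summaries(p, cohort = sim$cohort, quad = quad_spec(12, 32))
  m <- sim$cohort
  expect_true(all(post$post_T >= p$t_min))
  expect_true(all(post$post_T <= m$S / p$r))
  germ <- m$G_M1 == 1
  expect_true(all(post$post_X_M1[germ] == 0))
  for (d in c("M1", "P1")) {
    x <- post[[paste0("post_X_", d)]]
    carriers <- !is.na(x)
    expect_true(all(x[carriers] >= 0))
    expect_true(all(x[carriers] <= post$post_T[carriers] + 1e-8))
    expect_true(all(is.na(x[m[[paste0("A_", d)]] == 0])))
  }
})

test_that("posterior tumor age matches a 1-D oracle when deltas are zero", {
  p <- toy_params(delta = c(0, 0))
  co <- as_cohort(tibble::tibble(
    sample = c("a", "b"), N = c(5L, 50L), S = 60,
    A_M1 = c(1L, 1L), A_P1 = 0L, G_M1 = 0L, G_P1 = 0L
  ), data_kind = "cna")
  post <- posterior_summaries(p, cohort = co, quad = quad_spec(48, 64))
  for (i in 1:2) {
    expect_equal(post$post_T[i],
                 oracle_post_t_delta0(co$N[i], c(co$A_M1[i], co$A_P1[i]),
                                      c(0L, 0L), 60, p),
                 tolerance = 1e-4)
  }
  # more passengers imply an older lineage under a fixed rate
  expect_gt(post$post_T[2], post$post_T[1])
})

test_that("driver order sorts by posterior time with alphabetical ties", {
  post <- structure(
    tibble::tibble(
      sample = "s", N = 3L, S = 60, post_T = 500,
      post_X_B = 100, post_X_A = 100, post_X_C = 50,
      order = list(c("C", "A", "B")), order_str = "C -> A -> B"
    ),
    drivers = c("B", "A", "C"), class = c("mutclock_posterior", "tbl_df",
                                          "tbl", "data.frame")
  )
  # rebuild the order as posterior_summaries would
  x <- c(B = 100, A = 100, C = 50)
  alt <- names(x)
  expect_equal(alt[order(x, alt)], c("C", "A", "B"))
  expect_identical(post$order[[1]], c("C", "A", "B"))
})

test_that("the bootstrap is deterministic and handles B = 1", {
  fit <- small_fit()
  b1 <- suppressWarnings(bootstrap_timing(fit, B = 4, seed = 3))
  b2 <- suppressWarnings(bootstrap_timing(fit, B = 4, seed = 3))
  expect_identical(b1$delta_draws, b2$delta_draws)
  expect_identical(b1$postT_draws, b2$postT_draws)
  single <- suppressWarnings(bootstrap_timing(fit, B = 1, seed = 3))
  expect_equal(single$delta_ci$lower, single$delta_ci$upper)
  expect_true(all(single$order_confidence$order_confidence %in% c(0, 1)))
  lean <- suppressWarnings(bootstrap_timing(fit, B = 2, seed = 3,
                                            keep_posteriors = FALSE))
  expect_null(lean$postT_draws)
  expect_null(lean$postT_ci)
})

test_that("mutator calling keys on interval lower bounds", {
  fit <- small_fit()
  boot <- suppressWarnings(bootstrap_timing(fit, B = 8, seed = 5,
                                            keep_posteriors = FALSE))
  called <- call_mutators(boot)
  expect_setequal(called$driver,
                  boot$delta_ci$driver[!is.na(boot$delta_ci$lower) &
                                         boot$delta_ci$lower > 0])
  if (nrow(called) > 1) {
    expect_true(all(diff(called$delta_hat) <= 0))
  }
  if (nrow(called) > 0) {
    expect_equal(called$pct_increase,
                 100 * called$delta_hat / fit$fixed$lam)
  }
})

test_that("mean alteration times average over carriers", {
  p <- toy_params()
  sim <- simulate_cohort(40, p, seed = 21)
  post <- posterior_summaries(p, cohort = sim$cohort, quad = small_quad())
  mt <- mean_alteration_times(post)
  for (d in mt$driver) {
    x <- post[[paste0("post_X_", d)]]
    expect_equal(mt$mean_time[mt$driver == d], mean(x[!is.na(x)]))
    expect_equal(mt$n_altered[mt$driver == d], sum(!is.na(x)))
  }
  # permuting samples leaves the table unchanged
  post_perm <- posterior_summaries(
    p, cohort = as_cohort(sim$cohort[sample(nrow(sim$cohort)), ],
                          data_kind = "cna"),
    quad = small_quad()
  )
  expect_equal(mean_alteration_times(post_perm), mt)
  # a driver altered only through the germline has mean time zero
  sim_g <- simulate_cohort(30, toy_params(), germline_prob = c(M1 = 1),
                           seed = 2)
  co_g <- sim_g$cohort
  post_g <- posterior_summaries(p, cohort = co_g, quad = small_quad())
  mt_g <- mean_alteration_times(post_g)
  expect_equal(mt_g$mean_time[mt_g$driver == "M1"], 0)
})

test_that("order trees are tries with conserved counts", {
  post <- structure(
    tibble::tibble(
      sample = c("s1", "s2", "s3"), N = 1L, S = 60, post_T = 100,
      order = list(c("A", "B"), c("A", "C"), c("A", "B"))
    ),
    drivers = c("A", "B", "C"),
    class = c("mutclock_posterior", "tbl_df", "tbl", "data.frame")
  )
  tree <- build_order_tree(post, min_support = 1)
  nodes <- tree$nodes
  rootA <- nodes[nodes$depth == 1, ]
  expect_equal(rootA$driver, "A")
  expect_equal(rootA$count, 3L)
  kids <- nodes[nodes$parent == rootA$id, ]
  expect_setequal(kids$driver, c("B", "C"))
  expect_equal(sort(kids$count), c(1L, 2L))
  # count conservation: children + endings = node count
  for (id in nodes$id) {
    expect_equal(nodes$count[nodes$id == id],
                 sum(nodes$count[nodes$parent == id]) +
                   nodes$n_end[nodes$id == id])
  }
  # pruning: the (A, C) branch is unique at depth 2 and disappears
  pruned <- build_order_tree(post, min_support = 2)
  expect_false("C" %in% pruned$nodes$driver)
  # no repeated depth-2 prefix at all -> only depth-1 nodes survive
  post2 <- post
  post2$order <- list(c("A", "B"), c("B", "C"), c("C", "A"))
  t2 <- build_order_tree(post2, min_support = 2)
  expect_true(all(t2$nodes$depth == 1))
  expect_match(tree_newick(tree), "^\\(.*\\)root;$")
})

test_that("the comparator test behaves like a Welch test should", {
  co <- as_cohort(tibble::tibble(
    sample = sprintf("s%03d", 1:200),
    N = c(rpois(100, 20), rpois(100, 20)),
    S = 60,
    A_D1 = rep(c(1L, 0L), each = 100),
    G_D1 = 0L
  ), data_kind = "cna")
  set.seed(1)
  res <- comparator_test(co)
  expect_gt(res$p_value, 0.01)  # same distribution in both groups
  co2 <- co
  co2$N <- c(rpois(100, 200), rpois(100, 20))
  res2 <- comparator_test(as_cohort(co2, data_kind = "cna"))
  expect_lt(res2$p_value, 1e-6)
  # empty group -> NA
  co3 <- co
  co3$A_D1 <- 1L
  expect_true(is.na(comparator_test(as_cohort(co3,
                                              data_kind = "cna"))$p_value))
})
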