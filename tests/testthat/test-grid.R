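# Grid construction, ensemble weighting, Kobe classification and the
# regression tree.

test_that("grids enumerate the full Cartesian product deterministically", {
  g <- build_grid(list(a = c(1, 2), b = c("x", "y", "z")))
  expect_equal(g$n, 6)
  expect_equal(g$labels[1:3], c("a1_bx", "a1_by", "a1_bz"))
  g2 <- build_grid(list(a = c(1, 2), b = c("x", "y", "z")))
  expect_identical(g$labels, g2$labels)
  single <- build_grid(list(a = "only"))
  expect_equal(single$n, 1)
  expect_equal(single$labels, single$reference_label)
  expect_error(build_grid(list(a = c(1, 1))), "duplicate")
  expect_error(build_grid(list(a = 1:2), reference = c(a = "9")),
               "reference")
})

test_that("grid size is the product of level counts for random designs", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    fac <- lapply(seq_len(k), function(j)
      paste0("l", seq_len(sample(1:4, 1))))
    names(fac) <- paste0("f", seq_len(k))
    g <- build_grid(fac)
    expect_equal(g$n, prod(vapply(fac, length, integer(1))))
    expect_false(anyDuplicated(g$labels) > 0)
  }
})

test_that("the canonical grid converts to scenario configurations", {
  g <- build_grid(toy_factors(m_levels = c("0.3", "0.4/0.2")))
  cfgs <- grid_configs(g)
  expect_length(cfgs, 2)
  expect_equal(cfgs[[2]]$m_juvenile, 0.4)
  expect_equal(cfgs[[2]]$m_adult, 0.2)
  expect_equal(cfgs[[1]]$m_adult, 0.3)
  expect_error(grid_configs(build_grid(list(a = 1))), "canonical")
})

test_that("diagnostic weighting follows the normalised pass score", {
  pm <- rbind(A = c(TRUE, TRUE), B = c(TRUE, TRUE))
  w <- weight_scenarios(pm)
  expect_equal(w$weight, c(0.5, 0.5))
  pm2 <- rbind(A = c(TRUE, TRUE), B = c(FALSE, FALSE))
  expect_equal(weight_scenarios(pm2)$weight, c(1, 0))
  # A passes {rho}, B passes {rho, MASE}: weights 1/3, 2/3
  pm3 <- rbind(A = c(TRUE, FALSE), B = c(TRUE, TRUE))
  expect_equal(weight_scenarios(pm3)$weight, c(1 / 3, 2 / 3))
  # all fail: uniform with a warning
  pm4 <- rbind(A = c(FALSE, FALSE), B = c(FALSE, FALSE))
  expect_warning(w4 <- weight_scenarios(pm4), "uniform")
  expect_equal(w4$weight, c(0.5, 0.5))
  expect_error(weight_scenarios(pm3, c(-1, 1)), ">= 0")
})

test_that("splitting a diagnostic's weight across duplicates changes nothing", {
  pm <- rbind(A = c(TRUE, FALSE), B = c(TRUE, TRUE), C = c(FALSE, TRUE))
  w1 <- weight_scenarios(pm, c(1, 2))
  pm_dup <- cbind(pm, pm[, 2])
  w2 <- weight_scenarios(pm_dup, c(1, 1, 1))
  expect_equal(w1$weight, w2$weight, tolerance = 1e-12)
})

test_that("Kobe classification follows the precautionary quadrant rule", {
  expect_equal(as.character(kobe_classify(1.5, 0.5)), "green")
  expect_equal(as.character(kobe_classify(0.5, 1.5)), "red")
  expect_equal(as.character(kobe_classify(1.5, 1.5)), "yellow")
  expect_equal(as.character(kobe_classify(0.5, 0.5)), "orange")
  # the boundary is never green
  expect_false(as.character(kobe_classify(1, 1)) == "green")
  expect_false(as.character(kobe_classify(1, 0.5)) == "green")
  expect_false(as.character(kobe_classify(1.5, 1)) == "green")
  expect_error(kobe_classify(0, 1), "> 0")
})

test_that("Kobe probabilities are a weighted distribution over quadrants", {
  rec <- data.frame(label = c("a", "b", "c", "d"),
                    quadrant = c("green", "green", "green", "red"))
  wu <- data.frame(label = rec$label, weight = rep(0.25, 4))
  p <- kobe_probabilities(rec, wu)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p["green"]), 0.75)
  # all weight on one scenario: degenerate distribution
  w1 <- data.frame(label = rec$label, weight = c(0, 0, 0, 1))
  expect_equal(unname(kobe_probabilities(rec, w1)["red"]), 1)
  # (1/3, 2/3) on (green, red)
  rec2 <- data.frame(label = c("a", "b"), quadrant = c("green", "red"))
  w2 <- data.frame(label = c("a", "b"), weight = c(1 / 3, 2 / 3))
  expect_equal(unname(kobe_probabilities(rec2, w2)["red"]), 2 / 3)
  # invariant to scenario ordering
  p_rev <- kobe_probabilities(rec[4:1, ], wu)
  expect_equal(p, p_rev)
  expect_error(kobe_probabilities(rec, data.frame(label = "zz", weight = 1)),
               "labels")
})

test_that("regression tree splits on the dominant factor first", {
  g <- build_grid(list(Ma = c("0.2", "0.4"), other = c("u", "v")))
  # response depends only on Ma
  resp <- ifelse(g$levels$Ma == "0.4", 1, 0)
  tr <- regression_tree(g$levels, resp, min_leaf = 1)
  expect_equal(tr$split_factor, "Ma")
  expect_equal(tree_sse(tr), 0)
  # additive effects 1.0 and 0.1: the big one wins the root
  g2 <- build_grid(list(a = c("0", "1"), b = c("0", "1")))
  resp2 <- as.numeric(g2$levels$a) * 1.0 + as.numeric(g2$levels$b) * 0.1
  tr2 <- regression_tree(g2$levels, resp2, min_leaf = 1)
  expect_equal(tr2$split_factor, "a")
})

test_that("constant responses yield a single leaf at the global mean", {
  g <- build_grid(list(a = c("1", "2"), b = c("x", "y")))
  tr <- regression_tree(g$levels, rep(3.5, 4))
  expect_null(tr$split_factor)
  expect_equal(tr$mean, 3.5)
  # depth-0 tree predicts the global mean
  tr0 <- regression_tree(g$levels, c(1, 2, 3, 4), max_depth = 0)
  expect_equal(predict(tr0, g$levels), rep(2.5, 4))
})

test_that("tree SSE never increases with depth", {
  set.seed(21)
  g <- build_grid(list(a = c("1", "2", "3"), b = c("x", "y"),
                       c = c("p", "q")))
  resp <- rnorm(g$n) + 2 * (g$levels$a == "3")
  sse <- vapply(0:3, function(d)
    tree_sse(regression_tree(g$levels, resp, max_depth = d, min_leaf = 1)),
    numeric(1))
  expect_true(all(diff(sse) <= 1e-9))
  expect_equal(sse[1], sum((resp - mean(resp))^2))
})

test_that("toy grid evaluation matches a manual single-scenario run", {
  sim <- det_sim()
  # 2 x 2 toy grid: M {0.3, 0.4} x ESS {20, 50}
  g <- build_grid(toy_factors(e_levels = c("20", "50")))
  st <- list(n_peels = 2, hind_peels = 2, horizon = 1)
  cache <- new.env()
  res <- evaluate_grid(sim$data, g, settings = st,
                       base = det_params(), cache = cache)
  expect_equal(nrow(res), 4)
  expect_true(all(res$converged))
  # orchestration equals manual composition, bit for bit
  cfg <- grid_configs(g)[[1]]
  fit <- fit_assessment(sim$data, cfg, base = det_params())
  rp <- compute_refpts(fit)
  T_ <- length(fit$years)
  expect_identical(res$ssb_ratio[1], unname(fit$ssb_hat[T_] / rp$b_msy))
  expect_identical(res$f_ratio[1], unname(fit$f_hat[T_] / rp$f_msy))
  # re-running with unchanged inputs reuses every cached cell
  n_before <- length(ls(cache))
  res2 <- evaluate_grid(sim$data, g, settings = st,
                        base = det_params(), cache = cache)
  expect_identical(res, res2)
  expect_equal(length(ls(cache)), n_before)
})
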