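test_that("the fully expanded grid has 120 unique conditions", {
  g <- condition_grid()
  expect_equal(nrow(g), 120)
  expect_equal(anyDuplicated(g$condition_id), 0)
  expect_setequal(unique(g$N), c(100, 500))
  expect_setequal(unique(g$skew_pattern), c("None", "SP", "MM", "SM", "N+SM"))
})

test_that("condition grids can be read from a JSON config", {
  path <- system.file("extdata", "example_grid.json", package = "skewfa")
  g <- read_condition_grid(path)
  expect_equal(nrow(g), 2 * 1 * 2 * 2 * 2)
  expect_setequal(unique(g$p), 6)
  expect_setequal(unique(g$skew_pattern), c("None", "SM"))
})

test_that("grid runs produce one tidy row per condition-replicate-method", {
  g <- condition_grid()[5, ]
  rr <- run_grid(g, methods = "FA", replicates = 2, master_seed = 1)
  expect_s3_class(rr$decisions, "data.frame")
  expect_equal(nrow(rr$decisions), 2)
  expect_true(all(c("condition_id", "replicate", "method", "n_factors",
                    "retained", "p_value", "flag") %in% names(rr$decisions)))
  # byte-identical reruns under the same master seed
  rr2 <- run_grid(g, methods = "FA", replicates = 2, master_seed = 1)
  expect_identical(rr$decisions, rr2$decisions)
  # a different seed changes the p-values
  rr3 <- run_grid(g, methods = "FA", replicates = 2, master_seed = 2)
  expect_false(identical(rr$decisions$p_value, rr3$decisions$p_value))
})

test_that("EPS summaries aggregate the retention indicator exactly", {
  g <- condition_grid()
  sub <- g[g$N == 100 & g$p == 6 & g$loading == 0.6 &
             g$skew_pattern %in% c("None", "SM"), ]
  rr <- run_grid(sub, methods = c("FA", "PA"), replicates = 4,
                 master_seed = 3, pa_resamples = 20)
  s <- summarize_eps(rr, by = "skew_loading")
  expect_true(all(c("linear_model", "skew_pattern", "loading", "method",
                    "eps", "mc_se") %in% names(s)))
  # recompute one cell independently from the tidy table
  d <- rr$decisions
  cell <- d[d$method == "FA" & d$skew_pattern == "None", ]
  expect_equal(s$eps[s$method == "FA" & s$skew_pattern == "None"],
               mean(cell$retained, na.rm = TRUE))
  # linear-model flag marks None and SP only
  expect_true(all(s$linear_model == (s$skew_pattern %in% c("None", "SP"))))
  # mc_se bookkeeping: doubling the effective n shrinks se by sqrt(2)
  e1 <- eps(d[d$method == "FA", ][1:8, ])
  e2 <- eps(rbind(d[d$method == "FA", ][1:8, ], d[d$method == "FA", ][1:8, ]))
  expect_equal(e1$mc_se / e2$mc_se, sqrt(2), tolerance = 1e-10)
  expect_error(summarize_eps(rr, by = "not_a_key"), "unknown grouping")
})

test_that("partial eta-squared isolates coded effects", {
  # constant response: all effect sizes zero
  d <- expand.grid(N = c(100, 500), loading = c(0.6, 0.9),
                   skew_pattern = c("None", "SM"), replicate = 1:5)
  d$p <- 6; d$r <- 1
  d$method <- "FA"
  d$p_value <- 0.5
  out <- anova_partial_eta(d, "FA", factors = c("N", "loading", "skew_pattern"))
  expect_true(all(out$partial_eta2 == 0))
  # response equal to a coded main effect: that term has eta^2 = 1
  d2 <- d
  d2$p_value <- plogis(ifelse(d2$loading == 0.9, 2, -2))
  out2 <- anova_partial_eta(d2, "FA",
                            factors = c("N", "loading", "skew_pattern"))
  expect_equal(out2$partial_eta2[out2$term == "loading"], 1, tolerance = 1e-10)
  expect_equal(out2$term[1], "loading")
})

test_that("loading-skew interaction dominates the FA p-value surface", {
  g <- condition_grid()
  sub <- g[g$p == 6 & g$r == 1 & g$N == 500 &
             g$skew_pattern %in% c("None", "SM"), ]
  rr <- run_grid(sub, methods = "FA", replicates = 25, master_seed = 5)
  out <- anova_partial_eta(rr, "FA", factors = c("loading", "skew_pattern"))
  inter <- out$partial_eta2[out$term == "loading:skew_pattern"]
  expect_gt(inter, 0.1)   # among the important effects, as in the study
})

test_that("recovery RMSE bookkeeping and method ordering behave", {
  est <- data.frame(condition_id = "c1", replicate = 1, method = "FA",
                    item = 1:4, class = "lambda", index = 1,
                    estimate = c(0.6, 0.6, 0.6, 0.6), truth = rep(0.6, 4))
  expect_equal(rmse_recovery(est)$rmse, 0)
  est$estimate <- est$truth + 0.1
  expect_equal(rmse_recovery(est)$rmse, 0.1, tolerance = 1e-12)
  # FA suffers attenuation + structural error under SM/high-lambda;
  # WLSMV does not
  g <- condition_grid()
  sub <- g[g$N == 500 & g$p == 6 & g$r == 2 & g$loading == 0.9 &
             g$skew_pattern == "SM", ]
  rr <- run_grid(sub, methods = c("FA", "WLSMV"), replicates = 10,
                 master_seed = 6, store_estimates = TRUE)
  rec <- rmse_recovery(rr)
  lam <- rec[rec$class == "lambda", ]
  expect_gt(lam$rmse[lam$method == "FA"], lam$rmse[lam$method == "WLSMV"])
})
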