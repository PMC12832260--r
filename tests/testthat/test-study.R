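test_that("the default design grid spans 400 scenarios", {
  g <- scenario_grid()
  expect_equal(nrow(g), 400)
  expect_equal(length(unique(g$scenario_id)), 400)
  expect_equal(nrow(scenario_grid(20, 0.05, 100, 0)), 1)
  g2 <- scenario_grid(c(20, 40), 0.05, 100, 0)
  expect_equal(g2$tss, c(20, 40)) # order preserved
})

test_that("anchor counts follow the round-half-up rule with a floor of one", {
  expect_equal(n_anchor_for(20, 0.05), 1L)  # 1 item; never 0
  expect_equal(n_anchor_for(20, 0.10), 2L)
  expect_equal(n_anchor_for(60, 0.15), 9L)
  expect_equal(n_anchor_for(20, 0.175), 4L) # 3.5 rounds up
  expect_equal(n_anchor_for(80, 0.25), 20L)
  g <- scenario_grid()
  expect_true(all(g$n_anchor == pmax(1, floor(g$aip * g$tss + 0.5))))
})

test_that("one iteration is reproducible bit-identically", {
  scen <- scenario_grid(20, 0.25, 100, 0)[1, ]
  r1 <- run_iteration(scen, seed = 77, models = "2PL", methods = "MM")
  r2 <- run_iteration(scen, seed = 77, models = "2PL", methods = "MM")
  expect_identical(r1$indices, r2$indices)
  expect_identical(r1$coefficients, r2$coefficients)
  r3 <- run_iteration(scen, seed = 78, models = "2PL", methods = "MM")
  expect_false(identical(r1$indices$r, r3$indices$r))
})

test_that("both models consume identical response data within an iteration", {
  scen <- scenario_grid(20, 0.25, 50, 0.25)[1, ]
  r2pl <- run_iteration(scen, seed = 5, models = "2PL", methods = "MM",
                        keep_data = TRUE)
  r3pl <- run_iteration(scen, seed = 5, models = "3PL", methods = "MM",
                        keep_data = TRUE)
  for (j in 1:3)
    expect_identical(r2pl$data$responses[[j]], r3pl$data$responses[[j]])
})

test_that("anchor accounting matches the scenario", {
  scen <- scenario_grid(40, 0.15, 50, 0)[1, ]
  rec <- run_iteration(scen, seed = 3, models = "2PL", methods = "MM",
                       keep_data = TRUE)
  items <- rec$data$bank$items
  n12 <- sum(items$anchor_block == "link12")
  n23 <- sum(items$anchor_block == "link23")
  expect_equal(n12, n_anchor_for(40, 0.15))
  expect_equal(n23, n_anchor_for(40, 0.15))
  expect_length(intersect(items$item_id[items$anchor_block == "link12"],
                          items$item_id[items$anchor_block == "link23"]), 0)
  expect_equal(rec$M_aa,
               mean(items$a[items$anchor_block != "none"]))
})

test_that("run_study bookkeeping is deterministic and respects the config", {
  cfg <- study_config(tss = 20, aip = 0.25, n = c(50, 100), c = 0,
                      iterations = 3, seed = 42, models = "2PL",
                      methods = "MM")
  res <- run_study(cfg)
  # 2 scenarios x 3 iterations x 1 model x 1 method x 3 parameters
  expect_equal(nrow(res$records), 2 * 3 * 1 * 1 * 3)
  expect_equal(unique(res$records$method), "MM")
  expect_equal(nrow(res$convergence), 2 * 3)
  res2 <- run_study(cfg)
  expect_identical(res$records, res2$records)
})

test_that("convergence statistics aggregate correctly", {
  cv <- data.frame(scenario_id = "s1", model = "2PL",
                   converged_forms = c(3, 2), all_converged = c(TRUE, FALSE),
                   iteration = 1:2)
  st <- convergence_stats(cv)
  expect_equal(st$per_scenario$cr, 0.5)
  expect_equal(st$per_scenario$mean_forms, 2.5)
  expect_equal(st$overall$total_model_rate, 5 / 6)
  allok <- data.frame(scenario_id = "s1", model = "2PL",
                      converged_forms = 3, all_converged = TRUE)
  expect_equal(convergence_stats(allok)$per_scenario$cr, 1)
  expect_equal(convergence_stats(allok)$per_scenario$mean_forms, 3)
  expect_error(convergence_stats(allok[0, ]))
})

test_that("self-equating two calibrations of the same form is near-identity", {
  # same items, same ability distribution: the link should be ~ (1, 0)
  items <- generate_item_bank(20, 10, c = 0, seed = 60)
  f1 <- form_items(items, 1)
  devs <- t(vapply(1:20, function(s) {
    ab1 <- generate_abilities(1000, 0, 1, 1, seed = 7000 + s)
    ab2 <- generate_abilities(1000, 0, 1, 2, seed = 8000 + s)
    fits <- lapply(list(ab1, ab2), function(ab)
      fit_irt(simulate_responses(ab, f1, seed = 9000 + s +
                                   1000 * ab$form), "2PL"))
    co <- mm_coefficients(anchor_pairs(fits[[1]], fits[[2]]))
    c(A = co$A, B = co$B)
  }, numeric(2)))
  expect_true(all(abs(devs[, "A"] - 1) < 0.2))
  expect_true(all(abs(devs[, "B"]) < 0.2))
})

test_that("difficulty recovery is strong under favorable conditions", {
  # n = 1000, 40 items, 25% anchors, no guessing, 2PL
  scen <- scenario_grid(40, 0.25, 1000, 0)[1, ]
  rb <- vapply(1:20, function(s) {
    rec <- run_iteration(scen, seed = 1000 + s, models = "2PL",
                         methods = "MM")
    rec$indices$r[rec$indices$parameter == "b"]
  }, numeric(1))
  expect_gte(mean(rb >= 0.9), 0.9)
})

test_that("small samples with long tests fail to converge sometimes", {
  conv <- vapply(1:50, function(s) {
    bank <- generate_item_bank(80, 4, c = 0, seed = 5000 + s)
    ab <- generate_abilities(25, 0, 1, 1, seed = 6000 + s)
    x <- simulate_responses(ab, form_items(bank, 1), seed = 7000 + s)
    fit_irt(x, "2PL")$converged
  }, logical(1))
  expect_gt(sum(!conv), 0)
})

test_that("study config validates inputs", {
  expect_error(study_config(models = "4PL"))
  expect_error(study_config(methods = "XX"))
  expect_error(study_config(iterations = 0))
  cfg <- study_config(methods = c("MM", "IRF"))
  expect_equal(cfg$methods, c("MM", "IRF"))
})

test_that("analytic sampling errors and guessing mapping are correct", {
  se <- sampling_se(500)
  expect_equal(se$se_mean, 1 / sqrt(500), tolerance = 1e-12)
  expect_equal(se$se_variance, sqrt(2 / 499), tolerance = 1e-12)
  expect_equal(guessing_from_distractors(c(2, 3, 4, 6, 8)),
               c(0.5, 1 / 3, 0.25, 1 / 6, 0.125))
})
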