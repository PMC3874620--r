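test_that("constant fortification reproduces the bread worked example", {
  # mean bread consumer, mean intake, IOM target
  expect_equal(constant_fortification(15, 3.4, 180), 6.4444444, tolerance = 1e-6)
  expect_equal(constant_fortification(15, 15, 180), 0)
  expect_equal(constant_fortification(100, 3.4, 180), 53.6666667,
               tolerance = 1e-6)
  # intake already above recommendation floors to zero, not negative
  expect_equal(constant_fortification(15, 40, 180), 0)
  expect_error(constant_fortification(15, 3.4, 0), "nonzero-consumption")
})

test_that("seasonal fortification reproduces the January worked example and floors", {
  traj <- default_traj()
  fv <- varying_fortification(75, traj, 2.32, 180)
  expect_equal(fv[["Jan"]], 11.3027, tolerance = 1e-4)
  # July baseline 62.2 nmol/L exceeds a 50 nmol/L target: floored
  fv50 <- varying_fortification(50, traj, 2.32, 180)
  expect_equal(fv50[["Jul"]], 0)
  flat <- serum_trajectory(rep(45, 12))
  expect_equal(unname(varying_fortification(50, flat, 2.32, 100)),
               rep(2.1551724, 12), tolerance = 1e-6)
  expect_error(varying_fortification(75, traj, 0, 180), "positive")
  expect_error(varying_fortification(75, traj, 2.32, 0),
               "nonzero-consumption")
})

test_that("a flat baseline yields 12 equal seasonal levels", {
  flat <- generate_trajectory(seasonal_model(amplitude = 0))
  fv <- varying_fortification(75, flat, 2.32, 180)
  expect_equal(diff(range(fv)), 0)
})

test_that("formulas agree with independent one-line arithmetic on random draws", {
  d <- random_inputs(1000L)
  for (i in seq_len(nrow(d))) {
    expect_equal(constant_fortification(d$I_r[i], d$I_a[i], d$F_i[i]),
                 max(0, (d$I_r[i] - d$I_a[i]) * 100 / d$F_i[i]),
                 tolerance = 1e-12)
    traj <- serum_trajectory(rep(d$L_a[i], 12))
    expect_equal(varying_fortification(d$L_r[i], traj, d$c_f[i], d$F_i[i])[[1]],
                 max(0, (d$L_r[i] - d$L_a[i]) * 100 / (d$c_f[i] * d$F_i[i])),
                 tolerance = 1e-12)
    expect_equal(d$L_a[i] + d$c_f[i] * d$F_i[i] * d$level[i] / 100,
                 {
                   plan <- fortification_plan("x", "seasonal",
                                              rep(d$level[i], 12))
                   apply_fortification(traj, plan, d$F_i[i],
                                       d$c_f[i])$new_trajectory$values[[1]]
                 },
                 tolerance = 1e-12)
  }
})

test_that("constant level is monotone in recommendation, intake and consumption", {
  f0 <- constant_fortification(15, 3.4, 180)
  expect_gt(constant_fortification(20, 3.4, 180), f0)   # higher target
  expect_lt(constant_fortification(15, 5.0, 180), f0)   # better diet
  expect_lt(constant_fortification(15, 3.4, 377), f0)   # bigger consumer
  set.seed(5)
  for (i in 1:50) {
    I_r <- runif(1, 10, 90); I_a <- runif(1, 0, 9); F_i <- runif(1, 20, 900)
    eps <- runif(1, 0.01, 2)
    expect_gt(constant_fortification(I_r + eps, I_a, F_i),
              constant_fortification(I_r, I_a, F_i))
    expect_lt(constant_fortification(I_r, I_a + eps, F_i),
              constant_fortification(I_r, I_a, F_i))
    expect_lt(constant_fortification(I_r, I_a, F_i + eps),
              constant_fortification(I_r, I_a, F_i))
  }
})

test_that("clustering finds the circular zero run and never undershoots in winter", {
  traj <- default_traj()

  # 75 nmol/L mean-bread: every month needs fortification, winter = Jan level
  fv <- varying_fortification(75, traj, 2.32, 180)
  plan <- cluster_plan(fv, "bread")
  expect_equal(plan$clusters$winter_level, max(fv))
  expect_equal(plan$clusters$winter_level, fv[["Jan"]])

  # 50 nmol/L mean-bread: zero exactly May-September
  fv50 <- varying_fortification(50, traj, 2.32, 180)
  plan50 <- cluster_plan(fv50, "bread")
  expect_equal(plan50$clusters$summer, 5:9)
  expect_equal(unname(plan50$monthly_levels[5:9]), rep(0, 5))
  expect_true(all(plan50$monthly_levels[plan50$clusters$winter] >=
                  fv50[plan50$clusters$winter]))

  # zero run crossing the December-January boundary
  lv <- rep(3, 12); lv[c(11, 12, 1, 2)] <- 0
  wrap <- cluster_plan(lv, "bread")
  expect_setequal(wrap$clusters$summer, c(11, 12, 1, 2))
  expect_equal(wrap$clusters$winter_level, 3)

  # degenerate inputs
  all0 <- cluster_plan(rep(0, 12))
  expect_equal(all0$clusters$winter_level, 0)
  expect_equal(all0$clusters$summer, 1:12)
  none0 <- cluster_plan(rep(2, 12))
  expect_equal(none0$clusters$winter, 1:12)

  # mean aggregation available behind a flag
  pm <- cluster_plan(fv50, "bread", aggregate = "mean")
  expect_equal(pm$clusters$winter_level, mean(fv50[pm$clusters$winter]))
  expect_lte(pm$clusters$winter_level, plan50$clusters$winter_level)
})

test_that("plan invariants are enforced", {
  expect_error(fortification_plan("x", "constant", c(rep(2, 11), 3)),
               "equal")
  expect_error(fortification_plan("x", "seasonal", c(rep(2, 11), -1)),
               "non-negative")
  expect_error(fortification_plan("x", "seasonal", rep(2, 7)), "12 values")
})

test_that("the scenario grid enumerates all cells and flags infeasible ones", {
  p <- default_params()
  g <- scenario_grid(p)
  tab <- g$table

  expect_equal(sum(tab$mode == "constant"), 81)  # 3 carriers x 3 x 3 x 3
  # juice 5th percentile consumes 0 g: infeasible, never an error
  juice_p5 <- tab[tab$carrier == "juice" & tab$carrier_percentile == "p5", ]
  expect_true(all(!juice_p5$feasible))
  expect_true(all(is.na(juice_p5$level_ug_per_100g)))
  expect_true(all(tab$feasible[tab$carrier != "juice"]))

  # the dotted-box cell equals the direct formula evaluation
  cell <- tab[tab$carrier == "bread" & tab$mode == "constant" &
              tab$target_label == "IOM" & tab$vitd_percentile == "mean" &
              tab$carrier_percentile == "mean", ]
  expect_equal(cell$level_ug_per_100g, constant_fortification(15, 3.4, 180))

  # every emitted level is non-negative
  expect_true(all(tab$level_ug_per_100g >= 0, na.rm = TRUE))

  # seasonal cells carry 12 month rows with the clustered levels
  seas <- tab[tab$carrier == "bread" & tab$mode == "seasonal" &
              tab$target_label == "serum75" & tab$vitd_percentile == "mean" &
              tab$carrier_percentile == "mean", ]
  expect_equal(nrow(seas), 12)
  plan <- g$plans[["bread.mean.mean.serum75"]]
  expect_equal(seas$level_ug_per_100g, unname(plan$monthly_levels))
})
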