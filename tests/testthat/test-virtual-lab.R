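test_that("the landscape peaks exactly at the configured optimum", {
  specs <- eu_specs()
  cfg <- landscape_config(specs, optimum = 0.75, amplitude = 10, seed = 1)
  opt <- cfg$optimum * cfg$max_volume
  names(opt) <- cfg$components
  expect_equal(unname(true_yield(opt, cfg)), 10)
  # moving any single component off its optimum strictly lowers the yield
  for (cn in cfg$components) {
    off <- opt
    g <- specs[[match(cn, component_names(specs))]]$grid
    off[cn] <- g[which.min(abs(g - off[cn])) - 1L]
    expect_lt(true_yield(off, cfg), 10)
  }
})

test_that("grid argmax matches the analytic optimum on a small space", {
  specs <- with_value_grids(list(component_spec("A", 100),
                                 component_spec("B", 200),
                                 component_spec("C", 500)),
                            ratios = c(0, 0.25, 0.5, 0.75, 1))
  cfg <- landscape_config(specs, optimum = 0.75, amplitude = 7, seed = 2)
  full <- expand.grid(A = specs[[1]]$grid, B = specs[[2]]$grid,
                      C = specs[[3]]$grid)
  y <- true_yield(full, cfg)
  best <- full[which.max(y), ]
  expect_equal(unname(unlist(best)), unname(cfg$optimum * cfg$max_volume))
  expect_equal(max(y), 7)
})

test_that("the standard buffer is anchored to true yield 1", {
  cfg <- eu_landscape()
  expect_equal(unname(true_yield(standard_composition(cfg), cfg)), 1,
               tolerance = 1e-9)
  expect_equal(cfg$amplitude, 10)
})

test_that("the landscape is symmetric under component permutation", {
  specs <- eu_specs()
  cfg <- landscape_config(specs, optimum = c(0.2, 0.4, 0.6, 0.8),
                          width = c(0.1, 0.2, 0.3, 0.4), amplitude = 5)
  perm <- c(3, 1, 4, 2)
  specs_p <- specs[perm]
  cfg_p <- landscape_config(specs_p, optimum = c(0.2, 0.4, 0.6, 0.8)[perm],
                            width = c(0.1, 0.2, 0.3, 0.4)[perm], amplitude = 5)
  v <- c(`HeLa lysate` = 400, `Accessory proteins` = 120,
         `Reaction mix` = 200, DNA = 240)
  expect_equal(true_yield(v, cfg), true_yield(v[perm], cfg_p))
})

test_that("noise-free simulation reproduces true yields end to end", {
  specs <- eu_specs()
  cfg <- eu_landscape(noise_sd = 0, gain_sd = 0)
  refs <- data.frame(sample_id = c("STD", "CAL1"),
                     role = c("standard", "calibration"),
                     `HeLa lysate` = c(standard_composition(cfg)[1], 700),
                     `Accessory proteins` = c(standard_composition(cfg)[2], 140),
                     `Reaction mix` = c(standard_composition(cfg)[3], 280),
                     DNA = c(standard_composition(cfg)[4], 360),
                     check.names = FALSE)
  tab <- append_controls(lhs_sample(specs, 15, seed = 2), refs)
  lay <- assign_destination_wells(tab, 2, 2000)
  plates <- run_virtual_experiment(lay, cfg, seed = 5)
  # signals equal true yields exactly (gain 1, no noise)
  w <- lay[[1]]$wells
  expect_equal(unname(plates[[1]]$values[w$well]),
               unname(true_yield(w, cfg)))
  # and the computed fold-change yields equal true yields exactly
  res <- compute_yields(plates, lay)
  exp_rows <- res[res$role == "experiment", ]
  truth <- true_yield(tab[match(exp_rows$sample_id, tab$sample_id),
                          component_names(specs)], cfg)
  expect_equal(exp_rows$yield, unname(truth))
})

test_that("replicate wells differ only by the noise draw", {
  specs <- eu_specs()
  cfg <- eu_landscape(noise_sd = 0.1, gain_sd = 0)
  tab <- lhs_sample(specs, 5, seed = 3)
  lay <- assign_destination_wells(tab, 3, 2000)
  plates <- run_virtual_experiment(lay, cfg, seed = 6)
  w <- lay[[1]]$wells
  truth <- true_yield(w, cfg)
  log_resid <- log(plates[[1]]$values[w$well]) - log(truth)
  # residuals are iid normal around 0 on the log scale
  expect_lt(abs(mean(log_resid)), 0.1)
  expect_equal(sd(log_resid), 0.1, tolerance = 0.6)
  # same seed, same output
  plates2 <- run_virtual_experiment(lay, cfg, seed = 6)
  expect_identical(plates, plates2)
})

test_that("reader-plate CSVs round-trip through the readout parser", {
  specs <- eu_specs()
  cfg <- eu_landscape()
  tab <- lhs_sample(specs, 4, seed = 4)
  lay <- assign_destination_wells(tab, 2, 2000)
  plates <- run_virtual_experiment(lay, cfg, seed = 7)
  dir <- tempfile(); dir.create(dir)
  paths <- write_reader_plates(plates, dir)
  back <- parse_reader_matrix(paths[[1]], dims = c(16, 24),
                              plate_id = plates[[1]]$plate_id)
  expect_equal(back$values[names(plates[[1]]$values)], plates[[1]]$values,
               tolerance = 1e-12)
})

test_that("a short closed loop improves on its loop-0 best", {
  specs <- eu_specs()
  cfg <- eu_landscape()
  h <- closed_loop_benchmark(specs, cfg, loops = 2, method = "VAL", seeds = 1,
                             n_init = 25, n_batch = 10, pool_size = 400,
                             replicates = 2, sample_volume = 2000)
  expect_equal(h$loop, 0:2)
  expect_equal(h$n_tested, c(25, 35, 45))
  expect_true(all(diff(h$best_measured) >= -1e-9))
  expect_true(all(diff(h$best_true) >= -1e-9))
  expect_gt(h$best_true[3], h$best_true[1] - 1e-9)
  h1 <- closed_loop_benchmark(specs, cfg, loops = 1, method = "random",
                              seeds = 2, n_init = 10, n_batch = 5,
                              pool_size = 100, replicates = 2,
                              sample_volume = 2000)
  expect_equal(nrow(h1), 2)
})
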