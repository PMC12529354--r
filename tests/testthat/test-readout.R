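make_matrix_csv <- function(m, path = tempfile(fileext = ".csv")) {
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  path
}

test_that("reader matrices parse into named wells; shape errors are caught", {
  m <- matrix(seq_len(384), 16, 24, byrow = TRUE)
  p <- parse_reader_matrix(make_matrix_csv(m), dims = c(16, 24))
  expect_length(p$values, 384)
  expect_equal(unname(p$values[["A1"]]), 1)
  expect_equal(unname(p$values[["P24"]]), 384)

  expect_error(parse_reader_matrix(make_matrix_csv(m[1:15, ]), dims = c(16, 24)),
               "15 rows")
  bad <- matrix(as.character(m), 16, 24)
  bad[3, 3] <- "oops"
  expect_error(parse_reader_matrix(make_matrix_csv(bad), dims = c(16, 24)),
               "non-numeric")
})

test_that("kinetic exports split into timestamped plates; endpoint picks nearest", {
  f <- tempfile(fileext = ".csv")
  m8 <- matrix(1, 2, 3); m24 <- matrix(2, 2, 3)
  lines <- c("time,8", apply(m8, 1, paste, collapse = ","),
             "time,24", apply(m24, 1, paste, collapse = ","))
  writeLines(lines, f)
  series <- parse_reader_matrix(f, dims = c(2, 3))
  expect_length(series, 2)
  expect_equal(series[[2]]$time_point, 24)
  ep <- extract_endpoint(series, 24)
  expect_equal(unname(ep$values[["A1"]]), 2)
  expect_equal(extract_endpoint(series, 7)$time_point, 8)
  expect_equal(extract_endpoint(series[1], 4)$time_point, 8)  # single read
  expect_error(extract_endpoint(list(), 24), "empty")
})

# two-plate fixture sharing calibration compositions
two_plate_fixture <- function(factor_b = 2, base = c(100, 200, 400)) {
  wells <- function(prefix) {
    data.frame(well = c("A1", "A2", "A3", "A4"),
               sample_id = c("STD", "CAL1", paste0(prefix, "_X"), paste0(prefix, "_Y")),
               role = c("standard", "calibration", "experiment", "experiment"),
               A = c(50, 25, 10, 75), stringsAsFactors = FALSE)
  }
  layA <- new_plate_layout_for_test(wells("A"), plate_id = "P1")
  layB <- new_plate_layout_for_test(wells("B"), plate_id = "P2")
  sigA <- c(A1 = base[1], A2 = base[2], A3 = base[3], A4 = 500)
  sigB <- factor_b * sigA
  list(plates = list(reader_plate("P1", sigA, dims = c(16, 24)),
                     reader_plate("P2", sigB, dims = c(16, 24))),
       layouts = list(layA, layB))
}

test_that("a plate reading exactly 2x the reference gets scale factor 0.5", {
  fx <- two_plate_fixture(factor_b = 2)
  s <- calibrate_plates(fx$plates, fx$layouts, reference_plate = "P1")
  expect_equal(unname(s["P1"]), 1)
  expect_equal(unname(s["P2"]), 0.5)
  # single plate: factor 1
  s1 <- calibrate_plates(fx$plates[1], fx$layouts[1])
  expect_equal(unname(s1), 1)
})

test_that("scale factors are invariant to a global signal rescale", {
  fx <- two_plate_fixture(factor_b = 3.7)
  s <- calibrate_plates(fx$plates, fx$layouts, reference_plate = "P1")
  fx2 <- fx
  fx2$plates <- lapply(fx2$plates, function(p) { p$values <- p$values * 13; p })
  s2 <- calibrate_plates(fx2$plates, fx2$layouts, reference_plate = "P1")
  expect_equal(s, s2)
  # calibration-well means agree across plates after scaling
  for (pid in c("P1", "P2")) {
    fxp <- fx$plates[[match(pid, c("P1", "P2"))]]
    cal <- fxp$values[c("A1", "A2")] * s[[pid]]
    expect_equal(unname(mean(cal)), mean(fx$plates[[1]]$values[c("A1", "A2")]))
  }
})

test_that("a plate with no shared calibration composition errors", {
  fx <- two_plate_fixture()
  fx$layouts[[2]]$wells$sample_id <- c("OTHER1", "OTHER2", "B_X", "B_Y")
  fx$layouts[[2]]$wells$role <- c("experiment", "experiment", "experiment", "experiment")
  expect_error(calibrate_plates(fx$plates, fx$layouts, reference_plate = "P1"),
               "shares no calibration")
})

test_that("yields are fold changes with the standard pinned to 1", {
  fx <- two_plate_fixture(factor_b = 2)
  res <- compute_yields(fx$plates, fx$layouts, reference_plate = "P1")
  expect_s3_class(res, "calibrated_results")
  expect_equal(res$yield[res$sample_id == "STD"], 1)
  # sample with signal equal to the standard mean has yield 1
  expect_equal(res$yield[res$sample_id == "A_X"],
               400 / 100)
  # replicate aggregation across plates happened for STD (calibrated equal)
  expect_equal(res$n_replicates[res$sample_id == "STD"], 2)

  fx$plates[[1]]$values[["A3"]] <- 0
  fx$plates[[2]]$values[["A3"]] <- 0
  res0 <- compute_yields(fx$plates, fx$layouts, reference_plate = "P1")
  expect_equal(res0$yield[res0$sample_id == "A_X"], 0)

  fx$layouts[[1]]$wells$role[1] <- "experiment"
  fx$layouts[[2]]$wells$role[1] <- "experiment"
  expect_error(compute_yields(fx$plates, fx$layouts, reference_plate = "P1"),
               "standard")
})

test_that("replicate aggregation is permutation invariant", {
  wells <- data.frame(well = c("A1", "A2", "A3", "A4"),
                      sample_id = c("S1", "S1", "S1", "STD"),
                      role = c(rep("experiment", 3), "standard"),
                      A = 10, stringsAsFactors = FALSE)
  lay <- new_plate_layout_for_test(wells, plate_id = "P1")
  sig <- c(A1 = 5, A2 = 9, A3 = 1, A4 = 4)
  r1 <- compute_yields(list(reader_plate("P1", sig)), list(lay))
  perm <- wells[c(3, 1, 2, 4), ]
  perm$well <- c("A1", "A2", "A3", "A4")
  lay2 <- new_plate_layout_for_test(perm, plate_id = "P1")
  sig2 <- c(A1 = 1, A2 = 5, A3 = 9, A4 = 4)
  r2 <- compute_yields(list(reader_plate("P1", sig2)), list(lay2))
  expect_equal(r1$yield, r2$yield)
})

test_that("known per-plate gains are recovered from virtual-lab output", {
  specs <- eu_specs()
  cfg <- eu_landscape(noise_sd = 0.05, gain_sd = 0.5, seed = 3)
  refs <- data.frame(sample_id = c("STD", "CAL1"),
                     role = c("standard", "calibration"),
                     `HeLa lysate` = c(500, 700),
                     `Accessory proteins` = c(100, 140),
                     `Reaction mix` = c(200, 280), DNA = c(260, 360),
                     check.names = FALSE)
  tab <- append_controls(lhs_sample(specs, 20, seed = 3), refs)
  # two plates: same table laid out twice under different ids
  layA <- assign_destination_wells(tab, 3, 2000, plate_prefix = "PA")
  layB <- assign_destination_wells(tab, 3, 2000, plate_prefix = "PB")
  set.seed(99)
  plA <- run_virtual_experiment(layA, cfg, seed = 11)
  plB <- run_virtual_experiment(layB, cfg, seed = 12)
  # true gain ratio from the generator's own seeded draws
  set.seed(11); gA <- exp(rnorm(1, 0, cfg$gain_sd))
  set.seed(12); gB <- exp(rnorm(1, 0, cfg$gain_sd))
  s <- calibrate_plates(c(plA, plB), c(layA, layB),
                        reference_plate = plA[[1]]$plate_id)
  # recovered factor ~ gA/gB within a noise-sized tolerance
  expect_equal(unname(s[plB[[1]]$plate_id]), gA / gB,
               tolerance = 2 * cfg$noise_sd)
})
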