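#' Configure a simulated CFPS yield landscape
#'
#' The virtual lab stands in for the wet-lab Build/Test stages so the whole
#' optimization loop can run and be benchmarked at the desk. The true yield
#' is a multiplicative Gaussian bump over normalized composition fractions:
#' `y(v) = floor + (A - floor) * prod_i exp(-w_weight_i * (v_i/V_i - o_i)^2 / (2 w_i^2))`,
#' strictly maximal where every component sits at its optimum fraction
#' `o_i`. Multiplicative (not additive) structure reflects CFPS chemistry:
#' starving any essential component collapses the whole reaction. Reader
#' signals add log-normal observation noise and a log-normal per-plate gain,
#' emulating lysate/reader drift between plates.
#'
#' When `standard` fractions are supplied, the widths are rescaled by a
#' single common factor so that the standard buffer composition has true
#' yield exactly 1, making simulated fold-changes directly comparable to
#' the usual "standard buffer = 1" convention.
#'
#' @param specs List of [component_spec()] objects with grids attached.
#' @param optimum Named (or unnamed, recycled) optimum fractions in (0, 1];
#'   snapped to each component's grid so the optimum is attainable.
#' @param width Gaussian widths per component (fraction units).
#' @param weight Per-component exponent weights.
#' @param amplitude Peak true yield `A` (fold units).
#' @param floor Additive floor of the landscape.
#' @param standard Fractions of the standard buffer (snapped to grids);
#'   `NULL` to keep `width` as given.
#' @param noise_sd Log-scale observation noise SD.
#' @param gain_sd Log-scale per-plate gain SD.
#' @param seed Seed used for per-plate gain and noise draws.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(specs, optimum = 0.75, width = 0.2, weight = 1,
                             amplitude = 10, floor = 0, standard = NULL,
                             noise_sd = 0.1, gain_sd = 0.2, seed = 1L) {
  vs <- variable_components(specs)
  d <- length(vs)
  nm <- component_names(vs)
  rec <- function(x) {
    x <- rep_len(x, d)
    names(x) <- nm
    x
  }
  optimum <- rec(optimum); width <- rec(width); weight <- rec(weight)
  snap_frac <- function(frac, s) {
    g <- s$grid / s$max_volume
    g[which.min(abs(g - frac))]
  }
  for (i in seq_len(d)) optimum[i] <- snap_frac(optimum[i], vs[[i]])
  std_frac <- NULL
  if (!is.null(standard)) {
    std_frac <- rec(standard)
    for (i in seq_len(d)) std_frac[i] <- snap_frac(std_frac[i], vs[[i]])
    # one global width rescale so true_yield(standard) == 1 exactly
    expo <- sum(weight * (std_frac - optimum)^2 / (2 * width^2))
    if (expo <= 0) stop("standard coincides with the optimum; cannot anchor yield 1")
    target <- log((amplitude - floor) / (1 - floor))
    width <- width * sqrt(expo / target)
  }
  structure(list(components = nm,
                 max_volume = vapply(vs, function(s) s$max_volume, numeric(1)),
                 optimum = optimum, width = width, weight = weight,
                 amplitude = amplitude, floor = floor,
                 standard_fraction = std_frac,
                 noise_sd = noise_sd, gain_sd = gain_sd, seed = seed),
            class = "landscape_config")
}

#' @export
print.landscape_config <- function(x, ...) {
  cat(sprintf("Virtual CFPS landscape: %d components, peak %.3g at fractions (%s)\n",
              length(x$components), x$amplitude,
              paste(sprintf("%.3g", x$optimum), collapse = ", ")))
  cat(sprintf("  noise sd %.3g, plate gain sd %.3g (log scale)\n",
              x$noise_sd, x$gain_sd))
  invisible(x)
}

#' True (noise-free) yield of a composition
#'
#' @param volumes Named vector, matrix or data frame of component volumes
#'   (nL); columns must cover the landscape's components.
#' @param config A [landscape_config()].
#' @return True yield(s) in fold units.
#' @export
true_yield <- function(volumes, config) {
  if (is.null(dim(volumes))) volumes <- t(as.matrix(volumes))
  volumes <- as.matrix(as.data.frame(volumes)[, config$components, drop = FALSE])
  frac <- sweep(volumes, 2L, config$max_volume, "/")
  expo <- sweep(sweep(frac, 2L, config$optimum, "-")^2, 2L,
                config$weight / (2 * config$width^2), "*")
  config$floor + (config$amplitude - config$floor) * exp(-rowSums(expo))
}

#' Standard-buffer volumes of a landscape
#'
#' @param config A [landscape_config()] built with `standard` fractions.
#' @return Named volume vector (nL).
#' @export
standard_composition <- function(config) {
  if (is.null(config$standard_fraction))
    stop("landscape was configured without a standard composition")
  v <- config$standard_fraction * config$max_volume
  names(v) <- config$components
  v
}

#' Simulate reader output for destination plates
#'
#' Generates one endpoint `reader_plate` per destination layout: each
#' well's signal is `gain_p * true_yield * exp(eps)` with
#' `eps ~ N(0, noise_sd^2)` and a log-normal per-plate gain. Calibration
#' and standard wells are simulated like any other, so downstream
#' calibration can be exercised realistically. Deterministic for a fixed
#' seed.
#'
#' @param destinations List of destination `plate_layout` objects.
#' @param config A [landscape_config()].
#' @param seed Integer seed; defaults to the config's.
#' @param channel Reported channel label.
#' @return List of `reader_plate` objects (one per destination plate).
#' @export
run_virtual_experiment <- function(destinations, config, seed = config$seed,
                                   channel = "fluorescence") {
  set.seed(seed)
  gains <- exp(stats::rnorm(length(destinations), 0, config$gain_sd))
  lapply(seq_along(destinations), function(pi) {
    p <- destinations[[pi]]
    y <- true_yield(p$wells, config)
    eps <- stats::rnorm(length(y), 0, config$noise_sd)
    vals <- gains[pi] * y * exp(eps)
    names(vals) <- p$wells$well
    reader_plate(p$plate_id, vals, channel = channel, dims = p$dims)
  })
}

#' Write simulated reader plates as matrix CSVs
#'
#' Unlaid wells are written as 0 so the files have the full plate shape the
#' parser expects.
#'
#' @param plates List of `reader_plate` objects.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_reader_plates <- function(plates, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(plates, function(p) {
    m <- matrix(0, p$dims[1], p$dims[2])
    idx <- parse_well_name(names(p$values))
    m[cbind(idx$row, idx$col)] <- p$values
    path <- file.path(dir, sprintf("%s.csv", p$plate_id))
    utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

## reference compositions (standard + calibration + controls) appended to
## every loop's sample table so cross-plate calibration is always anchored
reference_compositions <- function(specs, config, n_calibration = 2L) {
  nm <- config$components
  std <- standard_composition(config)
  pick <- function(frac) {
    v <- vapply(seq_along(nm), function(i) {
      s <- variable_components(specs)[[i]]
      s$grid[which.min(abs(s$grid / s$max_volume - frac))]
    }, numeric(1))
    names(v) <- nm
    v
  }
  rows <- list(c(list(sample_id = "STD", role = "standard"), as.list(std)))
  fracs <- c(0.4, 0.8, 0.6, 0.2)[seq_len(min(n_calibration, 4L))]
  for (i in seq_along(fracs)) {
    rows[[length(rows) + 1L]] <-
      c(list(sample_id = sprintf("CAL%d", i), role = "calibration"),
        as.list(pick(fracs[i])))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' Closed-loop optimization benchmark on the virtual lab
#'
#' Runs the whole Design-Build-Test-Learn loop against the simulated
#' landscape, once per seed: a Latin-hypercube loop 0 (plus standard and
#' calibration buffers), destination plate layout, simulated reader output
#' with per-plate gain, cross-plate calibration and yield computation, then
#' `loops` rounds of surrogate-guided batch proposals. Every loop gets its
#' own plate (own simulated gain), calibrated back to the loop-0 plate.
#'
#' @param specs List of [component_spec()] objects with grids.
#' @param config A [landscape_config()] with a standard composition.
#' @param loops Number of learning loops after loop 0.
#' @param method `"VAL"`, `"CM"` or `"random"`.
#' @param seeds Integer vector: one independent run per seed.
#' @param n_init Loop-0 LHS size.
#' @param n_batch Compositions proposed per loop.
#' @param m_top,k,pool_size,xi Learner settings (see [propose_batch()]).
#' @param replicates Wells per composition.
#' @param sample_volume Reaction volume per well (nL).
#' @param dims Plate dimensions.
#' @return A `loop_history` data frame: one row per (seed, loop) with the
#'   number of tested compositions, the best measured and best true yield
#'   so far, and the method.
#' @export
closed_loop_benchmark <- function(specs, config, loops = 4L,
                                  method = c("VAL", "CM", "random"),
                                  seeds = 1:20, n_init = 50L, n_batch = 15L,
                                  m_top = 30L, k = 2L * n_batch,
                                  pool_size = 1000L, xi = 0.01,
                                  replicates = 3L, sample_volume = 6500,
                                  dims = c(16L, 24L)) {
  method <- match.arg(method)
  out <- lapply(seeds, function(seed) {
    run_closed_loop(specs, config, loops, method, seed, n_init, n_batch,
                    m_top, k, pool_size, xi, replicates, sample_volume, dims)
  })
  hist <- do.call(rbind, out)
  rownames(hist) <- NULL
  structure(hist, class = c("loop_history", "data.frame"))
}

run_closed_loop <- function(specs, config, loops, method, seed, n_init,
                            n_batch, m_top, k, pool_size, xi, replicates,
                            sample_volume, dims) {
  nm <- config$components
  refs <- reference_compositions(specs, config)
  tab0 <- append_controls(lhs_sample(specs, n_init, seed = seed), refs)

  all_layouts <- list()
  all_plates <- list()
  measure_loop <- function(table, loop_idx, gain_seed) {
    lay <- assign_destination_wells(table, replicates, sample_volume,
                                    dims = dims,
                                    plate_prefix = sprintf("L%d", loop_idx))
    pl <- run_virtual_experiment(lay, config, seed = gain_seed)
    all_layouts[c(length(all_layouts) + seq_along(lay))] <<- lay
    all_plates[c(length(all_plates) + seq_along(pl))] <<- pl
    invisible(NULL)
  }
  measure_loop(tab0, 0L, gain_seed = seed * 1000L + 1L)

  tested <- tab0[tab0$role == "experiment", nm, drop = FALSE]
  history <- list()
  record <- function(loop_idx) {
    res <- compute_yields(all_plates, all_layouts,
                          reference_plate = all_plates[[1]]$plate_id,
                          standard_plate = all_plates[[1]]$plate_id)
    exp_ids <- unlist(lapply(all_layouts, function(l)
      l$wells$sample_id[l$wells$role == "experiment"]))
    meas <- res[res$sample_id %in% exp_ids, ]
    history[[loop_idx + 1L]] <<- data.frame(
      seed = seed, method = method, loop = loop_idx,
      n_tested = nrow(tested),
      best_measured = max(meas$yield),
      best_true = max(true_yield(tested, config)),
      stringsAsFactors = FALSE)
    res
  }
  res <- record(0L)

  for (loop in seq_len(loops)) {
    # measured yields per tested composition, aligned with `tested`
    ids <- unique(unlist(lapply(all_layouts, function(l) {
      l$wells$sample_id[l$wells$role == "experiment"]
    })))
    y <- res$yield[match(ids, res$sample_id)]
    prop <- propose_batch(tested, y, specs, method = method,
                          n_batch = n_batch, m_top = m_top, k = k,
                          pool_size = pool_size, xi = xi,
                          seed = seed * 100L + loop)
    batch <- prop$batch
    btab <- cbind(data.frame(sample_id = sprintf("L%d_S%03d", loop, seq_len(nrow(batch))),
                             role = "experiment", stringsAsFactors = FALSE),
                  batch)
    btab <- structure(btab, class = c("sample_table", "data.frame"))
    # the same reference buffers ride on every plate (same sample_ids), so
    # plates share calibration anchors and standard replicates are pooled
    btab <- append_controls(btab, refs)
    measure_loop(btab, loop, gain_seed = seed * 1000L + loop + 1L)
    tested <- rbind(tested, batch[, nm, drop = FALSE])
    res <- record(loop)
  }
  do.call(rbind, history)
}

#' @export
print.loop_history <- function(x, ...) {
  cat(sprintf("Closed-loop history: %d seed(s), %d loop(s), method(s): %s\n",
              length(unique(x$seed)), max(x$loop),
              paste(unique(x$method), collapse = ", ")))
  fin <- x[x$loop == max(x$loop), ]
  cat(sprintf("  median final best measured yield: %.3g (true: %.3g)\n",
              stats::median(fin$best_measured), stats::median(fin$best_true)))
  invisible(x)
}
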