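#' Run configuration
#'
#' Collects every knob of a run in one object; [read_run_config()] loads
#' the same structure from a YAML file. Defaults mirror routine operation
#' on a 384-well acoustic platform.
#'
#' @param components_file Path to the component TSV (name, max volume nL).
#' @param n_samples Loop-0 LHS size.
#' @param seed Master seed; stage seeds are derived from it.
#' @param ratios,step Grid mode (see [build_value_grid()]).
#' @param fixed_values Named list of fixed volumes (nL).
#' @param replicates Wells per composition.
#' @param dims Plate dimensions `c(rows, cols)`.
#' @param sample_volume Reaction volume per destination well (nL).
#' @param dead_volume Source-well dead volume (nL).
#' @param max_well_volume Source-well capacity (nL).
#' @param source_overage Extra volume per allocated source well (nL)
#'   absorbing unreachable remainders left by whole-transfer well
#'   switching; one maximum transfer of slack guarantees replay.
#' @param constraints A [dispenser_constraints()] object.
#' @param method,m_top,n_batch,k,pool_size,xi Learner settings.
#' @param tol,patience Convergence settings (see [check_convergence()]).
#' @param dispense_classes Named vector of source-plate types per component.
#' @param out_dir Output directory for run artifacts.
#' @return An object of class `run_config` (a list).
#' @export
run_config <- function(components_file, n_samples = 100L, seed = 42L,
                       ratios = c(0, 0.2, 0.4, 0.6, 0.8, 1), step = NULL,
                       fixed_values = NULL, replicates = 4L,
                       dims = c(16L, 24L), sample_volume = 6500,
                       dead_volume = 20000, max_well_volume = 65000,
                       source_overage = 1000,
                       constraints = dispenser_constraints(),
                       method = "CM", m_top = 30L, n_batch = 15L,
                       k = 2L * n_batch, pool_size = 1000L, xi = 0.01,
                       tol = 0.01, patience = 1L,
                       dispense_classes = NULL, out_dir = ".") {
  if (!is.null(step)) ratios <- NULL
  structure(list(components_file = components_file, n_samples = n_samples,
                 seed = seed, ratios = ratios, step = step,
                 fixed_values = fixed_values, replicates = replicates,
                 dims = dims, sample_volume = sample_volume,
                 dead_volume = dead_volume, max_well_volume = max_well_volume,
                 source_overage = source_overage, constraints = constraints,
                 method = method, m_top = m_top, n_batch = n_batch, k = k,
                 pool_size = pool_size, xi = xi, tol = tol,
                 patience = patience, dispense_classes = dispense_classes,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Any field of [run_config()] may appear in the file; unspecified fields
#' take the defaults. Nested `constraints:` fields map onto
#' [dispenser_constraints()].
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$constraints))
    raw$constraints <- do.call(dispenser_constraints, raw$constraints)
  if (!is.null(raw$dims)) raw$dims <- as.integer(raw$dims)
  if (!is.null(raw$fixed_values)) raw$fixed_values <- as.list(raw$fixed_values)
  do.call(run_config, raw)
}

load_specs <- function(config) {
  specs <- parse_components_table(config$components_file,
                                  constraints = config$constraints,
                                  dispense_classes = config$dispense_classes)
  with_value_grids(specs, ratios = config$ratios, step = config$step,
                   fixed_values = config$fixed_values,
                   constraints = config$constraints)
}

write_manifest <- function(dir, config, files, seeds) {
  manifest <- list(
    config = config[setdiff(names(config), "constraints")],
    constraints = unclass(config$constraints),
    seeds = seeds,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' Init workflow: Sampler -> plate Designer -> Instructor
#'
#' Generates everything needed to run loop 0 in the lab: the LHS sampling
#' CSV (plus any supplied control/calibration/standard buffers), source and
#' destination plate layout CSVs, and one dispenser instruction CSV per
#' source-plate type, together with a manifest recording seeds and file
#' hashes for replay.
#'
#' @param config A [run_config()].
#' @param controls Optional data frame of reference compositions appended
#'   to the sampling (see [append_controls()]).
#' @return Invisibly, a list with the sample table, layouts, instructions
#'   and the paths written.
#' @export
run_init <- function(config, controls = NULL) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  specs <- load_specs(config)
  table <- lhs_sample(specs, config$n_samples, seed = config$seed)
  if (!is.null(controls)) table <- append_controls(table, controls)
  files <- character()
  p <- file.path(dir, "sampling.csv"); write_sample_table(table, p)
  files <- c(files, p)

  dest <- assign_destination_wells(table, config$replicates,
                                   config$sample_volume, dims = config$dims,
                                   constraints = config$constraints)
  src <- design_source_plate(dest, dead_volume = config$dead_volume,
                             max_well_volume = config$max_well_volume,
                             overage = config$source_overage,
                             dims = config$dims)
  p <- file.path(dir, "destination_layout.csv"); write_destination_layout(dest, p)
  files <- c(files, p)
  p <- file.path(dir, "source_layout.csv"); write_source_layout(src, p)
  files <- c(files, p)

  instr <- generate_instructions(src, dest, specs, config$constraints)
  files <- c(files, write_instructions(instr, dir))
  write_manifest(dir, config, files, seeds = list(sampler = config$seed))
  message(sprintf("init: %d compositions, %d destination wells on %d plate(s), %d transfers",
                  nrow(table), sum(vapply(dest, function(p) nrow(p$wells), numeric(1))),
                  length(dest), nrow(instr)))
  invisible(list(table = table, destinations = dest, source = src,
                 instructions = instr, files = files))
}

#' Core workflow: readout -> Learner -> plate Designer -> Instructor
#'
#' One learning loop: parses reader exports, calibrates plates against the
#' reference plate, computes fold-change yields, checks the convergence
#' plateau and, if not converged, proposes the next batch and writes its
#' plate layouts and dispenser instructions.
#'
#' @param config A [run_config()].
#' @param reader_files Character vector of reader matrix CSVs (one per
#'   plate, named after the destination plates) or a list of
#'   `reader_plate` objects.
#' @param layouts List of destination `plate_layout` objects matching the
#'   reader plates.
#' @param cumulative Optional data frame of compositions plus a `yield`
#'   column from previous loops (e.g. a previous loop's training CSV); the
#'   current plates' results are appended to it.
#' @param best_history Best-so-far yields of previous loops (may be empty).
#' @param loop Loop index used in output file names and sample ids.
#' @return Invisibly, a list with `results` (calibrated yields), `converged`,
#'   `batch` (next compositions, `NULL` if converged), the updated
#'   `training` table, layouts/instructions for the next loop and the paths
#'   written.
#' @export
run_core <- function(config, reader_files, layouts, cumulative = NULL,
                     best_history = numeric(), loop = 1L) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  specs <- load_specs(config)
  plates <- if (is.character(reader_files)) {
    lapply(reader_files, parse_reader_matrix, dims = config$dims)
  } else reader_files

  results <- compute_yields(plates, layouts)
  files <- character()
  p <- file.path(dir, sprintf("calibrated_results_loop%d.csv", loop))
  write_calibrated_results(results, p)
  files <- c(files, p)

  nm <- component_names(specs)
  # training table: previous loops' compositions+yields plus this round's
  cur <- sample_compositions(layouts, results, nm)
  cur$yield <- results$yield[results$role == "experiment"]
  training <- if (is.null(cumulative)) cur else
    rbind(as.data.frame(cumulative)[, c(nm, "yield")], cur)
  p <- file.path(dir, sprintf("training_loop%d.csv", loop))
  utils::write.csv(training, p, row.names = FALSE, quote = FALSE)
  files <- c(files, p)

  best_history <- c(best_history, max(training$yield))
  converged <- check_convergence(best_history, tol = config$tol,
                                 patience = config$patience)
  if (converged) {
    message(sprintf("core loop %d: converged (best yield %.3g); no new batch",
                    loop, max(best_history)))
    write_manifest(dir, config, files,
                   seeds = list(learner = config$seed + loop))
    return(invisible(list(results = results, converged = TRUE, batch = NULL,
                          training = training, best_history = best_history,
                          files = files)))
  }

  prop <- propose_batch(training[, nm, drop = FALSE], training$yield, specs,
                        method = config$method,
                        n_batch = config$n_batch, m_top = config$m_top,
                        k = config$k, pool_size = config$pool_size,
                        xi = config$xi, seed = config$seed + loop)
  batch <- cbind(data.frame(sample_id = sprintf("L%d_S%03d", loop, seq_len(nrow(prop$batch))),
                            role = "experiment", stringsAsFactors = FALSE),
                 prop$batch)
  batch <- structure(batch, class = c("sample_table", "data.frame"))
  p <- file.path(dir, sprintf("next_batch_loop%d.csv", loop))
  write_sample_table(batch, p)
  files <- c(files, p)

  dest <- assign_destination_wells(batch, config$replicates,
                                   config$sample_volume, dims = config$dims,
                                   plate_prefix = sprintf("L%d_Destination", loop),
                                   constraints = config$constraints)
  src <- design_source_plate(dest, dead_volume = config$dead_volume,
                             max_well_volume = config$max_well_volume,
                             overage = config$source_overage,
                             dims = config$dims,
                             plate_id = sprintf("L%d_Source", loop))
  p <- file.path(dir, sprintf("destination_layout_loop%d.csv", loop))
  write_destination_layout(dest, p); files <- c(files, p)
  p <- file.path(dir, sprintf("source_layout_loop%d.csv", loop))
  write_source_layout(src, p); files <- c(files, p)
  instr <- generate_instructions(src, dest, specs, config$constraints)
  files <- c(files, write_instructions(instr, dir,
                                       basename = sprintf("instructions_loop%d", loop)))
  write_manifest(dir, config, files, seeds = list(learner = config$seed + loop))
  message(sprintf("core loop %d: best yield %.3g, proposing %d compositions",
                  loop, max(best_history), nrow(prop$batch)))
  invisible(list(results = results, converged = FALSE, batch = batch,
                 training = training, destinations = dest, source = src,
                 instructions = instr, best_history = best_history,
                 files = files))
}

sample_compositions <- function(layouts, results, nm) {
  rows <- do.call(rbind, lapply(layouts, function(l) {
    d <- l$wells[l$wells$role == "experiment", c("sample_id", nm)]
    d[!duplicated(d$sample_id), ]
  }))
  rows <- rows[!duplicated(rows$sample_id), ]
  rows <- rows[match(results$sample_id[results$role == "experiment"], rows$sample_id), ]
  rows[, nm, drop = FALSE]
}

#' Simulate workflow: closed-loop benchmark report
#'
#' Runs [closed_loop_benchmark()] for one or more selection methods and
#' writes per-loop history and summary CSVs (per-loop mean and best yields
#' across seeds, swarm-style).
#'
#' @param config A [run_config()].
#' @param landscape A [landscape_config()].
#' @param methods Methods to benchmark.
#' @param seeds Seeds (independent runs) per method.
#' @param loops Learning loops after loop 0.
#' @return Invisibly, a list with the combined `loop_history` and the
#'   summary data frame.
#' @export
run_simulate <- function(config, landscape, methods = c("VAL", "CM", "random"),
                         seeds = 1:20, loops = 4L) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  specs <- load_specs(config)
  hist <- do.call(rbind, lapply(methods, function(m) {
    closed_loop_benchmark(specs, landscape, loops = loops, method = m,
                          seeds = seeds, n_init = config$n_samples,
                          n_batch = config$n_batch, m_top = config$m_top,
                          k = config$k, pool_size = config$pool_size,
                          xi = config$xi, replicates = config$replicates,
                          sample_volume = config$sample_volume,
                          dims = config$dims)
  }))
  utils::write.csv(hist, file.path(dir, "benchmark_history.csv"),
                   row.names = FALSE)
  summary <- do.call(rbind, lapply(split(hist, list(hist$method, hist$loop)),
                                   function(d) {
    data.frame(method = d$method[1], loop = d$loop[1],
               median_best_measured = stats::median(d$best_measured),
               mean_best_measured = mean(d$best_measured),
               median_best_true = stats::median(d$best_true),
               stringsAsFactors = FALSE)
  }))
  summary <- summary[order(summary$method, summary$loop), ]
  rownames(summary) <- NULL
  utils::write.csv(summary, file.path(dir, "benchmark_summary.csv"),
                   row.names = FALSE)
  invisible(list(history = hist, summary = summary))
}
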