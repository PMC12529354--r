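#' Parse a plate-reader matrix export
#'
#' Reads the canonical matrix form of an endpoint reader export: a
#' rows x cols numeric block of well signals (CSV, no header), optionally
#' repeated per time point where each block is preceded by a line
#' `time,<hours>`. Wells are named as in [well_name()], row-major.
#'
#' @param path File path.
#' @param dims Plate dimensions `c(rows, cols)`.
#' @param plate_id Plate identifier attached to the result.
#' @param channel `"fluorescence"` or `"luminescence"`.
#' @return A `reader_plate` (single block) or a list of `reader_plate`
#'   objects (kinetic file), each with fields `plate_id`, `channel`,
#'   `time_point` (hours or `NA`) and `values` (named well vector).
#' @export
parse_reader_matrix <- function(path, dims = c(16L, 24L), plate_id = NULL,
                                channel = c("fluorescence", "luminescence")) {
  channel <- match.arg(channel)
  if (is.null(plate_id)) plate_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty reader file: %s", path))
  is_time <- grepl("^\\s*time\\s*,", lines, ignore.case = TRUE)
  blocks <- list()
  if (any(is_time)) {
    starts <- which(is_time)
    ends <- c(starts[-1] - 1L, length(lines))
    for (b in seq_along(starts)) {
      t <- as.numeric(sub("^\\s*time\\s*,", "", lines[starts[b]], ignore.case = TRUE))
      blocks[[b]] <- list(time = t, body = lines[(starts[b] + 1L):ends[b]])
    }
  } else {
    blocks[[1]] <- list(time = NA_real_, body = lines)
  }
  plates <- lapply(blocks, function(b) {
    if (length(b$body) != dims[1])
      stop(sprintf("reader block has %d rows, expected %d", length(b$body), dims[1]))
    vals <- lapply(strsplit(b$body, ","), function(x) suppressWarnings(as.numeric(trimws(x))))
    ncols <- vapply(vals, length, integer(1))
    if (any(ncols != dims[2]))
      stop(sprintf("reader block has rows of %s columns, expected %d",
                   paste(unique(ncols), collapse = "/"), dims[2]))
    m <- do.call(rbind, vals)
    if (anyNA(m)) stop("non-numeric cell in reader block")
    v <- as.vector(t(m))
    names(v) <- as.vector(t(outer(seq_len(dims[1]), seq_len(dims[2]), well_name)))
    structure(list(plate_id = plate_id, channel = channel,
                   time_point = b$time, values = v, dims = dims),
              class = "reader_plate")
  })
  if (length(plates) == 1L) plates[[1]] else plates
}

#' Construct a reader plate in memory
#'
#' @param plate_id Plate identifier.
#' @param values Named numeric vector of well signals.
#' @param channel Signal channel.
#' @param time_point Hours, or `NA` for an endpoint read.
#' @param dims Plate dimensions.
#' @return A `reader_plate` object.
#' @export
reader_plate <- function(plate_id, values, channel = "fluorescence",
                         time_point = NA_real_, dims = c(16L, 24L)) {
  stopifnot(!is.null(names(values)), all(is.finite(values)))
  structure(list(plate_id = plate_id, channel = channel,
                 time_point = time_point, values = values, dims = dims),
            class = "reader_plate")
}

#' @export
print.reader_plate <- function(x, ...) {
  cat(sprintf("Reader plate '%s' (%s): %d wells%s\n", x$plate_id, x$channel,
              length(x$values),
              if (is.na(x$time_point)) "" else sprintf(" at %g h", x$time_point)))
  invisible(x)
}

#' Pick the endpoint read from a kinetic series
#'
#' Returns the plate whose time point is nearest `target_time`, preferring
#' an exact match; a 24 h endpoint is the usual choice for fluorescent
#' CFPS readouts, a single 4 h read for luminescent ones.
#'
#' @param series List of `reader_plate` objects (or a single one).
#' @param target_time Desired endpoint in hours.
#' @return One `reader_plate`.
#' @export
extract_endpoint <- function(series, target_time) {
  if (inherits(series, "reader_plate")) return(series)
  if (!length(series)) stop("empty reader series")
  if (length(series) == 1L) return(series[[1]])
  times <- vapply(series, function(p) p$time_point, numeric(1))
  if (anyNA(times)) stop("kinetic series has plates without time points")
  series[[which.min(abs(times - target_time))]]
}

#' Cross-plate calibration factors from shared calibration wells
#'
#' CFPS signal levels drift from plate to plate (lysate aging, reader gain),
#' so every plate carries wells of the same calibration compositions. Each
#' plate is rescaled by a single multiplicative factor
#' `s_p = mean(reference plate's calibration readings) / mean(plate p's
#' readings of the same compositions)`, computed over the calibration
#' compositions the two plates share; the reference plate's factor is 1.
#'
#' @param plates List of `reader_plate` objects.
#' @param layouts List of destination `plate_layout` objects matching the
#'   plates by `plate_id`.
#' @param reference_plate `plate_id` of the reference plate (default: the
#'   first plate).
#' @param calibration_roles Roles whose wells anchor the calibration.
#' @return Named numeric vector of per-plate scale factors.
#' @export
calibrate_plates <- function(plates, layouts, reference_plate = NULL,
                             calibration_roles = c("calibration", "standard")) {
  ids <- vapply(plates, function(p) p$plate_id, character(1))
  lay_ids <- vapply(layouts, function(l) l$plate_id, character(1))
  if (!all(ids %in% lay_ids))
    stop("every reader plate needs a matching layout (by plate_id)")
  if (is.null(reference_plate)) reference_plate <- ids[1]
  if (!reference_plate %in% ids) stop("reference plate not among the plates")

  calib_signals <- function(pid) {
    lay <- layouts[[match(pid, lay_ids)]]
    pl <- plates[[match(pid, ids)]]
    sel <- lay$wells$role %in% calibration_roles
    data.frame(sample_id = lay$wells$sample_id[sel],
               signal = unname(pl$values[lay$wells$well[sel]]),
               stringsAsFactors = FALSE)
  }
  ref <- calib_signals(reference_plate)
  s <- vapply(ids, function(pid) {
    if (pid == reference_plate) return(1)
    cur <- calib_signals(pid)
    shared <- intersect(unique(ref$sample_id), unique(cur$sample_id))
    if (!length(shared))
      stop(sprintf("plate '%s' shares no calibration composition with the reference", pid))
    m_ref <- mean(ref$signal[ref$sample_id %in% shared])
    m_cur <- mean(cur$signal[cur$sample_id %in% shared])
    if (!is.finite(m_cur) || m_cur == 0)
      stop(sprintf("plate '%s' has zero/non-finite calibration mean", pid))
    m_ref / m_cur
  }, numeric(1))
  names(s) <- ids
  s
}

#' Calibrated per-sample results and fold-change yields
#'
#' Applies per-plate scale factors, aggregates replicate wells per sample,
#' and expresses every sample's calibrated mean signal as a fold change
#' versus the standard buffer (the composition with role `"standard"`,
#' which by definition has yield 1).
#'
#' @param plates List of `reader_plate` objects.
#' @param layouts Matching destination `plate_layout` objects.
#' @param scale_factors Named per-plate factors from [calibrate_plates()];
#'   computed on the fly when `NULL`.
#' @param standard_id `sample_id` of the standard buffer; defaults to the
#'   unique sample with role `"standard"` in the layouts.
#' @param standard_plate Optional `plate_id`: when given, the yield
#'   denominator uses only the standard's wells on that plate, so yields of
#'   previously measured samples do not shift as later plates are added.
#' @param blank_id Optional `sample_id` of a blank (e.g. a No-DNA control);
#'   when given, its per-plate mean is subtracted from every well of that
#'   plate before calibration.
#' @param ... Passed to [calibrate_plates()].
#' @return A `calibrated_results` data frame: one row per sample with
#'   columns `sample_id`, `role`, `n_replicates`, `mean_signal`,
#'   `calibrated_signal`, `sd_calibrated`, `yield`.
#' @export
compute_yields <- function(plates, layouts, scale_factors = NULL,
                           standard_id = NULL, blank_id = NULL,
                           standard_plate = NULL, ...) {
  ids <- vapply(plates, function(p) p$plate_id, character(1))
  lay_ids <- vapply(layouts, function(l) l$plate_id, character(1))

  if (!is.null(blank_id)) {
    plates <- lapply(plates, function(pl) {
      lay <- layouts[[match(pl$plate_id, lay_ids)]]
      bw <- lay$wells$well[lay$wells$sample_id == blank_id]
      if (length(bw)) {
        pl$values <- pmax(pl$values - mean(pl$values[bw]), 0)
      }
      pl
    })
  }
  if (is.null(scale_factors)) scale_factors <- calibrate_plates(plates, layouts, ...)

  per_well <- do.call(rbind, lapply(plates, function(pl) {
    lay <- layouts[[match(pl$plate_id, lay_ids)]]
    data.frame(plate_id = pl$plate_id,
               sample_id = lay$wells$sample_id,
               role = lay$wells$role,
               signal = unname(pl$values[lay$wells$well]),
               calibrated = unname(pl$values[lay$wells$well]) *
                 scale_factors[[pl$plate_id]],
               stringsAsFactors = FALSE)
  }))
  if (any(!is.finite(per_well$signal)))
    stop("non-finite reader signal for a laid-out well")

  agg <- do.call(rbind, lapply(split(per_well, per_well$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1], role = d$role[1],
               n_replicates = nrow(d),
               mean_signal = mean(d$signal),
               calibrated_signal = mean(d$calibrated),
               sd_calibrated = if (nrow(d) > 1) stats::sd(d$calibrated) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(standard_id)) {
    std <- agg$sample_id[agg$role == "standard"]
    if (length(std) != 1L)
      stop("need exactly one sample with role 'standard' (or an explicit standard_id)")
    standard_id <- std
  }
  if (!standard_id %in% agg$sample_id) stop("standard composition not found")
  std_mean <- if (is.null(standard_plate)) {
    agg$calibrated_signal[agg$sample_id == standard_id]
  } else {
    sel <- per_well$sample_id == standard_id & per_well$plate_id == standard_plate
    if (!any(sel)) stop("standard composition not on the given standard_plate")
    mean(per_well$calibrated[sel])
  }
  if (!is.finite(std_mean) || std_mean == 0) stop("standard buffer has zero mean signal")
  agg$yield <- agg$calibrated_signal / std_mean
  rownames(agg) <- NULL
  attr(agg, "scale_factors") <- scale_factors
  attr(agg, "standard_id") <- standard_id
  structure(agg, class = c("calibrated_results", "data.frame"))
}

#' @export
print.calibrated_results <- function(x, ...) {
  cat(sprintf("Calibrated results: %d samples, yield range %.3g-%.3g (standard '%s' = 1)\n",
              nrow(x), min(x$yield), max(x$yield), attr(x, "standard_id")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Write calibrated results to CSV
#'
#' @param results A `calibrated_results` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibrated_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
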