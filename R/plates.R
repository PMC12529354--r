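#' Well naming on a rows x cols microplate
#'
#' Wells are named letter-row + 1-based column (`A1` ... `P24` on a 384-well
#' 16 x 24 plate). Rows beyond `Z` use two letters (`AA`, `AB`, ...), as on
#' 1536-well plates.
#'
#' @param row,col 1-based row and column indices.
#' @return Character vector of well names.
#' @export
#' @examples
#' well_name(1, 1)    # "A1"
#' well_name(16, 24)  # "P24"
well_name <- function(row, col) {
  letters1 <- ifelse(row <= 26L, LETTERS[row],
                     paste0(LETTERS[(row - 1L) %/% 26L], LETTERS[(row - 1L) %% 26L + 1L]))
  paste0(letters1, col)
}

parse_well_name <- function(well) {
  m <- regmatches(well, regexec("^([A-Z]+)([0-9]+)$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop(sprintf("malformed well name(s): %s", paste(well[bad], collapse = ", ")))
  row <- vapply(m, function(g) {
    sum((utf8ToInt(g[2]) - utf8ToInt("A") + 1L) * 26L^rev(seq_len(nchar(g[2])) - 1L))
  }, numeric(1))
  col <- vapply(m, function(g) as.integer(g[3]), integer(1))
  data.frame(row = as.integer(row), col = col)
}

well_sequence <- function(dims, fill_order = c("row-major", "column-major"),
                          start_well = "A1") {
  fill_order <- match.arg(fill_order)
  rows <- dims[1]; cols <- dims[2]
  grid <- if (fill_order == "row-major") {
    expand.grid(col = seq_len(cols), row = seq_len(rows))
  } else {
    expand.grid(row = seq_len(rows), col = seq_len(cols))
  }
  wells <- well_name(grid$row, grid$col)
  start <- parse_well_name(start_well)
  if (start$row > rows || start$col > cols)
    stop(sprintf("start well %s outside a %d x %d plate", start_well, rows, cols))
  pos <- match(well_name(start$row, start$col), wells)
  wells[seq(pos, length(wells))]
}

new_plate_layout <- function(plate_id, dims, kind, wells) {
  structure(list(plate_id = plate_id, dims = dims, kind = kind, wells = wells),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("%s plate '%s' (%d x %d): %d wells used\n",
              x$kind, x$plate_id, x$dims[1], x$dims[2], nrow(x$wells)))
  invisible(x)
}

#' Water needed to top a composition up to the reaction volume
#'
#' Each destination well holds exactly the configured sample volume; water
#' makes up the difference between the component volumes and that total.
#' Water is itself dispensed acoustically, so a non-zero water volume must
#' be at least the minimum dispense and on the granularity lattice.
#'
#' @param volumes Named numeric vector of component volumes in nL.
#' @param sample_volume Total reaction volume per well in nL.
#' @param constraints A [dispenser_constraints()] object.
#' @return Water volume in nL.
#' @export
#' @examples
#' compute_water_fill(c(A = 3000, B = 2000), 6500)  # 1500
compute_water_fill <- function(volumes, sample_volume,
                               constraints = dispenser_constraints()) {
  if (sample_volume <= 0) stop("sample volume must be positive")
  total <- sum(volumes)
  water <- sample_volume - total
  if (water < -1e-9)
    stop(sprintf("infeasible sample: component volumes sum to %g nL, above the %g nL sample volume",
                 total, sample_volume))
  water <- max(water, 0)
  if (water > 0 && water < constraints$min_dispense)
    stop(sprintf("water fill %g nL lies below the %g nL minimum dispense; adjust the grids or the sample volume",
                 water, constraints$min_dispense))
  if (!is_granular(water, constraints$granularity))
    stop(sprintf("water fill %g nL is not a multiple of the %g nL granularity", water,
                 constraints$granularity))
  water
}

#' Lay samples out on destination plates
#'
#' Places every composition of a sample table on 384-well (by default)
#' destination plates, with `replicates` adjacent wells per composition and
#' a computed water fill so each well sums exactly to `sample_volume`.
#' Samples overflowing one plate spill onto additional plates in order.
#'
#' @param table A `sample_table`.
#' @param replicates Wells per composition.
#' @param sample_volume Total reaction volume per well in nL.
#' @param dims Plate dimensions `c(rows, cols)`; default 16 x 24.
#' @param fill_order `"row-major"` (default) or `"column-major"`.
#' @param start_well First well used on the first plate.
#' @param plate_prefix Prefix for generated plate ids.
#' @param constraints A [dispenser_constraints()] object.
#' @param water_name Column name used for the water component.
#' @return List of destination `plate_layout` objects; each `wells` data
#'   frame has columns `well`, `sample_id`, `role`, one column per component
#'   and a water column.
#' @export
assign_destination_wells <- function(table, replicates, sample_volume,
                                     dims = c(16L, 24L),
                                     fill_order = "row-major",
                                     start_well = "A1",
                                     plate_prefix = "Destination",
                                     constraints = dispenser_constraints(),
                                     water_name = "Water") {
  if (replicates < 1) stop("replicates must be at least 1")
  comp <- setdiff(names(table), c("sample_id", "role"))
  if (water_name %in% comp)
    stop(sprintf("component name '%s' collides with the water column", water_name))
  water <- vapply(seq_len(nrow(table)), function(i) {
    compute_water_fill(unlist(table[i, comp]), sample_volume, constraints)
  }, numeric(1))

  # replicate rows back-to-back so replicate wells are contiguous
  rep_idx <- rep(seq_len(nrow(table)), each = replicates)
  n_wells <- length(rep_idx)
  seq1 <- well_sequence(dims, fill_order, start_well)
  per_first <- length(seq1)
  per_full <- dims[1] * dims[2]
  plates <- list()
  offset <- 0L
  plate_no <- 0L
  while (offset < n_wells) {
    plate_no <- plate_no + 1L
    wells_here <- if (plate_no == 1L) seq1 else well_sequence(dims, fill_order, "A1")
    take <- min(length(wells_here), n_wells - offset)
    idx <- rep_idx[offset + seq_len(take)]
    wdf <- cbind(data.frame(well = wells_here[seq_len(take)],
                            sample_id = table$sample_id[idx],
                            role = table$role[idx],
                            stringsAsFactors = FALSE),
                 table[idx, comp, drop = FALSE])
    wdf[[water_name]] <- water[idx]
    rownames(wdf) <- NULL
    plates[[plate_no]] <- new_plate_layout(sprintf("%s_%d", plate_prefix, plate_no),
                                           dims, "destination", wdf)
    offset <- offset + take
  }
  plates
}

#' Plan the source plate for a set of destination layouts
#'
#' Sums each component's demand over all destination wells (water included)
#' and allocates source wells: each well is filled to its usable capacity
#' (`max_well_volume - dead_volume`) plus the dead volume, with the last
#' well holding the remaining demand plus dead volume. The dead volume is
#' liquid the acoustic dispenser cannot draw from a well. An `overage` adds
#' slack to every allocated well to absorb the unreachable remainder left
#' behind when a whole transfer no longer fits and the instructor moves to
#' the next well; one maximum-transfer volume (1,000 nL) of slack per well
#' guarantees replay without shortfall, mirroring the usual lab practice of
#' overfilling source wells.
#'
#' @param destinations List of destination `plate_layout` objects.
#' @param dead_volume Undispensable volume per source well in nL.
#' @param max_well_volume Physical well capacity in nL (384-well
#'   polypropylene source plates hold 65,000 nL).
#' @param overage Extra volume per allocated source well in nL (default 0).
#' @param dims,fill_order,plate_id Source plate geometry and naming.
#' @return A source `plate_layout`; its `wells` data frame has columns
#'   `well`, `component`, `fill_volume`, `dispensable` (fill minus dead
#'   volume), in consumption order.
#' @export
design_source_plate <- function(destinations, dead_volume = 20000,
                                max_well_volume = 65000, overage = 0,
                                dims = c(16L, 24L), fill_order = "row-major",
                                plate_id = "Source_1") {
  if (max_well_volume <= dead_volume)
    stop("max_well_volume must exceed dead_volume")
  usable <- max_well_volume - dead_volume
  demand <- component_demand(destinations)
  demand <- demand[demand > 0]
  wells <- well_sequence(dims, fill_order, "A1")
  rows <- list()
  w <- 0L
  if (overage >= usable) stop("overage must be below the usable well volume")
  for (comp in names(demand)) {
    remaining <- demand[[comp]]
    while (remaining > 1e-9) {
      w <- w + 1L
      if (w > length(wells))
        stop("source plate capacity exceeded; use a larger plate or well volume")
      alloc <- min(remaining + overage, usable)
      rows[[w]] <- data.frame(well = wells[w], component = comp,
                              fill_volume = alloc + dead_volume,
                              dispensable = alloc, stringsAsFactors = FALSE)
      remaining <- remaining - (alloc - overage)
    }
  }
  wdf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well = character(), component = character(),
               fill_volume = numeric(), dispensable = numeric())
  new_plate_layout(plate_id, dims, "source", wdf)
}

#' Per-component demand over destination layouts
#'
#' @param destinations List of destination `plate_layout` objects.
#' @return Named numeric vector: total nL required per component (water
#'   included).
#' @export
component_demand <- function(destinations) {
  stopifnot(length(destinations) > 0)
  comp <- setdiff(names(destinations[[1]]$wells), c("well", "sample_id", "role"))
  out <- numeric(length(comp))
  names(out) <- comp
  for (p in destinations) {
    for (cn in comp) out[[cn]] <- out[[cn]] + sum(p$wells[[cn]])
  }
  out
}

#' Write / read plate layout CSVs
#'
#' Long-format CSVs: destination layouts with columns `plate_id, well,
#' sample_id, role, component, volume_nL`; source layouts with `plate_id,
#' well, component, fill_volume_nL`.
#'
#' @param layouts List of `plate_layout` objects (or one source layout).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_destination_layout <- function(layouts, path) {
  long <- do.call(rbind, lapply(layouts, function(p) {
    comp <- setdiff(names(p$wells), c("well", "sample_id", "role"))
    do.call(rbind, lapply(comp, function(cn) {
      data.frame(plate_id = p$plate_id, well = p$wells$well,
                 sample_id = p$wells$sample_id, role = p$wells$role,
                 component = cn, volume_nL = p$wells[[cn]],
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_destination_layout
#' @export
write_source_layout <- function(layouts, path) {
  if (inherits(layouts, "plate_layout")) layouts <- list(layouts)
  long <- do.call(rbind, lapply(layouts, function(p) {
    data.frame(plate_id = p$plate_id, well = p$wells$well,
               component = p$wells$component,
               fill_volume_nL = p$wells$fill_volume, stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
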