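#' Dispenser constraints for acoustic liquid handling
#'
#' Bundles the physical limits of an acoustic dispenser: the droplet
#' granularity (all volumes must be multiples of it), the smallest volume the
#' instrument can place in a single transfer, the largest single transfer,
#' and the threshold above which a requested volume is split into several
#' transfers. Defaults correspond to an Echo 650-class instrument: 2.5 nL
#' droplets, 20-1000 nL per transfer, splitting above 1000 nL.
#'
#' @param granularity Droplet size in nL; every legal volume is a multiple.
#' @param min_dispense Smallest single transfer in nL.
#' @param max_transfer Largest single transfer in nL.
#' @param split_threshold Volume above which transfers are split, in nL.
#' @return An object of class `dispenser_constraints`.
#' @export
#' @examples
#' dispenser_constraints()
dispenser_constraints <- function(granularity = 2.5, min_dispense = 20,
                                  max_transfer = 1000, split_threshold = 1000) {
  stopifnot(granularity > 0,
            min_dispense >= granularity,
            max_transfer >= min_dispense,
            split_threshold <= max_transfer)
  structure(list(granularity = granularity,
                 min_dispense = min_dispense,
                 max_transfer = max_transfer,
                 split_threshold = split_threshold),
            class = "dispenser_constraints")
}

#' @export
print.dispenser_constraints <- function(x, ...) {
  cat(sprintf("Dispenser constraints: %.1f nL granularity, %.0f-%.0f nL per transfer, split above %.0f nL\n",
              x$granularity, x$min_dispense, x$max_transfer, x$split_threshold))
  invisible(x)
}

is_granular <- function(v, granularity) {
  abs(v / granularity - round(v / granularity)) < 1e-9
}

snap_to_granularity <- function(v, granularity) {
  # round-half-up on the granularity lattice
  floor(v / granularity + 0.5) * granularity
}

#' Component specification
#'
#' One CFPS ingredient with its maximum dispensable volume, its discrete grid
#' of allowed volumes, an optional fixed volume (the component is then held
#' constant and excluded from the search space), and the source-plate
#' calibration mode used by the dispenser for it (aqueous vs. viscous
#' liquids use different acoustic settings).
#'
#' @param name Component name.
#' @param max_volume Maximum volume in nL.
#' @param grid Ordered vector of allowed volumes in nL; built with
#'   [build_value_grid()] if omitted and no fixed value is given.
#' @param fixed_value Optional constant volume in nL.
#' @param dispense_class Source-plate type label, e.g. `"384PP_AQ_GP3"` for
#'   aqueous or `"384PP_AQ_CP"` for viscous components.
#' @param constraints A [dispenser_constraints()] object.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, max_volume, grid = NULL, fixed_value = NULL,
                           dispense_class = "384PP_AQ_GP3",
                           constraints = dispenser_constraints()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("component name must be a non-empty string")
  if (!is.numeric(max_volume) || length(max_volume) != 1L ||
      !is.finite(max_volume) || max_volume <= 0)
    stop(sprintf("component '%s': maximum volume must be a positive number", name))
  if (!is_granular(max_volume, constraints$granularity))
    stop(sprintf("component '%s': maximum volume %g nL is not a multiple of the %g nL granularity",
                 name, max_volume, constraints$granularity))
  if (!is.null(fixed_value)) {
    if (!is_granular(fixed_value, constraints$granularity))
      stop(sprintf("component '%s': fixed value %g nL is not a multiple of the %g nL granularity",
                   name, fixed_value, constraints$granularity))
    if (fixed_value != 0 && fixed_value < constraints$min_dispense)
      stop(sprintf("component '%s': fixed value %g nL is below the %g nL minimum dispense",
                   name, fixed_value, constraints$min_dispense))
    grid <- fixed_value
  }
  if (!is.null(grid)) {
    check_grid(grid, name, max_volume, constraints)
  }
  structure(list(name = name, max_volume = max_volume, grid = grid,
                 fixed_value = fixed_value, dispense_class = dispense_class),
            class = "component_spec")
}

check_grid <- function(grid, name, max_volume, constraints) {
  if (any(!is.finite(grid)) || any(grid < 0))
    stop(sprintf("component '%s': grid values must be finite and non-negative", name))
  if (is.unsorted(grid, strictly = TRUE) && length(grid) > 1L)
    stop(sprintf("component '%s': grid must be strictly increasing", name))
  if (any(grid > max_volume + 1e-9))
    stop(sprintf("component '%s': grid values exceed the maximum volume %g nL", name, max_volume))
  bad <- grid[grid != 0 & grid < constraints$min_dispense]
  if (length(bad))
    stop(sprintf("component '%s': grid levels below the %g nL minimum dispense: %s",
                 name, constraints$min_dispense, paste(bad, collapse = ", ")))
  if (any(!is_granular(grid, constraints$granularity)))
    stop(sprintf("component '%s': grid values not on the %g nL granularity",
                 name, constraints$granularity))
  invisible(grid)
}

#' @export
print.component_spec <- function(x, ...) {
  cat(sprintf("Component '%s': max %g nL", x$name, x$max_volume))
  if (!is.null(x$fixed_value)) cat(sprintf(", fixed at %g nL", x$fixed_value))
  if (!is.null(x$grid)) cat(sprintf(", %d grid levels", length(x$grid)))
  cat(sprintf(" [%s]\n", x$dispense_class))
  invisible(x)
}

#' Read a component table
#'
#' Parses the tab-separated component table driving a run: one row per CFPS
#' ingredient with its maximum volume. A header row is detected and skipped
#' when the volume column is non-numeric on the first line.
#'
#' @param path Path to a TSV file with two columns: component name and
#'   maximum volume (nL).
#' @param constraints A [dispenser_constraints()] object.
#' @param dispense_classes Optional named character vector mapping component
#'   names to source-plate types; unnamed components default to aqueous.
#' @return A list of [component_spec()] objects, in file order.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("Component\tmaxValue", "HEPES\t1000", "Mg-glutamate\t400"), tsv)
#' specs <- parse_components_table(tsv)
#' sapply(specs, function(s) s$max_volume)
parse_components_table <- function(path, constraints = dispenser_constraints(),
                                   dispense_classes = NULL) {
  if (!file.exists(path)) stop(sprintf("component table not found: %s", path))
  if (!length(readLines(path, warn = FALSE))) stop("component table is empty")
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("component table is empty")
  if (ncol(raw) < 2L) stop("component table must have two columns: name, maximum volume")
  # drop a header row if the second field is not numeric
  if (is.na(suppressWarnings(as.numeric(raw[1L, 2L])))) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) stop("component table has a header but no data rows")
  names_col <- raw[[1L]]
  vols <- suppressWarnings(as.numeric(raw[[2L]]))
  if (anyNA(vols))
    stop(sprintf("non-numeric maximum volume for component(s): %s",
                 paste(names_col[is.na(vols)], collapse = ", ")))
  if (any(vols <= 0))
    stop(sprintf("non-positive maximum volume for component(s): %s",
                 paste(names_col[vols <= 0], collapse = ", ")))
  if (anyDuplicated(names_col))
    stop(sprintf("duplicate component name(s): %s",
                 paste(unique(names_col[duplicated(names_col)]), collapse = ", ")))
  lapply(seq_along(names_col), function(i) {
    cls <- if (!is.null(dispense_classes) && names_col[i] %in% names(dispense_classes))
      unname(dispense_classes[[names_col[i]]]) else "384PP_AQ_GP3"
    component_spec(names_col[i], vols[i], dispense_class = cls,
                   constraints = constraints)
  })
}

#' Build a discrete volume grid for one component
#'
#' Converts a component's maximum volume into the ordered set of volumes the
#' dispenser may place, either from a list of ratios of the maximum (ratio
#' mode, e.g. `c(0, 0.2, 0.4, 0.6, 0.8, 1)` gives six concentration levels)
#' or from a fixed volume increment (step mode, giving
#' `step, 2*step, ..., max_volume`; zero is not included). Ratio values are
#' snapped to the nearest granularity multiple. Any non-zero level below the
#' minimum dispensable volume signals an infeasible design and is an error.
#'
#' @param max_volume Maximum volume in nL.
#' @param ratios Ascending ratios in \[0, 1\] (ratio mode). Exactly one of
#'   `ratios` and `step` must be given.
#' @param step Volume increment in nL (step mode).
#' @param constraints A [dispenser_constraints()] object.
#' @return Ascending numeric vector of allowed volumes in nL.
#' @export
#' @examples
#' build_value_grid(100, ratios = c(0, 0.2, 0.4, 0.6, 0.8, 1))
#' length(build_value_grid(940, step = 20))  # 47 levels
build_value_grid <- function(max_volume, ratios = NULL, step = NULL,
                             constraints = dispenser_constraints()) {
  if (is.null(ratios) == is.null(step))
    stop("exactly one of 'ratios' or 'step' must be supplied")
  if (!is.null(ratios)) {
    if (any(ratios < 0) || any(ratios > 1)) stop("ratios must lie in [0, 1]")
    if (is.unsorted(ratios)) stop("ratios must be ascending")
    grid <- snap_to_granularity(ratios * max_volume, constraints$granularity)
  } else {
    if (step <= 0) stop("step must be positive")
    grid <- seq(step, max_volume, by = step)
  }
  grid <- sort(unique(grid))
  bad <- grid[grid != 0 & grid < constraints$min_dispense]
  if (length(bad))
    stop(sprintf("grid levels below the %g nL minimum dispense: %s (raise the ratios/step or the maximum volume)",
                 constraints$min_dispense, paste(bad, collapse = ", ")))
  check_grid(grid, "<grid>", max_volume, constraints)
  grid
}

#' Attach volume grids to a list of component specs
#'
#' Applies [build_value_grid()] to every non-fixed component and records
#' fixed values where supplied, mirroring the run configuration: one ratio
#' list or step size shared by all components plus a named list of fixed
#' volumes.
#'
#' @param specs List of [component_spec()] objects.
#' @param ratios,step Grid mode, as in [build_value_grid()].
#' @param fixed_values Named list/vector of fixed volumes in nL; names must
#'   match component names.
#' @param constraints A [dispenser_constraints()] object.
#' @return The list of specs with `grid` (and `fixed_value`) filled in.
#' @export
with_value_grids <- function(specs, ratios = NULL, step = NULL,
                             fixed_values = NULL,
                             constraints = dispenser_constraints()) {
  nm <- vapply(specs, function(s) s$name, character(1))
  if (!is.null(fixed_values)) {
    unknown <- setdiff(names(fixed_values), nm)
    if (length(unknown))
      stop(sprintf("fixed value(s) for unknown component(s): %s",
                   paste(unknown, collapse = ", ")))
  }
  lapply(specs, function(s) {
    if (!is.null(fixed_values) && s$name %in% names(fixed_values)) {
      component_spec(s$name, s$max_volume,
                     fixed_value = as.numeric(fixed_values[[s$name]]),
                     dispense_class = s$dispense_class, constraints = constraints)
    } else {
      grid <- build_value_grid(s$max_volume, ratios = ratios, step = step,
                               constraints = constraints)
      component_spec(s$name, s$max_volume, grid = grid,
                     dispense_class = s$dispense_class, constraints = constraints)
    }
  })
}

#' Size of the enumerable design space
#'
#' Product of grid sizes over variable (non-fixed) components: the number of
#' distinct buffer compositions the discrete design space contains.
#'
#' @param specs List of [component_spec()] objects with grids attached.
#' @return A single number (may be very large; returned as double).
#' @export
#' @examples
#' specs <- lapply(paste0("c", 1:9), component_spec, max_volume = 100)
#' specs <- with_value_grids(specs, ratios = seq(0, 1, 0.2))
#' design_space_size(specs)  # 6^9 = 10077696
design_space_size <- function(specs) {
  sizes <- vapply(specs, function(s) {
    if (!is.null(s$fixed_value)) 1 else length(s$grid)
  }, numeric(1))
  prod(sizes)
}

variable_components <- function(specs) {
  Filter(function(s) is.null(s$fixed_value), specs)
}

component_names <- function(specs) {
  vapply(specs, function(s) s$name, character(1))
}
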