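#' Discrete Latin-hypercube sample of buffer compositions
#'
#' Draws the initial (loop 0) experimental design: `n` buffer compositions
#' stratified over each component's discrete volume grid. For a component
#' with `L` levels, the unit interval is cut into `n` equal strata, each
#' stratum is mapped to the grid level containing its midpoint, and an
#' independent seeded permutation shuffles the strata per component. This
#' guarantees the Latin-hypercube marginal property on the discrete grid:
#' every level occurs either `floor(n/L)` or `ceiling(n/L)` times. Fixed
#' components are held at their fixed value. If the discretization produces
#' duplicate compositions the design is re-drawn from a derived seed a
#' bounded number of times, then accepted with a warning.
#'
#' @param specs List of [component_spec()] objects with grids attached
#'   (see [with_value_grids()]).
#' @param n Number of compositions to draw.
#' @param seed Integer seed; identical inputs give identical tables.
#' @param max_redraws Redraw attempts used to avoid duplicate compositions.
#' @return A `sample_table`: data frame with columns `sample_id`, `role`
#'   (all `"experiment"`) and one volume column (nL) per component.
#' @export
#' @examples
#' specs <- with_value_grids(list(component_spec("A", 100),
#'                                component_spec("B", 200)),
#'                           ratios = seq(0, 1, 0.2))
#' lhs_sample(specs, n = 6, seed = 42)
lhs_sample <- function(specs, n, seed = 42L, max_redraws = 10L) {
  if (n < 1) stop("n must be at least 1")
  nm <- component_names(specs)
  for (s in specs) {
    if (is.null(s$grid)) stop(sprintf("component '%s' has no value grid", s$name))
  }
  draw_once <- function(seed_i) {
    cols <- lapply(specs, function(s) {
      if (!is.null(s$fixed_value)) return(rep(s$fixed_value, n))
      L <- length(s$grid)
      # stratum midpoints mapped onto levels: counts per level differ by <= 1
      idx <- pmin(floor(((seq_len(n) - 1) + 0.5) * L / n) + 1L, L)
      s$grid[idx]
    })
    names(cols) <- nm
    set.seed(seed_i)
    var_idx <- which(vapply(specs, function(s) is.null(s$fixed_value), logical(1)))
    for (j in var_idx) cols[[j]] <- cols[[j]][sample.int(n)]
    as.data.frame(cols, check.names = FALSE)
  }
  vol <- draw_once(seed)
  attempt <- 0L
  while (anyDuplicated(vol) && attempt < max_redraws) {
    attempt <- attempt + 1L
    vol <- draw_once((seed + 7919L * attempt) %% .Machine$integer.max)
  }
  if (anyDuplicated(vol))
    warning(sprintf("%d duplicate composition(s) remain after %d redraws",
                    sum(duplicated(vol)), max_redraws))
  tab <- cbind(data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                          role = "experiment",
                          stringsAsFactors = FALSE),
               vol)
  structure(tab, class = c("sample_table", "data.frame"),
            seed = seed, provenance = "lhs_sample loop 0")
}

#' Append control, calibration and standard compositions
#'
#' Adds caller-supplied reference compositions to a sample table: controls
#' (known-good or known-bad buffers), calibration buffers (repeated on every
#' plate so plates can be scaled to a common signal level) and at most one
#' standard buffer (the literature reference composition, defining yield 1).
#'
#' @param table A `sample_table` from [lhs_sample()].
#' @param extra A data frame with columns `sample_id`, `role` and one volume
#'   column per component used; component names must match the table.
#' @return The extended `sample_table`; original rows are untouched.
#' @export
append_controls <- function(table, extra) {
  if (is.null(extra) || nrow(extra) == 0L) return(table)
  comp_cols <- setdiff(names(table), c("sample_id", "role"))
  extra_comp <- setdiff(names(extra), c("sample_id", "role"))
  unknown <- setdiff(extra_comp, comp_cols)
  if (length(unknown))
    stop(sprintf("extra composition(s) use unknown component(s): %s",
                 paste(unknown, collapse = ", ")))
  missing_cols <- setdiff(comp_cols, extra_comp)
  for (m in missing_cols) extra[[m]] <- 0
  if (!"role" %in% names(extra)) stop("extra compositions need a 'role' column")
  if (!"sample_id" %in% names(extra)) stop("extra compositions need a 'sample_id' column")
  bad_roles <- setdiff(unique(extra$role),
                       c("experiment", "control", "calibration", "standard"))
  if (length(bad_roles))
    stop(sprintf("unknown role(s): %s", paste(bad_roles, collapse = ", ")))
  out <- rbind(table[, c("sample_id", "role", comp_cols)],
               extra[, c("sample_id", "role", comp_cols)])
  if (sum(out$role == "standard") > 1L)
    stop("at most one composition may carry role 'standard'")
  if (anyDuplicated(out$sample_id))
    stop("sample_ids must be unique after appending")
  rownames(out) <- NULL
  structure(out, class = c("sample_table", "data.frame"),
            seed = attr(table, "seed"), provenance = attr(table, "provenance"))
}

#' Write / read a sample table CSV
#'
#' The on-disk form is a plain CSV with `sample_id` and `role` columns
#' followed by one volume column per component (nL).
#'
#' @param table A `sample_table`.
#' @param path Output file path.
#' @return `path`, invisibly (writer); a `sample_table` (reader).
#' @export
write_sample_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(tab)))
    stop("sample table CSV must have 'sample_id' and 'role' columns")
  structure(tab, class = c("sample_table", "data.frame"))
}

#' @export
print.sample_table <- function(x, ...) {
  comp <- setdiff(names(x), c("sample_id", "role"))
  cat(sprintf("Sample table: %d compositions x %d components (%s)\n",
              nrow(x), length(comp),
              paste(sprintf("%s %d", names(table(x$role)), table(x$role)),
                    collapse = ", ")))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

sample_volumes <- function(table) {
  comp <- setdiff(names(table), c("sample_id", "role"))
  as.matrix(table[, comp, drop = FALSE])
}
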