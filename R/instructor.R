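#' Split a requested volume into dispenser-legal transfers
#'
#' Volumes above the split threshold are delivered as several transfers:
#' greedy full-size chunks followed by the remainder. If the remainder would
#' fall below the minimum dispense, the last two chunks are rebalanced into
#' a near-equal granularity-aligned pair so every transfer stays legal.
#'
#' @param v Requested volume in nL; must be at least the minimum dispense
#'   and on the granularity lattice.
#' @param constraints A [dispenser_constraints()] object.
#' @return Numeric vector of transfer volumes summing to `v`, each within
#'   `[min_dispense, max_transfer]` and granularity-aligned.
#' @export
#' @examples
#' split_volume(2500)  # 1000 1000 500
#' split_volume(1010)  # 505 505
split_volume <- function(v, constraints = dispenser_constraints()) {
  g <- constraints$granularity
  if (v < constraints$min_dispense)
    stop(sprintf("volume %g nL is below the %g nL minimum dispense", v,
                 constraints$min_dispense))
  if (!is_granular(v, g))
    stop(sprintf("volume %g nL is not a multiple of the %g nL granularity", v, g))
  cap <- constraints$split_threshold
  if (v <= cap) return(v)
  n_full <- floor(v / cap)
  r <- v - n_full * cap
  if (r == 0) return(rep(cap, n_full))
  if (r >= constraints$min_dispense) return(c(rep(cap, n_full), r))
  # remainder too small to dispense: rebalance the final chunk with it
  t <- cap + r
  a <- snap_to_granularity(t / 2, g)
  c(rep(cap, n_full - 1L), a, t - a)
}

#' Generate dispenser transfer instructions
#'
#' Walks every destination well and emits one instruction per legal transfer
#' of each non-zero component volume (water included), drawing from the
#' source plate's wells in their planned order. A transfer is never split
#' across source wells; when the current well's dispensable volume cannot
#' cover the next transfer the instructor moves to the component's next
#' source well. Instructions are ordered by destination plate, destination
#' well, then component column order, and grouped by source-plate type so
#' viscous components can be dispensed with their own acoustic calibration.
#'
#' @param source A source `plate_layout` from [design_source_plate()].
#' @param destinations List of destination `plate_layout` objects.
#' @param specs List of [component_spec()] objects (used for source-plate
#'   types); components absent from `specs` (e.g. water) default to aqueous.
#' @param constraints A [dispenser_constraints()] object.
#' @return Data frame of class `instruction_set` with columns
#'   `source_plate`, `source_plate_type`, `source_well`,
#'   `destination_plate`, `destination_well`, `component`, `volume_nL`.
#' @export
generate_instructions <- function(source, destinations, specs,
                                  constraints = dispenser_constraints()) {
  class_of <- function(comp) {
    for (s in specs) if (s$name == comp) return(s$dispense_class)
    "384PP_AQ_GP3"
  }
  src <- source$wells
  state <- split(seq_len(nrow(src)), src$component)   # row indices per component
  remaining <- src$dispensable
  pointer <- rep(1L, length(state))
  names(pointer) <- names(state)

  acc_swell <- character(); acc_dplate <- character(); acc_dwell <- character()
  acc_comp <- character(); acc_vol <- numeric()

  for (p in destinations) {
    comp <- setdiff(names(p$wells), c("well", "sample_id", "role"))
    for (i in seq_len(nrow(p$wells))) {
      for (cn in comp) {
        v <- p$wells[[cn]][i]
        if (v <= 0) next
        rows_c <- state[[cn]]
        if (is.null(rows_c))
          stop(sprintf("no source well holds component '%s'", cn))
        for (chunk in split_volume(v, constraints)) {
          repeat {
            ptr <- pointer[[cn]]
            if (ptr > length(rows_c))
              stop(sprintf("source plate shortfall for component '%s'", cn))
            ridx <- rows_c[ptr]
            if (remaining[ridx] >= chunk - 1e-9) {
              remaining[ridx] <- remaining[ridx] - chunk
              acc_swell <- c(acc_swell, src$well[ridx])
              acc_dplate <- c(acc_dplate, p$plate_id)
              acc_dwell <- c(acc_dwell, p$wells$well[i])
              acc_comp <- c(acc_comp, cn)
              acc_vol <- c(acc_vol, chunk)
              break
            }
            pointer[[cn]] <- ptr + 1L   # well effectively exhausted; move on
          }
        }
      }
    }
  }
  instr <- data.frame(source_plate = rep(source$plate_id, length(acc_vol)),
                      source_plate_type = vapply(acc_comp, class_of, character(1)),
                      source_well = acc_swell,
                      destination_plate = acc_dplate,
                      destination_well = acc_dwell,
                      component = acc_comp, volume_nL = acc_vol,
                      stringsAsFactors = FALSE)
  rownames(instr) <- NULL
  structure(instr, class = c("instruction_set", "data.frame"))
}

#' @export
print.instruction_set <- function(x, ...) {
  cat(sprintf("Instruction set: %d transfers, %.0f nL total, %d source-plate type(s)\n",
              nrow(x), sum(x$volume_nL), length(unique(x$source_plate_type))))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Write instruction CSVs, one file per source-plate type
#'
#' Emits the Cherry Pick picker dialect: header `Source Plate Name, Source
#' Plate Type, Source Well, Destination Plate Name, Destination Well,
#' Transfer Volume`, volumes in nL. Files are named
#' `<basename>_<type>.csv`.
#'
#' @param instructions An `instruction_set` from [generate_instructions()].
#' @param dir Output directory.
#' @param basename File name stem.
#' @return Character vector of file paths written, invisibly.
#' @export
write_instructions <- function(instructions, dir, basename = "instructions") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (tp in unique(instructions$source_plate_type)) {
    sub <- instructions[instructions$source_plate_type == tp, , drop = FALSE]
    df <- data.frame(`Source Plate Name` = sub$source_plate,
                     `Source Plate Type` = sub$source_plate_type,
                     `Source Well` = sub$source_well,
                     `Destination Plate Name` = sub$destination_plate,
                     `Destination Well` = sub$destination_well,
                     `Transfer Volume` = sub$volume_nL,
                     check.names = FALSE)
    path <- file.path(dir, sprintf("%s_%s.csv", basename, tp))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
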