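#' Normalize compositions to the unit hypercube
#'
#' Each variable component's volume is divided by its maximum volume, so
#' the surrogate sees comparable ratio features regardless of the very
#' different absolute volumes CFPS ingredients use. Fixed components carry
#' no information and are dropped from the feature space.
#'
#' @param volumes Matrix or data frame of volumes (nL), one column per
#'   component (named), or a named vector for a single composition.
#' @param specs List of [component_spec()] objects.
#' @return Numeric matrix in `[0,1]^d`, columns = variable components.
#' @export
#' @examples
#' specs <- list(component_spec("A", 100), component_spec("B", 200))
#' normalize_features(c(A = 80, B = 50), specs)
normalize_features <- function(volumes, specs) {
  if (is.null(dim(volumes))) volumes <- t(as.matrix(volumes))
  volumes <- as.matrix(volumes)
  vs <- variable_components(specs)
  nm <- component_names(vs)
  missing <- setdiff(nm, colnames(volumes))
  if (length(missing))
    stop(sprintf("missing component column(s): %s", paste(missing, collapse = ", ")))
  out <- sapply(vs, function(s) {
    v <- volumes[, s$name]
    if (any(v > s$max_volume + 1e-9))
      stop(sprintf("volume above maximum for component '%s'", s$name))
    if (any(v < 0)) stop(sprintf("negative volume for component '%s'", s$name))
    v / s$max_volume
  })
  out <- matrix(out, nrow = nrow(volumes), dimnames = list(NULL, nm))
  out
}

#' Expected Improvement acquisition
#'
#' Scores candidate compositions by the expected gain over the incumbent
#' best response under the surrogate's Gaussian predictive distribution:
#' `EI = (m - y_best - xi) * pnorm(z) + s * dnorm(z)` with
#' `z = (m - y_best - xi)/s`, and the deterministic limit
#' `max(m - y_best - xi, 0)` when `s = 0`. The offset `xi` trades a little
#' exploitation for exploration.
#'
#' @param mean,sd Predictive mean and standard deviation per candidate.
#' @param y_best Incumbent best observed response.
#' @param xi Exploration offset (same units as the response).
#' @return Non-negative EI per candidate.
#' @export
#' @examples
#' expected_improvement(1, 1, y_best = 1)  # = dnorm(0) = 0.3989
expected_improvement <- function(mean, sd, y_best, xi = 0.01) {
  if (any(sd < 0)) stop("sd must be non-negative")
  imp <- mean - y_best - xi
  ei <- ifelse(sd > 0,
               {
                 z <- imp / sd
                 imp * stats::pnorm(z) + sd * stats::dnorm(z)
               },
               pmax(imp, 0))
  pmax(ei, 0)
}

composition_key <- function(volumes) {
  apply(as.matrix(volumes), 1L, function(r) paste(format(r, trim = TRUE), collapse = "|"))
}

#' Random candidate pool over the discrete design space
#'
#' Draws unique grid-valid compositions uniformly from the component grids,
#' excluding compositions already tested. When the remaining design space
#' is smaller than the requested pool, the whole remainder is returned
#' (enumerated exhaustively).
#'
#' @param specs List of [component_spec()] objects with grids attached.
#' @param size Pool size to aim for (1000 or more in routine use).
#' @param exclude Matrix/data frame of already-tested compositions (columns
#'   named per component), or `NULL`.
#' @param seed Integer seed.
#' @param max_tries Oversampling rounds before falling back to exhaustive
#'   enumeration.
#' @return Data frame of compositions, one column per component (nL).
#' @export
generate_candidate_pool <- function(specs, size = 1000L, exclude = NULL,
                                    seed = 1L, max_tries = 20L) {
  if (size < 1) stop("pool size must be at least 1")
  nm <- component_names(specs)
  grids <- lapply(specs, function(s) if (!is.null(s$fixed_value)) s$fixed_value else s$grid)
  names(grids) <- nm
  space <- prod(vapply(grids, length, numeric(1)))
  excl_keys <- if (!is.null(exclude) && nrow(as.matrix(exclude)))
    composition_key(as.data.frame(exclude)[, nm, drop = FALSE]) else character()

  remainder <- space - length(unique(excl_keys))
  if (remainder <= 0) stop("design space exhausted: nothing left to propose")

  set.seed(seed)
  if (space <= max(4L * size, 4096L)) {
    # small space: enumerate, drop tested, subsample if needed
    full <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    names(full) <- nm
    keep <- !(composition_key(full) %in% excl_keys)
    pool <- full[keep, , drop = FALSE]
    if (nrow(pool) > size) pool <- pool[sample.int(nrow(pool), size), , drop = FALSE]
    rownames(pool) <- NULL
    return(pool)
  }
  seen <- character()
  acc <- list()
  n_acc <- 0L
  for (try in seq_len(max_tries)) {
    draw <- as.data.frame(lapply(grids, function(g) g[sample.int(length(g), size, replace = TRUE)]),
                          check.names = FALSE)
    keys <- composition_key(draw)
    ok <- !(keys %in% excl_keys) & !(keys %in% seen) & !duplicated(keys)
    if (any(ok)) {
      acc[[length(acc) + 1L]] <- draw[ok, , drop = FALSE]
      seen <- c(seen, keys[ok])
      n_acc <- n_acc + sum(ok)
    }
    if (n_acc >= size) break
  }
  pool <- do.call(rbind, acc)
  pool <- pool[seq_len(min(size, nrow(pool))), , drop = FALSE]
  rownames(pool) <- NULL
  pool
}

#' Vanilla top-n batch selection
#'
#' The plain acquisition-driven rule: the `n` candidates with the highest
#' EI, ties broken by pool position (stable).
#'
#' @param pool Data frame of candidate compositions.
#' @param ei EI value per pool row.
#' @param n Batch size.
#' @return Integer vector of selected pool row indices, in EI order.
#' @export
select_val <- function(pool, ei, n) {
  if (n > nrow(pool)) stop("batch size exceeds the candidate pool")
  order(-ei, seq_along(ei))[seq_len(n)]
}

#' Average-linkage hierarchical clustering labels
#'
#' Cuts an average-linkage agglomerative tree into `k` clusters. Average
#' linkage measures cluster distance as the mean pairwise point distance,
#' avoiding the chaining behavior of single linkage.
#'
#' @param X Numeric matrix of points (rows).
#' @param k Number of clusters.
#' @return Integer cluster labels, one per row of `X`.
#' @export
hac_average_linkage <- function(X, k) {
  X <- as.matrix(X)
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(X)) stop("k exceeds the number of points")
  if (nrow(X) == 1L) return(1L)
  hc <- stats::hclust(stats::dist(X), method = "average")
  unname(stats::cutree(hc, k = k))
}

#' Cluster-Margin batch selection
#'
#' Balances informativeness and diversity: (a) keep the `m_top` highest-EI
#' candidates; (b) cluster the whole pool into `k` groups by average-linkage
#' HAC on the normalized features; (c) bucket the kept candidates by
#' cluster; (d) order non-empty buckets by ascending size; (e) round-robin
#' over the buckets, taking each bucket's highest-EI unselected candidate,
#' smallest bucket first, cycling until `n_batch` candidates are chosen.
#'
#' @param pool Data frame of candidate compositions.
#' @param ei EI per pool row.
#' @param X Normalized features of the pool (rows match `pool`).
#' @param m_top Pre-selection size (30 or 50 in routine use).
#' @param n_batch Batch size (15 or 20; must not exceed `m_top`).
#' @param k Number of HAC clusters; default `2 * n_batch`.
#' @param bucket_sizes How bucket sizes are counted for the ordering in
#'   step (d): over the `m_top` kept candidates (`"m_top"`, default) or
#'   over the whole pool (`"pool"`).
#' @return Integer vector of selected pool row indices, in pick order.
#' @export
select_cluster_margin <- function(pool, ei, X, m_top, n_batch,
                                  k = 2L * n_batch,
                                  bucket_sizes = c("m_top", "pool")) {
  bucket_sizes <- match.arg(bucket_sizes)
  if (n_batch > m_top) stop("n_batch must not exceed m_top")
  if (m_top > nrow(pool)) stop("m_top exceeds the candidate pool")
  k <- min(k, nrow(pool))
  labels <- hac_average_linkage(X, k)
  top <- select_val(pool, ei, m_top)
  buckets <- split(top, labels[top])       # members stay EI-sorted
  sizes <- if (bucket_sizes == "m_top") {
    vapply(buckets, length, integer(1))
  } else {
    tab <- table(labels)
    as.integer(tab[names(buckets)])
  }
  buckets <- buckets[order(sizes, as.integer(names(buckets)))]
  selected <- integer()
  while (length(selected) < n_batch) {
    took <- FALSE
    for (b in seq_along(buckets)) {
      avail <- setdiff(buckets[[b]], selected)
      if (length(avail)) {
        selected <- c(selected, avail[1L])
        took <- TRUE
        if (length(selected) == n_batch) break
      }
    }
    if (!took) break   # all buckets exhausted (n_batch > m_top cannot happen)
  }
  selected
}

#' Plateau-based convergence check
#'
#' The loop stops when the best-so-far response has plateaued: the relative
#' improvement over the last `patience` loops falls below `tol`.
#'
#' @param best_history Numeric vector of best-so-far responses, one per
#'   completed loop (non-decreasing).
#' @param tol Relative-improvement threshold.
#' @param patience Number of trailing loops the improvement is measured
#'   over.
#' @return `TRUE` if converged; `FALSE` with fewer than `patience + 1`
#'   loops of history.
#' @export
#' @examples
#' check_convergence(c(1, 5, 9, 9.05), tol = 0.01, patience = 1)  # TRUE
check_convergence <- function(best_history, tol = 0.01, patience = 1L) {
  n <- length(best_history)
  if (n < patience + 1L) return(FALSE)
  prev <- best_history[n - patience]
  if (prev <= 0) return(FALSE)
  (best_history[n] - prev) / prev < tol
}

#' Propose the next experimental batch
#'
#' One Learn step: fit the GP surrogate on everything measured so far,
#' score a fresh random candidate pool (tested compositions excluded) with
#' Expected Improvement, and select the next batch by vanilla top-n
#' (`"VAL"`), Cluster-Margin (`"CM"`) or uniform random (`"random"`,
#' baseline).
#'
#' @param tested Data frame of tested compositions (one column per
#'   component, nL).
#' @param yields Measured response per tested row.
#' @param specs List of [component_spec()] objects with grids.
#' @param method `"VAL"`, `"CM"` or `"random"`.
#' @param n_batch Number of compositions to propose.
#' @param m_top CM pre-selection size (ignored for VAL/random).
#' @param k CM cluster count; default `2 * n_batch`.
#' @param pool_size Candidate pool size.
#' @param xi EI exploration offset.
#' @param seed Integer seed (pool draw + GP restarts).
#' @return A list with `batch` (data frame of compositions), `ei` (scores
#'   of the selected candidates; `NA` for random), `pool_size` (actual) and
#'   `model` (the `cfps_gp` fit, or `NULL` for random).
#' @export
propose_batch <- function(tested, yields, specs,
                          method = c("VAL", "CM", "random"),
                          n_batch = 15L, m_top = 30L, k = 2L * n_batch,
                          pool_size = 1000L, xi = 0.01, seed = 1L) {
  method <- match.arg(method)
  nm <- component_names(specs)
  tested <- as.data.frame(tested)[, nm, drop = FALSE]
  pool <- generate_candidate_pool(specs, size = pool_size, exclude = tested,
                                  seed = seed)
  if (nrow(pool) < n_batch)
    stop("remaining design space smaller than the requested batch")
  if (method == "random") {
    set.seed(seed + 1L)
    idx <- sample.int(nrow(pool), n_batch)
    return(list(batch = pool[idx, , drop = FALSE], ei = rep(NA_real_, n_batch),
                pool_size = nrow(pool), model = NULL))
  }
  Xtr <- normalize_features(tested, specs)
  model <- fit_surrogate(Xtr, yields, seed = seed)
  Xp <- normalize_features(pool, specs)
  pr <- predict(model, Xp)
  ei <- expected_improvement(pr$mean, pr$sd, y_best = max(yields), xi = xi)
  idx <- if (method == "VAL") {
    select_val(pool, ei, n_batch)
  } else {
    select_cluster_margin(pool, ei, Xp, m_top = min(m_top, nrow(pool)),
                          n_batch = n_batch, k = k)
  }
  batch <- pool[idx, , drop = FALSE]
  rownames(batch) <- NULL
  list(batch = batch, ei = ei[idx], pool_size = nrow(pool), model = model)
}
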