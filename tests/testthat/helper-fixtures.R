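# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# nine-variable prokaryotic-style component table (volumes in nL)
pro_components_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "Component\tmaxValue",
    "Mg-glutamate\t400",
    "K-glutamate\t600",
    "Amino acids\t1200",
    "3-PGA\t900",
    "NTPs\t500",
    "Spermidine\t300",
    "PEG-8000\t800",
    "DNA1\t500",
    "DNA2\t500",
    "HEPES\t1000"), path)
  path
}

pro_specs <- function(fixed_hepes = TRUE) {
  specs <- parse_components_table(pro_components_tsv())
  with_value_grids(specs, ratios = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                   fixed_values = if (fixed_hepes) list(HEPES = 100) else NULL)
}

# eukaryotic-style 4-component table: maxima 940/200/380/480 nL, 20 nL steps
eu_components_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "Component\tmaxValue",
    "HeLa lysate\t940",
    "Accessory proteins\t200",
    "Reaction mix\t380",
    "DNA\t480"), path)
  path
}

eu_specs <- function() {
  with_value_grids(parse_components_table(eu_components_tsv()), step = 20)
}

# tiny two-component space for exhaustive checks
tiny_specs <- function() {
  with_value_grids(list(component_spec("A", 100), component_spec("B", 100)),
                   ratios = c(0, 0.5, 1))
}

# default benchmark landscape over the eukaryotic grids: standard buffer at
# yield 1, optimum amplitude 10
eu_landscape <- function(noise_sd = 0.1, gain_sd = 0.2, seed = 1L) {
  landscape_config(eu_specs(), optimum = 0.75, width = 0.2, amplitude = 10,
                   standard = 0.54, noise_sd = noise_sd, gain_sd = gain_sd,
                   seed = seed)
}

# bare destination layout wrapper for arithmetic-only tests
new_plate_layout_for_test <- function(wells, plate_id = "D1", dims = c(16L, 24L)) {
  structure(list(plate_id = plate_id, dims = dims, kind = "destination",
                 wells = wells),
            class = "plate_layout")
}

# brute-force average-linkage agglomeration, used as the clustering oracle
brute_force_hac_average <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  D <- as.matrix(dist(X))
  avg_dist <- function(a, b) mean(D[a, b, drop = FALSE])
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- avg_dist(clusters[[i]], clusters[[j]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  labels
}

# partition-agnostic comparison of two label vectors
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a))[order(vapply(split(seq_along(a), a), min, 1L))],
            unname(split(seq_along(b), b))[order(vapply(split(seq_along(b), b), min, 1L))])
}
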