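#' Construct a Calpha trace
#'
#' A Calpha trace is the minimal structural input for the distance
#' statistics: an ordered tibble of one-letter residue codes with 3D
#' coordinates in Angstroms, one row per residue.
#'
#' @param aa Character vector of one-letter amino-acid codes (the 20
#'   standard residues).
#' @param x,y,z Numeric coordinate vectors in Angstroms.
#' @param id Identifier carried in the `"id"` attribute.
#' @return A tibble of class `ca_trace` with columns `aa`, `x`, `y`, `z`.
#' @examples
#' ca_trace(c("A", "G"), x = c(0, 3.8), y = c(0, 0), z = c(0, 0))
#' @export
ca_trace <- function(aa, x, y, z, id = "trace") {
  aa <- as.character(aa)
  n <- length(aa)
  if (n < 2) {
    abort("a Calpha trace needs at least 2 residues", class = "admap_error_trace")
  }
  if (length(x) != n || length(y) != n || length(z) != n) {
    abort("aa, x, y, z must have equal length", class = "admap_error_trace")
  }
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    abort("coordinates must be finite", class = "admap_error_trace")
  }
  check_sequence(aa, allow_x = FALSE)
  out <- tibble(aa = aa, x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  attr(out, "id") <- id
  class(out) <- c("ca_trace", class(out))
  out
}

#' Sequence-separation range index
#'
#' Maps a sequence separation k = |i - j| to its pooling range M.
#' Range M = 1 covers 1 <= k <= 8, M = 2 covers 9 <= k <= 20, and each
#' subsequent range covers a decade: M >= 3 covers 10M - 9 <= k <= 10M.
#'
#' @param k Positive integer separation(s).
#' @param max_M Largest range index in use; separations beyond its upper
#'   bound return `NA`.
#' @return Integer vector of range indices (`NA` where k exceeds the last
#'   range).
#' @examples
#' range_index(c(5, 20, 31))
#' @export
range_index <- function(k, max_M = 9) {
  if (any(k < 1) || any(k != trunc(k))) {
    abort("separation k must be a positive integer", class = "admap_error_invalid_separation")
  }
  m <- ifelse(k <= 8, 1L, ifelse(k <= 20, 2L, as.integer(ceiling(k / 10))))
  m[m > max_M] <- NA_integer_
  m
}

#' Separation bounds of a range
#'
#' @param M Positive integer range index (vectorised).
#' @return Tibble with columns `M`, `k_min`, `k_max`.
#' @export
range_bounds <- function(M) {
  if (any(M < 1) || any(M != trunc(M))) {
    abort("range index M must be a positive integer", class = "admap_error_invalid_separation")
  }
  tibble(
    M = as.integer(M),
    k_min = ifelse(M == 1, 1L, ifelse(M == 2, 9L, 10L * as.integer(M) - 9L)),
    k_max = ifelse(M == 1, 8L, ifelse(M == 2, 20L, 10L * as.integer(M)))
  )
}

## largest separation covered by ranges 1..max_M
range_kmax <- function(max_M) if (max_M == 1) 8L else 10L * as.integer(max_M)

#' Construct an average distance statistics table
#'
#' Wraps a tibble of per-(residue pair, range) mean distances into the
#' `avg_dist_table` class used throughout the package. Residue pairs are
#' unordered: rows are canonicalised to `aa1 <= aa2` and duplicate keys are
#' pooled by count-weighted mean.
#'
#' @param entries Tibble with columns `aa1`, `aa2`, `M`, `mean_distance`,
#'   `count`.
#' @param min_count Minimum observation count for an entry to be considered
#'   statistically significant.
#' @param max_M Largest range index the table covers; defaults to the
#'   largest M present.
#' @return A tibble of class `avg_dist_table`.
#' @export
avg_dist_table <- function(entries, min_count = 10, max_M = NULL) {
  required <- c("aa1", "aa2", "M", "mean_distance", "count")
  if (!all(required %in% names(entries))) {
    abort(
      paste0("entries must have columns: ", paste(required, collapse = ", ")),
      class = "admap_error_table"
    )
  }
  entries <- as_tibble(entries)
  a <- pmin(entries$aa1, entries$aa2)
  b <- pmax(entries$aa1, entries$aa2)
  out <- entries |>
    mutate(aa1 = a, aa2 = b) |>
    group_by(aa1, aa2, M) |>
    summarise(
      mean_distance = sum(mean_distance * count) / sum(count),
      count = sum(count),
      .groups = "drop"
    ) |>
    arrange(aa1, aa2, M)
  if (any(out$count > 0 & !(out$mean_distance > 0))) {
    abort("mean distances must be positive where observed", class = "admap_error_table")
  }
  attr(out, "min_count") <- min_count
  attr(out, "max_M") <- max_M %||% (if (nrow(out)) max(out$M) else 0L)
  class(out) <- c("avg_dist_table", class(out))
  out
}

#' Build the inter-residue average distance table from structures
#'
#' Pools Calpha-Calpha Euclidean distances across a set of traces by
#' unordered residue-type pair and separation range M, recording the mean
#' and the observation count. This is the statistics an ADM is later built
#' from using sequence alone.
#'
#' @param traces A `ca_trace` or a list of them.
#' @param min_count Significance cutoff stored on the table (entries with
#'   `count >= min_count` are "statistically significant").
#' @param max_M Largest separation range compiled (range M covers decades
#'   of k; pairs separated beyond range `max_M` are ignored).
#' @return An [avg_dist_table()].
#' @examples
#' tr <- synth_chain("straight", 30, seed = 1)
#' build_distance_table(tr, min_count = 1)
#' @export
build_distance_table <- function(traces, min_count = 10, max_M = 9) {
  if (inherits(traces, "ca_trace")) traces <- list(traces)
  if (length(traces) == 0) {
    abort("at least one trace is required", class = "admap_error_empty_input")
  }
  if (min_count < 1) abort("min_count must be >= 1", class = "admap_error_table")
  rows <- map(traces, function(tr) {
    n <- nrow(tr)
    d <- as.matrix(dist(cbind(tr$x, tr$y, tr$z)))
    ks <- seq_len(min(n - 1, range_kmax(max_M)))
    k_vec <- rep(ks, times = n - ks)
    i <- sequence(n - ks)
    j <- i + k_vec
    tibble(
      aa1 = pmin(tr$aa[i], tr$aa[j]),
      aa2 = pmax(tr$aa[i], tr$aa[j]),
      M = range_index(k_vec, max_M),
      mean_distance = d[cbind(i, j)],
      count = 1L
    )
  }) |> list_rbind()
  avg_dist_table(rows, min_count = min_count, max_M = max_M)
}

#' Look up a table entry
#'
#' Symmetric lookup: `dist_lookup(tab, a, b, M)` equals
#' `dist_lookup(tab, b, a, M)`. Vectorised over all three keys.
#'
#' @param table An [avg_dist_table()].
#' @param a,b One-letter residue codes.
#' @param M Range index.
#' @return Tibble with columns `mean_distance`, `count`, `significant`
#'   (`NA` / `FALSE` rows where the entry is absent).
#' @export
dist_lookup <- function(table, a, b, M) {
  key <- paste(pmin(a, b), pmax(a, b), M, sep = "|")
  tab_key <- paste(table$aa1, table$aa2, table$M, sep = "|")
  idx <- match(key, tab_key)
  tibble(
    mean_distance = table$mean_distance[idx],
    count = ifelse(is.na(idx), 0L, table$count[idx]),
    significant = !is.na(idx) & table$count[idx] >= attr(table, "min_count")
  )
}

#' Real-distance-map density
#'
#' Fraction of residue pairs (any separation k >= 1) whose Calpha-Calpha
#' distance is strictly below the cutoff, over the N(N-1)/2 upper-triangle
#' cells. With the default 15 Angstrom cutoff this is the quantity the ADM
#' calibration constant C reproduces via rho = C/N.
#'
#' @param trace A [ca_trace()].
#' @param cutoff Distance cutoff in Angstroms (> 0).
#' @return A single density in `[0, 1]`.
#' @export
rdm_density <- function(trace, cutoff = 15) {
  if (cutoff <= 0) abort("cutoff must be positive", class = "admap_error_rdm")
  n <- nrow(trace)
  if (is.null(n) || n < 2) {
    abort("trace must have at least 2 residues", class = "admap_error_degenerate")
  }
  d <- dist(cbind(trace$x, trace$y, trace$z))
  sum(d < cutoff) / n_cells(n)
}
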