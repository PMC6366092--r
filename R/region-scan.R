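#' Density-difference scanning of an ADM
#'
#' At every residue index i the map is divided into a triangular part and
#' the remaining trapezoidal part, and the plot-density difference
#' delta_i = rho(triangle) - rho(trapezoid) is recorded. The horizontal
#' scan uses the triangle of pairs with both endpoints >= i (it peaks at
#' the start of a dense block); the vertical scan uses the triangle with
#' both endpoints <= i (it peaks at the end of a dense block). Densities
#' are per upper-triangle cell; cross pairs belong to the trapezoid.
#' Divisions where either part has no cells are left `NA`.
#'
#' @param adm An `adm` object (N >= 3).
#' @return Tibble of class `adm_scan` with columns `i`, `delta_h`,
#'   `delta_v`, and the part densities `rho_h_tri`, `rho_h_trap`,
#'   `rho_v_tri`, `rho_v_trap`. Attributes `N` and `n_plots`.
#' @export
adm_scan <- function(adm) {
  n <- adm$N
  if (n < 3) abort("scanning needs N >= 3", class = "admap_error_scan")
  plots <- adm$plots
  total <- nrow(plots)
  total_cells <- n_cells(n)
  i <- seq_len(n)

  ## plots with both endpoints >= i (suffix counts over the min index)
  cnt_min <- tabulate(plots$i, nbins = n)
  tri_h <- rev(cumsum(rev(cnt_min)))
  cells_h <- n_cells(n - i + 1)
  ## plots with both endpoints <= i (prefix counts over the max index)
  cnt_max <- tabulate(plots$j, nbins = n)
  tri_v <- cumsum(cnt_max)
  cells_v <- n_cells(i)

  part_density <- function(tri_plots, tri_cells) {
    trap_cells <- total_cells - tri_cells
    rho_tri <- ifelse(tri_cells > 0, tri_plots / tri_cells, NA_real_)
    rho_trap <- ifelse(trap_cells > 0, (total - tri_plots) / trap_cells, NA_real_)
    list(tri = rho_tri, trap = rho_trap, delta = rho_tri - rho_trap)
  }
  h <- part_density(tri_h, cells_h)
  v <- part_density(tri_v, cells_v)

  out <- tibble(
    i = i,
    delta_h = h$delta, delta_v = v$delta,
    rho_h_tri = h$tri, rho_h_trap = h$trap,
    rho_v_tri = v$tri, rho_v_trap = v$trap
  )
  attr(out, "N") <- n
  attr(out, "n_plots") <- total
  class(out) <- c("adm_scan", class(out))
  out
}

## local extrema of one profile; plateaus resolve to their leftmost index;
## runs at the ends of the defined stretch are not extrema (a monotone
## profile has no peaks)
local_extrema <- function(x, min_height) {
  idx <- which(!is.na(x))
  if (length(idx) < 3) {
    return(list(peaks = integer(), valleys = integer()))
  }
  v <- x[idx]
  r <- rle(v)
  nr <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peak_run <- valley_run <- logical(nr)
  for (q in seq_len(nr)[-c(1, nr)]) {
    peak_run[q] <- r$values[q] > r$values[q - 1] &&
      r$values[q] > r$values[q + 1]
    valley_run[q] <- r$values[q] < r$values[q - 1] &&
      r$values[q] < r$values[q + 1]
  }
  peaks <- idx[starts[peak_run & r$values > min_height]]
  valleys <- idx[starts[valley_run & r$values < -min_height]]
  list(peaks = peaks, valleys = valleys)
}

#' Peaks and valleys of a scanning profile
#'
#' Peaks are local maxima above `min_height`, valleys local minima below
#' `-min_height`; plateaus are resolved to their leftmost index. A peak
#' and a valley bracket the boundaries of a densely plotted region.
#' Divisions whose triangular part spans fewer than `min_part` residues
#' are excluded: their densities average so few map cells that sampling
#' noise dominates any real boundary signal.
#'
#' @param profile An [adm_scan()] profile.
#' @param min_height Minimum absolute density difference for an extremum
#'   to count.
#' @param min_part Minimum residue span of the triangular part.
#' @return Tibble with columns `direction` (`"h"`/`"v"`), `type`
#'   (`"peak"`/`"valley"`), `index`, `height`.
#' @export
scan_peaks <- function(profile, min_height = 0.01, min_part = 10) {
  n <- nrow(profile)
  out <- map_dfr(c(h = "h", v = "v"), function(dir) {
    x <- if (dir == "h") profile$delta_h else profile$delta_v
    if (dir == "h") {
      x[profile$i > n - min_part + 1] <- NA_real_
    } else {
      x[profile$i < min_part] <- NA_real_
    }
    ex <- local_extrema(x, min_height)
    bind_rows(
      tibble(type = "peak", index = ex$peaks, height = x[ex$peaks]),
      tibble(type = "valley", index = ex$valleys, height = x[ex$valleys])
    )
  }, .id = "direction")
  arrange(out, direction, index)
}

#' Predict compact regions from a scanning profile
#'
#' Candidate regions pair a horizontal-scan peak m (region start) with a
#' vertical-scan peak n (region end), n - m >= `min_span`, scored by the
#' compactness measure eta = delta_h[m] + delta_v[n]. Overlapping
#' candidates are resolved greedily in descending eta.
#'
#' @inheritParams scan_peaks
#' @param min_span Minimum region length in residues.
#' @return Tibble with columns `start`, `end`, `eta`, `delta_h`,
#'   `delta_v`, sorted by descending eta.
#' @export
predict_compact_regions <- function(profile, min_height = 0.01, min_span = 20,
                                    min_part = 10) {
  pk <- scan_peaks(profile, min_height, min_part) |> filter(type == "peak")
  hs <- pk |> filter(direction == "h")
  vs <- pk |> filter(direction == "v")
  if (nrow(hs) == 0 || nrow(vs) == 0) {
    return(tibble(
      start = integer(), end = integer(), eta = numeric(),
      delta_h = numeric(), delta_v = numeric()
    ))
  }
  cand <- tidyr_crossing(hs$index, vs$index) |>
    rename(start = x, end = y) |>
    filter(end - start >= min_span) |>
    mutate(
      delta_h = profile$delta_h[start],
      delta_v = profile$delta_v[end],
      eta = delta_h + delta_v
    ) |>
    arrange(desc(eta), start, end)
  kept <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    row <- cand[r, ]
    overlaps <- nrow(kept) > 0 &&
      any(row$start <= kept$end & kept$start <= row$end)
    if (!overlaps) kept <- bind_rows(kept, row)
  }
  select(kept, start, end, eta, delta_h, delta_v)
}

## small cross-join helper (avoids a tidyr dependency for one call)
tidyr_crossing <- function(a, b) {
  tibble(x = rep(a, each = length(b)), y = rep(b, times = length(a)))
}

#' @method autoplot adm_scan
#' @export
autoplot.adm_scan <- function(object, ...) {
  df <- bind_rows(
    tibble(i = object$i, delta = object$delta_h, scan = "horizontal"),
    tibble(i = object$i, delta = object$delta_v, scan = "vertical")
  )
  ggplot(df, aes(i, delta)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line(na.rm = TRUE) +
    facet_wrap(~scan, ncol = 1) +
    labs(x = "residue index", y = expression(Delta * rho[i])) +
    theme_minimal()
}

#' @export
plot.adm_scan <- function(x, ...) print(autoplot(x, ...))
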