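#' Target number of ADM plots for a sequence length
#'
#' The whole-map plot density of a real distance map follows rho = C/N, so
#' over the N(N-1)/2 upper-triangle cells the ADM aims for
#' round(C (N - 1) / 2) plots (half rounded away from zero).
#'
#' @param n Sequence length (>= 2).
#' @param C Calibration constant; 36.12 reproduces the 15-Angstrom RDM
#'   density.
#' @return Integer plot count.
#' @examples
#' target_plot_count(101)
#' @export
target_plot_count <- function(n, C = 36.12) {
  if (n < 2) abort("sequence length must be >= 2", class = "admap_error_adm")
  as.integer(round_half_up(C * (n - 1) / 2))
}

## all plottable (statistically significant) pairs of a sequence:
## tibble(i, j, k, M, mean_distance), 1-based, i < j
candidate_pairs <- function(s, table) {
  n <- length(s)
  max_M <- attr(table, "max_M")
  ks <- seq_len(min(n - 1, range_kmax(max_M)))
  k_vec <- rep(ks, times = n - ks)
  i <- sequence(n - ks)
  j <- i + k_vec
  m <- range_index(k_vec, max_M)
  look <- dist_lookup(table, s[i], s[j], m)
  keep <- look$significant & !is.na(look$mean_distance)
  tibble(
    i = i[keep], j = j[keep], k = k_vec[keep], M = m[keep],
    mean_distance = look$mean_distance[keep]
  )
}

## Solve for the global density-adjustment scalar D:
## f(D) = sum_M min((D/M) P(M), P(M)) is piecewise linear and increasing,
## with kinks at D = M; return the D with f(D) = target (or the saturation
## point max(M) if even plotting every candidate cannot reach the target).
solve_density_scale <- function(p_m, target) {
  ms <- as.numeric(names(p_m))
  p <- as.numeric(p_m)
  stopifnot(length(ms) > 0, all(p >= 0))
  if (target <= 0) {
    return(list(D = 0, shortfall = FALSE))
  }
  if (target >= sum(p)) {
    return(list(D = max(ms), shortfall = target > sum(p)))
  }
  kinks <- sort(unique(ms))
  f_at <- function(D) sum(pmin(D / ms * p, p))
  lo <- 0
  f_lo <- 0
  for (kk in kinks) {
    f_kk <- f_at(kk)
    if (f_kk >= target) {
      slope <- sum((p / ms)[ms >= kk])
      return(list(D = lo + (target - f_lo) / slope, shortfall = FALSE))
    }
    lo <- kk
    f_lo <- f_kk
  }
  list(D = max(ms), shortfall = FALSE)
}

#' Fit the density-adjustment parameter D and per-range plot counts
#'
#' Within each separation range M the number of pairs to plot obeys
#' P(M)_C = (D/M) P(M), where P(M) counts the sequence's residue pairs in
#' range M with statistically significant table entries and the shared
#' scalar D is chosen so that the total plot count meets the
#' [target_plot_count()] implied by rho = C/N. Counts are rounded half away
#' from zero and capped at P(M).
#'
#' @param sequence Amino-acid sequence (string or character vector;
#'   `X` is allowed and is unplottable).
#' @param table An [avg_dist_table()].
#' @param C Calibration constant.
#' @return List with elements `D`, `target`, `n`, and `counts` (tibble with
#'   columns `M`, `p_m`, `p_m_c`).
#' @export
fit_plot_counts <- function(sequence, table, C = 36.12) {
  s <- check_sequence(seq_chars(sequence))
  n <- length(s)
  if (n < 2) abort("sequence length must be >= 2", class = "admap_error_adm")
  cand <- candidate_pairs(s, table)
  if (nrow(cand) == 0) {
    abort(
      "no residue pair of this sequence has statistically significant distance statistics",
      class = "admap_error_no_statistics"
    )
  }
  p_m_tbl <- cand |> count(M, name = "p_m")
  p_m <- setNames(p_m_tbl$p_m, p_m_tbl$M)
  target <- target_plot_count(n, C)
  sol <- solve_density_scale(p_m, target)
  if (sol$shortfall) {
    warn(paste0(
      "only ", sum(p_m), " significant pairs available for a target of ",
      target, " plots; plotting all of them"
    ))
  }
  counts <- p_m_tbl |>
    mutate(p_m_c = pmin(round_half_up(sol$D / M * p_m), p_m)) |>
    mutate(p_m_c = as.integer(pmax(p_m_c, 0L)))
  list(D = sol$D, target = target, n = n, counts = counts)
}

## internal constructor for the ADM object
new_adm <- function(sequence, plots, counts, N, C, D, target, id = NULL) {
  structure(
    list(
      id = id %||% "adm",
      sequence = paste(sequence, collapse = ""),
      N = N,
      C = C,
      D = D,
      target = target,
      counts = counts,
      plots = plots,
      density = nrow(plots) / n_cells(N)
    ),
    class = "adm"
  )
}

#' Build an average distance map for a sequence
#'
#' Within each separation range M, the P(M)_C candidate pairs with the
#' smallest table mean distances are plotted (ties broken by ascending i,
#' then j), and the range's distance threshold is recorded as the midpoint
#' between the largest plotted mean and the next candidate value, so that
#' "average distance < threshold" reproduces the selection. Pairs without
#' statistically significant table entries are never plotted.
#'
#' @inheritParams fit_plot_counts
#' @param id Identifier attached to the map.
#' @return An object of class `adm`: sequence, plotted pairs (tibble
#'   `i, j, k, M, mean_distance`), per-range counts and thresholds, the
#'   fitted D, and the realised whole-map density.
#' @examples
#' tab <- synth_table("uniform", seed = 1)
#' adm <- build_adm(strrep("ACDEFGHIKL", 5), tab)
#' glance(adm)
#' @export
build_adm <- function(sequence, table, C = 36.12, id = NULL) {
  s <- check_sequence(seq_chars(sequence))
  n <- length(s)
  if (n < 2) abort("sequence length must be >= 2", class = "admap_error_adm")
  target <- target_plot_count(n, C)
  if (target == 0) {
    counts <- tibble(
      M = integer(), p_m = integer(), p_m_c = integer(),
      threshold = numeric()
    )
    return(new_adm(s, tibble(
      i = integer(), j = integer(), k = integer(), M = integer(),
      mean_distance = numeric()
    ), counts, n, C, 0, target, id))
  }
  fit <- fit_plot_counts(s, table, C)
  cand <- candidate_pairs(s, table) |>
    arrange(M, mean_distance, i, j) |>
    group_by(M) |>
    mutate(rank_in_range = row_number()) |>
    ungroup() |>
    left_join(fit$counts, by = "M")
  thresholds <- cand |>
    group_by(M) |>
    summarise(
      threshold = {
        dsort <- mean_distance # already sorted within range
        cnt <- p_m_c[1]
        if (cnt <= 0) {
          dsort[1]
        } else if (cnt >= length(dsort)) {
          dsort[length(dsort)] + 0.5
        } else {
          (dsort[cnt] + dsort[cnt + 1]) / 2
        }
      },
      n_candidates = n(),
      .groups = "drop"
    )
  plots <- cand |>
    filter(rank_in_range <= p_m_c) |>
    select(i, j, k, M, mean_distance) |>
    arrange(i, j)
  counts <- fit$counts |> left_join(thresholds, by = "M")
  new_adm(s, plots, counts, n, C, fit$D, fit$target, id)
}

#' @export
print.adm <- function(x, ...) {
  cat(sprintf(
    "<adm> %s: N = %d, plots = %d, density = %.4f (C = %.2f, D = %.3f, target = %d)\n",
    x$id, x$N, nrow(x$plots), x$density, x$C, x$D, x$target
  ))
  print(x$counts)
  invisible(x)
}

#' @describeIn build_adm Plotted pairs of an ADM as a tibble.
#' @param x An `adm` object.
#' @param ... Unused.
#' @method tidy adm
#' @export
tidy.adm <- function(x, ...) x$plots

#' @describeIn build_adm One-row summary of an ADM.
#' @method glance adm
#' @export
glance.adm <- function(x, ...) {
  tibble(
    id = x$id, N = x$N, n_plots = nrow(x$plots), density = x$density,
    density_N = x$density * x$N, C = x$C, D = x$D, target = x$target
  )
}

#' @method autoplot adm
#' @export
autoplot.adm <- function(object, ...) {
  ggplot(object$plots, aes(x = j, y = i)) +
    geom_point(shape = 15, size = 0.8, colour = "grey20") +
    scale_y_reverse(limits = c(object$N, 1)) +
    scale_x_continuous(limits = c(1, object$N)) +
    coord_fixed() +
    labs(
      title = sprintf("ADM %s (N = %d, density N = %.2f)",
                      object$id, object$N, object$density * object$N),
      x = "residue j", y = "residue i"
    ) +
    theme_minimal()
}

#' @export
plot.adm <- function(x, ...) print(autoplot(x, ...))

#' Short- and long-range ADM-plot ratios
#'
#' The ADM-plot ratio is the number of plots divided by the number of
#' residues. Short-range plots are pairs separated by fewer than 9
#' residues, long-range plots by more than 8. With an interval, only plots
#' with both endpoints inside the interval count and the denominator is
#' the interval length.
#'
#' @param adm An `adm` object.
#' @param interval Optional 1-based inclusive `c(start, end)` restriction.
#' @return One-row tibble: `n_residues`, `n_short`, `n_long`,
#'   `short_ratio`, `long_ratio`.
#' @export
plot_ratios <- function(adm, interval = NULL) {
  plots <- adm$plots
  n <- adm$N
  if (!is.null(interval)) {
    if (length(interval) != 2 || interval[1] > interval[2] ||
        interval[1] < 1 || interval[2] > n) {
      abort("interval must be c(start, end) within [1, N] with start <= end",
            class = "admap_error_invalid_interval")
    }
    plots <- plots |> filter(i >= interval[1], j <= interval[2])
    n <- interval[2] - interval[1] + 1
  }
  n_short <- sum(plots$k < 9)
  n_long <- sum(plots$k > 8)
  tibble(
    n_residues = n, n_short = n_short, n_long = n_long,
    short_ratio = n_short / n, long_ratio = n_long / n
  )
}
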