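#' Per-residue ADM plot counts
#'
#' Counts, for every residue i, the plotted pairs (i, j) whose sequence
#' separation lies in the counting band `k_lo <= |i - j| <= k_hi`, and
#' smooths the counts by a truncated moving average. The default band
#' 9..29 keeps long-range plots (separation more than 8 residues) while
#' restricting to separations below 30 to retain relatively short-range
#' effects.
#'
#' @param adm An `adm` object.
#' @param k_lo,k_hi Inclusive separation band (1 <= k_lo < k_hi).
#' @param half_width Smoothing half-width in residues; the window at i is
#'   `max(1, i - half_width) .. min(N, i + half_width)`.
#' @return Tibble with columns `index`, `residue`, `raw_count`,
#'   `smoothed_count`.
#' @export
residue_plot_counts <- function(adm, k_lo = 9, k_hi = 29, half_width = 5) {
  if (k_lo < 1 || k_lo >= k_hi) {
    abort("counting band must satisfy 1 <= k_lo < k_hi", class = "admap_error_band")
  }
  n <- adm$N
  in_band <- adm$plots |> filter(k >= k_lo, k <= k_hi)
  raw <- tabulate(in_band$i, nbins = n) + tabulate(in_band$j, nbins = n)
  tibble(
    index = seq_len(n),
    residue = seq_chars(adm$sequence),
    raw_count = as.integer(raw),
    smoothed_count = smooth_profile(raw, half_width)
  )
}

#' Truncated moving-average smoothing
#'
#' Mean over the window `[i - half_width, i + half_width]` intersected
#' with `[1, N]` (the window shrinks at the ends rather than padding).
#'
#' @param x Numeric series.
#' @param half_width Window half-width (5 residues forward and backward by
#'   default).
#' @return Numeric vector of the same length.
#' @export
smooth_profile <- function(x, half_width = 5) {
  n <- length(x)
  if (n == 0) return(numeric())
  cs <- c(0, cumsum(x))
  lo <- pmax(1, seq_len(n) - half_width)
  hi <- pmin(n, seq_len(n) + half_width)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

## per-residue truth labels from an interval annotation table
## (rows for one protein: start, end, label in {disordered, ordered});
## residues in neither class are NA (unannotated)
annotation_truth <- function(annotations, n) {
  truth <- rep(NA_character_, n)
  dis <- rep(FALSE, n)
  ord <- rep(FALSE, n)
  for (r in seq_len(nrow(annotations))) {
    s <- annotations$start[r]
    e <- annotations$end[r]
    if (s < 1 || e > n || s > e) {
      abort(
        sprintf("interval [%d, %d] outside sequence of length %d", s, e, n),
        class = "admap_error_annotation"
      )
    }
    if (annotations$label[r] == "disordered") dis[s:e] <- TRUE else ord[s:e] <- TRUE
  }
  if (any(dis & ord)) {
    abort("disordered and ordered intervals overlap", class = "admap_error_annotation")
  }
  truth[dis] <- "disordered"
  truth[ord] <- "ordered"
  truth
}

#' Pool per-residue calibration statistics
#'
#' Bins pooled residues by their integer-rounded smoothed plot count and
#' records, per bin, the number of residues and the fraction annotated
#' disordered. Bins with no residues are absent, not zero.
#'
#' @param residues Tibble with columns `count` (smoothed plot count) and
#'   `disordered` (logical).
#' @return Tibble with columns `count` (bin centre), `n`, `frac`.
#' @export
disorder_bins <- function(residues) {
  residues |>
    mutate(count = round_half_up(count)) |>
    group_by(count) |>
    summarise(n = n(), frac = mean(disordered), .groups = "drop") |>
    arrange(count)
}

#' Fit the disorder-probability curve to binned statistics
#'
#' Count-weighted least-squares polynomial fit (cubic by default) of the
#' per-bin disorder fraction against the plot-count bin centre. Outputs
#' are clamped to `[0, 1]`; outside the observed bin domain the curve
#' returns the boundary value. If fewer distinct bins than coefficients
#' are available the degree is reduced.
#'
#' @param bins Output of [disorder_bins()].
#' @param degree Polynomial degree.
#' @return Object of class `disorder_curve`.
#' @export
fit_disorder_curve <- function(bins, degree = 3) {
  if (nrow(bins) == 0) {
    abort("no calibration bins", class = "admap_error_calibration")
  }
  deg <- min(degree, nrow(bins) - 1)
  if (deg == 0) {
    coefs <- c(sum(bins$frac * bins$n) / sum(bins$n))
  } else {
    xs <- bins$count
    fml <- frac ~ poly(count, degree = deg, raw = TRUE)
    fit <- lm(fml, data = bins, weights = n)
    coefs <- unname(coef(fit))
    coefs[is.na(coefs)] <- 0
  }
  structure(
    list(
      coefficients = coefs,
      degree = deg,
      domain = range(bins$count),
      bins = bins,
      n_residues = sum(bins$n)
    ),
    class = "disorder_curve"
  )
}

#' Evaluate a disorder-probability curve
#'
#' @param curve A `disorder_curve`.
#' @param count Smoothed plot counts (numeric vector).
#' @return Disorder probabilities in `[0, 1]`; inputs outside the
#'   calibration domain are clamped to the nearest boundary first.
#' @export
curve_probability <- function(curve, count) {
  x <- pmin(pmax(count, curve$domain[1]), curve$domain[2])
  xp <- outer(x, 0:curve$degree, `^`)
  y <- drop(xp %*% curve$coefficients)
  pmin(pmax(y, 0), 1)
}

#' @export
print.disorder_curve <- function(x, ...) {
  cat(sprintf(
    "<disorder_curve> degree %d over counts [%g, %g], %d residues in %d bins\n",
    x$degree, x$domain[1], x$domain[2], x$n_residues, nrow(x$bins)
  ))
  invisible(x)
}

#' @describeIn fit_disorder_curve Calibration bins of the curve.
#' @param x A `disorder_curve`.
#' @param ... Unused.
#' @method tidy disorder_curve
#' @export
tidy.disorder_curve <- function(x, ...) x$bins

#' @describeIn fit_disorder_curve One-row curve summary.
#' @method glance disorder_curve
#' @export
glance.disorder_curve <- function(x, ...) {
  tibble(
    degree = x$degree, n_bins = nrow(x$bins), n_residues = x$n_residues,
    domain_lo = x$domain[1], domain_hi = x$domain[2]
  )
}

#' @method autoplot disorder_curve
#' @export
autoplot.disorder_curve <- function(object, ...) {
  grid <- tibble(
    count = seq(object$domain[1], object$domain[2], length.out = 200)
  )
  grid$probability <- curve_probability(object, grid$count)
  ggplot(object$bins, aes(count, frac)) +
    geom_point(aes(size = n), alpha = 0.6) +
    geom_line(
      data = grid, aes(count, probability),
      colour = "red", linetype = "dashed"
    ) +
    scale_size_area(max_size = 4) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "smoothed ADM plot count", y = "disorder probability") +
    theme_minimal()
}

#' @export
plot.disorder_curve <- function(x, ...) print(autoplot(x, ...))

#' Calibrate the disorder-probability curve on annotated proteins
#'
#' For every admissible training protein an ADM is built, per-residue plot
#' counts in the counting band are smoothed, and annotated residues are
#' pooled into plot-count bins whose disorder fractions are fitted by
#' count-weighted least squares. A protein is excluded when its disordered
#' regions cover less than `min_coverage` of the whole protein, or its
#' ordered regions do.
#'
#' @param train Tibble with columns `protein_id`, `sequence`.
#' @param annotations Tibble with columns `protein_id`, `start`, `end`,
#'   `label` (`"disordered"` / `"ordered"`), 1-based inclusive.
#' @param table An [avg_dist_table()].
#' @param C Calibration constant.
#' @param min_coverage Minimum per-class coverage fraction (default 0.10).
#' @param band Counting band `c(k_lo, k_hi)`.
#' @param half_width Smoothing half-width.
#' @param degree Polynomial degree of the fitted curve.
#' @return A `disorder_curve` (with the training pool retained in
#'   `$bins`).
#' @export
calibrate_disorder <- function(train, annotations, table, C = 36.12,
                               min_coverage = 0.10, band = c(9, 29),
                               half_width = 5, degree = 3) {
  pools <- map(seq_len(nrow(train)), function(r) {
    id <- train$protein_id[r]
    s <- seq_chars(train$sequence[r])
    n <- length(s)
    ann <- annotations |> filter(protein_id == id)
    truth <- annotation_truth(ann, n)
    cov_dis <- sum(truth == "disordered", na.rm = TRUE) / n
    cov_ord <- sum(truth == "ordered", na.rm = TRUE) / n
    if (cov_dis < min_coverage || cov_ord < min_coverage) {
      return(NULL)
    }
    adm <- build_adm(s, table, C, id = id)
    rc <- residue_plot_counts(adm, band[1], band[2], half_width)
    keep <- !is.na(truth)
    tibble(
      count = rc$smoothed_count[keep],
      disordered = truth[keep] == "disordered"
    )
  })
  pooled <- list_rbind(pools[!map_lgl(pools, is.null)])
  if (is.null(pooled) || nrow(pooled) == 0) {
    abort(
      "no admissible training protein after the coverage filter",
      class = "admap_error_calibration"
    )
  }
  curve <- fit_disorder_curve(disorder_bins(pooled), degree)
  curve$n_proteins <- sum(!map_lgl(pools, is.null))
  curve$band <- band
  curve$C <- C
  curve
}

## resolve a threshold preset
resolve_theta <- function(theta) {
  if (is.character(theta)) {
    theta <- match.arg(theta, c("accw", "accp"))
    return(if (theta == "accw") 0.62 else 0.53)
  }
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1) {
    abort("theta must be in [0, 1] or one of 'accw', 'accp'",
          class = "admap_error_theta")
  }
  theta
}

#' Predict disordered regions for a sequence
#'
#' Builds the ADM, computes smoothed per-residue plot counts, converts
#' them to disorder probabilities through the calibrated curve, and labels
#' residue i disordered when `probability_i >= theta`. Disordered segments
#' are the maximal runs of disordered labels.
#'
#' @param sequence Amino-acid sequence (string or character vector; `X`
#'   is treated as an unplottable residue).
#' @param table An [avg_dist_table()].
#' @param curve A calibrated [fit_disorder_curve()] /
#'   [calibrate_disorder()] curve.
#' @param C Calibration constant.
#' @param theta Probability threshold: a number in `[0, 1]` or a preset,
#'   `"accw"` (0.62, maximises balanced accuracy) or `"accp"` (0.53,
#'   maximises plain accuracy).
#' @param band,half_width Counting band and smoothing half-width (see
#'   [residue_plot_counts()]).
#' @param id Identifier attached to the prediction.
#' @return Tibble of class `disorder_prediction` with columns `index`,
#'   `residue`, `raw_count`, `smoothed_count`, `probability`, `label`
#'   (logical: disordered); attributes `theta`, `id`, `N`.
#' @export
predict_disorder <- function(sequence, table, curve, C = 36.12,
                             theta = "accw", band = c(9, 29),
                             half_width = 5, id = "query") {
  theta <- resolve_theta(theta)
  adm <- build_adm(sequence, table, C, id = id)
  rc <- residue_plot_counts(adm, band[1], band[2], half_width)
  out <- rc |>
    mutate(
      probability = curve_probability(curve, smoothed_count),
      label = probability >= theta
    )
  attr(out, "theta") <- theta
  attr(out, "id") <- id
  attr(out, "N") <- adm$N
  class(out) <- c("disorder_prediction", class(out))
  out
}

#' Disordered segments of a prediction
#'
#' Maximal runs of disordered labels as 1-based inclusive intervals.
#' The exact inverse of expanding the intervals back to labels.
#'
#' @param prediction A `disorder_prediction` (or any tibble with a logical
#'   `label` column).
#' @return Tibble with columns `start`, `end`.
#' @export
disorder_segments <- function(prediction) {
  r <- rle(prediction$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[r$values], end = ends[r$values])
}

#' @describeIn predict_disorder One-row prediction summary.
#' @param x A `disorder_prediction`.
#' @param ... Unused.
#' @method glance disorder_prediction
#' @export
glance.disorder_prediction <- function(x, ...) {
  seg <- disorder_segments(x)
  tibble(
    id = attr(x, "id"), N = nrow(x), theta = attr(x, "theta"),
    n_disordered = sum(x$label), n_segments = nrow(seg)
  )
}

#' @method autoplot disorder_prediction
#' @export
autoplot.disorder_prediction <- function(object, ...) {
  seg <- disorder_segments(object)
  p <- ggplot(object, aes(index, probability)) +
    geom_hline(yintercept = attr(object, "theta"),
               colour = "grey50", linetype = "dotted") +
    geom_line() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "residue index", y = "disorder probability") +
    theme_minimal()
  if (nrow(seg) > 0) {
    p <- p + geom_rect(
      data = seg,
      aes(xmin = start - 0.5, xmax = end + 0.5, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.15
    )
  }
  p
}

#' @export
plot.disorder_prediction <- function(x, ...) print(autoplot(x, ...))

#' Tandem-duplication (dimer-like) prediction
#'
#' Predicts on the sequence itself and on the sequence concatenated with
#' itself (length 2N). Plots spanning the junction let the tandem run pick
#' up order that only emerges through self-association; the tandem result
#' carries `copy` (1 or 2) and `copy_index` columns mapping back to the
#' monomer numbering.
#'
#' @inheritParams predict_disorder
#' @return List of class `tandem_prediction` with elements `monomer` and
#'   `tandem`, both `disorder_prediction` tibbles.
#' @export
predict_tandem <- function(sequence, table, curve, C = 36.12,
                           theta = "accw", band = c(9, 29),
                           half_width = 5, id = "query") {
  s <- seq_chars(sequence)
  n <- length(s)
  monomer <- predict_disorder(s, table, curve, C, theta, band, half_width,
                              id = paste0(id, "_monomer"))
  tandem <- predict_disorder(c(s, s), table, curve, C, theta, band,
                             half_width, id = paste0(id, "_tandem"))
  tandem$copy <- rep(1:2, each = n)
  tandem$copy_index <- rep(seq_len(n), times = 2)
  structure(list(monomer = monomer, tandem = tandem),
            class = "tandem_prediction")
}

#' @export
print.tandem_prediction <- function(x, ...) {
  cat("<tandem_prediction>\n monomer: ")
  print(glance(x$monomer))
  cat(" tandem: ")
  print(glance(x$tandem))
  invisible(x)
}
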