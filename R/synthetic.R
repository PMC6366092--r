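## Seeded synthetic-data generators: toy Calpha traces with realistic
## pairwise-distance structure, hand-settable statistics tables, and
## annotated sequence sets with a known disorder-generating law. All
## generators are pure functions of their parameters and seed.

#' Generate a synthetic Calpha trace
#'
#' Three geometries: `"straight"` is a colinear chain with the canonical
#' 3.8 Angstrom Calpha spacing; `"helix"` is an ideal alpha helix
#' (radius 2.3 A, rise 1.5 A per residue, 100 degree twist); and
#' `"collapsed"` is a seeded 3.8-A-step random walk rescaled into a
#' sphere of radius `2.5 * n^(1/3)` A, mimicking globular compaction.
#'
#' @param kind One of `"straight"`, `"helix"`, `"collapsed"`.
#' @param n Number of residues (>= 2).
#' @param seed Integer seed (mandatory randomness control; also seeds the
#'   residue composition).
#' @param aa Residue codes: `NULL` for a seeded random composition, a
#'   single code to repeat, or a length-`n` vector.
#' @return A [ca_trace()].
#' @examples
#' synth_chain("helix", 20, seed = 7)
#' @export
synth_chain <- function(kind = c("straight", "helix", "collapsed"), n,
                        seed = 1, aa = NULL) {
  kind <- match.arg(kind)
  if (n < 2) abort("n must be >= 2", class = "admap_error_synth")
  withr::with_seed(seed, {
    if (is.null(aa)) {
      aa <- sample(AA_STANDARD, n, replace = TRUE)
    } else if (length(aa) == 1) {
      aa <- rep(aa, n)
    }
    idx <- seq_len(n) - 1
    xyz <- switch(kind,
      straight = cbind(3.8 * idx, 0 * idx, 0 * idx),
      helix = {
        ang <- idx * 100 * pi / 180
        cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * idx)
      },
      collapsed = {
        steps <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
        steps <- steps / sqrt(rowSums(steps^2)) * 3.8
        pos <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
        pos <- sweep(pos, 2, colMeans(pos))
        r_max <- max(sqrt(rowSums(pos^2)))
        pos * (2.5 * n^(1 / 3)) / r_max
      }
    )
    ca_trace(aa, xyz[, 1], xyz[, 2], xyz[, 3],
             id = paste0("synth_", kind, "_", seed))
  })
}

#' Generate a synthetic average distance statistics table
#'
#' `"uniform"` makes every residue-type pair significant in every range
#' with mean distances drawn from a seeded spread (exact-oracle tests and
#' density calibration). `"two_class"` gives pairs within an order-prone
#' residue subset (`A C F I L M V W Y`) short mean distances, mixed pairs
#' intermediate, and pairs of the remaining (disorder-prone, hydrophilic)
#' types long ones, so sequences rich in order-prone letters accumulate
#' ADM plots.
#'
#' @param profile `"uniform"` or `"two_class"`.
#' @param seed Integer seed for the distance spread.
#' @param max_M Largest range index covered.
#' @param count Observation count recorded on every entry.
#' @param min_count Significance cutoff attached to the table.
#' @return An [avg_dist_table()].
#' @export
synth_table <- function(profile = c("uniform", "two_class"), seed = 1,
                        max_M = 9, count = 100, min_count = 10) {
  profile <- match.arg(profile)
  pairs <- t(combn(AA_STANDARD, 2))
  pairs <- rbind(pairs, cbind(AA_STANDARD, AA_STANDARD))
  grid <- tibble(
    aa1 = rep(pairs[, 1], times = max_M),
    aa2 = rep(pairs[, 2], times = max_M),
    M = rep(seq_len(max_M), each = nrow(pairs))
  )
  withr::with_seed(seed, {
    u <- runif(nrow(grid))
    base <- if (profile == "uniform") {
      5 + 15 * u
    } else {
      both_op <- grid$aa1 %in% AA_ORDER_PRONE & grid$aa2 %in% AA_ORDER_PRONE
      none_op <- !(grid$aa1 %in% AA_ORDER_PRONE) & !(grid$aa2 %in% AA_ORDER_PRONE)
      ifelse(both_op, 6 + 2 * u, ifelse(none_op, 20 + 4 * u, 14 + 3 * u))
    }
    avg_dist_table(
      grid |> mutate(mean_distance = base, count = as.integer(count)),
      min_count = min_count, max_M = max_M
    )
  })
}

#' Define a synthetic disorder-generating law
#'
#' A monotone non-increasing logistic law mapping a residue's smoothed
#' ADM plot count to its probability of being disordered:
#' `p(c) = plogis((midpoint - c)/scale)`. Defaults place the midpoint
#' between the smoothed-count modes that the two-class table produces for
#' disorder-prone (mostly below 8) and order-prone (mostly above 16)
#' segments of 100-199-residue sequences, with a transition gentle enough
#' for the cubic calibration fit to track.
#'
#' @param midpoint Count at which the disorder probability is 0.5.
#' @param scale Logistic scale in count units (smaller = sharper).
#' @return Object of class `synth_law` with a `$prob(count)` function.
#' @export
synth_law <- function(midpoint = 12, scale = 2) {
  structure(
    list(
      midpoint = midpoint, scale = scale,
      prob = function(count) plogis((midpoint - count) / scale)
    ),
    class = "synth_law"
  )
}

#' @export
print.synth_law <- function(x, ...) {
  cat(sprintf("<synth_law> logistic, midpoint %g counts, scale %g\n",
              x$midpoint, x$scale))
  invisible(x)
}

## seeded sequence of alternating order-prone / disorder-prone segments
synth_segmented_sequence <- function(n, purity = 0.95,
                                     seg_range = c(35, 65)) {
  other <- setdiff(AA_STANDARD, AA_ORDER_PRONE)
  s <- character(0)
  ordered_seg <- runif(1) < 0.5
  while (length(s) < n) {
    len <- sample(seg_range[1]:seg_range[2], 1)
    pool_major <- if (ordered_seg) AA_ORDER_PRONE else other
    pool_minor <- if (ordered_seg) other else AA_ORDER_PRONE
    major <- runif(len) < purity
    seg <- ifelse(
      major,
      sample(pool_major, len, replace = TRUE),
      sample(pool_minor, len, replace = TRUE)
    )
    s <- c(s, seg)
    ordered_seg <- !ordered_seg
  }
  s[seq_len(n)]
}

#' Generate an annotated synthetic protein set
#'
#' Sequences are composed of alternating order-prone and disorder-prone
#' segments; each protein's ADM (under the supplied two-class table) is
#' built, per-residue plot counts are smoothed, and each residue's
#' disordered/ordered label is a Bernoulli draw from the law applied to
#' its realised smoothed count. Annotations are the maximal runs of each
#' label, so they tile the sequence without overlap.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Inclusive sequence-length range, drawn uniformly.
#' @param law A [synth_law()].
#' @param seed Integer seed.
#' @param table Statistics table (default: two-class table seeded from
#'   `seed`).
#' @param C Calibration constant used when realising plot counts.
#' @param band,half_width Counting band and smoothing half-width.
#' @return List with elements `sequences` (tibble `protein_id, sequence`),
#'   `annotations` (tibble `protein_id, start, end, label`) and
#'   `residues` (tibble `protein_id, index, count, disordered` of the
#'   realised calibration pool).
#' @export
synth_annotated_set <- function(n_proteins, length_range = c(100, 199),
                                law = synth_law(), seed = 1, table = NULL,
                                C = 36.12, band = c(9, 29), half_width = 5) {
  if (n_proteins < 1) abort("n_proteins must be >= 1", class = "admap_error_synth")
  table <- table %||% synth_table("two_class", seed = seed)
  withr::with_seed(seed, {
    per <- map(seq_len(n_proteins), function(p) {
      pid <- sprintf("synth%03d", p)
      n <- sample(length_range[1]:length_range[2], 1)
      s <- synth_segmented_sequence(n)
      adm <- build_adm(s, table, C, id = pid)
      rc <- residue_plot_counts(adm, band[1], band[2], half_width)
      p_dis <- law$prob(rc$smoothed_count)
      lab <- rbinom(n, 1, p_dis) == 1
      r <- rle(lab)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      list(
        sequence = tibble(protein_id = pid, sequence = paste(s, collapse = "")),
        annotation = tibble(
          protein_id = pid, start = starts, end = ends,
          label = ifelse(r$values, "disordered", "ordered")
        ),
        residues = tibble(
          protein_id = pid, index = rc$index,
          count = rc$smoothed_count, disordered = lab
        )
      )
    })
    list(
      sequences = list_rbind(map(per, "sequence")),
      annotations = list_rbind(map(per, "annotation")),
      residues = list_rbind(map(per, "residues"))
    )
  })
}
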