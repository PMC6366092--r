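test_that("per-residue plot counts respect the separation band", {
  empty <- adm_stub(30, tibble::tibble(i = integer(), j = integer()))
  expect_true(all(residue_plot_counts(empty)$raw_count == 0))
  ## (10, 25): separation 15 lies in the default band, counted at both ends
  one <- adm_stub(30, tibble::tibble(i = 10L, j = 25L))
  rc <- residue_plot_counts(one)
  expect_equal(rc$raw_count[c(10, 25)], c(1L, 1L))
  expect_equal(sum(rc$raw_count), 2L)
  ## (10, 12): separation 2 is below the band, counted nowhere
  near <- adm_stub(30, tibble::tibble(i = 10L, j = 12L))
  expect_true(all(residue_plot_counts(near)$raw_count == 0))
  expect_error(residue_plot_counts(one, k_lo = 0, k_hi = 5),
               class = "admap_error_band")
  expect_error(residue_plot_counts(one, k_lo = 9, k_hi = 9),
               class = "admap_error_band")
})

test_that("smoothing is the truncated-window mean", {
  expect_equal(smooth_profile(rep(3, 40)), rep(3, 40))
  ## impulse of 11 at the centre of an 11-point series spreads to 1.0
  imp <- c(rep(0, 5), 11, rep(0, 5))
  expect_equal(smooth_profile(imp)[6], 1.0)
  ## brute-force window oracle on a random series
  x <- withr::with_seed(4, rpois(50, 5))
  sm <- smooth_profile(x)
  oracle <- vapply(seq_along(x), function(ii) {
    mean(x[max(1, ii - 5):min(50, ii + 5)])
  }, 0)
  expect_equal(sm, oracle)
  ## interior windows of an 11-periodic series reproduce the series mean
  per <- rep(c(1, 4, 2, 8, 5, 7, 0, 3, 9, 6, 10), 4)
  sm_per <- smooth_profile(per)
  expect_equal(sm_per[6:39], rep(mean(per[1:11]), 34))
})

test_that("calibration bins are the exact per-bin disorder fractions", {
  ## deterministic step fixture: counts below 3 disordered, others not
  residues <- tibble::tibble(
    count = c(rep(0, 10), rep(1, 20), rep(2, 15), rep(5, 30), rep(6, 10),
              rep(7, 20), rep(8, 15)),
    disordered = c(rep(TRUE, 45), rep(FALSE, 75))
  )
  bins <- disorder_bins(residues)
  expect_equal(bins$frac[bins$count < 3], rep(1, 3))
  expect_equal(bins$frac[bins$count >= 3], rep(0, 4))
  ## unobserved bins are absent, not zero
  expect_false(any(bins$count %in% c(3, 4)))
  ## the fitted curve separates the classes at the 0.62 threshold
  curve <- fit_disorder_curve(bins)
  expect_true(all(curve_probability(curve, c(0, 1, 2)) >= 0.62))
  expect_true(all(curve_probability(curve, c(5, 6, 7, 8)) < 0.62))
})

test_that("an all-disordered pool yields a curve that is identically 1", {
  tab <- synth_table("two_class", seed = 2)
  train <- tibble::tibble(protein_id = "p1",
                          sequence = strrep("ACDEFGHIKL", 12))
  ann <- tibble::tibble(protein_id = "p1", start = 1L, end = 120L,
                        label = "disordered")
  curve <- calibrate_disorder(train, ann, tab, min_coverage = 0)
  expect_equal(curve$bins$frac, rep(1, nrow(curve$bins)))
  grid <- seq(curve$domain[1], curve$domain[2], length.out = 20)
  expect_equal(curve_probability(curve, grid), rep(1, 20))
})

test_that("proteins under the coverage rule are excluded from calibration", {
  tab <- synth_table("two_class", seed = 2)
  s1 <- strrep("ACDEFGHIKL", 12)
  s2 <- strrep("LKIHGFEDCA", 10)
  train <- tibble::tibble(protein_id = c("ok", "low"),
                          sequence = c(s1, s2))
  ann <- dplyr::bind_rows(
    tibble::tibble(protein_id = "ok", start = c(1L, 61L), end = c(60L, 120L),
                   label = c("disordered", "ordered")),
    ## 5% disordered coverage: excluded at the default 10% rule
    tibble::tibble(protein_id = "low", start = c(1L, 6L), end = c(5L, 100L),
                   label = c("disordered", "ordered"))
  )
  with_low <- calibrate_disorder(train, ann, tab)
  without_low <- calibrate_disorder(train[1, ], ann, tab)
  expect_equal(with_low$bins, without_low$bins)
  expect_equal(with_low$n_proteins, 1L)
  ## nothing admissible -> calibration error
  expect_error(
    calibrate_disorder(train[2, ], ann, tab),
    class = "admap_error_calibration"
  )
})

test_that("thresholding has boundary semantics and monotone subsets", {
  tab <- synth_table("two_class", seed = 5)
  set <- synth_annotated_set(3, c(100, 140), seed = 5, table = tab)
  curve <- calibrate_disorder(set$sequences, set$annotations, tab)
  s <- set$sequences$sequence[1]
  all_dis <- predict_disorder(s, tab, curve, theta = 0)
  expect_true(all(all_dis$label))
  only_certain <- predict_disorder(s, tab, curve, theta = 1)
  expect_equal(only_certain$label, only_certain$probability == 1)
  expect_error(predict_disorder(s, tab, curve, theta = 1.2),
               class = "admap_error_theta")
  ## disordered set at a higher threshold nests inside a lower one
  thetas <- seq(0, 1, by = 0.1)
  preds <- lapply(thetas, function(th) {
    predict_disorder(s, tab, curve, theta = th)$label
  })
  for (t2 in seq_along(thetas)[-1]) {
    expect_true(all(preds[[t2]] <= preds[[t2 - 1]]))
  }
  ## named presets resolve to the published thresholds
  expect_equal(attr(predict_disorder(s, tab, curve, theta = "accw"), "theta"),
               0.62)
  expect_equal(attr(predict_disorder(s, tab, curve, theta = "accp"), "theta"),
               0.53)
})

test_that("segment extraction inverts label expansion exactly", {
  for (seed in 1:5) {
    lab <- withr::with_seed(seed, runif(80) < 0.4)
    pred <- tibble::tibble(label = lab)
    seg <- disorder_segments(pred)
    expanded <- rep(FALSE, 80)
    for (r in seq_len(nrow(seg))) expanded[seg$start[r]:seg$end[r]] <- TRUE
    expect_equal(expanded, lab)
  }
})

test_that("tandem duplication doubles the length and preserves numbering", {
  tab <- synth_table("two_class", seed = 5)
  set <- synth_annotated_set(2, c(100, 120), seed = 6, table = tab)
  curve <- calibrate_disorder(set$sequences, set$annotations, tab)
  s <- set$sequences$sequence[1]
  n <- nchar(s)
  td <- predict_tandem(s, tab, curve)
  expect_equal(nrow(td$tandem), 2 * n)
  expect_equal(nrow(td$monomer), n)
  expect_equal(td$tandem$copy_index, rep(1:n, 2))
  expect_equal(td$tandem$residue[1:n], td$tandem$residue[(n + 1):(2 * n)])
})

test_that("junction-spanning statistics raise tandem counts over the monomer", {
  ## termini are order-prone (short pair distances), the middle is
  ## disorder-prone; within one copy the termini are 31+ residues apart,
  ## outside the counting band, so only the tandem junction pairs them
  ## at band separations
  tab <- synth_table("two_class", seed = 8)
  s <- c(rep("L", 10), rep("E", 30), rep("V", 10))
  ## a low C keeps the selection confined to the shortest-distance pairs
  adm_mono <- build_adm(s, tab, C = 10)
  adm_tand <- build_adm(c(s, s), tab, C = 10)
  rc_mono <- residue_plot_counts(adm_mono)
  rc_tand <- residue_plot_counts(adm_tand)
  n <- length(s)
  junction <- (n - 5):(n + 5)
  expect_gt(
    mean(rc_tand$raw_count[junction]),
    mean(rc_mono$raw_count[(n - 5):n])
  )
  ## cross-copy plots exist in the junction band
  cross <- adm_tand$plots$i <= n & adm_tand$plots$j > n &
    adm_tand$plots$k >= 9 & adm_tand$plots$k <= 29
  expect_gt(sum(cross), 0)
})

test_that("a sequence with no table statistics cannot be predicted on", {
  tab <- avg_dist_table(
    tibble::tibble(aa1 = "A", aa2 = "A", M = 1L, mean_distance = 6,
                   count = 50L),
    min_count = 10
  )
  ## all-X input has no significant entries in the monomer or the tandem
  expect_error(build_adm(strrep("X", 40), tab),
               class = "admap_error_no_statistics")
  expect_error(build_adm(strrep("G", 40), tab),
               class = "admap_error_no_statistics")
})
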