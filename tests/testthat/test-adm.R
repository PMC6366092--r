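test_that("target plot count realises round(C (N - 1) / 2)", {
  expect_equal(target_plot_count(2), 18L)
  expect_equal(target_plot_count(101), 1806L)
  expect_equal(target_plot_count(50, C = 0), 0L)
  expect_error(target_plot_count(1), class = "admap_error_adm")
})

test_that("the density-adjustment solver matches hand-solved cases", {
  ## one range: (D/1) * 100 = 50
  sol <- admap:::solve_density_scale(c(`1` = 100), 50)
  expect_equal(sol$D, 0.5)
  ## two ranges: (D + D/2) * 100 = 90
  sol2 <- admap:::solve_density_scale(c(`1` = 100, `2` = 100), 90)
  expect_equal(sol2$D, 0.6)
  ## D = M for a single range saturates at P(M)
  sol3 <- admap:::solve_density_scale(c(`3` = 40), 40)
  expect_equal(sol3$D, 3)
  expect_false(sol3$shortfall)
})

test_that("fit_plot_counts caps counts at P(M) and flags missing statistics", {
  ## only (A, A) significant in range 1; an all-A sequence of length 20
  tab <- avg_dist_table(
    tibble::tibble(
      aa1 = c("A", "A"), aa2 = c("A", "G"), M = c(1L, 1L),
      mean_distance = c(6, 6), count = c(50L, 1L)
    ),
    min_count = 10, max_M = 2
  )
  fit <- suppressWarnings(fit_plot_counts(strrep("A", 20), tab))
  p1 <- 8 * 20 - 36 # pairs with k in 1..8
  expect_equal(fit$counts$p_m, p1)
  ## target (343) exceeds the 124 available pairs: all plotted, warned
  expect_equal(fit$counts$p_m_c, p1)
  expect_warning(fit_plot_counts(strrep("A", 20), tab), "significant pairs")
  ## a sequence with no significant pairs at all
  expect_error(
    fit_plot_counts(strrep("G", 20), tab),
    class = "admap_error_no_statistics"
  )
})

test_that("build_adm plots the smallest-mean pairs per range", {
  ## 3-residue sequence with exactly one significant pair
  tab <- avg_dist_table(
    tibble::tibble(
      aa1 = c("A", "A", "C"), aa2 = c("C", "G", "G"), M = 1L,
      mean_distance = c(9, 5, 9), count = c(1L, 50L, 1L)
    ),
    min_count = 10, max_M = 1
  )
  adm <- suppressWarnings(build_adm("ACG", tab))
  expect_equal(nrow(adm$plots), 1L)
  expect_equal(adm$plots$i, 1L)
  expect_equal(adm$plots$j, 3L)
  expect_equal(adm$density, 1 / 3)
  ## recorded threshold reproduces the selection by strict inequality
  expect_true(adm$plots$mean_distance < adm$counts$threshold)
  ## zero target gives an empty map
  empty <- build_adm("ACG", tab, C = 0)
  expect_equal(nrow(empty$plots), 0L)
})

test_that("selection matches the brute-force smallest-distance oracle", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(30:60, 1)
      s <- sample(AA20, n, replace = TRUE)
      tab <- synth_table(sample(c("uniform", "two_class"), 1), seed = seed)
      adm <- suppressWarnings(build_adm(s, tab))
      oracle <- suppressWarnings(oracle_adm_plots(s, tab))
      expect_equal(adm$plots$i, oracle$i)
      expect_equal(adm$plots$j, oracle$j)
    })
  }
})

test_that("whole-map density tracks C/N over the study length range", {
  tab <- synth_table("uniform", seed = 5)
  for (n in c(60, 101, 150, 219)) {
    s <- withr::with_seed(n, sample(AA20, n, replace = TRUE))
    adm <- build_adm(s, tab)
    expect_lt(abs(adm$density * n - 36.12), 36.12 * 0.05)
  }
})

test_that("raising C only ever adds plots (nested selection)", {
  tab <- synth_table("uniform", seed = 6)
  s <- withr::with_seed(1, sample(AA20, 80, replace = TRUE))
  lo <- build_adm(s, tab, C = 20)
  hi <- build_adm(s, tab, C = 36.12)
  key_lo <- paste(lo$plots$i, lo$plots$j)
  key_hi <- paste(hi$plots$i, hi$plots$j)
  expect_true(all(key_lo %in% key_hi))
})

test_that("identical inputs give identical plot sets", {
  tab <- synth_table("uniform", seed = 7)
  s <- withr::with_seed(2, sample(AA20, 70, replace = TRUE))
  a1 <- build_adm(s, tab)
  a2 <- build_adm(s, tab)
  expect_identical(a1$plots, a2$plots)
})

test_that("plot ratios split short- and long-range plots over N", {
  ## 12 plots all at separation 3 on a 60-residue map
  adm <- adm_stub(60, tibble::tibble(i = 1:12, j = 4:15))
  pr <- plot_ratios(adm)
  expect_equal(pr$short_ratio, 0.2)
  expect_equal(pr$long_ratio, 0)
  ## empty map
  pr0 <- plot_ratios(adm_stub(60, tibble::tibble(i = integer(), j = integer())))
  expect_equal(pr0$short_ratio, 0)
  expect_equal(pr0$long_ratio, 0)
  ## whole-sequence interval is the identity
  expect_equal(plot_ratios(adm, c(1, 60)), pr)
  ## short + long = total / N
  adm2 <- random_map(80, 0.2, seed = 3)
  pr2 <- plot_ratios(adm2)
  expect_equal(pr2$short_ratio + pr2$long_ratio, nrow(adm2$plots) / 80)
  ## interval restriction counts only fully inside pairs
  pr_in <- plot_ratios(adm, c(5, 10))
  expect_equal(pr_in$n_short, sum(adm$plots$i >= 5 & adm$plots$j <= 10))
  expect_error(plot_ratios(adm, c(10, 5)), class = "admap_error_invalid_interval")
  expect_error(plot_ratios(adm, c(0, 5)), class = "admap_error_invalid_interval")
})
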