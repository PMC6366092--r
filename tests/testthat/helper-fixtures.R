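## Shared fixtures, all built in code at test time.

AA20 <- admap:::AA_STANDARD

## wrap a bare plot set into an adm object (for scan/count tests that
## need full control over the map)
adm_stub <- function(n, plots, sequence = NULL) {
  sequence <- sequence %||% rep("A", n)
  plots$k <- plots$j - plots$i
  plots$M <- if (nrow(plots)) range_index(plots$k, max_M = 99) else integer()
  plots$mean_distance <- rep(1, nrow(plots))
  admap:::new_adm(
    sequence, plots[, c("i", "j", "k", "M", "mean_distance")],
    counts = tibble::tibble(), N = n, C = NA_real_, D = NA_real_,
    target = nrow(plots)
  )
}

## uniform random upper-triangular map: each cell plotted with prob rho
random_map <- function(n, rho, seed) {
  withr::with_seed(seed, {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(ut)) < rho
    adm_stub(n, tibble::tibble(i = ut[keep, 1], j = ut[keep, 2]))
  })
}

## map with uniform background plus dense rectangular blocks on the
## diagonal; blocks is a list of c(start, end, density)
block_map <- function(n, background, blocks, seed) {
  withr::with_seed(seed, {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    p <- rep(background, nrow(ut))
    for (b in blocks) {
      inside <- ut[, 1] >= b[1] & ut[, 2] <= b[2]
      p[inside] <- b[3]
    }
    keep <- runif(nrow(ut)) < p
    adm_stub(n, tibble::tibble(i = ut[keep, 1], j = ut[keep, 2]))
  })
}

## independent brute-force oracle for ADM construction: per range, sort
## the significant candidate pairs by (mean distance, i, j) and take the
## first P(M)_C
oracle_adm_plots <- function(sequence, table, C = 36.12) {
  s <- strsplit(paste(sequence, collapse = ""), "")[[1]]
  n <- length(s)
  max_M <- attr(table, "max_M")
  min_count <- attr(table, "min_count")
  rows <- list()
  for (ii in 1:(n - 1)) {
    for (jj in (ii + 1):n) {
      k <- jj - ii
      m <- tryCatch(range_index(k, max_M), error = function(e) NA)
      if (is.na(m)) next
      a <- min(s[ii], s[jj])
      b <- max(s[ii], s[jj])
      hit <- table[table$aa1 == a & table$aa2 == b & table$M == m, ]
      if (nrow(hit) == 1 && hit$count >= min_count) {
        rows[[length(rows) + 1]] <-
          data.frame(i = ii, j = jj, M = m, d = hit$mean_distance)
      }
    }
  }
  cand <- do.call(rbind, rows)
  p_m <- table(cand$M)
  fit <- fit_plot_counts(s, table, C)
  out <- list()
  for (r in seq_len(nrow(fit$counts))) {
    m <- fit$counts$M[r]
    cm <- cand[cand$M == m, ]
    cm <- cm[order(cm$d, cm$i, cm$j), ]
    take <- utils::head(cm, fit$counts$p_m_c[r])
    out[[r]] <- take[, c("i", "j")]
  }
  sel <- do.call(rbind, out)
  sel[order(sel$i, sel$j), ]
}

## minimal hand-written PDB text
pdb_atom_line <- function(serial, resname, chain, resno, x, y, z,
                          alt = " ", name = "CA") {
  sprintf(
    "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    serial, name, alt, resname, chain, resno, x, y, z
  )
}

write_fixture_pdb <- function(path, resnames, coords, chain = "A",
                              extra_lines = NULL) {
  lines <- c(
    "HEADER    FIXTURE",
    vapply(seq_along(resnames), function(r) {
      pdb_atom_line(r, resnames[r], chain, r,
                    coords[r, 1], coords[r, 2], coords[r, 3])
    }, ""),
    extra_lines,
    "END"
  )
  writeLines(lines, path)
  path
}

`%||%` <- rlang::`%||%`
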