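## Readers and writers for every external format the package touches:
## FASTA and PDB input, and strict TSV schemas for the statistics table,
## ADM pair lists, scanning profiles, compact regions, predictions,
## annotations and the disorder curve. Every writer/reader pair
## round-trips bit-identically on valid data.

read_tsv_strict <- function(path, expected, col_types) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "admap_error_io")
  }
  out <- suppressWarnings(
    readr::read_tsv(path, col_types = col_types, comment = "#",
                    progress = FALSE)
  )
  if (!identical(names(out), expected)) {
    abort(
      paste0(
        "unexpected header in ", path, ": got [",
        paste(names(out), collapse = ", "), "], expected [",
        paste(expected, collapse = ", "), "]"
      ),
      class = "admap_error_io"
    )
  }
  out
}

#' Read a multi-record FASTA file
#'
#' @param path Path to a FASTA file (gzip transparent).
#' @return Tibble with columns `protein_id` (first header token),
#'   `description` (remainder of the header) and `sequence` (uppercase).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "admap_error_io")
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      abort(paste0("FASTA parse error in ", path, ": ", conditionMessage(e)),
            class = "admap_error_io")
    }
  )
  if (length(set) == 0) {
    abort(paste0("no records in ", path), class = "admap_error_io")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  for (s in seqs) check_sequence(seq_chars(s))
  tibble(protein_id = ids, description = desc, sequence = unname(seqs))
}

#' Write sequences as FASTA
#'
#' @param records Tibble with columns `protein_id`, `sequence` and
#'   optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) {
    records$description
  } else {
    rep("", nrow(records))
  }
  names(set) <- ifelse(
    is.na(desc) | desc == "",
    records$protein_id,
    paste(records$protein_id, desc)
  )
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Calpha trace from a PDB file
#'
#' Reads the Calpha atoms of one chain: first model only, first alternate
#' location only (blank or "A"), one atom per residue. Non-standard
#' residues (anything outside the 20 standard amino acids) are dropped
#' with a warning.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; default is the first chain in the file.
#' @return A [ca_trace()].
#' @export
read_pdb_ca <- function(path, chain = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "admap_error_io")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0) {
    abort(paste0("no Calpha atoms in ", path), class = "admap_error_io")
  }
  chain <- chain %||% at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) {
    abort(paste0("no Calpha atoms for chain '", chain, "' in ", path),
          class = "admap_error_io")
  }
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ## one Calpha per residue: keep the first occurrence of each
  ## (resno, insert) pair, in file order
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  at <- at[!duplicated(key), , drop = FALSE]
  standard3 <- c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
  )
  one <- suppressWarnings(bio3d::aa321(at$resid))
  bad <- !(at$resid %in% standard3) | !(one %in% AA_STANDARD)
  if (any(bad)) {
    warn(paste0(
      "dropping ", sum(bad), " non-standard residue(s) in ", path, ": ",
      paste(unique(at$resid[bad]), collapse = ", ")
    ))
    at <- at[!bad, , drop = FALSE]
    one <- one[!bad]
  }
  if (nrow(at) < 2) {
    abort(paste0("fewer than 2 standard Calpha residues in ", path),
          class = "admap_error_io")
  }
  ca_trace(one, at$x, at$y, at$z,
           id = paste0(sub("\\.pdb$", "", basename(path)), "_", chain))
}

#' Read/write the average distance statistics table
#'
#' TSV with header `aa1, aa2, M, mean_distance, count`, one row per
#' unordered residue-type pair per range.
#'
#' @param path File path.
#' @param min_count Significance cutoff attached to the table on read.
#' @return [avg_dist_table()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_distance_table <- function(path, min_count = 10) {
  out <- read_tsv_strict(
    path, c("aa1", "aa2", "M", "mean_distance", "count"),
    readr::cols(
      aa1 = readr::col_character(), aa2 = readr::col_character(),
      M = readr::col_integer(), mean_distance = readr::col_double(),
      count = readr::col_integer()
    )
  )
  avg_dist_table(out, min_count = min_count)
}

#' @rdname read_distance_table
#' @param table An [avg_dist_table()].
#' @export
write_distance_table <- function(table, path) {
  out <- tibble(
    aa1 = table$aa1, aa2 = table$aa2, M = table$M,
    mean_distance = table$mean_distance, count = table$count
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read/write interval annotations
#'
#' TSV with header `protein_id, start, end, label`; labels are
#' `"disordered"` or `"ordered"`, intervals 1-based inclusive. Reading
#' validates labels, interval orientation, and that the two classes do
#' not overlap within a protein.
#'
#' @param path File path.
#' @return Annotation tibble for the reader; `path` invisibly for the
#'   writer.
#' @export
read_annotations <- function(path) {
  out <- read_tsv_strict(
    path, c("protein_id", "start", "end", "label"),
    readr::cols(
      protein_id = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), label = readr::col_character()
    )
  )
  if (!all(out$label %in% c("disordered", "ordered"))) {
    abort("annotation labels must be 'disordered' or 'ordered'",
          class = "admap_error_annotation")
  }
  if (any(out$start < 1) || any(out$start > out$end)) {
    abort("annotation intervals must satisfy 1 <= start <= end",
          class = "admap_error_annotation")
  }
  ## per-protein class-overlap validation
  for (pid in unique(out$protein_id)) {
    ann <- out[out$protein_id == pid, , drop = FALSE]
    annotation_truth(ann, max(ann$end))
  }
  out
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations[, c("protein_id", "start", "end", "label")], path)
  invisible(path)
}

#' Read/write an ADM
#'
#' A single TSV: a metadata block of `#key=value` comment lines
#' (id, sequence, N, C, D, target and the per-range counts/thresholds),
#' then the plotted pair list `i, j, M, mean_distance`.
#'
#' @param path File path.
#' @return The `adm` for the reader; `path` invisibly for the writer.
#' @export
read_adm <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- setNames(
    map_chr(kv, function(p) paste(p[-1], collapse = "=")),
    map_chr(kv, 1)
  )
  pairs <- read_tsv_strict(
    path, c("i", "j", "M", "mean_distance"),
    readr::cols(
      i = readr::col_integer(), j = readr::col_integer(),
      M = readr::col_integer(), mean_distance = readr::col_double()
    )
  )
  counts_keys <- grep("^range_", names(meta), value = TRUE)
  counts <- map_dfr(counts_keys, function(key) {
    v <- as.numeric(strsplit(meta[[key]], ",", fixed = TRUE)[[1]])
    tibble(M = as.integer(sub("range_", "", key)),
           p_m = as.integer(v[1]), p_m_c = as.integer(v[2]),
           threshold = v[3], n_candidates = as.integer(v[4]))
  }) |> arrange(M)
  s <- seq_chars(meta[["sequence"]])
  plots <- pairs |> mutate(k = j - i, .after = j)
  new_adm(
    s, plots, counts,
    N = as.integer(meta[["N"]]), C = as.numeric(meta[["C"]]),
    D = as.numeric(meta[["D"]]), target = as.integer(meta[["target"]]),
    id = meta[["id"]]
  )
}

#' @rdname read_adm
#' @param adm An `adm` object.
#' @export
write_adm <- function(adm, path) {
  meta <- c(
    sprintf("#id=%s", adm$id),
    sprintf("#sequence=%s", adm$sequence),
    sprintf("#N=%d", adm$N),
    sprintf("#C=%.17g", adm$C),
    sprintf("#D=%.17g", adm$D),
    sprintf("#target=%d", adm$target),
    sprintf(
      "#range_%d=%d,%d,%.17g,%d",
      adm$counts$M, adm$counts$p_m, adm$counts$p_m_c,
      adm$counts$threshold, adm$counts$n_candidates
    )
  )
  body <- c(
    "i\tj\tM\tmean_distance",
    sprintf("%d\t%d\t%d\t%.17g",
            adm$plots$i, adm$plots$j, adm$plots$M, adm$plots$mean_distance)
  )
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Read/write a scanning profile
#'
#' TSV with header `i, delta_h, delta_v` (undefined divisions are `NA`).
#'
#' @param path File path.
#' @param profile An [adm_scan()] tibble.
#' @return Tibble for the reader; `path` invisibly for the writer.
#' @export
read_scan_profile <- function(path) {
  read_tsv_strict(
    path, c("i", "delta_h", "delta_v"),
    readr::cols(
      i = readr::col_integer(), delta_h = readr::col_double(),
      delta_v = readr::col_double()
    )
  )
}

#' @rdname read_scan_profile
#' @export
write_scan_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile)[, c("i", "delta_h", "delta_v")], path)
  invisible(path)
}

#' Read/write predicted compact regions
#'
#' TSV with header `start, end, eta`.
#'
#' @param path File path.
#' @param regions Output of [predict_compact_regions()].
#' @return Tibble for the reader; `path` invisibly for the writer.
#' @export
read_regions <- function(path) {
  read_tsv_strict(
    path, c("start", "end", "eta"),
    readr::cols(
      start = readr::col_integer(), end = readr::col_integer(),
      eta = readr::col_double()
    )
  )
}

#' @rdname read_regions
#' @export
write_regions <- function(regions, path) {
  readr::write_tsv(as_tibble(regions)[, c("start", "end", "eta")], path)
  invisible(path)
}

#' Write a disorder prediction
#'
#' Per-residue TSV (`index, residue, raw_count, smoothed_count,
#' probability, label`) via `write_prediction()`, and the disordered
#' segments in DisProt-like interval form (`protein_id, start, end,
#' label`) via `write_prediction_intervals()`.
#'
#' @param prediction A `disorder_prediction`.
#' @param path File path.
#' @return `path`, invisibly (reader returns the tibble).
#' @export
write_prediction <- function(prediction, path) {
  readr::write_tsv(
    as_tibble(prediction)[
      , c("index", "residue", "raw_count", "smoothed_count",
          "probability", "label")
    ],
    path
  )
  invisible(path)
}

#' @rdname write_prediction
#' @export
read_prediction <- function(path) {
  read_tsv_strict(
    path,
    c("index", "residue", "raw_count", "smoothed_count", "probability",
      "label"),
    readr::cols(
      index = readr::col_integer(), residue = readr::col_character(),
      raw_count = readr::col_integer(), smoothed_count = readr::col_double(),
      probability = readr::col_double(), label = readr::col_logical()
    )
  )
}

#' @rdname write_prediction
#' @export
write_prediction_intervals <- function(prediction, path) {
  seg <- disorder_segments(prediction)
  out <- tibble(
    protein_id = attr(prediction, "id") %||% "query",
    start = seg$start, end = seg$end, label = "disordered"
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read/write a calibrated disorder curve
#'
#' Text serialisation with a format-version tag: comment lines carry the
#' version, fit coefficients, degree and domain, followed by the TSV of
#' calibration bins (`count, n, frac`).
#'
#' @param path File path.
#' @param curve A `disorder_curve`.
#' @return The curve for the reader; `path` invisibly for the writer.
#' @export
write_disorder_curve <- function(curve, path) {
  lines <- c(
    "#admap_disorder_curve=1",
    sprintf("#degree=%d", curve$degree),
    sprintf("#coefficients=%s",
            paste(sprintf("%.17g", curve$coefficients), collapse = ",")),
    sprintf("#domain=%.17g,%.17g", curve$domain[1], curve$domain[2]),
    "count\tn\tfrac",
    sprintf("%.17g\t%d\t%.17g", curve$bins$count, curve$bins$n,
            curve$bins$frac)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_disorder_curve
#' @export
read_disorder_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- setNames(map_chr(kv, 2), map_chr(kv, 1))
  if (is.na(meta["admap_disorder_curve"])) {
    abort("not an admap disorder-curve file (missing format tag)",
          class = "admap_error_io")
  }
  bins <- read_tsv_strict(
    path, c("count", "n", "frac"),
    readr::cols(
      count = readr::col_double(), n = readr::col_integer(),
      frac = readr::col_double()
    )
  )
  structure(
    list(
      coefficients = as.numeric(
        strsplit(meta[["coefficients"]], ",", fixed = TRUE)[[1]]
      ),
      degree = as.integer(meta[["degree"]]),
      domain = as.numeric(strsplit(meta[["domain"]], ",", fixed = TRUE)[[1]]),
      bins = bins,
      n_residues = sum(bins$n)
    ),
    class = "disorder_curve"
  )
}

## documented configuration keys and their defaults
config_defaults <- function() {
  list(
    C = 36.12, max_M = 9L, min_count = 10L, band = c(9L, 29L),
    theta = "accw", half_width = 5L, fit_degree = 3L,
    min_height = 0.01, min_span = 20L, seed = 1L
  )
}

#' Read a run configuration file
#'
#' YAML key-value file; unknown keys are rejected. Documented keys (with
#' defaults): `C` (36.12), `max_M` (9), `min_count` (10), `band`
#' ([9, 29]), `theta` ("accw"), `half_width` (5), `fit_degree` (3),
#' `min_height` (0.01), `min_span` (20), `seed` (1).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Named list of effective configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- config_defaults()
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "admap_error_config")
  }
  modifyList(defaults, cfg)
}
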