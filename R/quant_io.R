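#' Column dialect for protein-group tables
#'
#' Quantification software disagrees on column headers, so the reader takes a
#' small dialect descriptor mapping the fields it needs onto the headers of
#' the file at hand. The default matches MaxQuant 1.3 `proteinGroups.txt`
#' (`"Ratio H/L normalized"`, `"Unique + razor peptides"`, ...). Set
#' `ratio = "Ratio H/L"` to feed raw rather than normalized ratios into the
#' significance analysis.
#'
#' Per-experiment ("wide") tables append an experiment suffix to the ratio,
#' intensity and peptide columns (e.g. `"Ratio H/L normalized F1"`); the
#' reader melts these to one record per (group, experiment). Long tables
#' instead carry an explicit experiment-id column named by `experiment`.
#'
#' @param group_id,accessions,gene_id,peptides,ratio,intensity_h,intensity_l
#'   Header names for the corresponding fields. `gene_id` may be `NA` when
#'   the table has no gene column.
#' @param experiment Header of the experiment-id column in long tables; `NA`
#'   means the table is wide (per-experiment column suffixes).
#' @return A named list of class `pg_dialect`.
#' @export
#' @examples
#' pg_dialect()
#' pg_dialect(ratio = "Ratio H/L") # raw rather than normalized ratios
pg_dialect <- function(group_id = "id",
                       accessions = "Majority protein IDs",
                       gene_id = "Gene names",
                       peptides = "Unique + razor peptides",
                       ratio = "Ratio H/L normalized",
                       intensity_h = "Intensity H",
                       intensity_l = "Intensity L",
                       experiment = NA_character_) {
  structure(
    list(
      group_id = group_id, accessions = accessions, gene_id = gene_id,
      peptides = peptides, ratio = ratio,
      intensity_h = intensity_h, intensity_l = intensity_l,
      experiment = experiment
    ),
    class = "pg_dialect"
  )
}

#' @rdname pg_dialect
#' @description `pg_dialect_native()` is the long dialect this package
#'   itself writes (e.g. by [cmd_simulate()]): explicit `experiment_id`
#'   column, snake_case headers.
#' @export
pg_dialect_native <- function() {
  pg_dialect(
    group_id = "group_id", accessions = "accessions", gene_id = "gene_id",
    peptides = "unique_razor_peptides", ratio = "ratio_hl",
    intensity_h = "intensity_h", intensity_l = "intensity_l",
    experiment = "experiment_id"
  )
}

# Read a delimited table, sniffing tab vs comma from the header line.
read_delim_auto <- function(path) {
  first <- readLines(con <- gzfile(path), n = 1L)
  close(con)
  if (length(first) == 0L) abort(sprintf("'%s' is empty", path))
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

parse_ratio_column <- function(x, path, column) {
  x[x %in% c("", "NaN", "NA", "nan")] <- NA_character_
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(val))
  if (length(bad) > 0L) {
    abort(sprintf(
      "non-numeric value '%s' in column '%s' of '%s' at row %d",
      x[bad[1L]], column, path, bad[1L]
    ))
  }
  val
}

parse_num_column <- function(x, path, column) {
  x[x == ""] <- NA_character_
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(val))
  if (length(bad) > 0L) {
    abort(sprintf(
      "non-numeric value '%s' in column '%s' of '%s' at row %d",
      x[bad[1L]], column, path, bad[1L]
    ))
  }
  val
}

#' Read a protein-group quantification table
#'
#' Reads a tab- or comma-separated protein-group table (MaxQuant
#' `proteinGroups`-like) into one record per (protein group, experiment).
#' Wide tables — per-experiment column suffixes such as
#' `"Ratio H/L normalized F1"` — are melted to long form; an experiment is
#' included for a group only when at least one of its per-experiment cells is
#' present. Empty or `NaN` ratio cells become absent ratios (`NA`), the
#' signal that a protein was detected in only one SILAC channel and must be
#' handled by presence/absence logic rather than ratio arithmetic. Ratios of
#' exactly 0 or `Inf` encode the same situation and are likewise coerced to
#' `NA` with a warning.
#'
#' @param path Path to the table (plain or gzip-compressed).
#' @param dialect A [pg_dialect()] describing the column headers.
#' @return A tibble with columns `group_id`, `accessions` (`;`-separated,
#'   first entry the representative), `gene_id`, `unique_razor_peptides`,
#'   `ratio_hl`, `intensity_h`, `intensity_l`, `experiment_id`.
#' @export
read_protein_groups <- function(path, dialect = pg_dialect()) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  stopifnot(inherits(dialect, "pg_dialect"))
  tbl <- read_delim_auto(path)

  mandatory <- c("group_id", "accessions", "peptides")
  for (f in mandatory) {
    if (!dialect[[f]] %in% names(tbl)) {
      abort(sprintf("mandatory column '%s' (%s) missing from '%s'",
                    dialect[[f]], f, path))
    }
  }

  wide <- is.na(dialect$experiment)
  if (wide) {
    out <- melt_wide_groups(tbl, dialect, path)
  } else {
    for (f in c("ratio", "intensity_h", "intensity_l", "experiment")) {
      if (!dialect[[f]] %in% names(tbl)) {
        abort(sprintf("mandatory column '%s' (%s) missing from '%s'",
                      dialect[[f]], f, path))
      }
    }
    out <- tibble::tibble(
      group_id = tbl[[dialect$group_id]],
      accessions = tbl[[dialect$accessions]],
      gene_id = if (!is.na(dialect$gene_id) && dialect$gene_id %in% names(tbl))
        tbl[[dialect$gene_id]] else NA_character_,
      unique_razor_peptides = parse_num_column(tbl[[dialect$peptides]], path,
                                               dialect$peptides),
      ratio_hl = parse_ratio_column(tbl[[dialect$ratio]], path, dialect$ratio),
      intensity_h = parse_num_column(tbl[[dialect$intensity_h]], path,
                                     dialect$intensity_h),
      intensity_l = parse_num_column(tbl[[dialect$intensity_l]], path,
                                     dialect$intensity_l),
      experiment_id = tbl[[dialect$experiment]]
    )
  }

  dup <- duplicated(out[, c("group_id", "experiment_id")])
  if (any(dup)) {
    d <- out[which(dup)[1L], ]
    abort(sprintf("duplicate record for group '%s' in experiment '%s'",
                  d$group_id, d$experiment_id))
  }
  if (any(out$accessions == "" | is.na(out$accessions))) {
    abort("record with empty accession list")
  }
  bad_ratio <- !is.na(out$ratio_hl) &
    (out$ratio_hl == 0 | is.infinite(out$ratio_hl))
  if (any(bad_ratio)) {
    warn(sprintf(
      "%d ratio(s) of exactly 0 or Inf coerced to absent (single-channel detection)",
      sum(bad_ratio)
    ))
    out$ratio_hl[bad_ratio] <- NA_real_
  }
  out$unique_razor_peptides <- as.integer(out$unique_razor_peptides)
  out$intensity_h[is.na(out$intensity_h)] <- 0
  out$intensity_l[is.na(out$intensity_l)] <- 0
  out
}

# Melt per-experiment suffixed columns ("Ratio H/L normalized F1", ...) into
# long records. Experiments are discovered from suffixes of the ratio column.
melt_wide_groups <- function(tbl, dialect, path) {
  ratio_rx <- paste0("^", escape_rx(dialect$ratio), " (.+)$")
  ratio_cols <- grep(ratio_rx, names(tbl), value = TRUE)
  if (length(ratio_cols) == 0L) {
    abort(sprintf(
      "mandatory column '%s' missing from '%s': no per-experiment columns '%s <exp>' and no experiment column declared",
      dialect$ratio, path, dialect$ratio
    ))
  }
  exps <- sub(ratio_rx, "\\1", ratio_cols)
  pieces <- lapply(exps, function(e) {
    pick <- function(base) {
      nm <- paste(base, e)
      if (nm %in% names(tbl)) tbl[[nm]] else rep(NA_character_, nrow(tbl))
    }
    pep_cells <- pick(dialect$peptides)
    if (all(is.na(pep_cells))) pep_cells <- tbl[[dialect$peptides]]
    tibble::tibble(
      group_id = tbl[[dialect$group_id]],
      accessions = tbl[[dialect$accessions]],
      gene_id = if (!is.na(dialect$gene_id) && dialect$gene_id %in% names(tbl))
        tbl[[dialect$gene_id]] else NA_character_,
      unique_razor_peptides = parse_num_column(pep_cells, path, dialect$peptides),
      ratio_hl = parse_ratio_column(pick(dialect$ratio), path,
                                    paste(dialect$ratio, e)),
      intensity_h = parse_num_column(pick(dialect$intensity_h), path,
                                     paste(dialect$intensity_h, e)),
      intensity_l = parse_num_column(pick(dialect$intensity_l), path,
                                     paste(dialect$intensity_l, e)),
      experiment_id = e
    )
  })
  out <- dplyr::bind_rows(pieces)
  # keep only (group, experiment) cells with any evidence
  seen <- !is.na(out$ratio_hl) |
    (!is.na(out$intensity_h) & out$intensity_h > 0) |
    (!is.na(out$intensity_l) & out$intensity_l > 0)
  out <- out[seen, , drop = FALSE]
  dplyr::arrange(out, .data$experiment_id)
}

escape_rx <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Read and validate an experiment-design table
#'
#' The design maps each experiment id to its affinity resin, labelling
#' orientation (`tagged_heavy` when the tagged cell line was grown in heavy
#' SILAC medium, `tagged_light` for the reciprocal labelling), replicate
#' index and bait accession. A reciprocal pair exists for a resin when both
#' orientations occur; designs without any reciprocal pair are valid but
#' flagged with a warning, since single-orientation evidence caps confidence.
#'
#' @param path Tab- or comma-separated file with header columns
#'   `experiment_id`, `resin`, `orientation`, `replicate`, `bait_accession`
#'   and optionally `is_control_only`.
#' @return A tibble of the design with attribute `"reciprocal_resins"` (the
#'   resins having both orientations).
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  tbl <- read_delim_auto(path)
  needed <- c("experiment_id", "resin", "orientation", "replicate",
              "bait_accession")
  miss <- setdiff(needed, names(tbl))
  if (length(miss) > 0L) {
    abort(sprintf("design is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  design <- tibble::tibble(
    experiment_id = tbl$experiment_id,
    resin = tbl$resin,
    orientation = tbl$orientation,
    replicate = as.integer(tbl$replicate),
    bait_accession = tbl$bait_accession,
    is_control_only = if ("is_control_only" %in% names(tbl))
      tolower(tbl$is_control_only) %in% c("true", "1", "yes") else FALSE
  )
  validate_design(design)
}

#' Validate an experiment design
#'
#' Checks the invariants [read_design()] promises: unique experiment ids,
#' known orientation tokens, positive replicate indices. Usable directly on
#' designs built in code (e.g. by [simulate_dataset()]).
#'
#' @param design A design tibble.
#' @return The design, invisibly augmented with the `"reciprocal_resins"`
#'   attribute.
#' @export
validate_design <- function(design) {
  bad <- setdiff(unique(design$orientation), ORIENTATIONS)
  if (length(bad) > 0L) {
    abort(sprintf("unknown orientation '%s'; allowed: %s",
                  bad[1L], paste(ORIENTATIONS, collapse = ", ")))
  }
  dup <- duplicated(design$experiment_id)
  if (any(dup)) {
    abort(sprintf("duplicate experiment_id '%s' in design",
                  design$experiment_id[which(dup)[1L]]))
  }
  if (any(is.na(design$replicate) | design$replicate < 1L)) {
    abort("replicate indices must be positive integers")
  }
  per_resin <- dplyr::summarise(
    dplyr::group_by(design[!design$is_control_only, ], .data$resin),
    both = all(ORIENTATIONS %in% .data$orientation), .groups = "drop"
  )
  recip <- per_resin$resin[per_resin$both]
  if (length(recip) == 0L) {
    warn("design has no reciprocal labelling pairs")
  }
  attr(design, "reciprocal_resins") <- recip
  design
}

#' Read a FASTA proteome
#'
#' Parses accessions from the first whitespace-delimited header token,
#' unwrapping the UniProt `db|ACC|NAME` convention when present. Sequences
#' containing letters outside the 20 canonical amino acids are kept but
#' flagged `nonstandard`; a header with an empty sequence is an error.
#'
#' @param path FASTA file (plain or gzipped).
#' @return Tibble with columns `accession`, `description`, `sequence`,
#'   `nonstandard`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) abort(sprintf("FASTA '%s' contains no records", path))
  headers <- names(aa)
  first_tok <- sub("\\s.*$", "", headers)
  acc <- ifelse(grepl("^[^|]+\\|[^|]+\\|", first_tok),
                sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", first_tok),
                first_tok)
  seqs <- unname(toupper(as.character(aa)))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    abort(sprintf("FASTA record '%s' has an empty sequence", acc[empty[1L]]))
  }
  tibble::tibble(
    accession = acc,
    description = sub("^\\S+\\s*", "", headers),
    sequence = seqs,
    nonstandard = grepl(sprintf("[^%s]", AA_CANONICAL), seqs)
  )
}

verdict_columns <- c(
  "protein", "verdict", "confidence", "in_beadome",
  "n_resins_significant", "n_experiments_significant",
  "n_experiments_observed", "mean_log2_enrichment"
)

#' Write / read an interaction-verdict report
#'
#' Tab-separated, UTF-8, one row per protein in a deterministic order:
#' verdict class (bait first, then genuine, tag-specific artefact,
#' non-specific, insufficient data), then confidence, then accession.
#'
#' @param verdicts Verdict tibble from [ipac_classify()].
#' @param path Output path.
#' @return `write_verdicts()` returns `path` invisibly; `read_verdicts()`
#'   returns the tibble.
#' @export
write_verdicts <- function(verdicts, path) {
  out <- verdicts[, intersect(verdict_columns, names(verdicts))]
  ord <- order(match(out$verdict, rev(VERDICT_CLASSES)),
               match(out$confidence, CONFIDENCE_LEVELS),
               out$protein)
  readr::write_tsv(out[ord, ], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_verdicts
#' @export
read_verdicts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    protein = readr::col_character(),
                    verdict = readr::col_character(),
                    confidence = readr::col_character(),
                    in_beadome = readr::col_logical(),
                    .default = readr::col_double()
                  ))
}

#' Write / read a beadome table
#'
#' Tab-separated contaminant list: accession, observed resins
#' (`;`-separated), resin count, abundome membership. Rows are sorted by
#' descending resin count then accession.
#'
#' @param entries Beadome tibble from [build_beadome()].
#' @param path Output path.
#' @export
write_beadome <- function(entries, path) {
  out <- tibble::tibble(
    accession = entries$accession,
    resins_observed = vapply(entries$resins_observed, paste,
                             character(1), collapse = ";"),
    n_resins = entries$n_resins,
    in_abundome = entries$in_abundome
  )
  out <- out[order(-out$n_resins, out$accession), ]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_beadome
#' @export
read_beadome <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           accession = readr::col_character(),
                           resins_observed = readr::col_character(),
                           n_resins = readr::col_integer(),
                           in_abundome = readr::col_logical()
                         ))
  tbl$resins_observed <- strsplit(tbl$resins_observed, ";", fixed = TRUE)
  tbl
}
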