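# In-code fixtures shared across test files.

# Write a MaxQuant-style wide proteinGroups table and return its path.
write_wide_pg <- function(rows, experiments = c("F1", "F2"),
                          dir = withr::local_tempdir(.local_envir = parent.frame())) {
  header <- c("id", "Majority protein IDs", "Gene names",
              "Unique + razor peptides",
              unlist(lapply(experiments, function(e) {
                c(paste("Ratio H/L normalized", e),
                  paste("Intensity H", e), paste("Intensity L", e))
              })))
  path <- file.path(dir, "proteinGroups.txt")
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

# Minimal long-format (native dialect) protein-group table on disk.
write_native_pg <- function(tbl, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "pg.tsv")
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

write_design_file <- function(design, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "design.tsv")
  readr::write_tsv(design, path, progress = FALSE)
  path
}

# Standard 2-resin x 2-orientation x n-replicate design.
make_design <- function(resins = c("FLAG", "TALON"), replicates = 2,
                        bait = "BAIT1") {
  g <- expand.grid(replicate = seq_len(replicates),
                   orientation = c("tagged_heavy", "tagged_light"),
                   resin = resins, stringsAsFactors = FALSE)
  tibble::tibble(
    experiment_id = sprintf("%s_%s_r%d", g$resin,
                            ifelse(g$orientation == "tagged_heavy", "TH", "TL"),
                            g$replicate),
    resin = g$resin,
    orientation = g$orientation,
    replicate = g$replicate,
    bait_accession = bait,
    is_control_only = FALSE
  )
}

# Build a protein-group record tibble directly (native long form).
make_records <- function(protein, experiment_id, ratio_hl,
                         peptides = 3L, intensity_h = 1e6, intensity_l = 1e6) {
  tibble::tibble(
    group_id = protein, accessions = protein,
    gene_id = paste0("G_", protein),
    unique_razor_peptides = as.integer(peptides),
    ratio_hl = ratio_hl,
    intensity_h = intensity_h, intensity_l = intensity_l,
    experiment_id = experiment_id
  )
}

# Significance-call rows built directly (for classifier-level tests).
make_calls <- function(protein, experiment_id, status, log2e = NA_real_) {
  quant <- !status %in% c("exclusive_tagged", "exclusive_control",
                          "unquantified")
  l2 <- ifelse(is.na(log2e) & quant, 0.5, log2e)
  l2[!quant] <- NA_real_
  tibble::tibble(
    protein = protein, experiment_id = experiment_id,
    status = factor(status, levels = ipac:::CALL_STATUSES),
    z_distance = ifelse(quant, 1.5, NA_real_),
    k_used = 1, log2_enrichment = l2, peptides = 3L
  )
}

# Independent brute-force decision table over raw per-experiment statuses.
# Deliberately written from the rule text, not via summarize_resin().
oracle_verdict <- function(status_by_resin, is_bait = FALSE,
                           min_sig = 1L, consistent = FALSE) {
  if (is_bait) return("bait")
  sig_n <- vapply(status_by_resin, function(s)
    sum(s %in% c("significant_enriched", "exclusive_tagged")), integer(1))
  near_n <- vapply(status_by_resin, function(s)
    sum(s %in% c("not_significant", "significant_depleted",
                 "exclusive_control")), integer(1))
  obs_n <- vapply(status_by_resin, function(s)
    sum(s != "unquantified"), integer(1))
  floor_n <- if (consistent) {
    pmax(min_sig, floor(obs_n / 2) + 1L)
  } else {
    rep(min_sig, length(obs_n))
  }
  supports <- obs_n > 0L & sig_n >= floor_n
  if (sum(supports) >= 2L) return("genuine")
  if (any(sig_n >= 1L) && any(near_n >= 1L & sig_n == 0L)) {
    return("tag_specific_artefact")
  }
  if (any(near_n >= 1L) && !any(sig_n >= 1L)) return("non_specific")
  "insufficient_data"
}

# Random amino-acid sequence over the canonical alphabet.
random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
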