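#' Minimum-peptide quantification filter
#'
#' Retains protein-group records supported by at least `min_peptides` unique
#' plus razor peptides (default 2, the conventional floor for trustworthy
#' SILAC quantification). Dropped records are reported via a message.
#'
#' @param records Protein-group tibble from [read_protein_groups()].
#' @param min_peptides Minimum unique+razor peptide count to keep.
#' @return The filtered tibble.
#' @export
quantification_filter <- function(records, min_peptides = 2L) {
  keep <- records$unique_razor_peptides >= min_peptides
  if (any(!keep)) {
    inform(sprintf("quantification_filter: dropped %d record(s) with < %d unique+razor peptides",
                   sum(!keep), min_peptides))
  }
  records[keep, , drop = FALSE]
}

#' Orient H/L ratios onto the tagged/control axis
#'
#' SILAC channel assignment alternates between reciprocal labellings, so raw
#' H/L ratios from a `tagged_light` experiment point the "wrong" way. This
#' puts every experiment on a common axis: `log2_enrichment = log2(H/L)`
#' when the tagged line was grown heavy, `-log2(H/L)` when grown light, so
#' positive values always mean enrichment with the tagged bait.
#'
#' Records without a ratio are candidates for exclusive detection: when
#' intensity is present only in the tagged channel and the record carries at
#' least `exclusive_min_peptides` peptides it becomes `exclusive_tagged`
#' (the strongest possible qualitative evidence — the control channel gave
#' no signal at all); only in the control channel, `exclusive_control`;
#' anything else is `unquantified`.
#'
#' @param records Filtered protein-group tibble.
#' @param design Experiment design (see [read_design()]).
#' @param exclusive_min_peptides Peptide floor for presence/absence calls.
#' @return Tibble with one row per record: `protein`, `experiment_id`,
#'   `log2_enrichment`, `quantified`, `exclusive_tagged`,
#'   `exclusive_control`, `peptides`.
#' @export
orient_ratios <- function(records, design, exclusive_min_peptides = 2L) {
  unknown <- setdiff(unique(records$experiment_id), design$experiment_id)
  if (length(unknown) > 0L) {
    abort(sprintf("experiment '%s' not in design", unknown[1L]))
  }
  x <- dplyr::left_join(records,
                        design[, c("experiment_id", "orientation")],
                        by = "experiment_id")
  sign <- ifelse(x$orientation == "tagged_heavy", 1, -1)
  quant <- !is.na(x$ratio_hl)
  log2e <- ifelse(quant, sign * log2(x$ratio_hl), NA_real_)

  tagged_int <- ifelse(x$orientation == "tagged_heavy",
                       x$intensity_h, x$intensity_l)
  control_int <- ifelse(x$orientation == "tagged_heavy",
                        x$intensity_l, x$intensity_h)
  pep_ok <- x$unique_razor_peptides >= exclusive_min_peptides
  excl_tag <- !quant & pep_ok & tagged_int > 0 & control_int == 0
  excl_ctl <- !quant & pep_ok & control_int > 0 & tagged_int == 0

  tibble::tibble(
    protein = first_accession(x$accessions),
    experiment_id = x$experiment_id,
    log2_enrichment = log2e,
    quantified = quant,
    exclusive_tagged = excl_tag,
    exclusive_control = excl_ctl,
    peptides = x$unique_razor_peptides
  )
}

first_accession <- function(accessions) sub(";.*$", "", accessions)

#' Per-experiment log2 ratio distribution statistics
#'
#' The significance call is relative: a protein is interesting when its
#' oriented log2 enrichment sits far from the bulk of the experiment's
#' distribution, which is dominated by non-specific binders centred near 0.
#' This computes, per experiment, the median, standard deviation (sample,
#' `n - 1`, by default; population `n` on request) and MAD (scaled by the
#' usual 1.4826 so it estimates the SD under normality) over quantified
#' proteins only.
#'
#' @param oriented Oriented-ratio tibble from [orient_ratios()].
#' @param min_stats_n Minimum quantified proteins per experiment; fewer is
#'   an error, since the median/SD would be meaningless.
#' @param population_sd Use the `n` denominator instead of `n - 1`.
#' @return Tibble with one row per experiment: `experiment_id`,
#'   `n_quantified`, `median_log2`, `sd_log2`, `mad_log2`.
#' @export
distribution_stats <- function(oriented, min_stats_n = 10L,
                               population_sd = FALSE) {
  q <- oriented[oriented$quantified, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(q, .data$experiment_id),
    n_quantified = dplyr::n(),
    median_log2 = median(.data$log2_enrichment),
    sd_log2 = sd(.data$log2_enrichment),
    mad_log2 = mad(.data$log2_enrichment),
    .groups = "drop"
  )
  if (population_sd) {
    out$sd_log2 <- out$sd_log2 * sqrt((out$n_quantified - 1) / out$n_quantified)
  }
  out$sd_log2[out$n_quantified == 1L] <- 0
  low <- out$experiment_id[out$n_quantified < min_stats_n]
  missing <- setdiff(unique(oriented$experiment_id), out$experiment_id)
  low <- c(low, missing)
  if (length(low) > 0L) {
    abort(sprintf(
      "insufficient distribution: experiment(s) %s have fewer than %d quantified proteins",
      paste(sort(low), collapse = ", "), min_stats_n
    ))
  }
  if (any(out$sd_log2 == 0)) {
    warn("degenerate ratio distribution (SD = 0); significance calls will be impossible")
  }
  out
}

#' Call per-experiment significance
#'
#' A quantified protein is significant in an experiment when its oriented
#' log2 enrichment lies more than `k` scale units from the experiment
#' median (the classical "ratio beyond +/- k SD of the median" rule; `k = 1`
#' is the permissive default, `k = 2` the stricter call). The distance
#' `z = |log2_enrichment - median| / scale` is reported for every
#' quantified protein. With `robust = TRUE` the scale is the scaled MAD
#' instead of the SD, which resists the heavy tails that genuine
#' interactors and artefacts add to the distribution. Exclusive detections
#' pass through as their own statuses and carry no z-distance.
#'
#' @param oriented Oriented-ratio tibble.
#' @param stats Per-experiment statistics from [distribution_stats()].
#' @param k Significance threshold in scale units (> 0).
#' @param robust Use the MAD-based scale instead of the SD.
#' @return Tibble: `protein`, `experiment_id`, `status`, `z_distance`,
#'   `k_used`, `log2_enrichment`, `peptides`.
#' @export
call_significance <- function(oriented, stats, k = 1, robust = FALSE) {
  stopifnot(k > 0)
  x <- dplyr::left_join(oriented, stats, by = "experiment_id")
  scale <- if (robust) x$mad_log2 else x$sd_log2
  if (any(is.na(scale) & x$quantified)) {
    abort("stats are missing for some experiments present in the calls")
  }
  zero_scale <- !is.na(scale) & scale == 0
  if (any(zero_scale & x$quantified)) {
    warn("scale is 0 in some experiment(s); quantified proteins there are not_significant")
  }
  z <- ifelse(x$quantified & scale > 0,
              abs(x$log2_enrichment - x$median_log2) / scale, NA_real_)
  status <- dplyr::case_when(
    x$exclusive_tagged ~ "exclusive_tagged",
    x$exclusive_control ~ "exclusive_control",
    !x$quantified ~ "unquantified",
    !is.na(z) & z > k & x$log2_enrichment > x$median_log2 ~ "significant_enriched",
    !is.na(z) & z > k ~ "significant_depleted",
    TRUE ~ "not_significant"
  )
  tibble::tibble(
    protein = x$protein,
    experiment_id = x$experiment_id,
    status = factor(status, levels = CALL_STATUSES),
    z_distance = z,
    k_used = k,
    log2_enrichment = x$log2_enrichment,
    peptides = x$peptides
  )
}
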