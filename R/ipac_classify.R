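#' Classifier configuration
#'
#' Tunable rules for combining per-experiment significance calls into a
#' cross-resin verdict.
#'
#' @param min_sig_per_resin Significant (enriched or exclusive-tagged)
#'   experiments a resin must contribute before it supports a genuine call.
#'   The default 1 is permissive: a single significant replicate per resin
#'   suffices.
#' @param consistent Majority mode: a resin supports a genuine call only
#'   when significant in a majority (> half) of its observed experiments.
#'   Trades sensitivity for a much lower false-genuine rate.
#' @param frac_high,frac_med Per-resin significant fractions (of observed
#'   experiments) required in every resin for high and medium confidence.
#' @param match_on `"accession"` or `"gene"`: how beadome membership is
#'   matched in [beadome_flag()].
#' @return A named list of class `ipac_config`.
#' @export
ipac_config <- function(min_sig_per_resin = 1L, consistent = FALSE,
                        frac_high = 0.75, frac_med = 0.5,
                        match_on = c("accession", "gene")) {
  stopifnot(min_sig_per_resin >= 1L, frac_high > frac_med, frac_med > 0)
  structure(
    list(min_sig_per_resin = as.integer(min_sig_per_resin),
         consistent = isTRUE(consistent),
         frac_high = frac_high, frac_med = frac_med,
         match_on = match.arg(match_on)),
    class = "ipac_config"
  )
}

#' Summarise significance calls for one protein on one resin
#'
#' Aggregates the per-experiment calls a single (protein, resin) pair
#' accumulated across replicates and reciprocal labellings. "Significant"
#' counts enriched and exclusive-tagged calls; depleted and
#' exclusive-control calls are tallied separately (the model treats only
#' enrichment with the tagged bait as specific); quantified-but-unremarkable
#' calls are "near one".
#'
#' @param calls Significance-call tibble rows for one protein and one resin.
#' @param design Experiment design (provides resin and orientation).
#' @return One-row tibble: `resin`, `n_experiments`, `n_significant`,
#'   `n_near_one`, `n_depleted`, `n_unobserved`, `orientations_supporting`
#'   (list column), `mean_log2_enrichment`.
#' @export
summarize_resin <- function(calls, design) {
  x <- dplyr::left_join(calls,
                        design[, c("experiment_id", "resin", "orientation")],
                        by = "experiment_id")
  if (nrow(x) == 0L) abort("summarize_resin: no calls supplied")
  if (length(unique(x$protein)) > 1L) {
    abort("summarize_resin: calls span more than one protein")
  }
  if (length(unique(x$resin)) > 1L) {
    abort("summarize_resin: calls span more than one resin")
  }
  dplyr::bind_cols(tibble::tibble(resin = x$resin[1L]),
                   evidence_counts(x$status, x$orientation, x$log2_enrichment))
}

# Shared evidence-count definitions for one (protein, resin) cell.
evidence_counts <- function(status, orientation, log2_enrichment) {
  status <- as.character(status)
  sig <- status %in% c("significant_enriched", "exclusive_tagged")
  quantified <- !is.na(log2_enrichment)
  tibble::tibble(
    n_experiments = length(status),
    n_significant = sum(sig),
    n_near_one = sum(status == "not_significant"),
    n_depleted = sum(status %in% c("significant_depleted", "exclusive_control")),
    n_unobserved = sum(status == "unquantified"),
    orientations_supporting = list(sort(unique(orientation[sig]))),
    mean_log2_enrichment = if (any(quantified))
      mean(log2_enrichment[quantified]) else NA_real_
  )
}

majority <- function(n) floor(n / 2) + 1L

# Does this resin's evidence support a genuine call under the config?
resin_supports <- function(ev, config) {
  n_obs <- ev$n_experiments - ev$n_unobserved
  floor <- if (config$consistent) {
    pmax(config$min_sig_per_resin, majority(n_obs))
  } else {
    config$min_sig_per_resin
  }
  n_obs > 0L & ev$n_significant >= floor
}

#' Classify one protein from its per-resin evidence
#'
#' The decision order embodies the parallel-capture logic: (1) the declared
#' bait is always reported as such; (2) a protein significant on two or more
#' independent resins is a genuine partner — agreement between unrelated
#' resin chemistries is the core specificity guarantee; (3) significant or
#' exclusive with one resin while sitting quietly at ratio ~ 1 on another
#' is the tag-specific-artefact signature that single-tag experiments
#' cannot detect (depleted calls count as near-one here); (4) quantified
#' somewhere with no significant call anywhere is a non-specific binder;
#' (5) anything else — e.g. significant on one resin and entirely unseen on
#' the rest — is insufficient data. A protein significant on >= 2 resins
#' that is also near-one on a third is still called genuine (multi-resin
#' support dominates) with a warning.
#'
#' @param evidence Tibble of [summarize_resin()] rows, one per resin, for a
#'   single protein.
#' @param config An [ipac_config()].
#' @param is_bait Whether this protein is the declared bait.
#' @return The verdict string: `"bait"`, `"genuine"`,
#'   `"tag_specific_artefact"`, `"non_specific"` or `"insufficient_data"`.
#' @export
classify_protein <- function(evidence, config = ipac_config(),
                             is_bait = FALSE) {
  if (nrow(evidence) == 0L ||
      all(evidence$n_experiments == evidence$n_unobserved)) {
    abort("classify_protein: protein has no observed experiment on any resin")
  }
  if (is_bait) return("bait")

  supporting <- resin_supports(evidence, config)
  near <- evidence$n_near_one + evidence$n_depleted
  any_sig <- evidence$n_significant >= 1L
  if (sum(supporting) >= 2L) {
    if (any(near >= 1L & !any_sig)) {
      warn("protein(s) significant on >= 2 resins but near 1 on another; calling genuine",
           .frequency = "once", .frequency_id = "ipac_genuine_tie")
    }
    return("genuine")
  }
  if (any(any_sig) && any(near >= 1L & evidence$n_significant == 0L)) {
    return("tag_specific_artefact")
  }
  if (any(near >= 1L) && !any(any_sig)) {
    return("non_specific")
  }
  "insufficient_data"
}

#' Rank the confidence of a genuine verdict
#'
#' Confidence reflects how reproducible the enrichment was across
#' replicates, reciprocal labellings and resins. With per-resin significant
#' fraction f = significant / observed experiments: **high** requires
#' f >= `frac_high` in every resin *and* both labelling orientations
#' contributing significant calls on at least one resin; **medium**
#' requires f >= `frac_med` in every resin (or the high fractions with only
#' one orientation supporting); **low** is a genuine call that only meets
#' the floor.
#'
#' @param evidence Per-resin evidence tibble for one protein.
#' @param verdict Its verdict string.
#' @param config An [ipac_config()].
#' @return `"high"`, `"medium"`, `"low"`, or `"not_applicable"` for
#'   non-genuine verdicts.
#' @export
rank_confidence <- function(evidence, verdict, config = ipac_config()) {
  if (!identical(verdict, "genuine")) return("not_applicable")
  n_obs <- evidence$n_experiments - evidence$n_unobserved
  frac <- ifelse(n_obs > 0, evidence$n_significant / n_obs, 0)
  dual <- any(vapply(evidence$orientations_supporting,
                     function(o) length(o) >= 2L, logical(1)))
  if (all(frac >= config$frac_high) && dual) return("high")
  if (all(frac >= config$frac_med)) return("medium")
  "low"
}

#' Classify every protein in a called dataset
#'
#' Runs [summarize_resin()], [classify_protein()] and [rank_confidence()]
#' over all proteins in a significance-call table. Control-only experiments
#' in the design are excluded from verdict evidence (they feed the beadome
#' instead). Bait accessions are taken from the design.
#'
#' @param calls Significance-call tibble from [call_significance()].
#' @param design Experiment design.
#' @param config An [ipac_config()].
#' @return Verdict tibble: `protein`, `verdict`, `confidence`,
#'   `in_beadome` (initialised `FALSE`; see [beadome_flag()]), summary
#'   counts, and a list column `per_resin` of evidence tibbles.
#' @export
ipac_classify <- function(calls, design, config = ipac_config()) {
  design <- design[!design$is_control_only, , drop = FALSE]
  calls <- calls[calls$experiment_id %in% design$experiment_id, , drop = FALSE]
  baits <- unique(design$bait_accession)
  x <- dplyr::left_join(
    calls, design[, c("experiment_id", "resin", "orientation")],
    by = "experiment_id"
  )
  # Vectorised (protein, resin) aggregation; definitions mirror
  # evidence_counts()/summarize_resin(), which tests hold as the reference.
  st <- as.character(x$status)
  sig <- st %in% c("significant_enriched", "exclusive_tagged")
  key <- paste(as.integer(factor(x$protein)),
               as.integer(factor(x$resin)), sep = "_")
  ind <- cbind(
    n_experiments = 1,
    n_significant = sig,
    n_near_one = st == "not_significant",
    n_depleted = st %in% c("significant_depleted", "exclusive_control"),
    n_unobserved = st == "unquantified",
    sig_th = sig & x$orientation == "tagged_heavy",
    sig_tl = sig & x$orientation == "tagged_light",
    l2_sum = ifelse(is.na(x$log2_enrichment), 0, x$log2_enrichment),
    l2_n = !is.na(x$log2_enrichment)
  )
  agg <- rowsum(ind, key)
  rep_row <- match(rownames(agg), key)
  evidence <- tibble::tibble(
    protein = x$protein[rep_row],
    resin = x$resin[rep_row],
    n_experiments = as.integer(agg[, "n_experiments"]),
    n_significant = as.integer(agg[, "n_significant"]),
    n_near_one = as.integer(agg[, "n_near_one"]),
    n_depleted = as.integer(agg[, "n_depleted"]),
    n_unobserved = as.integer(agg[, "n_unobserved"]),
    orientations_supporting = lapply(seq_len(nrow(agg)), function(i) {
      ORIENTATIONS[c(agg[i, "sig_th"] > 0, agg[i, "sig_tl"] > 0)]
    }),
    mean_log2_enrichment = unname(ifelse(agg[, "l2_n"] > 0,
                                         agg[, "l2_sum"] / agg[, "l2_n"],
                                         NA_real_))
  )
  evidence <- evidence[order(evidence$protein, evidence$resin), ]
  ev_df <- as.data.frame(evidence[, setdiff(names(evidence), "protein")])
  idx <- split(seq_len(nrow(evidence)), evidence$protein)
  proteins <- names(idx)
  verdict <- character(length(idx))
  confidence <- character(length(idx))
  keep <- logical(length(idx))
  stats_m <- matrix(0, nrow = length(idx), ncol = 3)
  mean_l2 <- numeric(length(idx))
  for (j in seq_along(idx)) {
    ev <- ev_df[idx[[j]], , drop = FALSE]
    observed <- ev$n_experiments - ev$n_unobserved
    if (all(observed == 0L)) next
    keep[j] <- TRUE
    verdict[j] <- classify_protein(ev, config,
                                   is_bait = proteins[j] %in% baits)
    confidence[j] <- rank_confidence(ev, verdict[j], config)
    stats_m[j, ] <- c(sum(ev$n_significant >= 1L), sum(ev$n_significant),
                      sum(observed))
    m <- ev$mean_log2_enrichment[!is.na(ev$mean_log2_enrichment)]
    mean_l2[j] <- if (length(m) > 0) mean(m) else NA_real_
  }
  out <- tibble::tibble(
    protein = proteins,
    verdict = verdict,
    confidence = confidence,
    in_beadome = FALSE,
    n_resins_significant = as.integer(stats_m[, 1]),
    n_experiments_significant = as.integer(stats_m[, 2]),
    n_experiments_observed = as.integer(stats_m[, 3]),
    mean_log2_enrichment = mean_l2,
    per_resin = lapply(idx, function(i)
      evidence[i, setdiff(names(evidence), "protein"), drop = FALSE])
  )[keep, , drop = FALSE]
  out[order(match(out$verdict, rev(VERDICT_CLASSES)),
            match(out$confidence, CONFIDENCE_LEVELS), out$protein), ]
}

#' Flag verdicts that appear in a beadome
#'
#' Annotation, not a veto: a genuine partner that also sticks to naked
#' beads stays genuine, but readers deserve the warning. Matching is by
#' accession (default) or gene, per the config.
#'
#' @param verdicts Verdict tibble.
#' @param beadome Beadome tibble ([build_beadome()]) or a character vector
#'   of accessions.
#' @param config An [ipac_config()] (for `match_on`).
#' @return The verdict tibble with `in_beadome` set.
#' @export
beadome_flag <- function(verdicts, beadome, config = ipac_config()) {
  ids <- if (is.character(beadome)) beadome else beadome$accession
  verdicts$in_beadome <- verdicts$protein %in% ids
  verdicts
}

#' Overlap (Venn) report for named identifier sets
#'
#' Computes the cardinality of all `2^n - 1` membership regions of up to a
#' handful of named sets, plus each region's percentage of the union —
#' the numbers behind a Venn diagram. Regions are ordered by the number of
#' sets they involve, then by set order, so the output is deterministic.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return Tibble: `region` (`&`-joined set names), `n_sets`, `count`,
#'   `pct` (percentage of the union, unrounded).
#' @export
overlap_report <- function(sets) {
  if (is.null(names(sets)) || length(sets) < 2L || any(names(sets) == "")) {
    abort("overlap_report needs >= 2 named sets")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  n <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- as.logical(combos[i, ])
    in_region <- rowSums(membership[, inc, drop = FALSE]) == sum(inc) &
      rowSums(membership[, !inc, drop = FALSE]) == 0
    tibble::tibble(
      region = paste(names(sets)[inc], collapse = "&"),
      n_sets = sum(inc),
      count = sum(in_region)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$n_sets, match(out$region, out$region)), ]
  out$pct <- if (length(universe) > 0) 100 * out$count / length(universe) else 0
  attr(out, "union_size") <- length(universe)
  out
}
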