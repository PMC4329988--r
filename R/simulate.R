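#' Simulation configuration
#'
#' Defines a synthetic reciprocal-SILAC parallel-capture study. The default
#' scenario mirrors a two-resin screen of a low-abundance complex: 500
#' detectable proteins, of which 20 are planted genuine partners (log2
#' tagged/control enrichment drawn around `log2_enrichment_mean` and shared
#' across resins), 5 per resin are tag-specific artefacts (enriched or
#' exclusive on their sticky resin only, ratio ~ 1 elsewhere), one is the
#' bait, and the remainder are non-specific binders at true ratio 1. Each
#' resin is run in both labelling orientations with
#' `replicates_per_orientation` replicates.
#'
#' Noise is multiplicative on the ratio scale: the tagged-sample signal is
#' multiplied by `exp(Normal(0, noise_sd * ln 2))`, i.e. `noise_sd` is the
#' SD of the log2 ratio of a non-specific binder. Isotope incorporation
#' `i < 1` is applied at the channel level — the heavy-grown sample
#' contributes fraction `i` to the heavy channel and leaks `1 - i` into
#' light — which shrinks observed enrichment toward 1, exactly as
#' incomplete labelling does in practice (typical SILAC incorporation is
#' ~98%). Detection of a protein in an experiment is Bernoulli with a
#' logistic probability in log abundance (slope `detection_slope`, centred
#' 2.5 abundance-SDs below the mean so detection is near-certain for
#' average proteins and degrades for rare ones). The strongest planted
#' interactors (planted enrichment at or above `log2_enrichment_mean`)
#' lose their control channel with probability `exclusive_rate` per
#' experiment, exercising the presence/absence path.
#'
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param n_proteins Total simulated proteins (including bait, genuine and
#'   artefacts).
#' @param n_true_interactors Planted genuine partners.
#' @param n_tag_artefacts_per_resin Planted tag-specific artefacts per resin.
#' @param resins Resin labels (>= 2).
#' @param replicates_per_orientation Replicates per (resin, orientation).
#' @param log2_enrichment_mean,log2_enrichment_sd Planted log2 enrichment
#'   distribution for genuine partners and artefacts.
#' @param noise_sd SD of multiplicative log2 ratio noise.
#' @param abundance_mu,abundance_sigma Log-normal abundance parameters
#'   (natural-log scale) for channel intensities.
#' @param detection_slope Slope of the logistic detection model in log
#'   abundance.
#' @param incorporation Heavy-isotope incorporation fraction in (0, 1].
#' @param exclusive_rate Per-experiment probability that a strong planted
#'   interactor loses its control channel.
#' @param bait_accession Accession given to the simulated bait.
#' @return A validated list of class `sim_config`.
#' @export
simulate_config <- function(seed = 1L,
                            n_proteins = 500L,
                            n_true_interactors = 20L,
                            n_tag_artefacts_per_resin = 5L,
                            resins = c("FLAG", "TALON"),
                            replicates_per_orientation = 2L,
                            log2_enrichment_mean = 2,
                            log2_enrichment_sd = 0.25,
                            noise_sd = 0.5,
                            abundance_mu = log(1e7),
                            abundance_sigma = 1.5,
                            detection_slope = 1.2,
                            incorporation = 0.98,
                            exclusive_rate = 0.05,
                            bait_accession = "BAIT0001") {
  cfg <- list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    n_true_interactors = as.integer(n_true_interactors),
    n_tag_artefacts_per_resin = as.integer(n_tag_artefacts_per_resin),
    resins = resins,
    replicates_per_orientation = as.integer(replicates_per_orientation),
    log2_enrichment_mean = log2_enrichment_mean,
    log2_enrichment_sd = log2_enrichment_sd,
    noise_sd = noise_sd,
    abundance_mu = abundance_mu, abundance_sigma = abundance_sigma,
    detection_slope = detection_slope,
    incorporation = incorporation, exclusive_rate = exclusive_rate,
    bait_accession = bait_accession
  )
  n_special <- 1L + cfg$n_true_interactors +
    cfg$n_tag_artefacts_per_resin * length(resins)
  if (length(resins) < 2L) abort("at least 2 resins are required")
  if (anyDuplicated(resins)) abort("resin labels must be unique")
  if (n_special > cfg$n_proteins) {
    abort("n_true_interactors + artefacts (+ bait) exceed n_proteins")
  }
  if (cfg$incorporation <= 0 || cfg$incorporation > 1) {
    abort("incorporation must be in (0, 1]")
  }
  if (cfg$noise_sd < 0 || cfg$log2_enrichment_sd < 0 ||
      cfg$abundance_sigma < 0) {
    abort("standard deviations must be >= 0")
  }
  if (cfg$exclusive_rate < 0 || cfg$exclusive_rate > 1) {
    abort("exclusive_rate must be a probability")
  }
  if (cfg$replicates_per_orientation < 1L) {
    abort("replicates_per_orientation must be >= 1")
  }
  structure(cfg, class = "sim_config")
}

LN2 <- log(2)

#' Simulate a reciprocal-SILAC parallel-capture dataset
#'
#' Generates protein-group records, the matching experiment design, and a
#' ground-truth ledger for every simulated protein, per the generative
#' model described in [simulate_config()]. Output tables are in the long
#' dialect [read_protein_groups()] produces, so the simulated data flow
#' through the same pipeline as real data.
#'
#' @param config A [simulate_config()].
#' @return List with elements `records` (protein-group tibble), `design`
#'   (experiment-design tibble) and `truth` (tibble: `protein`, `class`,
#'   `planted_log2_enrichment`, `sticky_resin`).
#' @export
simulate_dataset <- function(config = simulate_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_proteins
  acc <- sprintf("P%05d", seq_len(n))
  acc[1L] <- cfg$bait_accession
  n_art <- cfg$n_tag_artefacts_per_resin * length(cfg$resins)
  class <- rep("non_specific", n)
  class[1L] <- "bait"
  genuine_idx <- seq.int(2L, length.out = cfg$n_true_interactors)
  class[genuine_idx] <- "genuine"
  art_idx <- seq.int(2L + cfg$n_true_interactors, length.out = n_art)
  class[art_idx] <- "tag_specific_artefact"
  sticky <- rep(NA_character_, n)
  sticky[art_idx] <- rep(cfg$resins, each = cfg$n_tag_artefacts_per_resin)

  planted <- rep(0, n)
  interactor <- class %in% c("bait", "genuine", "tag_specific_artefact")
  planted[interactor] <- rnorm(sum(interactor), cfg$log2_enrichment_mean,
                               cfg$log2_enrichment_sd)
  planted[1L] <- cfg$log2_enrichment_mean + 1  # bait: strongest enrichment

  abundance <- rlnorm(n, cfg$abundance_mu, cfg$abundance_sigma)
  length_proxy <- pmax(50L, round(rlnorm(n, log(450), 0.3)))
  p_detect <- plogis(cfg$detection_slope *
                       (log(abundance) -
                          (cfg$abundance_mu - 2.5 * cfg$abundance_sigma)))
  strong <- interactor & planted >= cfg$log2_enrichment_mean

  design <- tidyr::expand_grid(
    resin = cfg$resins,
    orientation = ORIENTATIONS,
    replicate = seq_len(cfg$replicates_per_orientation)
  )
  design$experiment_id <- sprintf("%s_%s_r%d", design$resin,
                                  ifelse(design$orientation == "tagged_heavy",
                                         "TH", "TL"),
                                  design$replicate)
  design$bait_accession <- cfg$bait_accession
  design$is_control_only <- FALSE
  design <- validate_design(
    design[, c("experiment_id", "resin", "orientation", "replicate",
               "bait_accession", "is_control_only")]
  )

  recs <- lapply(seq_len(nrow(design)), function(e) {
    resin <- design$resin[e]
    tagged_heavy <- design$orientation[e] == "tagged_heavy"
    enriched_here <- class == "genuine" | class == "bait" |
      (class == "tag_specific_artefact" & !is.na(sticky) & sticky == resin)
    true_ratio <- ifelse(enriched_here, 2^planted, 1)

    detected <- runif(n) < p_detect
    detected[1L] <- TRUE  # the purified bait is always seen
    noise <- if (cfg$noise_sd > 0) exp(rnorm(n, 0, cfg$noise_sd * LN2)) else 1
    s_tagged <- abundance * true_ratio * noise
    s_control <- abundance
    lose_control <- strong & enriched_here &
      runif(n) < cfg$exclusive_rate
    s_control[lose_control] <- 0

    i <- cfg$incorporation
    s_heavy <- if (tagged_heavy) s_tagged else s_control
    s_light <- if (tagged_heavy) s_control else s_tagged
    int_h <- i * s_heavy
    int_l <- s_light + (1 - i) * s_heavy
    ratio <- ifelse(int_h > 0 & int_l > 0, int_h / int_l, NA_real_)

    peptides <- 1L + rpois(n, length_proxy / 75)
    tibble::tibble(
      group_id = acc,
      accessions = acc,
      gene_id = paste0("G_", acc),
      unique_razor_peptides = peptides,
      ratio_hl = ratio,
      intensity_h = int_h,
      intensity_l = int_l,
      experiment_id = design$experiment_id[e]
    )[detected, , drop = FALSE]
  })

  list(
    records = dplyr::bind_rows(recs),
    design = design,
    truth = tibble::tibble(
      protein = acc,
      class = class,
      planted_log2_enrichment = ifelse(interactor, planted, 0),
      sticky_resin = sticky
    )
  )
}

#' Score verdicts against simulated ground truth
#'
#' Confusion matrix and headline recovery metrics for a benchmarking run:
#' sensitivity and specificity for the genuine class, the false-genuine
#' rate among planted non-specifics, and the fraction of planted
#' tag-specific artefacts recovered as such.
#'
#' @param verdicts Verdict tibble from [ipac_classify()].
#' @param truth Ground-truth tibble from [simulate_dataset()].
#' @return List: `confusion` (truth x verdict table), `sensitivity`,
#'   `specificity`, `false_genuine_rate`, `artefact_detection_rate`,
#'   `n_scored`.
#' @export
score_against_truth <- function(verdicts, truth) {
  x <- dplyr::left_join(truth, verdicts[, c("protein", "verdict")],
                        by = "protein")
  x$verdict[is.na(x$verdict)] <- "insufficient_data"  # never detected
  conf <- table(truth = factor(x$class, levels = VERDICT_CLASSES),
                verdict = factor(x$verdict, levels = VERDICT_CLASSES))
  is_gen <- x$class == "genuine"
  called_gen <- x$verdict == "genuine"
  is_ns <- x$class == "non_specific"
  is_art <- x$class == "tag_specific_artefact"
  list(
    confusion = conf,
    sensitivity = if (any(is_gen)) mean(called_gen[is_gen]) else NA_real_,
    specificity = if (any(!is_gen)) 1 - mean(called_gen[!is_gen]) else NA_real_,
    false_genuine_rate = if (any(is_ns)) mean(called_gen[is_ns]) else NA_real_,
    artefact_detection_rate = if (any(is_art))
      mean(x$verdict[is_art] == "tag_specific_artefact") else NA_real_,
    n_scored = nrow(x)
  )
}
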