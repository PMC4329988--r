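# Canonical amino-acid alphabet and monoisotopic residue masses (Da).
AA_CANONICAL <- "ACDEFGHIKLMNPQRSTVWY"

MONOISOTOPIC_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

WATER_MONO <- 18.010565

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to every K or R that is not followed by P (the
#' classical trypsin rule used by Mascot-style search engines), then
#' enumerates all peptides retaining up to `missed_cleavages` internal
#' sites. With `collapse_duplicates = TRUE` (the default) the result has
#' set semantics — repeated peptides from repetitive sequence collapse;
#' with `FALSE` and `missed_cleavages = 0` the returned peptides are in
#' sequence order and concatenate back to the input.
#'
#' @param sequence Amino-acid string over the canonical 20-letter alphabet.
#' @param missed_cleavages Maximum retained internal cleavage sites (>= 0).
#' @param collapse_duplicates Collapse duplicate peptides (set semantics).
#' @return Character vector of peptides; empty for an empty sequence.
#' @export
#' @examples
#' digest("AKPLRGK", 0) # "AKPLR" "GK" — no cleavage before P
#' digest("MKR", 1)     # "MK" "R" "MKR"
digest <- function(sequence, missed_cleavages = 0L,
                   collapse_duplicates = TRUE) {
  stopifnot(length(sequence) == 1L, missed_cleavages >= 0L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) return(character(0))
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  # cut after position i when chars[i] is K/R and chars[i+1] is not P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, if (n %in% cut_after) NULL else n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  base <- substring(sequence, starts, ends)
  nb <- length(base)
  peps <- unlist(lapply(0:min(missed_cleavages, nb - 1L), function(m) {
    i <- seq_len(nb - m)
    substring(sequence, starts[i], ends[i + m])
  }), use.names = FALSE)
  if (collapse_duplicates) unique(peps) else peps
}

#' Monoisotopic peptide mass
#'
#' Sum of canonical monoisotopic residue masses plus one water
#' (18.010565 Da). Vectorised over peptides.
#'
#' @param peptide Character vector of peptide sequences.
#' @return Numeric vector of masses in Da; `NA` for peptides containing a
#'   non-canonical letter.
#' @export
#' @examples
#' peptide_mass("G") # 75.03203
peptide_mass <- function(peptide) {
  if (any(nchar(peptide) == 0L)) abort("empty peptide has no mass")
  vapply(strsplit(toupper(peptide), ""), function(ch) {
    m <- MONOISOTOPIC_RESIDUE[ch]
    if (anyNA(m)) NA_real_ else sum(m) + WATER_MONO
  }, numeric(1))
}

#' Count observable peptides
#'
#' The emPAI denominator: how many distinct in-silico peptides of a protein
#' fall inside the mass range the instrument can see. The closed default
#' window 500–3000 Da brackets typical tryptic LC-MS/MS coverage.
#'
#' @param peptides Character vector (typically a [digest()] result).
#' @param mass_window Closed `[low, high]` window in Da.
#' @return Integer count of distinct in-window peptides.
#' @export
count_observable <- function(peptides, mass_window = c(500, 3000)) {
  stopifnot(length(mass_window) == 2L, mass_window[1] <= mass_window[2])
  peptides <- unique(peptides)
  if (length(peptides) == 0L) return(0L)
  m <- peptide_mass(peptides)
  sum(!is.na(m) & m >= mass_window[1] & m <= mass_window[2])
}

#' emPAI abundance score
#'
#' The exponentially modified protein abundance index:
#' `PAI = n_observed / n_observable`, `emPAI = 10^PAI - 1`. A label-free
#' abundance estimate: proteins whose observable peptides are all actually
#' seen score high. Vectorised; scoreable only when `n_observable >= 1`
#' (otherwise the record is returned with `pai`/`empai` absent).
#'
#' @param n_observed Distinct observed peptides (modification- and
#'   charge-agnostic).
#' @param n_observable Distinct in-silico peptides in the observable mass
#'   window.
#' @param accession Optional accession labels.
#' @return Tibble: `accession`, `n_observed`, `n_observable`, `pai`,
#'   `empai`.
#' @export
#' @examples
#' empai_score(4, 20) # pai 0.2, emPAI 10^0.2 - 1 = 0.5849
empai_score <- function(n_observed, n_observable, accession = NA_character_) {
  stopifnot(all(n_observed >= 0), all(n_observable >= 0))
  n <- max(length(n_observed), length(n_observable))
  n_observed <- rep_len(n_observed, n)
  n_observable <- rep_len(n_observable, n)
  if (any(n_observable == 0L)) {
    warn("protein(s) with no observable peptides are unscoreable (empai = NA)")
  }
  pai <- ifelse(n_observable >= 1L, n_observed / n_observable, NA_real_)
  tibble::tibble(
    accession = rep_len(accession, length(pai)),
    n_observed = as.integer(n_observed),
    n_observable = as.integer(n_observable),
    pai = pai,
    empai = 10^pai - 1
  )
}

#' emPAI table from a proteome and observed peptide counts
#'
#' Convenience wrapper: digests each protein (default 2 missed cleavages,
#' the usual search setting), counts observable peptides in the mass
#' window, and scores emPAI against the supplied observed counts.
#'
#' @param proteome Tibble from [read_fasta()].
#' @param observed Named integer vector: accession -> distinct observed
#'   peptides. Missing accessions count as 0.
#' @param missed_cleavages,mass_window Digestion and observability settings.
#' @return An emPAI tibble as from [empai_score()].
#' @export
empai_table <- function(proteome, observed, missed_cleavages = 2L,
                        mass_window = c(500, 3000)) {
  n_observable <- vapply(proteome$sequence, function(s) {
    count_observable(digest(s, missed_cleavages), mass_window)
  }, integer(1), USE.NAMES = FALSE)
  n_observed <- unname(observed[proteome$accession])
  n_observed[is.na(n_observed)] <- 0L
  empai_score(n_observed, n_observable, accession = proteome$accession)
}

#' Rank an abundome
#'
#' Orders emPAI records by descending score (ties broken by descending
#' observed-peptide count, then accession) and truncates to the `top_n`
#' most abundant proteins.
#'
#' @param empai_records Tibble from [empai_score()] / [empai_table()].
#' @param top_n Number of proteins to keep (default 150).
#' @return The ranked, truncated tibble with a `rank` column.
#' @export
build_abundome <- function(empai_records, top_n = 150L) {
  x <- empai_records[!is.na(empai_records$empai), , drop = FALSE]
  x <- x[order(-x$empai, -x$n_observed, x$accession), ]
  x <- head(x, top_n)
  x$rank <- seq_len(nrow(x))
  x
}

#' Build a beadome from control-only pull-downs
#'
#' The beadome is the union of proteins identified in control (untagged)
#' pull-downs, annotated with which resins each bound. Proteins sticking
#' to `min_resins` or more chemically distinct resins (default 2) form the
#' multi-resin subset — the promiscuous binders most likely to contaminate
#' any affinity experiment.
#'
#' @param ids_by_resin Named list: resin label -> character vector of
#'   accessions identified in that resin's control pull-down.
#' @param min_resins Membership floor for the multi-resin subset.
#' @param abundome Optional abundome tibble (or accession vector) used to
#'   set `in_abundome`.
#' @return Tibble: `accession`, `resins_observed` (list column),
#'   `n_resins`, `multi_resin`, `in_abundome`; sorted by descending
#'   `n_resins` then accession.
#' @export
build_beadome <- function(ids_by_resin, min_resins = 2L, abundome = NULL) {
  if (is.null(names(ids_by_resin)) || any(names(ids_by_resin) == "")) {
    abort("ids_by_resin must be a named list (resin -> accessions)")
  }
  ids_by_resin <- lapply(ids_by_resin, unique)
  long <- tibble::tibble(
    resin = rep(names(ids_by_resin), lengths(ids_by_resin)),
    accession = unlist(ids_by_resin, use.names = FALSE)
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$accession),
    resins_observed = list(sort(unique(.data$resin))),
    .groups = "drop"
  )
  out$n_resins <- lengths(out$resins_observed)
  out$multi_resin <- out$n_resins >= min_resins
  ab_ids <- if (is.null(abundome)) character(0)
            else if (is.character(abundome)) abundome
            else abundome$accession
  out$in_abundome <- out$accession %in% ab_ids
  out[order(-out$n_resins, out$accession), ]
}
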