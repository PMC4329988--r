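---
title: "Calling protein interactions from reciprocal-SILAC parallel affinity capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling protein interactions from reciprocal-SILAC parallel affinity capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipac)
```

## The problem

Affinity-purification mass spectrometry (AP-MS) of a tagged bait returns long
protein lists in which genuine complex members are buried among non-specific
binders. Two experimental ideas make the separation quantitative:

* **Reciprocal SILAC labelling.** Tagged and control cell lines are grown in
  heavy and light media, lysates are mixed 1:1, and co-purifying proteins are
  quantified as heavy/light (H/L) ratios. A protein that binds the beads
  regardless of the bait is present equally in both lysates and shows
  H/L ≈ 1; a genuine partner is enriched with the tagged bait and its ratio
  deviates from 1 — in opposite directions in the two reciprocal labellings.
* **Parallel affinity capture.** The bait carries two different tags and is
  purified on each tag's resin in separate experiments. Genuine partners are
  enriched on *both* chemically unrelated resins; a protein enriched on one
  resin but flat on the other is a *tag-specific artefact*, a failure mode
  invisible to single-tag designs.

This package implements the scoring side of that design: per-experiment
significance calling on oriented log2 ratios, cross-resin combination into
verdicts, contaminant ("beadome") and abundance ("abundome") reference lists,
and a ground-truthed simulator used to benchmark all of it.

## The ratio model

Raw H/L ratios are first put on a common *tagged/control* axis:
`log2 E = log2(H/L)` when the tagged line was grown heavy, `-log2(H/L)` for
the reciprocal labelling, so positive values always mean enrichment with the
bait. Only records with at least `min_peptides = 2` unique+razor peptides are
quantified — the conventional floor below which SILAC ratios are noisy.

Each experiment's quantified log2 enrichments are summarised by their median
and standard deviation (sample SD by default). A protein is *significant* in
an experiment when

\[ z = \frac{|\log_2 E - \mathrm{median}|}{\mathrm{SD}} > k \]

with direction (enriched vs depleted). `k = 1` is the permissive default;
`k = 2` gives the stricter call, and by construction the `k = 2` set nests
inside the `k = 1` set. A `--robust` option substitutes the scaled MAD
(`1.4826 × MAD`, as computed by `stats::mad()`) for the SD, because genuine
interactors and artefacts put mass in the tails and inflate the classical SD;
the default stays the classical SD, the convention in this experimental
design. Statistics are computed per experiment (per resin × orientation ×
replicate), not pooled, because each MaxQuant table is separately normalised.
Significance is applied on the log2 scale, matching how such ratio
distributions are plotted and made symmetric.

Proteins detected in only one SILAC channel have no ratio at all. When the
signal is in the tagged channel and the record carries ≥ 2 peptides this is
treated as `exclusive_tagged` — the strongest qualitative evidence, since
the control lysate contributed nothing — and counts as a significant call
downstream. Ratios of exactly 0 or ∞ in input tables encode the same
situation and are coerced to "absent" on read. Degenerate experiments
(SD = 0) yield no significant calls and a warning rather than an error.

## The verdict decision table

Per protein and resin, calls are aggregated into counts of significant
(enriched or exclusive-tagged), near-one (quantified, unremarkable),
depleted and unobserved experiments. The verdict order is:

1. **bait** — the declared bait accession, always reported first;
2. **genuine** — at least `min_sig_per_resin` significant experiments on
   each of ≥ 2 resins;
3. **tag_specific_artefact** — significant/exclusive on ≥ 1 resin while some
   other resin is quantified near 1 with no significant call (depleted calls
   count as near-one here: only enrichment with the bait is specific);
4. **non_specific** — quantified somewhere, significant nowhere;
5. **insufficient_data** — anything else, e.g. significant on one resin and
   entirely unobserved on the rest. Such single-resin candidates are listed
   but never promoted: resin agreement is the specificity guarantee, and
   promoting unreplicated enrichment would re-admit exactly the artefact
   class the design exists to catch.

A protein significant on ≥ 2 resins but near 1 on a third is called genuine
with a warning — multi-resin support dominates.

### Lenient versus consistent combination

`min_sig_per_resin = 1` (the default) accepts a single significant replicate
per resin. That is deliberately sensitive, but with a `k = 1` threshold the
one-sided tail of a null log2 ratio distribution is ≈ 14%, so with four
experiments per resin a pure contaminant has a ≈ 40% chance of one stray
significant call per resin, and a two-resin design admits a noticeable
false-genuine rate. `ipac_config(consistent = TRUE)` therefore requires a
*majority of observed experiments* per resin to be significant. Simple
binomial arithmetic shows this drives the false-genuine probability to the
10⁻⁴ scale while barely touching sensitivity for effects several noise-SDs
in size, and the benchmark suite runs recovery checks in this mode. Both
modes are exposed because the lenient rule is the appropriate screen when
candidate lists go on to orthogonal validation.

### Confidence ranks

Genuine verdicts are ranked by reproducibility. With per-resin significant
fraction `f = significant / observed`:

* **high** — `f ≥ 0.75` in every resin *and* both labelling orientations
  contribute significant calls on at least one resin;
* **medium** — `f ≥ 0.5` in every resin, or the high fractions with only
  single-orientation support;
* **low** — the genuine floor only (e.g. 4/4 on one resin but 1/4 on the
  other).

The fractions 0.75/0.5 are declared conventions of this package, exposed in
`ipac_config()`; the field's practice ranks candidates qualitatively and
never fixes numeric cutoffs, so any implementation must pick and document
its own.

## Beadome and abundome

Control (untagged) pull-downs against each resin define the *beadome*: the
union of proteins that bind beads non-specifically, annotated with which
resins each bound. Proteins on ≥ 2 resins form the multi-resin subset — the
promiscuous binders worth flagging in any experiment. Beadome membership
*annotates* verdicts (`in_beadome`), it never vetoes them: an abundant
protein can be both sticky and a genuine partner.

Lysate abundance is ranked by emPAI,
\[ \mathrm{emPAI} = 10^{N_\text{observed}/N_\text{observable}} - 1, \]
with `N_observable` computed by in-silico tryptic digestion (cleave after
K/R except before P, up to 2 missed cleavages — the Mascot convention) and a
peptide monoisotopic-mass window of 500–3000 Da. The window is not fixed by
any convention and is exposed in configuration and recorded in output
headers; observed peptides are counted as distinct sequences, modification-
and charge-agnostic. `build_abundome()` keeps the top 150 by default.

## The simulator

`simulate_dataset()` generates the statistical structure the classifier is
designed for, with a ground-truth ledger per protein:

* non-specific binders at true tagged/control ratio 1;
* genuine partners with a planted log2 enrichment shared across *all*
  resins (default mean 2, SD 0.25);
* tag-specific artefacts enriched only on their sticky resin;
* one bait, planted one log2 unit above the genuine mean and always
  detected.

Observed ratios get multiplicative noise `exp(N(0, noise_sd · ln 2))`, i.e.
`noise_sd` is the log2-scale SD of a null protein (default 0.5, a realistic
between-replicate spread for SILAC AP-MS). Isotope incorporation `i`
(default 0.98, the level typically reached after ~8 days of SILAC culture)
acts at the channel level: the heavy-grown sample contributes `i` of its
signal to the heavy channel and leaks `1 − i` into light, which attenuates
observed enrichment toward 1 monotonically — the direction real incomplete
labelling pushes. Detection is Bernoulli with logistic probability in log
abundance (log-normal abundances, slope 1.2, centred 2.5 abundance-SDs below
the mean so typical proteins are seen in ~99% of experiments and rare ones
drop out). The strongest planted interactors lose their control channel with
probability `exclusive_rate = 0.05` per experiment, exercising the
presence/absence path. Peptide counts are a shifted Poisson with floor 1
driven by a protein-length proxy; their only downstream role is the ≥ 2
filter.

The defaults — 500 proteins, 20 genuine partners, 5 artefacts per resin,
2 resins × 2 orientations × 2 replicates — define the benchmark scenario
used throughout the test suite; they were fixed once as a realistic
medium-size screen and are not tuned per test. What the simulator does *not*
model: peptide-level variance, correlated contaminant abundances, ratio
compression from co-eluting species, retention-time or spectrum-level
effects. Passing recovery benchmarks therefore demonstrates the logic of the
classifier under its own generative assumptions, not performance on any real
instrument's output.

## Numerical and interface choices

* Identical seeds give bit-identical datasets (`withr::with_seed`).
* Abundome ties break by observed-peptide count then accession; report rows
  sort by verdict class, confidence, accession — all outputs are
  deterministic.
* Sample SD (`n − 1`) is the default denominator; population SD is an
  option. Experiments with fewer than `min_stats_n = 10` quantified proteins
  are an error, not a silent statistic.
* The wide-table reader includes a (group, experiment) cell only when the
  ratio or an intensity is present, so absence is represented as a missing
  record, and an absent ratio with channel evidence as `NA`.
* The benchmark problem sizes (500–2000 proteins, 8–16 experiments, 10,000
  random decision-table patterns) were chosen as the smallest at which the
  Monte-Carlo checks are statistically meaningful.

## Limitations

* The significance model assumes the per-experiment log2 ratio distribution
  is dominated by null proteins; screens where most detected proteins are
  true partners would violate the median/SD estimate (the robust mode
  mitigates, not removes, this).
* Protein-group redundancy is handled only by representative-accession
  matching; heavily redundant databases can split evidence across groups.
* emPAI here is recomputed from the digest, so values can differ from a
  search engine's built-in emPAI when the engine uses a different
  observable-peptide convention.
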