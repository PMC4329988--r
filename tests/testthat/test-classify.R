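design4 <- make_design(replicates = 2)   # 2 resins x 2 orientations x 2 reps
flag_exps <- design4$experiment_id[design4$resin == "FLAG"]
talon_exps <- design4$experiment_id[design4$resin == "TALON"]

test_that("summarize_resin counts calls and supporting orientations", {
  calls <- make_calls("P1", flag_exps,
                      c("significant_enriched", "significant_enriched",
                        "exclusive_tagged", "not_significant"))
  got <- summarize_resin(calls, design4)
  expect_equal(got$n_experiments, 4)
  expect_equal(got$n_significant, 3)
  expect_equal(got$n_near_one, 1)
  expect_setequal(got$orientations_supporting[[1]],
                  c("tagged_heavy", "tagged_light"))

  un <- make_calls("P1", flag_exps[1:2], rep("unquantified", 2))
  got_un <- summarize_resin(un, design4)
  expect_equal(got_un$n_unobserved, 2)
  expect_true(is.na(got_un$mean_log2_enrichment))

  mixed <- make_calls("P1", c(flag_exps[1], talon_exps[1]),
                      rep("not_significant", 2))
  expect_error(summarize_resin(mixed, design4), "more than one resin")
  expect_error(summarize_resin(mixed[0, ], design4), "no calls")
})

evidence_for <- function(flag_statuses, talon_statuses) {
  calls <- dplyr::bind_rows(
    make_calls("P1", flag_exps[seq_along(flag_statuses)], flag_statuses),
    make_calls("P1", talon_exps[seq_along(talon_statuses)], talon_statuses)
  )
  dplyr::bind_rows(
    summarize_resin(calls[calls$experiment_id %in% flag_exps, ], design4),
    summarize_resin(calls[calls$experiment_id %in% talon_exps, ], design4)
  )
}

test_that("classify_protein applies the parallel-capture decision order", {
  sig <- "significant_enriched"; ns <- "not_significant"
  # significant on both resins -> genuine
  expect_equal(classify_protein(evidence_for(c(sig, sig, sig, ns),
                                             c(sig, sig, ns, ns))),
               "genuine")
  # exclusive on one resin, quietly near 1 on the other -> artefact
  expect_equal(classify_protein(evidence_for(rep("exclusive_tagged", 2),
                                             rep(ns, 2))),
               "tag_specific_artefact")
  # near 1 everywhere -> non-specific
  expect_equal(classify_protein(evidence_for(rep(ns, 4), rep(ns, 4))),
               "non_specific")
  # significant on one resin, never seen on the other -> insufficient
  expect_equal(classify_protein(evidence_for(c(sig, sig),
                                             rep("unquantified", 2))),
               "insufficient_data")
  # declared bait wins outright
  expect_equal(classify_protein(evidence_for(rep(sig, 2), rep(sig, 2)),
                                is_bait = TRUE),
               "bait")
  # depleted calls count as near-one for the artefact pattern
  expect_equal(classify_protein(evidence_for(c(sig, sig),
                                             rep("significant_depleted", 2))),
               "tag_specific_artefact")
  expect_error(classify_protein(evidence_for(rep("unquantified", 2),
                                             rep("unquantified", 2))),
               "no observed experiment")
})

test_that("consistent mode demands majority support per resin", {
  sig <- "significant_enriched"; ns <- "not_significant"
  cfg <- ipac_config(consistent = TRUE)
  ev <- evidence_for(c(sig, ns, ns, ns), c(sig, ns, ns, ns))
  expect_equal(classify_protein(ev), "genuine")           # lenient default
  # one stray call per resin is no longer conclusive evidence of anything
  expect_equal(classify_protein(ev, cfg), "insufficient_data")
  ev2 <- evidence_for(c(sig, sig, sig, ns), c(sig, sig, sig, ns))
  expect_equal(classify_protein(ev2, cfg), "genuine")
})

test_that("confidence ranking follows reproducibility across resins and orientations", {
  sig <- "significant_enriched"; ns <- "not_significant"
  # 4/4 and 3/4 with both orientations -> high
  ev_high <- evidence_for(rep(sig, 4), c(sig, sig, sig, ns))
  expect_equal(rank_confidence(ev_high, "genuine"), "high")
  # 4/4 and 1/4 -> low (one resin far below reproducibility floor)
  ev_low <- evidence_for(rep(sig, 4), c(sig, ns, ns, ns))
  expect_equal(rank_confidence(ev_low, "genuine"), "low")
  # single-orientation support only -> medium even at full reproducibility
  # (experiments 1,2 are the tagged_heavy replicates; 3,4 never observed)
  ev_single <- evidence_for(c(sig, sig, "unquantified", "unquantified"),
                            c(sig, sig, "unquantified", "unquantified"))
  expect_equal(rank_confidence(ev_single, "genuine"), "medium")
  expect_equal(rank_confidence(ev_high, "non_specific"), "not_applicable")
})

test_that("every protein gets exactly one verdict and bait is reported first", {
  sig <- "significant_enriched"; ns <- "not_significant"
  calls <- dplyr::bind_rows(
    make_calls("BAIT1", c(flag_exps, talon_exps), rep(sig, 8), log2e = 3),
    make_calls("PART", c(flag_exps, talon_exps), rep(c(sig, ns), each = 4)),
    make_calls("PNS", c(flag_exps, talon_exps), rep(ns, 8))
  )
  calls_gen <- make_calls("PGEN2", c(flag_exps[1:2], talon_exps[1:2]),
                          c(sig, sig, sig, ns))
  verdicts <- ipac_classify(dplyr::bind_rows(calls, calls_gen), design4)
  expect_equal(nrow(verdicts), 4)
  expect_equal(anyDuplicated(verdicts$protein), 0)
  expect_equal(verdicts$verdict[1], "bait")
  expect_equal(verdicts$protein[1], "BAIT1")
  expect_true(all(verdicts$verdict %in% c("bait", "genuine",
                                          "tag_specific_artefact",
                                          "non_specific", "insufficient_data")))
})

test_that("vectorised classification agrees with the scalar reference path", {
  set.seed(21)
  statuses <- ipac:::CALL_STATUSES
  proteins <- sprintf("P%03d", 1:40)
  calls <- dplyr::bind_rows(lapply(proteins, function(p) {
    make_calls(p, design4$experiment_id,
               sample(statuses, 8, replace = TRUE))
  }))
  verdicts <- suppressWarnings(ipac_classify(calls, design4))
  for (p in verdicts$protein) {
    sub <- calls[calls$protein == p, ]
    ev <- dplyr::bind_rows(lapply(split(sub, design4$resin[match(
      sub$experiment_id, design4$experiment_id)]), summarize_resin,
      design = design4))
    expect_equal(
      suppressWarnings(classify_protein(ev, is_bait = p == "BAIT1")),
      verdicts$verdict[verdicts$protein == p],
      label = p
    )
  }
})

test_that("adding a significant call never demotes a verdict", {
  rank_of <- c(insufficient_data = 0, non_specific = 1,
               tag_specific_artefact = 2, genuine = 2, bait = 3)
  set.seed(31)
  statuses <- ipac:::CALL_STATUSES
  for (i in 1:60) {
    st <- sample(statuses, 8, replace = TRUE)
    calls <- make_calls("P1", design4$experiment_id, st)
    base_ev <- function(cc) {
      dplyr::bind_rows(
        summarize_resin(cc[cc$experiment_id %in% flag_exps, ], design4),
        summarize_resin(cc[cc$experiment_id %in% talon_exps, ], design4)
      )
    }
    v0 <- tryCatch(suppressWarnings(classify_protein(base_ev(calls))),
                   error = function(e) NA_character_)
    if (is.na(v0)) next
    j <- sample(8, 1)
    upgraded <- calls
    upgraded$status[j] <- factor("significant_enriched", levels = statuses)
    upgraded$log2_enrichment[j] <- 2
    v1 <- suppressWarnings(classify_protein(base_ev(upgraded)))
    expect_gte(rank_of[[v1]], rank_of[[v0]])
  }
})

test_that("overlap_report enumerates every region with union percentages", {
  got <- overlap_report(list(X = c("a", "b", "c"), Y = c("b", "c", "d")))
  expect_equal(nrow(got), 3)
  expect_equal(attr(got, "union_size"), 4)
  counts <- setNames(got$count, got$region)
  expect_equal(counts[["X"]], 1)
  expect_equal(counts[["Y"]], 1)
  expect_equal(counts[["X&Y"]], 2)
  expect_equal(sum(got$count), 4)
  expect_equal(got$pct, 100 * got$count / 4)

  same <- overlap_report(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(same$count[same$region == "A&B"], 5)
  expect_equal(sum(same$count[same$region != "A&B"]), 0)

  expect_error(overlap_report(list(letters[1:2], letters[2:3])), "named")
})

test_that("beadome flagging annotates without changing verdicts", {
  verdicts <- tibble::tibble(
    protein = c("P1", "P2"),
    verdict = c("genuine", "non_specific"),
    confidence = c("high", "not_applicable"),
    in_beadome = FALSE
  )
  flagged <- beadome_flag(verdicts, c("P1", "P9"))
  expect_equal(flagged$in_beadome, c(TRUE, FALSE))
  expect_equal(flagged$verdict, verdicts$verdict)
  none <- beadome_flag(verdicts, character(0))
  expect_false(any(none$in_beadome))
  via_tbl <- beadome_flag(verdicts,
                          build_beadome(list(FLAG = "P1", IgG = "P1")))
  expect_equal(via_tbl$in_beadome, c(TRUE, FALSE))
})
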