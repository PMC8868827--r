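test_that("transcript model and coordinate conversions validate and invert", {
  tx <- transcript_model("t1", c(100, 50, 80), cds_start = 10)
  expect_error(transcript_model("t", c(100, 0), 5), "> 0")
  expect_error(transcript_model("t", c(100, 50), 200), "outside transcript")
  expect_error(transcript_model("t", c(9), 1, "ACGTACGTACGT"), "length")
  loc <- transcript_to_exon(tx, 120)
  expect_equal(loc$exon, 2L)
  expect_equal(loc$offset, 20L)
  # round-trip on every position of the transcript
  for (pos in c(1, 99, 100, 101, 150, 151, 230)) {
    l <- transcript_to_exon(tx, pos)
    expect_equal(exon_to_transcript(tx, l$exon, l$offset), pos)
  }
  expect_error(transcript_to_exon(tx, 231), "outside")
  expect_error(exon_to_transcript(tx, 2, 51), "outside exon")
})

test_that("PTC location handles nonsense, frameshift and no-PTC variants", {
  fx <- simulate_transcript_fixtures(seed = 1)
  tx <- fx$all_rules_pass$transcript
  nl <- locate_ptc(tx, variant("nonsense", position = 340))
  expect_equal(nl$ptc, 340L)
  expect_true(is.na(nl$flag))
  mi <- locate_ptc(tx, variant("missense", position = 340))
  expect_true(is.na(mi$ptc))
  expect_equal(mi$flag, "no_ptc")
  # toy CDS ATG AAA GGG TAA: a T inserted after the ATG puts an
  # immediate TAA in the shifted frame
  toy <- fx$toy_immediate_stop
  loc <- locate_ptc(toy$transcript, toy$variant)
  expect_equal(loc$ptc, 4L)
  # insertion shifts the downstream junction by its length
  expect_equal(loc$transcript$exon_lengths,
               toy$transcript$exon_lengths + c(1L, 0L))
  # a frameshift needs the spliced sequence
  bare <- transcript_model("bare", c(100, 100), 10)
  expect_error(locate_ptc(bare, variant("frameshift_ins", 50, 1)),
               "spliced sequence")
  expect_error(variant("frameshift_del", 10, length = 3), "multiple of 3")
})

test_that("frameshift PTC scanning matches the translation oracle", {
  fx <- simulate_transcript_fixtures(seed = 6)
  fs <- fx[vapply(fx, function(p)
    grepl("frameshift", p$variant$type), logical(1))]
  expect_gte(length(fs), 3L)
  for (case in fs) {
    got <- locate_ptc(case$transcript, case$variant)
    expect_equal(got$ptc, biostrings_ptc(case$transcript, case$variant),
                 info = case$name)
  }
  # nonsense fixtures: the placed stop is also the first in-frame stop
  ns <- fx[vapply(fx, function(p) p$variant$type == "nonsense", logical(1))]
  for (case in ns) {
    tx <- case$transcript
    first_stop <- biostrings_ptc(tx, variant("missense", 1))
    expect_equal(first_stop, case$variant$position, info = case$name)
  }
})

test_that("the three NMD rules reproduce the hand-enumerated truth table", {
  fx <- simulate_transcript_fixtures(seed = 3)
  res <- classify_variants(fx)
  expected <- vapply(fx, `[[`, character(1), "expected_call")
  known <- !is.na(expected)
  expect_equal(res$call[known], unname(expected[known]))
  # rule bookkeeping on the all-pass case
  row <- res[res$transcript == "all_rules_pass", ]
  expect_true(row$rule1 && row$rule2 && row$rule3)
  expect_gt(row$junction_distance, 50)
  expect_gt(row$start_distance, 200)
  expect_gt(row$n_exons, 2)
})

test_that("predict_nmd applies each rule boundary as specified", {
  # many-exon transcript, PTC 300 nt downstream of start and 100 nt
  # upstream of the last junction: all rules pass
  tx24 <- transcript_model("t24", rep(100L, 24L), cds_start = 50L)
  last_j <- sum(rep(100L, 23L))
  pred <- predict_nmd(tx24, ptc = last_j - 100L)
  expect_equal(pred$call, "NMD_predicted")
  # PTC in the last exon fails rule 1
  expect_equal(predict_nmd(tx24, ptc = last_j + 50L)$call, "NMD_escape")
  expect_false(predict_nmd(tx24, ptc = last_j + 50L)$rule1)
  # two-exon transcript fails rule 2 regardless of distances
  tx2 <- transcript_model("t2", c(1000L, 400L), cds_start = 10L)
  p2 <- predict_nmd(tx2, ptc = 500L)
  expect_false(p2$rule2)
  expect_equal(p2$call, "NMD_escape")
  # PTC 150 nt from the start codon fails rule 3
  p3 <- predict_nmd(tx24, ptc = 50L + 150L)
  expect_false(p3$rule3)
  expect_equal(p3$call, "NMD_escape")
  # junction threshold is a strict "more than"
  at <- predict_nmd(tx24, ptc = last_j - 50L)
  expect_false(at$rule1)
  above <- predict_nmd(tx24, ptc = last_j - 51L)
  expect_true(above$rule1)
  # configurable thresholds stay in the validated range
  expect_error(nmd_rule_config(junction_threshold = 49), "50..55")
  cfg55 <- nmd_rule_config(junction_threshold = 55)
  expect_false(predict_nmd(tx24, ptc = last_j - 53L, cfg55)$rule1)
  # no PTC -> not applicable
  expect_equal(predict_nmd(tx24, NA)$call, "not_applicable")
})

test_that("moving a PTC upstream never rescues a predicted transcript", {
  tx <- transcript_model("mono", rep(150L, 8L), cds_start = 30L)
  cfg <- nmd_rule_config()
  calls <- vapply(seq(sum(tx$exon_lengths) - 3L, 231L, by = -7L),
                  function(p) predict_nmd(tx, p, cfg)$call, character(1))
  # once predicted while scanning upstream (>200 nt from start), it
  # stays predicted
  first_pred <- match("NMD_predicted", calls)
  if (!is.na(first_pred))
    expect_true(all(calls[first_pred:length(calls)] == "NMD_predicted"))
})
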