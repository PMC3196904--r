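test_that("exact consensus tiling is detected with full identity", {
  ann <- detect_repeats(strrep(CONSENSUS_FILL, 8))
  expect_equal(nrow(ann), 8)
  expect_equal(ann$start, seq(1, 113, by = 16))
  expect_equal(ann$identity, rep(1, 8))
  expect_false(any(ann$partial))
})

test_that("a 49-residue three-block segment yields 3 complete repeats plus a partial", {
  seg <- substr(strrep(CONSENSUS_FILL, 4), 1, 49)  # residues 217-265 layout
  ann <- detect_repeats(seg, numbering_start = 217)
  complete <- ann[!ann$partial, ]
  expect_equal(nrow(complete), 3)
  expect_equal(complete$start, c(217, 233, 249))
  expect_equal(sum(ann$partial), 1)
  expect_equal(ann$end[nrow(ann)], 265)
})

test_that("detection recovers generator truth at the default substitution level", {
  g <- generate_inp_sequence(64, substitution_rate = 0.15,
                             anchor_substitution_rate = 0.05, seed = 101)
  ann <- detect_repeats(g$sequence, min_identity = 0.3)
  complete <- ann[!ann$partial, ]
  expect_equal(nrow(complete), 64)
  expect_equal(complete$start, g$truth$spans$start)
  expect_equal(complete$end, g$truth$spans$end)
})

test_that("detection is deterministic and phase-invariant", {
  g <- generate_inp_sequence(16, seed = 7)
  a1 <- detect_repeats(g$sequence)
  a2 <- detect_repeats(g$sequence)
  expect_identical(tibble::as_tibble(a1), tibble::as_tibble(a2))
  # prepending junk shifts the spans but preserves the motif content
  shifted <- paste0("AAAAA", g$sequence)
  a3 <- detect_repeats(shifted)
  m1 <- segment_motifs(a1)
  m3 <- segment_motifs(a3)
  expect_equal(m3$strand_txta[!m3$partial], m1$strand_txta[!m1$partial])
  expect_equal(a3$start[!a3$partial], a1$start[!a1$partial] + 5L)
})

test_that("sequence validation rejects bad input", {
  expect_error(detect_repeats(""), "empty")
  expect_error(detect_repeats("GYGSTQTAXB1"), "non-standard")
  expect_error(detect_repeats("GYGSBQTA"), "B")
  expect_error(detect_repeats(strrep(CONSENSUS_FILL, 2), min_identity = 1.5),
               "min_identity")
})

test_that("motif segmentation cuts each repeat into its four tetra-peptides", {
  ann <- segment_motifs(consensus_annotation(8))
  expect_equal(unique(ann$turn_gygs), "GYGS")
  expect_equal(unique(ann$strand_txta), "TQTA")
  expect_equal(unique(ann$turn_xxxs), "GEGS")
  expect_equal(unique(ann$strand_xlta), "SLTA")
  # partition identity on noisy repeats
  g <- generate_inp_sequence(12, substitution_rate = 0.2, seed = 3)
  noisy <- segment_motifs(detect_repeats(g$sequence, min_identity = 0.3))
  ok <- !noisy$partial
  rebuilt <- paste0(noisy$turn_gygs[ok], noisy$strand_txta[ok],
                    noisy$turn_xxxs[ok], noisy$strand_xlta[ok])
  expect_equal(rebuilt, substring(g$sequence, noisy$start[ok], noisy$end[ok]))
})

test_that("truncated terminal repeats are flagged partial and excluded from motifs", {
  seq49 <- substr(strrep(CONSENSUS_FILL, 4), 1, 49)
  ann <- segment_motifs(detect_repeats(seq49))
  expect_true(is.na(ann$turn_gygs[ann$partial]))
  expect_false(any(is.na(ann$turn_gygs[!ann$partial])))
})

test_that("position frequencies behave on identical repeats and sum to one", {
  ann <- consensus_annotation(10)  # 10 identical repeats
  pft <- position_frequencies(ann)
  expect_equal(pft$n_repeats, 10)
  expect_true(all(abs(rowSums(pft$frequencies) - 1) < 1e-9))
  occupied <- pft$frequencies[pft$frequencies > 0]
  expect_true(all(occupied == 1))
  expect_equal(unname(rowSums(pft$counts)), rep(10, 16))
})

test_that("adding one repeat increments every position count by one", {
  a9 <- detect_repeats(strrep(CONSENSUS_FILL, 9))
  a10 <- detect_repeats(strrep(CONSENSUS_FILL, 10))
  p9 <- position_frequencies(a9)
  p10 <- position_frequencies(a10)
  expect_equal(rowSums(p10$counts) - rowSums(p9$counts), rep(1, 16),
               ignore_attr = TRUE)
})

test_that("a planted threonine profile is recovered within its binomial interval", {
  prof <- tibble::tibble(position = c(5L, 7L), residue = "T",
                         frequency = c(0.87, 0.92))
  g <- generate_inp_sequence(64, profile = prof, seed = 11)
  pft <- position_frequencies(detect_repeats(g$sequence, min_identity = 0.3))
  for (r in 1:2) {
    k <- pft$counts[prof$position[r], "T"]
    ci <- stats::binom.test(k, 64)$conf.int  # exact binomial oracle
    expect_gte(prof$frequency[r], ci[1])
    expect_lte(prof$frequency[r], ci[2])
  }
  ms <- pft$motif_summary
  expect_equal(ms$frequency[ms$statistic == "thr_txta_pos1"],
               unname(pft$frequencies[5, "T"]))
})

test_that("position_frequencies errors without complete repeats", {
  ann <- detect_repeats(substr(CONSENSUS_FILL, 1, 12))
  expect_error(position_frequencies(ann), "complete")
})
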