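test_that("segments without significant hits yield zero candidates", {
  withr::with_seed(73, {
    segs <- random_segments(3, 200)
    m <- sharp_pswm("TCATTAAAAAGTTCA", id = 1, core = TRUE)
    cs <- two_round_select(segs, list(m))
    expect_equal(sum(cs$candidates$accepted), 0)
    expect_error(two_round_select(segs, list()), "empty matrix set")
  })
})

test_that("core plants are accepted, non-core plants retained but rejected", {
  fx <- planted_fixture()
  cs <- two_round_select(fx$segments, list(fx$core, fx$oe))
  cand <- cs$candidates
  planted_core <- fx$truth$segment_id[fx$truth$matrix_id == 1]
  planted_oe <- fx$truth$segment_id[fx$truth$matrix_id == 9]
  expect_true(cand$accepted[cand$segment_id == planted_core])
  expect_true(cand$retained[cand$segment_id == planted_oe])
  expect_false(cand$accepted[cand$segment_id == planted_oe])
  # accepted subset of retained subset of scanned
  expect_true(all(!cand$accepted | cand$retained))
  expect_lte(sum(cand$retained), cs$n_scanned)
  # round-2 hits only on retained segments
  expect_true(all(cs$round2_hits$segment_id %in%
                    cand$segment_id[cand$retained]))
})

test_that("acceptance is invariant to removing non-core matrices", {
  for (seed in c(71, 171, 271)) {
    fx <- planted_fixture(seed)
    both <- two_round_select(fx$segments, list(fx$core, fx$oe))
    core_only <- two_round_select(fx$segments, list(fx$core))
    acc_both <- both$candidates$segment_id[both$candidates$accepted]
    acc_core <- core_only$candidates$segment_id[core_only$candidates$accepted]
    expect_setequal(acc_both, acc_core)
    expect_lte(sum(core_only$candidates$retained),
               sum(both$candidates$retained))
  }
})

test_that("candidate numbering follows chromosomal location", {
  fx <- planted_fixture()
  # plant a second core instance on another chromosome, upstream name order
  withr::with_seed(81, {
    extra <- random_segments(1, 350, chrom = "chr2", start0 = 100)
    pl <- plant_motif_instances(extra, list(fx$core),
                                data.frame(segment_id = names(extra),
                                           matrix_id = 1), seed = 9)
    segs <- c(fx$segments, pl$segments)
    cs <- two_round_select(segs, list(fx$core, fx$oe))
    acc <- cs$candidates[cs$candidates$accepted, ]
    expect_equal(acc$enhancer_number[order(chrom_rank(acc$chrom),
                                           acc$start)],
                 seq_len(nrow(acc)))
  })
  # identical inputs give identical outputs
  cs1 <- two_round_select(fx$segments, list(fx$core, fx$oe))
  cs2 <- two_round_select(fx$segments, list(fx$core, fx$oe))
  expect_identical(cs1$candidates, cs2$candidates)
})

test_that("13-mer variant ranks exact matches first and screens by
           allowed matrices", {
  withr::with_seed(83, {
    core <- sharp_pswm("TCATTAAAAAGTTCA", id = 1, core = TRUE)
    late <- sharp_pswm("GGATCCGGATCCGG", id = 4, core = TRUE)
    segs <- random_segments(5, 300)
    # segment 2 carries the exact 13-mer (inside the core consensus)
    pl <- plant_motif_instances(segs, list(core),
                                data.frame(segment_id = names(segs)[2],
                                           matrix_id = 1, offset = 100,
                                           strand = "+"), seed = 3)
    # segment 4 carries only the non-allowed matrix consensus
    pl2 <- plant_motif_instances(pl$segments, list(late),
                                 data.frame(segment_id = names(segs)[4],
                                            matrix_id = 4, offset = 50,
                                            strand = "+"), seed = 4)
    expect_message(
      res <- variant_core_motif_search(
        list(GERP = pl2$segments), list(core, late),
        variant_config(top_n = 100, allowed_matrices = 1)),
      "keeping all")
    expect_equal(nrow(res), 5)                      # small database: all kept
    expect_equal(res$segment_id[1], names(segs)[2]) # exact 13-mer ranks first
    expect_equal(res$best_13mer_score[1], 13)
    expect_true(res$retained[res$segment_id == names(segs)[2]])
    # the late-only segment has hits but is not retained (matrix 4 not allowed)
    expect_false(res$retained[res$segment_id == names(segs)[4]])
    r1 <- res$round1_matrices[res$segment_id == names(segs)[4]]
    expect_match(r1, "4")
  })
})

test_that("rediscovery labels overlaps, novelty and own-matrix provenance", {
  cand <- data.frame(
    segment_id = c("chr1:1001-1400", "chr2:5001-5400"),
    chrom = c("chr1", "chr2"), start = c(1000, 5000),
    end = c(1400, 5400), accepted = TRUE,
    round1_matrices = c("1,2", "1"), stringsAsFactors = FALSE)
  known <- data.frame(chrom = "chr1", start = 1200, end = 1600,
                      name = "H", stringsAsFactors = FALSE)
  out <- rediscovery_check(cand, known_coords = known,
                           matrix_provenance = list(`1` = c("H", "P"),
                                                    `2` = c("J")))
  expect_equal(out$label, c("overlaps H", "novel"))
  expect_false(out$derived_from_own_matrix[1])   # matrix 2 is H-independent

  out2 <- rediscovery_check(cand, known_coords = known,
                            matrix_provenance = list(`1` = c("H", "P"),
                                                     `2` = c("H")))
  expect_true(out2$derived_from_own_matrix[1])   # all hits trace back to H
  expect_false(out2$derived_from_own_matrix[2])
})
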