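test_that("single-column table gives the exact letter tail", {
  m <- build_pswm("A", pseudocount = 0.4)   # unique best letter A
  tab <- pvalue_table(m, rep(0.25, 4))
  expect_equal(tab$tail[1], 1)                       # p(min attainable) = 1
  expect_equal(tab$tail[length(tab$tail)], 0.25)     # p(max score) = P(A)
  expect_true(all(diff(tab$tail) <= 1e-12))          # non-increasing
})

test_that("DP p-values match exhaustive enumeration within one bin", {
  withr::with_seed(303, {
    for (w in c(2, 4, 6)) {
      bg <- c(0.3, 0.2, 0.2, 0.3)
      block <- vapply(1:6, function(i)
        paste(sample(c("A", "C", "G", "T"), w, TRUE), collapse = ""), "")
      m <- build_pswm(block, pseudocount = 0.2)
      tab <- pvalue_table(m, bg, bins = 1000)
      oracle <- bf_pvalues(m, bg)
      # integer-grid enumeration must agree exactly with the convolution
      imat <- tab$imat
      words <- as.matrix(expand.grid(rep(list(1:4), w)))
      for (r in sample(nrow(words), min(40, nrow(words)))) {
        idx <- words[r, ]
        s_int <- sum(imat[cbind(seq_len(w), idx)])
        p_dp <- tab$tail[s_int + 1]
        p_int_enum <- sum(apply(words, 1, function(v)
          if (sum(imat[cbind(seq_len(w), v)]) >= s_int)
            prod(bg[v]) else 0))
        expect_equal(p_dp, p_int_enum, tolerance = 1e-12)
        # and against real-score enumeration within discretization slack
        score <- sum(log_odds(m, bg)[cbind(seq_len(w), idx)])
        delta <- w / tab$scale       # max rounding drift across columns
        expect_gte(p_dp + 1e-12, oracle$p_of(score + delta))
        expect_lte(p_dp - 1e-12, oracle$p_of(score - delta))
      }
    }
  })
})

test_that("a planted consensus is the top hit at the planted offset", {
  withr::with_seed(41, {
    m <- sharp_pswm("TCATTAAAAAGTTCA", id = 1, core = TRUE)
    seg <- random_segments(1, 300)
    pl <- plant_motif_instances(seg, list(m), data.frame(
      segment_id = names(seg), matrix_id = 1, offset = 37, strand = "+"))
    hits <- scan_segments(pl$segments, list(m),
                          scan_config(background = "uniform"))
    top <- hits[which.min(hits$p_value), ]
    expect_equal(top$start, 37)
    expect_equal(top$strand, "+")
    expect_equal(top$stop, 37 + 15)
    expect_equal(top$matched_seq, "TCATTAAAAAGTTCA")

    # strand symmetry: scanning the reverse complement mirrors the hit
    rc <- Biostrings::reverseComplement(pl$segments)
    names(rc) <- names(pl$segments)
    hits_rc <- scan_segments(rc, list(m),
                             scan_config(background = "uniform"))
    top_rc <- hits_rc[which.min(hits_rc$p_value), ]
    expect_equal(top_rc$strand, "-")
    expect_equal(top_rc$start, 300 - 37 - 15)
    expect_equal(top_rc$score, top$score)
    expect_equal(top_rc$p_value, top$p_value)
  })
})

test_that("segments shorter than the motif yield no windows", {
  m <- sharp_pswm("ACGTACGTAC")
  short <- Biostrings::DNAStringSet(c(s1 = "ACGT"))
  hits <- scan_segments(short, list(m))
  expect_equal(nrow(hits), 0)
  expect_equal(attr(hits, "n_tests"), 0)
})

test_that("mostly-N segments are skipped with a message", {
  m <- sharp_pswm("ACGTA")
  segs <- Biostrings::DNAStringSet(c(
    ok = "ACGTACGTACGTACGTACGT",
    gappy = paste(c(rep("N", 30), "ACGTA"), collapse = "")))
  expect_message(hits <- scan_segments(segs, list(m),
                                       scan_config(alpha = 0.999)),
                 "skipping")
  expect_false("gappy" %in% hits$segment_id)
})

test_that("scan output is deterministic and ordered", {
  withr::with_seed(47, {
    segs <- random_segments(3, 120)
    ms <- list(sharp_pswm("ACGTAC", 1), sharp_pswm("TTAACC", 2))
    h1 <- scan_segments(segs, ms, scan_config(alpha = 0.5))
    h2 <- scan_segments(segs, ms, scan_config(alpha = 0.5))
    expect_identical(h1, h2)
    seg_rank <- match(h1$segment_id, names(segs))
    expect_true(all(diff(order(seg_rank, h1$start, h1$matrix_id,
                               h1$strand)) == 1))
  })
})

test_that("BH q-values match the direct step-up evaluation", {
  hits <- data.frame(p_value = c(0.01, 0.02, 0.04))
  q <- bh_qvalues(hits)$q_value
  expect_equal(q, c(0.03, 0.03, 0.04))
  expect_equal(q, bf_bh(c(0.01, 0.02, 0.04)))

  expect_equal(bh_qvalues(data.frame(p_value = 0.2))$q_value, 0.2)  # m = 1

  withr::with_seed(53, {
    p <- runif(40)^2
    got <- bh_qvalues(data.frame(p_value = p))$q_value
    expect_equal(got, bf_bh(p))
    expect_true(all(got >= p))
    expect_true(all(diff(got[order(p)]) >= -1e-12))    # order-preserving
    # explicit pool size m > number of hits
    expect_equal(bh_qvalues(data.frame(p_value = p), m = 100)$q_value,
                 bf_bh(p, m = 100))
  })
  empty <- data.frame(p_value = numeric())
  expect_equal(nrow(bh_qvalues(empty)), 0)
})

test_that("significance filtering applies both thresholds and stars", {
  hits <- data.frame(p_value = c(0.01, 0.0005, 0.2, 0.03),
                     q_value = c(0.20, 0.0008, 0.3, 0.04))
  sig <- significant(hits, scan_config())
  expect_equal(nrow(sig), 2)                 # p<=a & q<=a only
  expect_equal(sig$q_level, c("***", "*"))
  expect_equal(nrow(significant(hits[0, ], scan_config())), 0)
  # single-filter switches
  expect_equal(nrow(significant(hits, scan_config(filter = "p"))), 3)
  expect_equal(nrow(significant(hits, scan_config(filter = "q"))), 2)
})

test_that("false-positive rate on background is calibrated at alpha", {
  withr::with_seed(59, {
    segs <- random_segments(4, 2500, at = 0.5)
    m <- sharp_pswm("ACGTTAACGTAC")
    cfg <- scan_config(alpha = 0.05, background = "uniform")
    hits <- scan_segments(segs, list(m), cfg)
    n <- attr(hits, "n_tests")
    frac <- nrow(hits) / n
    se <- sqrt(0.05 * 0.95 / n)
    expect_lte(frac, 0.05 + 3 * se)
  })
})

test_that("doubling bins moves p-values by at most neighboring-bin mass", {
  withr::with_seed(61, {
    m <- build_pswm(c("ACGTTA", "ACGTAA", "TCGTTA", "ACATTA"),
                    pseudocount = 0.2)
    bg <- rep(0.25, 4)
    t1 <- pvalue_table(m, bg, bins = 1000)
    t2 <- pvalue_table(m, bg, bins = 2000)
    oracle <- bf_pvalues(m, bg)
    words <- as.matrix(expand.grid(rep(list(1:4), 6)))
    for (r in sample(nrow(words), 30)) {
      idx <- words[r, ]
      score <- sum(log_odds(m, bg)[cbind(1:6, idx)])
      p1 <- pvalue_lookup(t1, score)
      p2 <- pvalue_lookup(t2, score)
      slack <- oracle$p_of(score - 6 / t1$scale) -
        oracle$p_of(score + 6 / t1$scale)
      expect_lte(abs(p1 - p2), slack + 1e-12)
    }
  })
})
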