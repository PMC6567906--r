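test_that("reference aggregation is the arithmetic mean of reference Cts", {
  expect_equal(aggregate_reference(c(HPRT1 = 20, `18S` = 10),
                                   c("HPRT1", "18S")), 15)
  expect_equal(aggregate_reference(c(HPRT1 = 20), "HPRT1"), 20)
  expect_equal(aggregate_reference(c(HPRT1 = 22.4, `18S` = 9.6),
                                   c("HPRT1", "18S")), 16)
  expect_error(aggregate_reference(c(HPRT1 = 20), c("HPRT1", "18S")),
               "missing reference")
  expect_error(aggregate_reference(c(HPRT1 = NA_real_), "HPRT1"),
               "undetermined")
})

test_that("delta-delta-Ct fold changes follow 2^-ddct with calibrator at 1", {
  ct <- make_ct_table(list(S1 = c(GENE = 24)), calibrator_delta = 3)
  rq <- compute_rq(ct, calibrator = "CAL")
  s1 <- rq[rq$sample_id == "S1", ]
  expect_equal(s1$delta_ct, 24 - 15)
  expect_equal(s1$ddct, 9 - 3)
  expect_equal(s1$rq, 2^-6)
  # hand oracle: target 24, reference aggregate 20, calibrator delta 3
  ct2 <- make_ct_table(list(S1 = c(G = 24)),
                       ref = list(HPRT1 = 20), calibrator_delta = 3)
  r2 <- compute_rq(ct2, reference_genes = "HPRT1", calibrator = "CAL")
  expect_equal(r2$ddct[r2$sample_id == "S1"], 1)
  expect_equal(r2$rq[r2$sample_id == "S1"], 0.5)
  expect_equal(r2$rq[r2$sample_id == "CAL"], 1)
})

test_that("every calibrator RQ is exactly one and a unit Ct shift halves RQ", {
  set.seed(42)
  for (rep in 1:5) {
    genes <- paste0("G", 1:4)
    samples <- paste0("S", 1:6)
    cts <- lapply(samples, function(s)
      stats::setNames(runif(4, 18, 30), genes))
    names(cts) <- samples
    ct <- make_ct_table(cts)
    rq <- compute_rq(ct, calibrator = "CAL")
    expect_equal(rq$rq[rq$sample_id == "CAL"], rep(1, 4))
    # +1 cycle on every target Ct of one sample halves all its RQs
    ct_shift <- dplyr::mutate(ct, ct = ct +
      ifelse(sample_id == "S1" & gene %in% genes, 1, 0))
    rq_shift <- compute_rq(ct_shift, calibrator = "CAL")
    expect_equal(rq_shift$rq[rq_shift$sample_id == "S1"],
                 rq$rq[rq$sample_id == "S1"] / 2)
  }
})

test_that("RQ output is invariant to input row order", {
  set.seed(7)
  ct <- make_ct_table(list(S1 = c(A = 24, B = 26), S2 = c(A = 22, B = 28)))
  rq1 <- compute_rq(ct, calibrator = "CAL")
  rq2 <- compute_rq(ct[sample(nrow(ct)), ], calibrator = "CAL")
  expect_equal(as.data.frame(rq1), as.data.frame(rq2))
})

test_that("replicates are averaged on the Ct scale before normalisation", {
  ct <- make_ct_table(list(S1 = c(G = 24)))
  ct$replicate <- 1L
  extra <- ct[ct$sample_id == "S1" & ct$gene == "G", ]
  extra$ct <- 26
  extra$replicate <- 2L
  rq <- compute_rq(dplyr::bind_rows(ct, extra), calibrator = "CAL")
  # mean Ct 25 -> delta 10, ddct 7
  expect_equal(rq$rq[rq$sample_id == "S1"], 2^-7)
})

test_that("undetermined targets stay missing and broken samples are excluded", {
  ct <- make_ct_table(list(S1 = c(A = 24, B = NA), S2 = c(A = 22, B = 23)))
  rq <- compute_rq(ct, calibrator = "CAL")
  expect_true(is.na(rq$rq[rq$sample_id == "S1" & rq$gene == "B"]))
  expect_false(anyNA(rq$rq[rq$sample_id == "S2"]))

  # missing reference gene excludes the sample, with a logged reason
  ct_bad <- dplyr::filter(ct, !(sample_id == "S1" & gene == "HPRT1"))
  expect_warning(rq_b <- compute_rq(ct_bad, calibrator = "CAL"), "excluded")
  expect_false("S1" %in% rq_b$sample_id)
  excl <- attr(rq_b, "excluded")
  expect_identical(excl$sample_id, "S1")

  expect_error(compute_rq(ct, calibrator = "missing"), "not present")
  dup <- dplyr::bind_rows(ct, ct[1, ])
  expect_error(compute_rq(dup, calibrator = "CAL"), "duplicate")
  ct_neg <- ct
  ct_neg$ct[1] <- -1
  expect_error(compute_rq(ct_neg, calibrator = "CAL"), "non-negative")
})

test_that("panel counts are normalised by the housekeeping geometric mean", {
  counts <- tibble::tibble(
    sample_id = "S1",
    gene = c("HPRT1", "NRDC", "OTUD5", "T1", "T2", "T3"),
    count = c(10, 10, 10, 100, 0, 120)
  )
  out <- panel_normalize(counts)
  expect_equal(out$norm_count[out$gene == "T1"], 10)
  expect_equal(out$norm_count[out$gene == "T2"], 0)
  # geometric mean of {8, 27, 1} is 6
  counts2 <- tibble::tibble(
    sample_id = "S2", gene = c("HPRT1", "NRDC", "OTUD5", "T1"),
    count = c(8, 27, 1, 120)
  )
  out2 <- panel_normalize(counts2)
  expect_equal(out2$norm_count, 20)

  # a zero housekeeping count invalidates the whole sample
  counts3 <- dplyr::mutate(counts2,
                           count = ifelse(gene == "NRDC", 0, count))
  expect_warning(out3 <- panel_normalize(counts3), "excluded")
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "excluded")$sample_id, "S2")
})
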