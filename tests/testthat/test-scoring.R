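test_that("healthy-control reference takes per-gene medians", {
  rq <- make_rq_table(list(C1 = c(g = 1), C2 = c(g = 2), C3 = c(g = 3)))
  panel <- isg_panel("custom", genes = "g", min_genes_required = 1)
  ref <- build_hc_reference(rq, panel)
  expect_equal(ref$medians$median_rq, 2)
  expect_equal(ref$n_controls, 3)

  rq2 <- make_rq_table(list(C1 = c(g = 1), C2 = c(g = 100)))
  expect_equal(build_hc_reference(rq2, panel)$medians$median_rq, 50.5)

  expect_error(build_hc_reference(make_rq_table(list(C1 = c(g = 1))), panel),
               "at least 2")
  panel2 <- isg_panel("custom", genes = c("g", "h"), min_genes_required = 1)
  expect_error(build_hc_reference(rq, panel2), "absent in all controls: h")
})

test_that("simulated control medians sit near the generating median", {
  set.seed(11)
  genes <- qpcr6_genes()
  rq <- purrr::map_dfr(sprintf("HC%02d", 1:29), function(s) {
    tibble::tibble(sample_id = s, gene = genes,
                   rq = rlnorm(6, 0, 0.25))
  })
  ref <- build_hc_reference(rq, isg_panel("qpcr6"))
  expect_true(all(abs(ref$medians$median_rq - 1) < 0.1))
})

test_that("the ISG score is the median fold change against HC medians", {
  genes <- qpcr6_genes()
  ref <- unit_reference(genes)
  panel <- isg_panel("qpcr6")

  rq <- make_rq_table(list(S1 = stats::setNames(rep(1, 6), genes)))
  expect_equal(compute_isg_score(rq, ref, panel)$score, 1)

  fc <- stats::setNames(c(0.5, 1, 2, 3, 4, 8), genes)
  rq2 <- make_rq_table(list(S1 = fc))
  s <- compute_isg_score(rq2, ref, panel)
  expect_equal(s$score, 2.5)
  expect_equal(s$n_genes_used, 6L)
  expect_equal(sort(unname(s$fold_changes[[1]])), sort(unname(fc)))
})

test_that("scoring matches a sort-based median oracle on random samples", {
  set.seed(101)
  genes <- qpcr6_genes()
  ref <- unit_reference(genes)
  panel <- isg_panel("qpcr6")
  sort_median <- function(x) {
    x <- sort(x)
    n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  for (i in 1:50) {
    fc <- stats::setNames(rlnorm(6, 0, 1), genes)
    rq <- make_rq_table(list(S = fc))
    expect_identical(compute_isg_score(rq, ref, panel)$score,
                     sort_median(unname(fc)))
  }
})

test_that("scores are scale-equivariant and monotone in fold changes", {
  set.seed(55)
  genes <- qpcr6_genes()
  panel <- isg_panel("qpcr6")
  for (i in 1:10) {
    med <- rlnorm(6, 0, 0.5)
    ref <- structure(list(panel_id = "qpcr6",
                          medians = tibble::tibble(gene = genes,
                                                   median_rq = med),
                          n_controls = 10),
                     class = "hc_reference")
    rqv <- stats::setNames(rlnorm(6, 0, 1), genes)
    s0 <- compute_isg_score(make_rq_table(list(S = rqv)), ref, panel)$score

    # multiply one gene's RQ and its HC median by the same constant
    k <- runif(1, 0.1, 10)
    g <- sample(genes, 1)
    med2 <- med; med2[genes == g] <- med2[genes == g] * k
    rqv2 <- rqv; rqv2[g] <- rqv2[g] * k
    ref2 <- structure(list(panel_id = "qpcr6",
                           medians = tibble::tibble(gene = genes,
                                                    median_rq = med2),
                           n_controls = 10),
                      class = "hc_reference")
    s1 <- compute_isg_score(make_rq_table(list(S = rqv2)), ref2, panel)$score
    expect_equal(s1, s0)

    # increasing one fold change never decreases the score
    rqv3 <- rqv; rqv3[g] <- rqv3[g] * 2
    s2 <- compute_isg_score(make_rq_table(list(S = rqv3)), ref, panel)$score
    expect_gte(s2, s0)
  }
})

test_that("samples below the minimum gene count are scored missing", {
  genes <- qpcr6_genes()
  ref <- unit_reference(genes)
  panel <- isg_panel("qpcr6")  # needs 4 of 6
  rq <- make_rq_table(list(S1 = stats::setNames(c(1, 2, 3), genes[1:3]),
                           S2 = stats::setNames(rep(2, 4), genes[1:4])))
  expect_warning(s <- compute_isg_score(rq, ref, panel), "missing")
  expect_true(is.na(s$score[s$sample_id == "S1"]))
  expect_equal(s$n_genes_used[s$sample_id == "S1"], 3L)
  expect_equal(s$score[s$sample_id == "S2"], 2)
})

test_that("threshold calibration is the control mean plus two sample SDs", {
  expect_identical(calibrate_threshold(c(2, 2, 2))$threshold, 2)
  cal <- calibrate_threshold(c(1, 2, 3))
  expect_identical(cal$threshold, 4)
  expect_identical(cal$hc_mean, 2)
  expect_identical(cal$hc_sd, 1)
  expect_error(calibrate_threshold(3), "at least 2")

  # independent two-pass mean/SD computation
  set.seed(12)
  x <- rlnorm(29, 0, 0.5)
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(calibrate_threshold(x)$threshold, m + 2 * s,
               tolerance = 1e-12)
})

test_that("positivity is strictly above the threshold", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                       panel_id = "qpcr6",
                       score = c(7.052, 0.8115, 2.466, NA),
                       n_genes_used = 6L)
  out <- classify_samples(sc, fixed_threshold("qpcr6"))
  expect_identical(out$positive, c(TRUE, FALSE, FALSE, NA))
  expect_equal(attr(out, "threshold"), 2.466)

  # monotone: any sample scoring at least a positive sample is positive
  set.seed(3)
  sc2 <- tibble::tibble(sample_id = as.character(1:50), panel_id = "qpcr6",
                        score = rlnorm(50, 0, 1), n_genes_used = 6L)
  out2 <- classify_samples(sc2, 1.5)
  pos_min <- min(out2$score[out2$positive])
  expect_true(all(out2$positive[out2$score >= pos_min]))
})

test_that("fixed thresholds carry the published cutoffs", {
  expect_equal(fixed_threshold("qpcr6")$threshold, 2.466)
  expect_equal(fixed_threshold("panel30")$threshold, 1.642)
  expect_equal(fixed_threshold("x", threshold = 3)$threshold, 3)
})
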