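test_that("cohort configuration is validated", {
  expect_s3_class(cohort_config(seed = 1), "cohort_config")
  expect_error(cohort_config(positivity_prevalence = 1.5, seed = 1),
               "positivity_prevalence")
  expect_error(cohort_config(seed = NA), "seed")
  expect_error(cohort_config(not_a_field = 1, seed = 1), "unknown")
  expect_error(cohort_config(n_protein = 200, seed = 1), "n_protein")
})

test_that("generation is bit-identical for identical seeds and configs", {
  cfg <- cohort_config(n_patients = 40, n_controls = 10,
                       n_nar_patients = 30, n_nar_controls = 8,
                       n_protein = 20, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$ct_qpcr, b$ct_qpcr)
  expect_identical(a$ct_nar, b$ct_nar)
  expect_identical(a$protein, b$protein)
  c2 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$ct_qpcr, c2$ct_qpcr))
})

test_that("degenerate cohort sizes behave per contract", {
  empty <- generate_cohort(cohort_config(
    n_patients = 0, n_controls = 0, n_nar_patients = 0, n_nar_controls = 0,
    n_protein = 0, n_blanks = 0, seed = 1
  ))
  expect_equal(nrow(empty$patients), 0)
  expect_true(all(c("sample_id", "gene", "ct") %in% names(empty$ct_qpcr)))
  expect_true(all(c("sample_id", "concentration_fg_ml", "is_blank") %in%
                    names(empty$protein)))

  all_pos <- generate_cohort(cohort_config(
    n_patients = 30, positivity_prevalence = 1, n_nar_patients = 30,
    n_protein = 30, seed = 2
  ))
  expect_true(all(all_pos$truth$samples$latent_positive[
    all_pos$truth$samples$group == "patient"]))
})

test_that("back-computed Ct tables round-trip through the RQ pipeline", {
  cfg <- cohort_config(seed = 3)
  coh <- generate_cohort(cfg)
  rq <- compute_rq(coh$ct_qpcr, calibrator = "CAL")
  joined <- dplyr::inner_join(
    rq, dplyr::select(coh$truth$gene_truth, sample_id, gene, true_rq,
                      true_fold_change),
    by = c("sample_id", "gene")
  )
  # RQ recovery is exact up to floating point
  expect_equal(joined$rq, joined$true_rq, tolerance = 1e-9)

  # scoring against the generator's true HC medians recovers each drawn
  # score up to the per-gene noise
  ref <- structure(
    list(panel_id = "qpcr6",
         medians = tibble::tibble(gene = names(cfg$hc_median_rq),
                                  median_rq = unname(cfg$hc_median_rq)),
         n_controls = cfg$n_controls),
    class = "hc_reference"
  )
  pat_ids <- coh$meta$sample_id[coh$meta$group == "patient"]
  scores <- compute_isg_score(dplyr::filter(rq, sample_id %in% pat_ids),
                              ref, isg_panel("qpcr6"))
  truth <- dplyr::inner_join(scores, coh$truth$samples, by = "sample_id")
  rel_err <- abs(truth$score / truth$true_score - 1)
  expect_lt(median(rel_err), 0.05)
})

test_that("the copula pair generator hits its Spearman targets", {
  near <- generate_correlated_pair(100, 0.99, seed = 1)
  expect_gt(cor(near$x, near$y, method = "spearman"), 0.9)

  null <- generate_correlated_pair(155, 0, seed = 2)
  expect_lt(abs(cor(null$x, null$y, method = "spearman")), 0.16)

  # marginals are respected
  ln <- generate_correlated_pair(2000, 0.5, qy = function(p)
    qlnorm(p, 1, 2), seed = 3)
  expect_equal(median(ln$y), exp(1), tolerance = 0.15)

  expect_error(generate_correlated_pair(10, 1), "inside")
  expect_error(generate_correlated_pair(10, 0.5, qx = "not a function"),
               "quantile")
})

test_that("truth checking scores recovery and rejects mismatched cohorts", {
  cfg <- cohort_config(seed = 4)
  coh <- generate_cohort(cfg)
  res <- run_full_analysis(coh, seed = 4)
  calls <- dplyr::select(res$scores, sample_id, score, positive)
  tc <- truth_check(coh, calls)
  expect_gte(tc$accuracy, 0.9)
  expect_equal(sum(tc$confusion), 164)
  # most recovered antibody ORs should cover their generating values
  covered <- with(tc$antibody_or,
                  generating_or >= ci_low & generating_or <= ci_high)
  expect_gte(mean(covered), 0.7)
  expect_equal(tc$protein_corr$target, 0.8307)
  expect_equal(tc$protein_corr$recovered, 0.8307, tolerance = 0.12)

  other <- generate_cohort(cohort_config(n_patients = 10, n_protein = 5,
                                         n_nar_patients = 10, seed = 9))
  expect_error(truth_check(other, calls), "mismatch")
})

test_that("cohort CSVs are written with matching schemas", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_config(n_patients = 12, n_controls = 5,
                                       n_nar_patients = 10,
                                       n_nar_controls = 4, n_protein = 8,
                                       seed = 8))
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(dir, "ct_qpcr.csv"))
  expect_identical(names(back), c("sample_id", "gene", "ct"))
  expect_equal(nrow(back), nrow(coh$ct_qpcr))
})
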