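#' Run the full interferon-signature analysis end to end
#'
#' Orchestrates every stage over an in-memory cohort (such as a
#' [generate_cohort()] result or equivalently shaped tibbles read from
#' file): relative quantification, healthy-control reference and ISG
#' scoring, threshold classification, mixture classification and
#' concordance, protein LOD and positivity, the clinical association
#' surface (group summary, haematology rank tests, autoantibody odds-ratio
#' ladder, diagnosis model, antibody-count trend), and NAR profiling
#' (control comparison, score correlations, k-means subgroups, neutrophil
#' model ladder, correlation matrix). Any stage failure aborts with the
#' stage name.
#'
#' @param cohort List with `patients`, `ct_qpcr`, `meta`, and optionally
#'   `ct_nar`, `nar_meta`, `protein` (see [generate_cohort()] for shapes).
#' @param panel [isg_panel()] to score (default the six-gene qPCR panel).
#' @param threshold `"fixed"` (published cutoff for the panel),
#'   `"calibrate"` (healthy-control mean + 2 SD), or a numeric cutoff.
#' @param reference_genes Reference genes for the Ct tables.
#' @param calibrator Calibrator sample id (default `"CAL"`).
#' @param k Number of NAR k-means clusters (default 6).
#' @param seed Integer seed for the mixture restarts and clustering.
#' @return Object of class `ifn_analysis`: list with `rq`, `hc_reference`,
#'   `calibration`, `scores` (classified patient scores), `control_scores`,
#'   `mixture`, `mixture_calls`, `concordance`, `protein`, `lod`,
#'   `protein_score_corr`, `table1`, `haematology`, `antibody_or`,
#'   `diagnosis_model`, `antibody_trend`, `nar` (sub-list) and `manifest`.
#' @export
run_full_analysis <- function(cohort, panel = isg_panel("qpcr6"),
                              threshold = c("fixed", "calibrate"),
                              reference_genes = c("HPRT1", "18S"),
                              calibrator = "CAL", k = 6, seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  for (tab in c("patients", "ct_qpcr", "meta")) {
    if (is.null(cohort[[tab]])) {
      stop("cohort is missing the '", tab, "' table", call. = FALSE)
    }
  }

  rq <- stage("relquant", compute_rq(cohort$ct_qpcr, reference_genes,
                                     calibrator = calibrator))
  control_ids <- cohort$meta$sample_id[cohort$meta$group == "control"]
  patient_ids <- cohort$meta$sample_id[cohort$meta$group == "patient"]

  hc_ref <- stage("scoring", build_hc_reference(
    dplyr::filter(rq, .data$sample_id %in% control_ids), panel
  ))
  control_scores <- stage("scoring", compute_isg_score(
    dplyr::filter(rq, .data$sample_id %in% control_ids), hc_ref, panel
  ))
  patient_scores <- stage("scoring", compute_isg_score(
    dplyr::filter(rq, .data$sample_id %in% patient_ids), hc_ref, panel
  ))

  calibration <- stage("threshold", {
    if (is.numeric(threshold)) {
      fixed_threshold(panel$panel_id, threshold = threshold)
    } else {
      switch(match.arg(threshold),
        fixed = fixed_threshold(panel$panel_id),
        calibrate = calibrate_threshold(control_scores$score,
                                        panel_id = panel$panel_id)
      )
    }
  })
  scores <- stage("classify", classify_samples(patient_scores, calibration))

  mixture <- stage("mixture", {
    ok <- !is.na(scores$score) & scores$score > 0
    fit <- fit_mixture_em(log10(scores$score[ok]), seed = seed)
    calls <- stats::setNames(classify_mixture(fit), scores$sample_id[ok])
    thr_calls <- stats::setNames(scores$positive[ok], scores$sample_id[ok])
    list(fit = fit, calls = calls,
         concordance = concordance(thr_calls, calls))
  })

  protein_res <- if (!is.null(cohort$protein)) {
    stage("protein", {
      blanks <- cohort$protein$concentration_fg_ml[cohort$protein$is_blank]
      lod <- if (length(blanks) >= 2) compute_lod(blanks) else 0.23
      cls <- classify_protein(cohort$protein, lod = lod)
      joined <- dplyr::inner_join(
        cls, dplyr::select(scores, "sample_id", "score"), by = "sample_id"
      )
      r <- if (nrow(joined) >= 3) {
        suppressWarnings(stats::cor(joined$concentration_fg_ml,
                                    joined$score, method = "spearman"))
      } else NA_real_
      list(classified = cls, lod = lod, score_corr = r)
    })
  } else NULL

  calls_tbl <- dplyr::select(scores, "sample_id", "score", "positive")
  table1 <- stage("table1", summarize_table1(cohort$patients, calls_tbl))

  haem_vars <- intersect(
    c("haemoglobin", "wcc", "lymphocytes", "neutrophils", "platelets",
      "esr", "crp"),
    names(cohort$patients)
  )
  haem <- stage("haematology", {
    dat <- dplyr::inner_join(cohort$patients, calls_tbl, by = "sample_id")
    purrr::map_dfr(haem_vars, function(v) {
      rank_tests(dat[[v]], dat$positive) |>
        dplyr::mutate(variable = v, .before = 1)
    })
  })

  ab_names <- intersect(names(cohort$truth$config$antibodies$negative %||%
                                c(dsDNA = NA)),
                        names(cohort$patients))
  if (length(ab_names) == 0) {
    ab_names <- intersect(c("dsDNA", "Ro", "La", "Smith", "RNP", "chromatin",
                            "rheumatoid_factor", "CCP", "SSc_specific",
                            "Jo1"), names(cohort$patients))
  }
  antibody_or <- stage("associations", {
    dat <- dplyr::inner_join(cohort$patients, calls_tbl, by = "sample_id")
    purrr::map_dfr(ab_names, function(ab) {
      abv <- as.logical(dat[[ab]])
      odds_ratio_2x2(sum(dat$positive & abv), sum(dat$positive & !abv),
                     sum(!dat$positive & abv), sum(!dat$positive & !abv),
                     term = ab)
    })
  })
  diagnosis_model <- stage("associations", {
    dat <- dplyr::inner_join(cohort$patients, calls_tbl, by = "sample_id")
    if (dplyr::n_distinct(dat$diagnosis) > 1 &&
        all(c(TRUE, FALSE) %in% dat$positive)) {
      # sparse diagnosis strata are expected in replicate cohorts; the
      # per-term `flagged` column carries any separation signal
      suppressWarnings(logistic_fit(dat, positive ~ diagnosis))
    } else NULL
  })
  antibody_trend <- stage("associations", {
    tryCatch(antibody_count_trend(cohort$patients, calls_tbl,
                                  antibodies = setdiff(ab_names, "Jo1")),
             error = function(e) NULL)
  })

  nar_res <- if (!is.null(cohort$ct_nar)) {
    stage("nar", {
      rq_nar <- compute_rq(cohort$ct_nar, reference_genes,
                           calibrator = calibrator)
      nar_pat <- dplyr::filter(
        rq_nar, .data$sample_id %in%
          cohort$nar_meta$sample_id[cohort$nar_meta$group == "patient"])
      nar_ctl <- dplyr::filter(
        rq_nar, .data$sample_id %in%
          cohort$nar_meta$sample_id[cohort$nar_meta$group == "control"])
      clusters <- cluster_patients(nar_pat, k = k, seed = seed)
      corr_data <- nar_pat |>
        dplyr::mutate(rq = log10(.data$rq)) |>
        tidyr::pivot_wider(id_cols = "sample_id", names_from = "gene",
                           values_from = "rq") |>
        dplyr::inner_join(calls_tbl, by = "sample_id") |>
        dplyr::inner_join(
          dplyr::select(cohort$patients, "sample_id",
                        dplyr::any_of(haem_vars)),
          by = "sample_id")
      list(
        vs_controls = nar_vs_controls(nar_pat, nar_ctl),
        score_corr = nar_score_correlation(nar_pat, calls_tbl),
        clusters = clusters,
        neutrophil_ladder = if ("neutrophils" %in% names(cohort$patients)) {
          neutrophil_model_ladder(cohort$patients, nar_pat, calls_tbl)
        } else NULL,
        corr_matrix = spearman_matrix(
          dplyr::select(corr_data, -"sample_id", -"positive"))
      )
    })
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("ifnsig")),
    seed = seed,
    panel = panel$panel_id,
    threshold = calibration$threshold,
    threshold_source = calibration$source,
    n_patients = length(patient_ids),
    n_controls = length(control_ids),
    n_scored = sum(!is.na(scores$score)),
    config_hash = rlang::hash(list(panel, calibration$threshold, seed))
  )

  structure(
    list(
      rq = rq, hc_reference = hc_ref, calibration = calibration,
      scores = scores, control_scores = control_scores,
      mixture = mixture$fit, mixture_calls = mixture$calls,
      concordance = mixture$concordance,
      protein = protein_res$classified, lod = protein_res$lod,
      protein_score_corr = protein_res$score_corr,
      table1 = table1, haematology = haem, antibody_or = antibody_or,
      diagnosis_model = diagnosis_model, antibody_trend = antibody_trend,
      nar = nar_res, manifest = manifest
    ),
    class = "ifn_analysis"
  )
}

#' @export
print.ifn_analysis <- function(x, ...) {
  m <- x$manifest
  cat("Interferon-signature analysis (panel '", m$panel, "', seed ",
      m$seed, ")\n", sep = "")
  cat("  ", m$n_patients, " patients, ", m$n_controls, " controls; ",
      "threshold ", format(m$threshold), " (", m$threshold_source, ")\n",
      sep = "")
  pos <- sum(x$scores$positive, na.rm = TRUE)
  cat(sprintf("  ISG-positive: %d/%d (%.1f%%)\n", pos, m$n_scored,
              100 * pos / m$n_scored))
  cat("  mixture discordant:", nrow(x$concordance$discordant), "\n")
  invisible(x)
}

#' Grouped cohort summary split by ISG status
#'
#' Builds the standard clinical baseline table: for each variable, `n (%)`
#' for binary and categorical columns or `median (IQR)` for continuous
#' ones, split into ISG-negative and ISG-positive columns, with the
#' matching two-group test (Mann-Whitney U for continuous, Fisher exact
#' for categorical) in a p-value column. Percentages are reported to one
#' decimal.
#'
#' @param patients Patient tibble (`sample_id` plus covariates).
#' @param calls Classified score tibble (`sample_id`, `positive`).
#' @param variables Columns to summarise (default: every column except
#'   identifiers).
#' @return Tibble with `variable`, `level`, `overall`, `isg_negative`,
#'   `isg_positive`, `p_value` (p on the first row of each variable).
#' @export
summarize_table1 <- function(patients, calls,
                             variables = setdiff(names(patients),
                                                 c("sample_id", "group"))) {
  dat <- dplyr::inner_join(patients,
                           dplyr::select(calls, "sample_id", "positive"),
                           by = "sample_id")
  npos <- sum(dat$positive, na.rm = TRUE)
  nneg <- sum(!dat$positive, na.rm = TRUE)

  fmt_np <- function(k, n) {
    if (n == 0) "" else sprintf("%d (%.1f)", k, 100 * k / n)
  }
  fmt_miqr <- function(v) {
    if (all(is.na(v))) return("")
    q <- stats::quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.3g (%.3g, %.3g)", q[1], q[2], q[3])
  }

  purrr::map_dfr(variables, function(v) {
    x <- dat[[v]]
    neg <- x[!dat$positive]; pos <- x[dat$positive]
    if (is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1, NA)))) {
      x <- as.logical(x)
      p <- if (npos > 0 && nneg > 0) {
        fisher_exact(sum(pos == TRUE, na.rm = TRUE),
                     sum(pos == FALSE, na.rm = TRUE),
                     sum(neg == TRUE, na.rm = TRUE),
                     sum(neg == FALSE, na.rm = TRUE))
      } else NA_real_
      tibble::tibble(
        variable = v, level = "yes",
        overall = fmt_np(sum(x, na.rm = TRUE), length(x)),
        isg_negative = fmt_np(sum(neg, na.rm = TRUE), nneg),
        isg_positive = fmt_np(sum(pos, na.rm = TRUE), npos),
        p_value = p
      )
    } else if (is.numeric(x)) {
      p <- if (npos > 0 && nneg > 0) {
        rank_tests(x, dat$positive)$p_value
      } else NA_real_
      tibble::tibble(
        variable = v, level = "",
        overall = fmt_miqr(x), isg_negative = fmt_miqr(neg),
        isg_positive = fmt_miqr(pos), p_value = p
      )
    } else {
      x <- factor(x)
      p <- if (npos > 0 && nneg > 0 && nlevels(droplevels(x)) > 1) {
        tab <- table(x, dat$positive)
        tryCatch(
          stats::fisher.test(tab, workspace = 2e6)$p.value,
          error = function(e)
            suppressWarnings(stats::chisq.test(tab)$p.value)
        )
      } else NA_real_
      purrr::imap_dfr(levels(x), function(lv, i) {
        tibble::tibble(
          variable = v, level = lv,
          overall = fmt_np(sum(x == lv, na.rm = TRUE), length(x)),
          isg_negative = fmt_np(sum(neg == lv, na.rm = TRUE), nneg),
          isg_positive = fmt_np(sum(pos == lv, na.rm = TRUE), npos),
          p_value = if (i == 1) p else NA_real_
        )
      })
    }
  })
}
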