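#' Synthetic SARD cohort configuration
#'
#' Generative parameters for a synthetic mixed systemic-autoimmune cohort
#' with the statistical structure the analysis pipeline assumes: a bimodal
#' log10 ISG score (two Gaussian components), status-conditional diagnosis,
#' autoantibody, medication, clinical-feature and haematology
#' distributions, rank-correlation-targeted nucleic-acid-receptor (NAR)
#' expression and plasma protein levels, and qPCR Ct tables back-computed
#' from the drawn fold changes so the whole relative-quantification
#' pipeline can be exercised end to end.
#'
#' Defaults encode the motivating study's cohort: 164 patients, 29 healthy
#' controls, 38.4% latent ISG positivity, conditional prevalences and
#' lognormal haematology parameters matched to the published group tables,
#' NAR-score rank correlation targets (DDX58 0.7386, TLR7 0.3262, MB21D1
#' 0.2266, others null), a protein-score rank correlation target of 0.8307
#' with an LOD floor of 0.23 fg/ml, and healthy-control scores whose
#' natural-scale mean + 2 SD calibration lands near the published 2.466
#' cutoff.
#'
#' @param n_patients,n_controls,n_nar_patients,n_nar_controls,n_protein,n_blanks
#'   Cohort sizes (defaults 164, 29, 155, 16, 92, 40).
#' @param positivity_prevalence Latent probability of ISG positivity
#'   (default 0.384).
#' @param score_low,score_high Length-2 numeric `c(mean, sd)` of the log10
#'   score components (defaults `c(-0.3, 0.3)` and `c(0.9, 0.35)`).
#' @param hc_score `c(mean, sd)` of healthy-control log10 scores (default
#'   `c(0, 0.23)`, giving a lognormal with median 1 whose mean + 2 SD is
#'   approximately 2.466).
#' @param gene_noise_sd Per-gene log10 multiplicative noise around the
#'   drawn score (default 0.05).
#' @param threshold Positivity threshold the fixed classification mode uses
#'   (default 2.466).
#' @param seed Mandatory integer seed.
#' @param ... Expert overrides for the remaining generative blocks (see
#'   the object returned for their names and shapes).
#' @return Object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_patients = 164, n_controls = 29,
                          n_nar_patients = 155, n_nar_controls = 16,
                          n_protein = 92, n_blanks = 40,
                          positivity_prevalence = 0.384,
                          score_low = c(-0.3, 0.3),
                          score_high = c(0.9, 0.35),
                          hc_score = c(0, 0.23),
                          gene_noise_sd = 0.05,
                          threshold = 2.466,
                          seed = 1, ...) {
  cfg <- list(
    n_patients = n_patients, n_controls = n_controls,
    n_nar_patients = n_nar_patients, n_nar_controls = n_nar_controls,
    n_protein = n_protein, n_blanks = n_blanks,
    positivity_prevalence = positivity_prevalence,
    score_low = score_low, score_high = score_high, hc_score = hc_score,
    gene_noise_sd = gene_noise_sd, threshold = threshold, seed = seed,

    # per-gene healthy-control median RQ levels (exogenous, exercise scale
    # equivariance of the scoring rule)
    hc_median_rq = c(IFI27 = 0.8, IFI44L = 1.2, IFIT1 = 1.0, ISG15 = 0.9,
                     RSAD2 = 1.1, SIGLEC1 = 1.0),
    reference_ct = c(HPRT1 = 20, `18S` = 10),
    reference_ct_sd = 0.2,
    calibrator_delta_ct = 3,

    # status-conditional diagnosis proportions (ISG-negative, ISG-positive)
    diagnosis = list(
      levels = c("UCTD", "SLE", "MCTD", "SS", "IIM", "SSc"),
      p_negative = c(34, 40, 4, 6, 6, 11) / 101,
      p_positive = c(9, 27, 9, 14, 2, 2) / 63
    ),
    # conditional autoantibody prevalences P(ab+ | status)
    antibodies = list(
      negative = c(dsDNA = 24, Ro = 18, La = 9, Smith = 5, RNP = 13,
                   chromatin = 9, rheumatoid_factor = 12, CCP = 3,
                   SSc_specific = 11, Jo1 = 3) / 101,
      positive = c(dsDNA = 22, Ro = 31, La = 14, Smith = 18, RNP = 26,
                   chromatin = 24, rheumatoid_factor = 25, CCP = 4,
                   SSc_specific = 4, Jo1 = 1) / 63
    ),
    medications = list(
      negative = c(prednisolone = 28 / 101, anti_malarial = 64 / 101,
                   immunosuppressant = 28 / 101),
      positive = c(prednisolone = 17 / 63, anti_malarial = 32 / 63,
                   immunosuppressant = 19 / 63)
    ),
    clinical_features = list(
      negative = c(photosensitivity = 43 / 101, mucosal_ulcers = 41 / 101,
                   raynauds = 55 / 101, arthritis = 42 / 100,
                   renal = 13 / 99, neurological = 2 / 101,
                   haem_disorder = 35 / 99),
      positive = c(photosensitivity = 21 / 62, mucosal_ulcers = 22 / 62,
                   raynauds = 32 / 62, arthritis = 33 / 63,
                   renal = 11 / 62, neurological = 2 / 63,
                   haem_disorder = 39 / 61)
    ),
    # lognormal (median, q1, q3) per ISG status for continuous clinicals
    continuous = list(
      haemoglobin = list(negative = c(13.4, 12.5, 13.9),
                         positive = c(12.9, 11.6, 13.3)),
      wcc         = list(negative = c(5.80, 4.55, 7.25),
                         positive = c(4.95, 3.60, 5.80)),
      lymphocytes = list(negative = c(1.62, 1.27, 2.10),
                         positive = c(1.31, 0.96, 1.75)),
      neutrophils = list(negative = c(3.39, 2.47, 4.51),
                         positive = c(2.81, 1.99, 3.86)),
      platelets   = list(negative = c(253, 221, 311),
                         positive = c(249, 191, 286)),
      esr         = list(negative = c(8, 5, 17.5),
                         positive = c(14, 8, 35.5)),
      crp         = list(negative = c(1.5, 1.0, 5.0),
                         positive = c(2.0, 1.0, 4.0)),
      disease_duration = list(negative = c(6.84, 3.06, 15.3),
                              positive = c(8.08, 3.56, 16.1))
    ),
    age = list(negative = c(mean = 50.3, sd = 14.0),
               positive = c(mean = 44.8, sd = 15.7)),
    female = c(negative = 97 / 101, positive = 58 / 63),
    ethnicity = list(
      levels = c("Caucasian", "Mixed", "Asian or Asian British",
                 "Black or Black British", "Other", "Unknown"),
      p_negative = c(80, 1, 3, 12, 4, 1) / 101,
      p_positive = c(42, 0, 5, 12, 4, 0) / 63
    ),

    # NAR generation: rank-correlation targets with the score, lognormal
    # marginals (patient elevation over controls for all but TLR3), and
    # planted log-neutrophil effects per unit of log10 RQ
    nar = list(
      score_rank_corr = c(TLR3 = 0, TLR7 = 0.3262, TLR9 = 0,
                          DDX58 = 0.7386, MB21D1 = 0.2266, TMEM173 = 0),
      patient_meanlog = c(TLR3 = 0, TLR7 = log(6), TLR9 = log(6),
                          DDX58 = log(6), MB21D1 = log(6), TMEM173 = log(6)),
      control_meanlog = c(TLR3 = 0, TLR7 = 0, TLR9 = 0, DDX58 = 0,
                          MB21D1 = 0, TMEM173 = 0),
      sdlog = 2.3,
      neutrophil_beta = c(TLR3 = -0.113, TLR9 = 0.161, MB21D1 = 0.151)
    ),
    protein = list(
      meanlog = log(3.178), sdlog = 3.18, score_rank_corr = 0.8307,
      lod = 0.23, blanks_mean = 0.08, blanks_sd = 0.05
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown cohort_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, what) if (!isTRUE(cond)) bad <<- c(bad, what)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed")
  for (f in c("n_patients", "n_controls", "n_nar_patients", "n_nar_controls",
              "n_protein", "n_blanks")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] == round(cfg[[f]]), f)
  }
  chk(cfg$positivity_prevalence >= 0 && cfg$positivity_prevalence <= 1,
      "positivity_prevalence")
  chk(all(vapply(cfg$antibodies, function(p) all(p >= 0 & p <= 1),
                 logical(1))), "antibodies")
  chk(cfg$score_low[2] > 0 && cfg$score_high[2] > 0 && cfg$hc_score[2] > 0,
      "score component sds")
  chk(cfg$gene_noise_sd >= 0, "gene_noise_sd")
  chk(cfg$n_nar_patients <= cfg$n_patients, "n_nar_patients")
  chk(cfg$n_protein <= cfg$n_patients, "n_protein")
  chk(abs(sum(cfg$diagnosis$p_negative) - 1) < 1e-6 &&
        abs(sum(cfg$diagnosis$p_positive) - 1) < 1e-6, "diagnosis")
  chk(abs(cfg$protein$score_rank_corr) < 1, "protein$score_rank_corr")
  chk(all(abs(cfg$nar$score_rank_corr) < 1), "nar$score_rank_corr")
  if (length(bad) > 0) {
    stop("invalid cohort_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic SARD cohort config: ", x$n_patients, " patients + ",
      x$n_controls, " controls, prevalence ", x$positivity_prevalence,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# lognormal parameters from a (median, q1, q3) triple
lnorm_from_quartiles <- function(q) {
  list(meanlog = log(q[1]), sdlog = log(q[3] / q[2]) / (2 * stats::qnorm(0.75)))
}

rlnorm_quartiles <- function(n, q) {
  p <- lnorm_from_quartiles(q)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

# y with target Spearman correlation to an existing x, Gaussian copula on
# the normal scores of x; qmarginal is a quantile function
copula_correlate <- function(x, rho_s, qmarginal) {
  n <- length(x)
  rho_p <- 2 * sin(pi * rho_s / 6)
  zx <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  zy <- rho_p * zx + sqrt(1 - rho_p^2) * stats::rnorm(n)
  qmarginal(stats::pnorm(zy))
}

#' Generate a pair of vectors with a target Spearman correlation
#'
#' Gaussian-copula construction: latent standard normals are correlated at
#' the Pearson parameter `2 sin(pi rho_s / 6)` that maps to the requested
#' Spearman correlation, then pushed through the requested marginal
#' quantile functions.
#'
#' @param n Number of pairs.
#' @param rho_s Target Spearman correlation, in (-1, 1).
#' @param qx,qy Quantile functions for the two marginals (default standard
#'   normal).
#' @param seed Optional integer seed.
#' @return Tibble with columns `x` and `y`.
#' @export
generate_correlated_pair <- function(n, rho_s, qx = stats::qnorm,
                                     qy = stats::qnorm, seed = NULL) {
  if (!is.numeric(rho_s) || abs(rho_s) >= 1) {
    stop("`rho_s` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (!is.function(qx) || !is.function(qy)) {
    stop("`qx` and `qy` must be quantile functions", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rho_p <- 2 * sin(pi * rho_s / 6)
  z1 <- stats::rnorm(n)
  z2 <- rho_p * z1 + sqrt(1 - rho_p^2) * stats::rnorm(n)
  tibble::tibble(x = qx(stats::pnorm(z1)), y = qy(stats::pnorm(z2)))
}

# back-compute a long Ct table from true RQ values:
#   Ct_target = mean(reference Ct) + calibrator delta_ct - log2(rq)
# so that compute_rq() recovers rq exactly; includes reference-gene rows
# and the calibrator sample "CAL" (rq = 1 for every gene).
ct_from_rq <- function(rq_long, cfg) {
  samples <- unique(rq_long$sample_id)
  genes <- unique(rq_long$gene)
  ref_names <- names(cfg$reference_ct)
  all_ids <- c(samples, "CAL")
  ref <- tidyr::expand_grid(sample_id = all_ids, gene = ref_names) |>
    dplyr::mutate(
      ct = unname(cfg$reference_ct[.data$gene]) +
        stats::rnorm(dplyr::n(), 0, cfg$reference_ct_sd)
    )
  ref_agg <- ref |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ref_ct = mean(.data$ct), .groups = "drop")
  targets <- rq_long |>
    dplyr::bind_rows(
      tidyr::expand_grid(sample_id = "CAL", gene = genes, rq = 1)
    ) |>
    dplyr::inner_join(ref_agg, by = "sample_id") |>
    dplyr::mutate(
      ct = .data$ref_ct + cfg$calibrator_delta_ct - log2(.data$rq)
    ) |>
    dplyr::select("sample_id", "gene", "ct")
  dplyr::bind_rows(dplyr::select(ref, "sample_id", "gene", "ct"), targets) |>
    dplyr::arrange(.data$sample_id, .data$gene)
}

#' Generate a synthetic SARD cohort
#'
#' Draws a full synthetic cohort from a [cohort_config()]: latent ISG
#' status, bimodal log10 scores, per-gene fold changes whose median tracks
#' the drawn score, back-computed qPCR Ct tables for the ISG and NAR
#' panels (with reference genes and a calibrator sample `"CAL"`),
#' status-conditional clinical records, copula-linked protein
#' concentrations with blank runs, and a truth record for every emitted
#' sample. Deterministic (bit-identical) given config and seed.
#'
#' @param config A [cohort_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @return Object of class `synthetic_cohort`: list with `patients`,
#'   `ct_qpcr`, `ct_nar`, `protein`, `meta` (sample_id/group for the ISG Ct
#'   table), `nar_meta`, and `truth` (list: `samples`, `gene_truth`,
#'   `hc_median_rq`, `config`, `seed`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(seed)
  n <- cfg$n_patients
  isg_genes <- names(cfg$hc_median_rq)

  pid <- sprintf("P%03d", seq_len(n))
  hid <- sprintf("HC%02d", seq_len(cfg$n_controls))
  ncid <- sprintf("NC%02d", seq_len(cfg$n_nar_controls))

  status <- stats::rbinom(n, 1, cfg$positivity_prevalence) == 1
  log10_score <- ifelse(
    status,
    stats::rnorm(n, cfg$score_high[1], cfg$score_high[2]),
    stats::rnorm(n, cfg$score_low[1], cfg$score_low[2])
  )
  # control scores: drawn at the configured log10 location/spread, then
  # restricted (log-affine adjustment) so that the empirical median is
  # exactly 1 and the natural-scale mean + 2 SD calibration lands exactly
  # on the configured threshold
  hc_log10 <- stats::rnorm(cfg$n_controls, cfg$hc_score[1], cfg$hc_score[2])
  if (cfg$n_controls >= 3 && stats::sd(hc_log10) > 0) {
    centred <- hc_log10 - stats::median(hc_log10)
    cal_at <- function(b) {
      s <- 10^(b * centred)
      mean(s) + 2 * stats::sd(s) - cfg$threshold
    }
    b <- tryCatch(stats::uniroot(cal_at, c(1e-3, 10))$root,
                  error = function(e) 1)
    hc_log10 <- b * centred
  }

  # per-gene fold changes: score times lognormal noise, so the median over
  # the panel tracks the drawn score
  gene_truth <- tidyr::expand_grid(sample_id = c(pid, hid),
                                   gene = isg_genes) |>
    dplyr::mutate(
      true_fold_change = 10^(
        rep(c(log10_score, hc_log10), each = length(isg_genes)) +
          stats::rnorm(dplyr::n(), 0, cfg$gene_noise_sd)
      ),
      true_rq = .data$true_fold_change *
        unname(cfg$hc_median_rq[.data$gene])
    )
  ct_qpcr <- ct_from_rq(
    dplyr::select(gene_truth, "sample_id", "gene", rq = "true_rq"), cfg
  )
  meta <- tibble::tibble(
    sample_id = c(pid, hid, "CAL"),
    group = c(rep("patient", n), rep("control", cfg$n_controls), "calibrator")
  )

  draw_cond <- function(p_neg, p_pos) {
    stats::rbinom(n, 1, ifelse(status, p_pos, p_neg)) == 1
  }
  diagnosis <- character(n)
  diagnosis[!status] <- sample(cfg$diagnosis$levels, sum(!status),
                               replace = TRUE, prob = cfg$diagnosis$p_negative)
  diagnosis[status] <- sample(cfg$diagnosis$levels, sum(status),
                              replace = TRUE, prob = cfg$diagnosis$p_positive)
  ethnicity <- character(n)
  ethnicity[!status] <- sample(cfg$ethnicity$levels, sum(!status),
                               replace = TRUE, prob = cfg$ethnicity$p_negative)
  ethnicity[status] <- sample(cfg$ethnicity$levels, sum(status),
                              replace = TRUE, prob = cfg$ethnicity$p_positive)

  draw_cont <- function(var) {
    q_neg <- cfg$continuous[[var]]$negative
    q_pos <- cfg$continuous[[var]]$positive
    ifelse(status, rlnorm_quartiles(n, q_pos), rlnorm_quartiles(n, q_neg))
  }

  patients <- tibble::tibble(
    sample_id = pid,
    group = "patient",
    age = pmin(pmax(ifelse(
      status,
      stats::rnorm(n, cfg$age$positive["mean"], cfg$age$positive["sd"]),
      stats::rnorm(n, cfg$age$negative["mean"], cfg$age$negative["sd"])
    ), 18), 90),
    gender = ifelse(
      stats::rbinom(n, 1, ifelse(status, cfg$female["positive"],
                                 cfg$female["negative"])) == 1, "F", "M"),
    ethnicity = ethnicity,
    ethnicity_caucasian = ethnicity == "Caucasian",
    diagnosis = factor(diagnosis, levels = cfg$diagnosis$levels),
    disease_duration = draw_cont("disease_duration")
  )
  for (ab in names(cfg$antibodies$negative)) {
    patients[[ab]] <- draw_cond(cfg$antibodies$negative[[ab]],
                                cfg$antibodies$positive[[ab]])
  }
  for (m in names(cfg$medications$negative)) {
    patients[[m]] <- draw_cond(cfg$medications$negative[[m]],
                               cfg$medications$positive[[m]])
  }
  for (f in names(cfg$clinical_features$negative)) {
    patients[[f]] <- draw_cond(cfg$clinical_features$negative[[f]],
                               cfg$clinical_features$positive[[f]])
  }
  for (v in c("haemoglobin", "wcc", "lymphocytes", "platelets", "esr",
              "crp")) {
    patients[[v]] <- draw_cont(v)
  }

  # NAR expression for every patient (emitted for the first n_nar_patients):
  # copula-linked to the score, lognormal marginals
  nar_names <- names(cfg$nar$score_rank_corr)
  nar_rq_pat <- vapply(nar_names, function(g) {
    copula_correlate(
      log10_score, cfg$nar$score_rank_corr[[g]],
      function(p) stats::qlnorm(p, cfg$nar$patient_meanlog[[g]],
                                cfg$nar$sdlog)
    )
  }, numeric(n))

  # neutrophils carry the planted NAR effects on the natural-log scale
  beta <- cfg$nar$neutrophil_beta
  nar_l10 <- log10(nar_rq_pat[, names(beta), drop = FALSE])
  nar_term <- as.numeric(nar_l10 %*% beta) -
    sum(beta * colMeans(nar_l10))
  explained <- sum(beta^2) * (cfg$nar$sdlog / log(10))^2
  resid_sd <- function(q) {
    s <- lnorm_from_quartiles(q)$sdlog
    sqrt(max(s^2 - explained, 0.05^2))
  }
  neut_meanlog <- ifelse(
    status, lnorm_from_quartiles(cfg$continuous$neutrophils$positive)$meanlog,
    lnorm_from_quartiles(cfg$continuous$neutrophils$negative)$meanlog
  )
  neut_sd <- ifelse(
    status, resid_sd(cfg$continuous$neutrophils$positive),
    resid_sd(cfg$continuous$neutrophils$negative)
  )
  patients$neutrophils <- exp(
    neut_meanlog + nar_term + stats::rnorm(n, 0, neut_sd)
  )

  nar_pat_ids <- pid[seq_len(cfg$n_nar_patients)]
  nar_truth <- tibble::tibble(
    sample_id = rep(nar_pat_ids, times = length(nar_names)),
    gene = rep(nar_names, each = length(nar_pat_ids)),
    true_rq = as.numeric(nar_rq_pat[seq_len(cfg$n_nar_patients), ])
  )
  nar_ctrl <- tidyr::expand_grid(sample_id = ncid, gene = nar_names) |>
    dplyr::mutate(
      true_rq = stats::rlnorm(dplyr::n(),
                              unname(cfg$nar$control_meanlog[.data$gene]),
                              cfg$nar$sdlog)
    )
  ct_nar <- ct_from_rq(
    dplyr::bind_rows(nar_truth, nar_ctrl) |>
      dplyr::select("sample_id", "gene", rq = "true_rq"),
    cfg
  )
  nar_meta <- tibble::tibble(
    sample_id = c(nar_pat_ids, ncid, "CAL"),
    group = c(rep("patient", length(nar_pat_ids)),
              rep("control", length(ncid)), "calibrator")
  )

  # plasma protein: copula-linked to the score in the measured subset,
  # below-LOD values emitted at their drawn value (flagged downstream)
  prot_ids <- pid[seq_len(cfg$n_protein)]
  prot_conc <- copula_correlate(
    log10_score[seq_len(cfg$n_protein)], cfg$protein$score_rank_corr,
    function(p) stats::qlnorm(p, cfg$protein$meanlog, cfg$protein$sdlog)
  )
  blanks <- pmax(stats::rnorm(cfg$n_blanks, cfg$protein$blanks_mean,
                              cfg$protein$blanks_sd), 0)
  protein <- dplyr::bind_rows(
    tibble::tibble(sample_id = prot_ids, concentration_fg_ml = prot_conc,
                   is_blank = FALSE),
    tibble::tibble(sample_id = sprintf("BLANK%02d", seq_len(cfg$n_blanks)),
                   concentration_fg_ml = blanks, is_blank = TRUE)
  )

  truth <- list(
    samples = tibble::tibble(
      sample_id = c(pid, hid),
      group = c(rep("patient", n), rep("control", cfg$n_controls)),
      latent_positive = c(status, rep(NA, cfg$n_controls)),
      true_score = 10^c(log10_score, hc_log10)
    ),
    gene_truth = dplyr::bind_rows(gene_truth,
                                  dplyr::mutate(nar_truth,
                                                true_fold_change = NA_real_)),
    hc_median_rq = cfg$hc_median_rq,
    config = cfg,
    seed = seed
  )

  structure(
    list(patients = patients, ct_qpcr = ct_qpcr, ct_nar = ct_nar,
         protein = protein, meta = meta, nar_meta = nar_meta, truth = truth),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic SARD cohort: ", nrow(x$patients), " patients, ",
      sum(x$meta$group == "control"), " ISG controls, seed ",
      x$truth$seed, "\n", sep = "")
  cat("  latent ISG-positive: ",
      sum(x$truth$samples$latent_positive, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `patients.csv`, `ct_qpcr.csv`, `ct_nar.csv`, `protein.csv`,
#' `meta.csv`, `nar_meta.csv` and `truth_samples.csv` into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    patients = cohort$patients, ct_qpcr = cohort$ct_qpcr,
    ct_nar = cohort$ct_nar, protein = cohort$protein, meta = cohort$meta,
    nar_meta = cohort$nar_meta, truth_samples = cohort$truth$samples
  )
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Check pipeline recovery against the generator's truth
#'
#' Confronts pipeline outputs with the latent truth of the cohort they
#' were computed from: the confusion matrix of the ISG classification
#' against latent status, recovered autoantibody odds ratios against the
#' generating ones, and the recovered score-protein rank correlation
#' against its target.
#'
#' @param cohort A `synthetic_cohort`.
#' @param calls Classified score tibble (`sample_id`, `score`, `positive`)
#'   for the cohort's patients; the sample sets must match (a mismatch
#'   usually means outputs from a different seed).
#' @return List with `confusion` (2 x 2 table), `accuracy`, `antibody_or`
#'   (tibble: antibody, generating_or, recovered_or, ci_low, ci_high) and
#'   `protein_corr` (list: target, recovered).
#' @export
truth_check <- function(cohort, calls) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  truth <- cohort$truth$samples |> dplyr::filter(.data$group == "patient")
  if (!setequal(truth$sample_id, calls$sample_id)) {
    stop("sample sets differ between truth and outputs ",
         "(seed or cohort mismatch?)", call. = FALSE)
  }
  dat <- dplyr::inner_join(truth, calls, by = "sample_id")
  confusion <- table(latent = dat$latent_positive, called = dat$positive)
  accuracy <- mean(dat$latent_positive == dat$positive, na.rm = TRUE)

  cfg <- cohort$truth$config
  ab_or <- purrr::map_dfr(names(cfg$antibodies$negative), function(ab) {
    p1 <- cfg$antibodies$positive[[ab]]; p0 <- cfg$antibodies$negative[[ab]]
    gen_or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
    pats <- dplyr::inner_join(cohort$patients,
                              dplyr::select(dat, "sample_id", "positive"),
                              by = "sample_id")
    abv <- as.logical(pats[[ab]])
    posv <- pats$positive
    res <- odds_ratio_2x2(sum(posv & abv), sum(posv & !abv),
                          sum(!posv & abv), sum(!posv & !abv), term = ab)
    tibble::tibble(antibody = ab, generating_or = gen_or,
                   recovered_or = res$estimate,
                   ci_low = res$ci_low, ci_high = res$ci_high)
  })

  prot <- cohort$protein |> dplyr::filter(!.data$is_blank)
  pc <- dplyr::inner_join(prot, dplyr::select(dat, "sample_id", "score"),
                          by = "sample_id")
  prot_r <- if (nrow(pc) >= 3) {
    suppressWarnings(stats::cor(pc$concentration_fg_ml, pc$score,
                                method = "spearman"))
  } else NA_real_

  list(
    confusion = confusion,
    accuracy = accuracy,
    antibody_or = ab_or,
    protein_corr = list(target = cfg$protein$score_rank_corr,
                        recovered = prot_r)
  )
}
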