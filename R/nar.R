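#' Nucleic-acid receptor panel
#'
#' The six innate nucleic-acid sensors profiled alongside the ISG score:
#' TLR3, TLR7, TLR9, DDX58 (RIG-I), MB21D1 (cGAS) and TMEM173 (STING).
#'
#' @return Character vector of the six gene symbols.
#' @export
nar_genes <- function() {
  c("TLR3", "TLR7", "TLR9", "DDX58", "MB21D1", "TMEM173")
}

#' Compare NAR expression between patients and healthy controls
#'
#' Per-gene two-group rank test (Mann-Whitney U via [rank_tests()]) of
#' patient versus control RQ, with the effect direction summarised as the
#' ratio of group medians. Genes absent from either group are reported as
#' untested.
#'
#' @param patient_rq,control_rq RQ tibbles (`sample_id`, `gene`, `rq`).
#' @param genes Genes to test (default [nar_genes()]).
#' @return Tibble with `gene`, `median_patient`, `median_control`,
#'   `direction` (`"increased"` / `"decreased"`), `statistic`, `p_value`,
#'   `tested`.
#' @export
nar_vs_controls <- function(patient_rq, control_rq, genes = nar_genes()) {
  purrr::map_dfr(genes, function(g) {
    x <- patient_rq$rq[patient_rq$gene == g & !is.na(patient_rq$rq)]
    y <- control_rq$rq[control_rq$gene == g & !is.na(control_rq$rq)]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(
        gene = g, median_patient = NA_real_, median_control = NA_real_,
        direction = NA_character_, statistic = NA_real_,
        p_value = NA_real_, tested = FALSE
      ))
    }
    rt <- rank_tests(c(x, y), rep(c("patient", "control"),
                                  c(length(x), length(y))))
    tibble::tibble(
      gene = g,
      median_patient = stats::median(x),
      median_control = stats::median(y),
      direction = ifelse(stats::median(x) >= stats::median(y),
                         "increased", "decreased"),
      statistic = rt$statistic, p_value = rt$p_value, tested = TRUE
    )
  })
}

#' Correlate NAR expression with the ISG score
#'
#' Spearman rank correlation of each gene's RQ against the ISG score over
#' paired samples. Constant genes are reported untested.
#'
#' @param nar_rq RQ tibble (`sample_id`, `gene`, `rq`).
#' @param scores Score tibble (`sample_id`, `score`).
#' @param genes Genes to correlate (default [nar_genes()]).
#' @return Tibble with `gene`, `r`, `p_value`, `n`, `tested`.
#' @export
nar_score_correlation <- function(nar_rq, scores, genes = nar_genes()) {
  purrr::map_dfr(genes, function(g) {
    dat <- nar_rq |>
      dplyr::filter(.data$gene == g) |>
      dplyr::inner_join(dplyr::select(scores, "sample_id", "score"),
                        by = "sample_id") |>
      dplyr::filter(!is.na(.data$rq), !is.na(.data$score))
    if (nrow(dat) < 3 || length(unique(dat$rq)) < 2 ||
        length(unique(dat$score)) < 2) {
      return(tibble::tibble(gene = g, r = NA_real_, p_value = NA_real_,
                            n = nrow(dat), tested = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(dat$rq, dat$score, method = "spearman", exact = FALSE)
    )
    tibble::tibble(gene = g, r = unname(ct$estimate), p_value = ct$p.value,
                   n = nrow(dat), tested = TRUE)
  })
}

#' K-means subgrouping of patients on NAR expression
#'
#' Clusters patients in standardised log10 RQ space: RQ is log10
#' transformed (optionally skipped), each gene is z-scored, and k-means is
#' run with `n_init` random initialisations, keeping the lowest-inertia
#' solution. Deterministic given `seed`.
#'
#' @param nar_rq RQ tibble (`sample_id`, `gene`, `rq`); only samples with a
#'   complete, positive RQ vector over `genes` are clustered.
#' @param k Number of clusters (default 6).
#' @param seed Integer seed.
#' @param n_init Number of random initialisations (default 20).
#' @param genes Genes used (default [nar_genes()]).
#' @param log_transform Log10 transform the RQ before z-scoring
#'   (default TRUE).
#' @return Object of class `nar_clusters`: list with `assignments` (tibble
#'   `sample_id`, `cluster`), `centroids` (k x gene matrix in standardised
#'   space), `inertia`, `k`, `seed`.
#' @export
cluster_patients <- function(nar_rq, k = 6, seed = 1, n_init = 20,
                             genes = nar_genes(), log_transform = TRUE) {
  wide <- nar_rq |>
    dplyr::filter(.data$gene %in% genes) |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "gene",
                       values_from = "rq") |>
    dplyr::filter(dplyr::if_all(dplyr::all_of(genes),
                                ~ !is.na(.x) & .x > 0))
  if (nrow(wide) < k) {
    stop("need at least k = ", k, " samples with complete NAR vectors",
         call. = FALSE)
  }
  m <- as.matrix(wide[genes])
  if (log_transform) m <- log10(m)
  m <- scale(m)
  # a constant gene z-scores to NaN; keep it as zeros (carries no signal)
  m[is.nan(m)] <- 0
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = n_init, iter.max = 100)
  structure(
    list(
      assignments = tibble::tibble(sample_id = wide$sample_id,
                                   cluster = km$cluster),
      centroids = km$centers,
      inertia = km$tot.withinss,
      k = k, seed = seed
    ),
    class = "nar_clusters"
  )
}

#' @export
print.nar_clusters <- function(x, ...) {
  cat("K-means NAR subgrouping: k = ", x$k, ", n = ",
      nrow(x$assignments), ", inertia = ", format(x$inertia), "\n", sep = "")
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' @rdname cluster_patients
#' @param x A `nar_clusters` object.
#' @param ... Unused.
#' @export
tidy.nar_clusters <- function(x, ...) {
  x$assignments
}

#' Neutrophil model ladder over NAR genes
#'
#' Ordinary least squares of log-transformed neutrophil counts on each NAR
#' gene's log10 RQ, across the published ladder: univariate; model 1
#' (+ age, gender, ethnicity, diagnosis); model 2 (+ prednisolone,
#' anti-malarial, immunosuppressant); model 3 (+ ISG score). Complete-case
#' per model.
#'
#' @param patients Patient tibble with `sample_id`, `neutrophils`, `age`,
#'   `gender`, `ethnicity_caucasian`, `diagnosis`, `prednisolone`,
#'   `anti_malarial`, `immunosuppressant`.
#' @param nar_rq RQ tibble for the NAR panel.
#' @param scores Score tibble (`sample_id`, `score`).
#' @param genes Genes to model (default the three with published neutrophil
#'   associations: TLR3, TLR9, MB21D1).
#' @return Tibble of [linear_fit()] rows with `gene` and `ladder_model`.
#' @export
neutrophil_model_ladder <- function(patients, nar_rq, scores,
                                    genes = c("TLR3", "TLR9", "MB21D1")) {
  ladders <- list(
    univariate = character(0),
    model1 = c("age", "gender", "ethnicity_caucasian", "diagnosis"),
    model2 = c("age", "gender", "ethnicity_caucasian", "diagnosis",
               "prednisolone", "anti_malarial", "immunosuppressant"),
    model3 = c("age", "gender", "ethnicity_caucasian", "diagnosis",
               "prednisolone", "anti_malarial", "immunosuppressant",
               "log10_score")
  )
  purrr::map_dfr(genes, function(g) {
    dat <- nar_rq |>
      dplyr::filter(.data$gene == g, !is.na(.data$rq), .data$rq > 0) |>
      dplyr::mutate(log10_rq = log10(.data$rq)) |>
      dplyr::select("sample_id", "log10_rq") |>
      dplyr::inner_join(patients, by = "sample_id") |>
      dplyr::inner_join(dplyr::select(scores, "sample_id", "score"),
                        by = "sample_id") |>
      dplyr::filter(.data$neutrophils > 0, .data$score > 0) |>
      dplyr::mutate(
        log_neutrophils = log(.data$neutrophils),
        log10_score = log10(.data$score)
      )
    linear_ladder(dat, "log_neutrophils", "log10_rq", ladders) |>
      dplyr::mutate(gene = g, .before = 1)
  })
}
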