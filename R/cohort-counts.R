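#' Aggregate autoantibody counts from the motivating SARD cohort
#'
#' Published cross-tabulation of autoantibody status by ISG score group in
#' the motivating mixed-SARD cohort (63 ISG-positive, 101 ISG-negative
#' patients). These aggregate counts are the inputs for reproducing the
#' cohort's univariate odds ratios; `n_positive_with` is the number of
#' ISG-positive patients carrying the antibody, and so on. The rheumatoid
#' factor count follows the consistent 25/63 reading (the published
#' percentage next to it is a typographical error).
#'
#' @return Tibble with `antibody`, `n_positive_with`, `n_positive_without`,
#'   `n_negative_with`, `n_negative_without`.
#' @export
sard_autoantibody_counts <- function() {
  counts <- tibble::tribble(
    ~antibody,           ~n_positive_with, ~n_negative_with,
    "dsDNA",             22L,              24L,
    "Ro",                31L,              18L,
    "La",                14L,               9L,
    "Smith",             18L,               5L,
    "RNP",               26L,              13L,
    "chromatin",         24L,               9L,
    "rheumatoid_factor", 25L,              12L,
    "CCP",                4L,               3L,
    "SSc_specific",       4L,              11L,
    "Jo1",                1L,               3L
  )
  counts |>
    dplyr::mutate(
      n_positive_without = 63L - .data$n_positive_with,
      n_negative_without = 101L - .data$n_negative_with,
      .after = "n_positive_with"
    ) |>
    dplyr::relocate("n_negative_with", .after = "n_positive_without")
}

#' Aggregate diagnosis counts from the motivating SARD cohort
#'
#' Published counts of clinical diagnosis by ISG score group (63
#' ISG-positive, 101 ISG-negative patients); the input for the
#' diagnosis-only logistic model with UCTD as the reference level.
#'
#' @return Tibble with `diagnosis` (factor, UCTD reference),
#'   `n_positive`, `n_negative`.
#' @export
sard_diagnosis_counts <- function() {
  lev <- c("UCTD", "SLE", "MCTD", "SS", "IIM", "SSc")
  tibble::tibble(
    diagnosis = factor(lev, levels = lev),
    n_positive = c(9L, 27L, 9L, 14L, 2L, 2L),
    n_negative = c(34L, 40L, 4L, 6L, 6L, 11L)
  )
}

#' Univariate autoantibody odds ratios from published counts
#'
#' Runs [odds_ratio_2x2()] over every row of [sard_autoantibody_counts()]
#' (or a same-shaped table), reproducing the cohort's univariate
#' association column.
#'
#' @param counts Count table shaped like [sard_autoantibody_counts()].
#' @return Tibble of [odds_ratio_2x2()] rows, one per antibody.
#' @export
autoantibody_odds_ratios <- function(counts = sard_autoantibody_counts()) {
  purrr::pmap_dfr(counts, function(antibody, n_positive_with,
                                   n_positive_without, n_negative_with,
                                   n_negative_without) {
    odds_ratio_2x2(n_positive_with, n_positive_without,
                   n_negative_with, n_negative_without, term = antibody)
  })
}

#' Diagnosis-group logistic model from published counts
#'
#' Fits ISG positivity on clinical diagnosis (UCTD reference) over the
#' grouped counts of [sard_diagnosis_counts()] via a weighted logistic
#' regression, yielding the per-diagnosis odds ratios versus UCTD.
#'
#' @param counts Count table shaped like [sard_diagnosis_counts()].
#' @return Tibble of [logistic_fit()] rows, one per non-reference
#'   diagnosis.
#' @export
diagnosis_odds_ratios <- function(counts = sard_diagnosis_counts()) {
  grouped <- counts |>
    tidyr::pivot_longer(c("n_positive", "n_negative"),
                        names_to = "isg", values_to = "count") |>
    dplyr::mutate(positive = as.integer(.data$isg == "n_positive"))
  logistic_fit(grouped, positive ~ diagnosis, weights = "count") |>
    dplyr::mutate(term = sub("^diagnosis", "", .data$term))
}
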