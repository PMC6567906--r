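#' ISG score panel definition
#'
#' The six-gene RT-qPCR interferon-stimulated-gene (ISG) panel comprises
#' IFI27, IFI44L, IFIT1, ISG15, RSAD2 and SIGLEC1. The 30-gene count-panel
#' score uses the same scoring rule; because its gene list is
#' site-configurable, `"panel30"` ships with a documented placeholder list
#' (`ISG30_01 ... ISG30_30`) that callers are expected to replace via
#' `genes =`.
#'
#' @param panel_id `"qpcr6"`, `"panel30"`, or any label for a custom panel.
#' @param genes Optional character vector overriding the panel gene list
#'   (required for custom panel ids).
#' @param min_genes_required Minimum number of non-missing panel genes a
#'   sample needs to receive a score. Defaults to 4 for `"qpcr6"`, and to
#'   two-thirds of the panel (rounded up) otherwise.
#' @return An object of class `isg_panel`: a list with `panel_id`, `genes`
#'   and `min_genes_required`.
#' @examples
#' isg_panel("qpcr6")
#' @export
isg_panel <- function(panel_id = c("qpcr6", "panel30"), genes = NULL,
                      min_genes_required = NULL) {
  if (is.null(genes)) {
    panel_id <- match.arg(panel_id)
    genes <- switch(panel_id,
      qpcr6  = c("IFI27", "IFI44L", "IFIT1", "ISG15", "RSAD2", "SIGLEC1"),
      panel30 = sprintf("ISG30_%02d", 1:30)
    )
  } else {
    panel_id <- panel_id[1]
  }
  if (anyDuplicated(genes) || length(genes) == 0) {
    stop("panel genes must be non-empty and unique", call. = FALSE)
  }
  if (is.null(min_genes_required)) {
    min_genes_required <-
      if (identical(panel_id, "qpcr6")) 4L else ceiling(2 * length(genes) / 3)
  }
  if (min_genes_required > length(genes) || min_genes_required < 1) {
    stop("`min_genes_required` must be in [1, number of panel genes]",
         call. = FALSE)
  }
  structure(
    list(panel_id = panel_id, genes = genes,
         min_genes_required = as.integer(min_genes_required)),
    class = "isg_panel"
  )
}

#' @export
print.isg_panel <- function(x, ...) {
  cat("ISG panel '", x$panel_id, "': ", length(x$genes), " genes (",
      paste(utils::head(x$genes, 6), collapse = ", "),
      if (length(x$genes) > 6) ", ..." else "",
      "), min ", x$min_genes_required, " required\n", sep = "")
  invisible(x)
}

#' Build the healthy-control reference for ISG scoring
#'
#' Computes, for each panel gene, the median RQ over the supplied healthy
#' controls. Sample fold changes are later expressed against these medians.
#'
#' @param rq_table RQ tibble (as from [compute_rq()]) restricted to healthy
#'   control samples; columns `sample_id`, `gene`, `rq`.
#' @param panel An [isg_panel()].
#' @return Object of class `hc_reference`: list with `panel_id`, `medians`
#'   (tibble `gene`, `median_rq`) and `n_controls`.
#' @export
build_hc_reference <- function(rq_table, panel = isg_panel("qpcr6")) {
  stopifnot(inherits(panel, "isg_panel"))
  rq_table <- rq_table |> dplyr::filter(.data$gene %in% panel$genes)
  n_controls <- dplyr::n_distinct(rq_table$sample_id)
  if (n_controls < 2) {
    stop("need at least 2 control samples to build a reference", call. = FALSE)
  }
  med <- rq_table |>
    dplyr::filter(!is.na(.data$rq)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(median_rq = stats::median(.data$rq), .groups = "drop")
  absent <- setdiff(panel$genes, med$gene)
  if (length(absent) > 0) {
    stop("panel gene(s) absent in all controls: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (any(med$median_rq <= 0)) {
    stop("control median RQ must be positive", call. = FALSE)
  }
  structure(
    list(panel_id = panel$panel_id, medians = med, n_controls = n_controls),
    class = "hc_reference"
  )
}

#' @export
print.hc_reference <- function(x, ...) {
  cat("Healthy-control reference for panel '", x$panel_id, "' (",
      x$n_controls, " controls)\n", sep = "")
  print(x$medians)
  invisible(x)
}

#' Compute ISG scores
#'
#' For every sample in `rq_table`, divides each panel gene's RQ by the
#' healthy-control median RQ of that gene and takes the median of the
#' resulting fold changes (midpoint of the central pair for an even count)
#' as the sample's ISG score. Samples with fewer than
#' `panel$min_genes_required` non-missing panel genes receive a missing
#' score (`NA`) and are flagged.
#'
#' @param rq_table RQ tibble with columns `sample_id`, `gene`, `rq`.
#' @param reference An `hc_reference` from [build_hc_reference()].
#' @param panel The [isg_panel()] used (must match the reference panel id).
#' @return Tibble with `sample_id`, `panel_id`, `score`, `n_genes_used`
#'   and a list-column `fold_changes` (named numeric per gene).
#' @export
compute_isg_score <- function(rq_table, reference,
                              panel = isg_panel("qpcr6")) {
  stopifnot(inherits(panel, "isg_panel"), inherits(reference, "hc_reference"))
  if (!identical(reference$panel_id, panel$panel_id)) {
    stop("reference panel '", reference$panel_id,
         "' does not match scoring panel '", panel$panel_id, "'",
         call. = FALSE)
  }
  fc <- rq_table |>
    dplyr::filter(.data$gene %in% panel$genes) |>
    dplyr::inner_join(reference$medians, by = "gene") |>
    dplyr::mutate(fold_change = .data$rq / .data$median_rq)

  out <- fc |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      fold_changes = list(stats::setNames(
        .data$fold_change[!is.na(.data$fold_change)],
        .data$gene[!is.na(.data$fold_change)]
      )),
      n_genes_used = sum(!is.na(.data$fold_change)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      panel_id = panel$panel_id,
      score = purrr::map2_dbl(
        .data$fold_changes, .data$n_genes_used,
        function(f, n) if (n >= panel$min_genes_required) stats::median(f) else NA_real_
      )
    ) |>
    dplyr::select("sample_id", "panel_id", "score", "n_genes_used",
                  "fold_changes")
  flagged <- out$sample_id[is.na(out$score)]
  if (length(flagged) > 0) {
    warning(length(flagged), " sample(s) below the minimum gene count, ",
            "scored as missing: ", paste(flagged, collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Calibrate the ISG positivity threshold from healthy-control scores
#'
#' The positivity threshold is the mean healthy-control score plus two
#' sample standard deviations (n - 1 denominator). The published defaults
#' are 2.466 for the six-gene qPCR score and 1.642 for the 30-gene count
#' panel; use [fixed_threshold()] to wrap those.
#'
#' @param hc_scores Numeric vector of healthy-control ISG scores (>= 2).
#' @param panel_id Panel label recorded in the calibration.
#' @return Object of class `threshold_calibration`: list with `panel_id`,
#'   `hc_mean`, `hc_sd`, `threshold`, `n_controls`, `source = "calibrated"`.
#' @examples
#' calibrate_threshold(c(1, 2, 3))  # threshold 4
#' @export
calibrate_threshold <- function(hc_scores, panel_id = "qpcr6") {
  hc_scores <- hc_scores[!is.na(hc_scores)]
  if (length(hc_scores) < 2) {
    stop("need at least 2 control scores (SD undefined otherwise)",
         call. = FALSE)
  }
  m <- mean(hc_scores)
  s <- stats::sd(hc_scores)
  structure(
    list(panel_id = panel_id, hc_mean = m, hc_sd = s,
         threshold = m + 2 * s, n_controls = length(hc_scores),
         source = "calibrated"),
    class = "threshold_calibration"
  )
}

#' Fixed published positivity thresholds
#'
#' @param panel_id `"qpcr6"` (threshold 2.466) or `"panel30"` (1.642), or a
#'   custom label with `threshold` supplied.
#' @param threshold Explicit threshold value for custom panels.
#' @return A `threshold_calibration` with `source = "fixed"`.
#' @export
fixed_threshold <- function(panel_id = c("qpcr6", "panel30"),
                            threshold = NULL) {
  if (is.null(threshold)) {
    panel_id <- match.arg(panel_id)
    threshold <- switch(panel_id, qpcr6 = 2.466, panel30 = 1.642)
  } else {
    panel_id <- panel_id[1]
  }
  structure(
    list(panel_id = panel_id, hc_mean = NA_real_, hc_sd = NA_real_,
         threshold = threshold, n_controls = NA_integer_, source = "fixed"),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat("ISG positivity threshold for '", x$panel_id, "': ",
      format(x$threshold), " (", x$source, ")\n", sep = "")
  if (identical(x$source, "calibrated")) {
    cat("  HC mean ", format(x$hc_mean), " + 2 x SD ", format(x$hc_sd),
        " over ", x$n_controls, " controls\n", sep = "")
  }
  invisible(x)
}

#' Classify samples against the positivity threshold
#'
#' A sample is ISG-positive when its score is strictly greater than the
#' threshold; a score exactly equal to the threshold is negative. Missing
#' scores stay missing and are counted separately.
#'
#' @param scores Score tibble from [compute_isg_score()].
#' @param calibration A `threshold_calibration` (from [calibrate_threshold()]
#'   or [fixed_threshold()]), or a bare numeric threshold.
#' @return `scores` with added logical column `positive` and attribute
#'   `"threshold"`.
#' @export
classify_samples <- function(scores, calibration) {
  thr <- if (inherits(calibration, "threshold_calibration")) {
    if ("panel_id" %in% names(scores) &&
        !all(scores$panel_id == calibration$panel_id)) {
      stop("score panel does not match calibration panel", call. = FALSE)
    }
    calibration$threshold
  } else {
    as.numeric(calibration)
  }
  stopifnot(is.finite(thr))
  out <- dplyr::mutate(scores, positive = .data$score > thr)
  attr(out, "threshold") <- thr
  out
}
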