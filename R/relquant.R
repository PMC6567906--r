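#' Aggregate reference-gene Ct values for one sample
#'
#' Collapses the Ct values of the configured reference genes into a single
#' per-sample reference Ct by taking their arithmetic mean on the Ct scale.
#' Because Ct is a log2 quantity, this equals the geometric mean of the
#' reference genes' linear abundances.
#'
#' @param ct_values Named numeric vector of Ct values, names are gene symbols.
#' @param reference_genes Character vector of reference gene symbols; every
#'   one must be present in `ct_values`.
#' @return A single numeric reference Ct (cycles).
#' @examples
#' aggregate_reference(c(HPRT1 = 20, `18S` = 10), c("HPRT1", "18S"))
#' @export
aggregate_reference <- function(ct_values, reference_genes) {
  stopifnot(is.numeric(ct_values), length(reference_genes) >= 1)
  missing_ref <- setdiff(reference_genes, names(ct_values))
  if (length(missing_ref) > 0) {
    stop("missing reference gene(s): ", paste(missing_ref, collapse = ", "),
         call. = FALSE)
  }
  vals <- ct_values[reference_genes]
  if (anyNA(vals)) {
    stop("undetermined Ct for reference gene(s): ",
         paste(reference_genes[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  mean(vals)
}

#' Relative quantification of qPCR Ct tables (delta-delta-Ct)
#'
#' Converts a long-format Ct table into relative quantification (RQ) values.
#' For each sample, replicate Ct values are averaged on the Ct scale, target
#' Ct is normalised against the arithmetic mean Ct of the reference genes
#' (`delta_ct`), expressed relative to a designated calibrator sample
#' (`ddct = delta_ct - delta_ct[calibrator]`), and transformed to a fold
#' change `rq = 2^(-ddct)`. The calibrator's own RQ is exactly 1 for every
#' gene by construction.
#'
#' Samples missing a reference-gene Ct cannot be normalised; they are dropped
#' from the output with a warning, and the excluded sample ids with reasons
#' are attached as the `"excluded"` attribute. An undetermined ("NA") target
#' Ct yields a missing RQ for that (sample, gene) only; it is never imputed.
#'
#' @param ct_table Data frame with columns `sample_id`, `gene`, `ct` and
#'   optionally `replicate`. `ct` is the threshold cycle; `NA` encodes an
#'   undetermined reaction.
#' @param reference_genes Character vector of reference gene symbols
#'   (default `c("HPRT1", "18S")`).
#' @param calibrator Sample id of the calibrator; must have a determined Ct
#'   for all reference genes and every target gene.
#' @return A tibble with columns `sample_id`, `gene`, `delta_ct`, `ddct`,
#'   `rq` (one row per sample and target gene), with an `"excluded"`
#'   attribute listing dropped samples.
#' @export
compute_rq <- function(ct_table, reference_genes = c("HPRT1", "18S"),
                       calibrator) {
  ct_table <- validate_ct_table(ct_table)
  if (missing(calibrator) || length(calibrator) != 1) {
    stop("`calibrator` must be a single sample id", call. = FALSE)
  }
  if (!calibrator %in% ct_table$sample_id) {
    stop("calibrator sample '", calibrator, "' not present in the Ct table",
         call. = FALSE)
  }

  # replicate average on the Ct scale; an undetermined replicate poisons the
  # mean so partially-determined replicate sets stay conservative
  ct_mean <- ct_table |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  ref <- ct_mean |>
    dplyr::filter(.data$gene %in% reference_genes) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      ref_ct = mean(.data$ct),
      n_ref  = dplyr::n(),
      .groups = "drop"
    )

  all_samples <- unique(ct_mean$sample_id)
  bad <- ref |>
    dplyr::filter(is.na(.data$ref_ct) | .data$n_ref < length(reference_genes))
  absent <- setdiff(all_samples, ref$sample_id)
  excluded <- tibble::tibble(
    sample_id = c(bad$sample_id, absent),
    reason    = c(
      rep("undetermined or incomplete reference-gene Ct", nrow(bad)),
      rep("no reference-gene measurements", length(absent))
    )
  )
  if (calibrator %in% excluded$sample_id) {
    stop("calibrator sample '", calibrator,
         "' lacks complete reference-gene Ct values", call. = FALSE)
  }
  if (nrow(excluded) > 0) {
    warning(nrow(excluded), " sample(s) excluded from RQ: ",
            paste(excluded$sample_id, collapse = ", "), call. = FALSE)
  }

  ok_ref <- ref |>
    dplyr::filter(!.data$sample_id %in% excluded$sample_id) |>
    dplyr::select("sample_id", "ref_ct")

  targets <- ct_mean |>
    dplyr::filter(!.data$gene %in% reference_genes) |>
    dplyr::inner_join(ok_ref, by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct)

  cal <- targets |>
    dplyr::filter(.data$sample_id == calibrator) |>
    dplyr::select("gene", cal_delta_ct = "delta_ct")
  if (anyNA(cal$cal_delta_ct)) {
    stop("calibrator sample '", calibrator,
         "' has undetermined Ct for gene(s): ",
         paste(cal$gene[is.na(cal$cal_delta_ct)], collapse = ", "),
         call. = FALSE)
  }

  out <- targets |>
    dplyr::inner_join(cal, by = "gene") |>
    dplyr::mutate(
      ddct = .data$delta_ct - .data$cal_delta_ct,
      rq   = 2^(-.data$ddct)
    ) |>
    dplyr::arrange(.data$sample_id, .data$gene) |>
    dplyr::select("sample_id", "gene", "delta_ct", "ddct", "rq")

  attr(out, "excluded") <- excluded
  out
}

#' Normalise count-panel expression to housekeeping genes
#'
#' Divides each target gene's count by the geometric mean of the sample's
#' housekeeping-gene counts, the standard normalisation for hybridisation
#' count panels. Samples with any zero or missing housekeeping count cannot
#' be normalised and are excluded with a warning (ids in the `"excluded"`
#' attribute).
#'
#' @param count_table Data frame with columns `sample_id`, `gene`, `count`
#'   (non-negative).
#' @param housekeeping_genes Character vector of housekeeping gene symbols
#'   (default `c("HPRT1", "NRDC", "OTUD5")`).
#' @return Tibble with `sample_id`, `gene`, `norm_count` for target genes.
#' @export
panel_normalize <- function(count_table,
                            housekeeping_genes = c("HPRT1", "NRDC", "OTUD5")) {
  req <- c("sample_id", "gene", "count")
  if (!all(req %in% names(count_table))) {
    stop("`count_table` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(count_table$count < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }

  hk <- count_table |>
    dplyr::filter(.data$gene %in% housekeeping_genes) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      hk_geomean = exp(mean(log(.data$count))),
      n_hk = dplyr::n(),
      any_zero = any(.data$count <= 0 | is.na(.data$count)),
      .groups = "drop"
    )

  bad <- hk |>
    dplyr::filter(.data$any_zero | .data$n_hk < length(housekeeping_genes))
  absent <- setdiff(unique(count_table$sample_id), hk$sample_id)
  excluded <- tibble::tibble(
    sample_id = c(bad$sample_id, absent),
    reason = c(rep("zero or missing housekeeping count", nrow(bad)),
               rep("no housekeeping measurements", length(absent)))
  )
  if (nrow(excluded) > 0) {
    warning(nrow(excluded), " sample(s) excluded from panel normalisation: ",
            paste(excluded$sample_id, collapse = ", "), call. = FALSE)
  }

  out <- count_table |>
    dplyr::filter(!.data$gene %in% housekeeping_genes) |>
    dplyr::inner_join(
      dplyr::filter(hk, !.data$sample_id %in% excluded$sample_id) |>
        dplyr::select("sample_id", "hk_geomean"),
      by = "sample_id"
    ) |>
    dplyr::mutate(norm_count = .data$count / .data$hk_geomean) |>
    dplyr::arrange(.data$sample_id, .data$gene) |>
    dplyr::select("sample_id", "gene", "norm_count")

  attr(out, "excluded") <- excluded
  out
}

validate_ct_table <- function(ct_table) {
  req <- c("sample_id", "gene", "ct")
  if (!all(req %in% names(ct_table))) {
    stop("`ct_table` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(ct_table)) {
    ct_table$replicate <- 1L
  }
  if (any(!is.na(ct_table$ct) &
            (ct_table$ct < 0 | !is.finite(ct_table$ct)))) {
    stop("Ct values must be finite and non-negative (use NA for undetermined)",
         call. = FALSE)
  }
  dup <- ct_table |>
    dplyr::count(.data$sample_id, .data$gene, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (sample_id, gene, replicate) rows, e.g. ",
         dup$sample_id[1], "/", dup$gene[1], call. = FALSE)
  }
  tibble::as_tibble(ct_table)
}
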