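# small deterministic fixtures used across test files

# long Ct table for one calibrator + arbitrary samples; targets specified as
# a named list sample -> named vector gene -> ct
make_ct_table <- function(targets, ref = list(HPRT1 = 20, `18S` = 10),
                          calibrator_delta = 3) {
  rows <- list()
  ref_genes <- names(ref)
  for (s in names(targets)) {
    for (g in ref_genes) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = s, gene = g, ct = ref[[g]]
      )
    }
    for (g in names(targets[[s]])) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = s, gene = g, ct = targets[[s]][[g]]
      )
    }
  }
  ref_ct <- mean(unlist(ref))
  genes <- unique(unlist(lapply(targets, names)))
  cal <- tibble::tibble(
    sample_id = "CAL",
    gene = c(ref_genes, genes),
    ct = c(unlist(ref), rep(ref_ct + calibrator_delta, length(genes)))
  )
  dplyr::bind_rows(dplyr::bind_rows(rows), cal)
}

# RQ table straight from per-sample fold-change vectors and unit HC medians
make_rq_table <- function(fold_changes) {
  purrr::imap_dfr(fold_changes, function(fc, s) {
    tibble::tibble(sample_id = s, gene = names(fc), rq = unname(fc))
  })
}

unit_reference <- function(genes, n_controls = 10, panel_id = "qpcr6") {
  structure(
    list(
      panel_id = panel_id,
      medians = tibble::tibble(gene = genes, median_rq = 1),
      n_controls = n_controls
    ),
    class = "hc_reference"
  )
}

qpcr6_genes <- function() isg_panel("qpcr6")$genes
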