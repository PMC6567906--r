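#' Odds ratio for a 2x2 table with Woolf confidence interval
#'
#' Computes `OR = (a d) / (b c)` with the Woolf (log-scale normal
#' approximation) 95% confidence interval
#' `exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))` and a two-sided Wald p
#' value. If any cell is zero the Haldane-Anscombe correction (0.5 added to
#' every cell) is applied and flagged in the `corrected` column.
#'
#' @param a,b,c,d Non-negative integer counts: exposed/outcome-positive,
#'   exposed/outcome-negative, unexposed/outcome-positive,
#'   unexposed/outcome-negative.
#' @param conf_level Confidence level (default 0.95).
#' @param term Optional label for the output row.
#' @return One-row tibble: `term`, `estimate` (OR), `ci_low`, `ci_high`,
#'   `p_value`, `corrected`, `n`.
#' @examples
#' odds_ratio_2x2(31, 32, 18, 83)  # OR 4.47 (2.20, 9.08)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95, term = "exposure") {
  cells <- unname(c(a, b, c, d))
  if (any(cells < 0) || any(!is.finite(cells))) {
    stop("cell counts must be finite and non-negative", call. = FALSE)
  }
  if ((a + b == 0 && c + d == 0) || (a + c == 0 && b + d == 0)) {
    stop("odds ratio undefined: an entire margin is zero", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  lor <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = term,
    estimate = exp(lor),
    ci_low = exp(lor - z * se),
    ci_high = exp(lor + z * se),
    p_value = 2 * stats::pnorm(-abs(lor / se)),
    corrected = corrected,
    n = sum(a, b, c, d)
  )
}

#' Logistic regression returning a tidy odds-ratio table
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) with
#' exponentiated coefficients and Wald confidence intervals. Categorical
#' predictors are expanded against their declared reference level (set the
#' factor levels, or pass `reference` for a single-predictor model).
#' Aggregated (grouped) data are supported through `weights`.
#'
#' Perfect or quasi-perfect separation (a diverging coefficient) is
#' detected from the glm convergence warning and absurd standard errors;
#' affected terms are flagged in the `flagged` column and a warning is
#' raised — never silent output.
#'
#' @param data Data frame of outcome and covariates.
#' @param formula Model formula; left side must be a binary outcome (0/1 or
#'   logical).
#' @param weights Optional column name (string) holding case counts for
#'   grouped data.
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @return Tibble with `term`, `estimate` (odds ratio), `ci_low`,
#'   `ci_high`, `p_value`, `flagged`, `model`, `n` (non-intercept terms).
#' @export
logistic_fit <- function(data, formula, weights = NULL, conf_level = 0.95) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; logistic model undefined",
         call. = FALSE)
  }
  w <- if (!is.null(weights)) data[[weights]] else NULL
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    if (is.null(w)) {
      stats::glm(formula, data = data, family = stats::binomial())
    } else {
      dat <- data
      dat$.w <- w
      stats::glm(formula, data = dat, family = stats::binomial(),
                 weights = .w)
    },
    warning = function(wrn) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(wrn))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- rownames(sm) != "(Intercept)"
  est <- unname(sm[keep, 1]); se <- unname(sm[keep, 2])
  p <- unname(sm[keep, 4])
  flagged <- sep_warned | abs(est) > 15 | se > 15
  if (any(flagged)) {
    warning("possible separation: unstable coefficient(s) for ",
            paste(rownames(sm)[keep][flagged], collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(
    term = rownames(sm)[keep],
    estimate = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se),
    p_value = p,
    flagged = flagged,
    model = deparse1(formula),
    n = if (is.null(w)) stats::nobs(fit) else sum(w)
  )
}

#' Ordinary least squares returning a tidy coefficient table
#'
#' Linear regression via [stats::lm()] with 95% confidence intervals and
#' p values per term; the workhorse behind the log-neutrophil model
#' ladders. A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @inheritParams logistic_fit
#' @return Tibble with `term`, `estimate` (beta), `ci_low`, `ci_high`,
#'   `p_value`, `model`, `n` (non-intercept terms).
#' @export
linear_fit <- function(data, formula, conf_level = 0.95) {
  fit <- stats::lm(formula, data = data, na.action = stats::na.omit)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  if (stats::nobs(fit) <= length(co)) {
    stop("not enough observations for the number of parameters",
         call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit))$coefficients
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  keep <- rownames(sm) != "(Intercept)"
  tibble::tibble(
    term = rownames(sm)[keep],
    estimate = unname(sm[keep, 1]),
    ci_low = unname(ci[keep, 1]),
    ci_high = unname(ci[keep, 2]),
    p_value = unname(sm[keep, 4]),
    model = deparse1(formula),
    n = stats::nobs(fit)
  )
}

#' Nonparametric group comparison
#'
#' Two groups are compared with the Mann-Whitney U test (two-sided, normal
#' approximation with tie correction); more than two with the
#' Kruskal-Wallis test. Use [dunn_test()] for pairwise follow-up.
#'
#' @param values Numeric vector.
#' @param group Grouping vector of the same length (>= 2 non-empty groups).
#' @return One-row tibble: `method`, `statistic`, `p_value`, `n_groups`, `n`.
#' @export
rank_tests <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- factor(group[keep])
  group <- droplevels(group)
  if (nlevels(group) < 2) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (any(table(group) == 0)) stop("empty group", call. = FALSE)
  if (nlevels(group) == 2) {
    if (length(unique(values)) == 1) {
      # all observations tied across both groups: no evidence either way
      return(tibble::tibble(method = "Mann-Whitney U",
                            statistic = NA_real_, p_value = 1,
                            n_groups = 2L, n = length(values)))
    }
    ht <- stats::wilcox.test(values ~ group, exact = FALSE, correct = FALSE)
    tibble::tibble(method = "Mann-Whitney U",
                   statistic = unname(ht$statistic), p_value = ht$p.value,
                   n_groups = 2L, n = length(values))
  } else {
    ht <- stats::kruskal.test(values, group)
    tibble::tibble(method = "Kruskal-Wallis",
                   statistic = unname(ht$statistic), p_value = ht$p.value,
                   n_groups = nlevels(group), n = length(values))
  }
}

#' Dunn pairwise rank z-tests
#'
#' Post-hoc pairwise comparisons after Kruskal-Wallis: z statistics on mean
#' ranks with the usual tie correction, two-sided p values, Bonferroni
#' adjusted by default.
#'
#' @inheritParams rank_tests
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return Tibble with `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, group, p_adjust = "bonferroni") {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, group, mean)
  n_g <- tapply(r, group, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(group), 2)
  res <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = res["z", ], p_value = res["p", ],
    p_adjusted = stats::p.adjust(res["p", ], method = p_adjust)
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' @inheritParams odds_ratio_2x2
#' @return Two-sided exact p value (hypergeometric).
#' @export
fisher_exact <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative", call. = FALSE)
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Spearman correlation matrix with significance mask
#'
#' Pairwise-complete Spearman rank correlations (average ranks for ties)
#' over the numeric columns of `data`, with a p value per pair and a mask
#' of entries significant at `alpha`. Constant vectors have undefined
#' correlations; their pairs are `NA` and masked.
#'
#' @param data Data frame whose numeric columns are correlated.
#' @param alpha Significance level for the mask (default 0.05).
#' @return Object of class `spearman_matrix`: list with matrices `r`, `p`,
#'   logical `significant`, and `n` (pairwise counts).
#' @export
spearman_matrix <- function(data, alpha = 0.05) {
  data <- as.data.frame(data)[vapply(data, is.numeric, logical(1))]
  vars <- names(data)
  k <- length(vars)
  if (k < 2) stop("need at least 2 numeric variables", call. = FALSE)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- data[[i]]; y <- data[[j]]
      ok <- stats::complete.cases(x, y)
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3 || length(unique(x[ok])) < 2 ||
          length(unique(y[ok])) < 2) next
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
      )
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(nmat) <- vapply(data, function(v) sum(!is.na(v)), numeric(1))
  structure(
    list(r = r, p = p, significant = !is.na(p) & p < alpha, n = nmat,
         alpha = alpha),
    class = "spearman_matrix"
  )
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("Spearman correlation matrix (", ncol(x$r), " variables, mask at p < ",
      x$alpha, ")\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' @rdname spearman_matrix
#' @param x A `spearman_matrix`.
#' @param ... Unused.
#' @export
tidy.spearman_matrix <- function(x, ...) {
  vars <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
    r = x$r[idx], p_value = x$p[idx],
    significant = x$significant[idx], n = x$n[idx]
  )
}

#' Autoantibody-count trend in the ISG score
#'
#' Counts each patient's autoantibodies over the declared set, summarises
#' the ISG score per count stratum (median, IQR), tests for a shift across
#' strata (Kruskal-Wallis), and fits the trend of ISG positivity on the
#' count as a linear logistic term.
#'
#' @param patients Patient tibble with logical/0-1 autoantibody columns.
#' @param scores Classified score tibble (`sample_id`, `score`, `positive`).
#' @param antibodies Character vector of autoantibody column names; the
#'   default is the published counting set (dsDNA, Smith, RNP, Ro, La, CCP,
#'   chromatin, SSc-specific).
#' @return List with `strata` (per-count tibble `n_antibodies`, `n`,
#'   `median`, `q1`, `q3`), `kruskal` (tibble from [rank_tests()]) and
#'   `trend` (tibble from [logistic_fit()] for the count term).
#' @export
antibody_count_trend <- function(patients, scores,
                                 antibodies = c("dsDNA", "Smith", "RNP",
                                                "Ro", "La", "CCP",
                                                "chromatin", "SSc_specific")) {
  missing_ab <- setdiff(antibodies, names(patients))
  if (length(missing_ab) > 0) {
    stop("missing autoantibody column(s): ",
         paste(missing_ab, collapse = ", "), call. = FALSE)
  }
  dat <- patients |>
    dplyr::mutate(
      n_antibodies = rowSums(dplyr::across(dplyr::all_of(antibodies)))
    ) |>
    dplyr::inner_join(
      dplyr::select(scores, "sample_id", "score", "positive"),
      by = "sample_id"
    )
  if (length(unique(dat$n_antibodies)) < 2) {
    stop("autoantibody count is constant; trend undefined", call. = FALSE)
  }
  strata <- dat |>
    dplyr::group_by(n_antibodies = .data$n_antibodies) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$score, na.rm = TRUE),
      q1 = stats::quantile(.data$score, 0.25, na.rm = TRUE, names = FALSE),
      q3 = stats::quantile(.data$score, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
  list(
    strata = strata,
    kruskal = rank_tests(dat$score, dat$n_antibodies),
    trend = logistic_fit(dat, positive ~ n_antibodies)
  )
}

#' Logistic model ladder for one exposure
#'
#' Fits the same exposure against ISG positivity across a ladder of
#' adjustment sets (e.g. univariate; age + gender; plus ethnicity and
#' diagnosis; plus medications) and stacks the exposure rows.
#'
#' @param data Modelling data frame.
#' @param outcome Name of the binary outcome column (string).
#' @param exposure Name of the exposure column (string).
#' @param adjustments Named list of character vectors of adjustment
#'   covariates; `character(0)` is the univariate model.
#' @return Tibble of exposure terms, one row per ladder model, with a
#'   `ladder_model` column.
#' @export
logistic_ladder <- function(data, outcome, exposure,
                            adjustments = list(univariate = character(0))) {
  purrr::imap_dfr(adjustments, function(adj, label) {
    rhs <- paste(c(exposure, adj), collapse = " + ")
    f <- stats::as.formula(paste(outcome, "~", rhs))
    logistic_fit(data, f) |>
      dplyr::filter(startsWith(.data$term, exposure)) |>
      dplyr::mutate(ladder_model = label, .before = 1)
  })
}

#' Linear model ladder for one exposure
#'
#' @inheritParams logistic_ladder
#' @return Tibble of exposure terms per ladder model ([linear_fit()] rows).
#' @export
linear_ladder <- function(data, outcome, exposure,
                          adjustments = list(univariate = character(0))) {
  purrr::imap_dfr(adjustments, function(adj, label) {
    rhs <- paste(c(exposure, adj), collapse = " + ")
    f <- stats::as.formula(paste(outcome, "~", rhs))
    linear_fit(data, f) |>
      dplyr::filter(startsWith(.data$term, exposure)) |>
      dplyr::mutate(ladder_model = label, .before = 1)
  })
}
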