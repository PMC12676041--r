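#' Configuration for the differential-expression stage
#'
#' Holds the fold-change dead zone, the significance level, which corrected
#' or raw significance value the classifier uses, the t-test variant, and
#' the minimum number of observed intensities a protein needs in each group
#' to be testable. Defaults are the thresholds of the study design this
#' pipeline reproduces: fold change > 1.20 or < 0.83 and a
#' Benjamini-Hochberg q below 0.05.
#'
#' @param fc_up Up-regulation ratio threshold (default 1.20).
#' @param fc_down Down-regulation ratio threshold (default 0.83).
#' @param alpha Significance level (default 0.05).
#' @param significance_on `"q_value"` (FDR, default) or `"p_value"`.
#' @param t_variant `"student"` (pooled variance, default) or `"welch"`.
#' @param min_valid_per_group Minimum observed intensities per group
#'   (default 2).
#' @return A list of class `dep_config`.
#' @export
dep_config <- function(fc_up = 1.20, fc_down = 0.83, alpha = 0.05,
                       significance_on = c("q_value", "p_value"),
                       t_variant = c("student", "welch"),
                       min_valid_per_group = 2) {
  significance_on <- match.arg(significance_on)
  t_variant <- match.arg(t_variant)
  if (!(is.numeric(fc_up) && is.numeric(fc_down) &&
        fc_down > 0 && fc_down < 1 && fc_up > 1)) {
    abort_validation("Need 0 < fc_down < 1 < fc_up.")
  }
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1)) {
    abort_validation("`alpha` must lie in (0, 1).")
  }
  if (!(is.numeric(min_valid_per_group) && min_valid_per_group >= 2)) {
    abort_validation("`min_valid_per_group` must be at least 2.")
  }
  structure(
    list(fc_up = fc_up, fc_down = fc_down, alpha = alpha,
         significance_on = significance_on, t_variant = t_variant,
         min_valid_per_group = as.integer(min_valid_per_group)),
    class = "dep_config"
  )
}

#' Two-sample t-test with degenerate-input handling
#'
#' Two-sided two-sample t-test (pooled-variance Student or Welch) with the
#' sign convention that `t > 0` when `mean(b) > mean(a)`. The regular case
#' is delegated to [stats::t.test()]; zero-variance inputs, which `t.test`
#' refuses, are resolved by the limit of the statistic: equal means give
#' `t = 0, p = 1`, unequal means with zero variance give `p` equal to the
#' smallest representable positive double.
#'
#' @param a,b Numeric vectors (missing values removed; each needs >= 2
#'   remaining finite values).
#' @param variant `"student"` or `"welch"`.
#' @return A list with elements `t_stat` and `p_value`, or `NULL` when
#'   either group has fewer than 2 finite values (the caller records status
#'   `not_tested`).
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    return(NULL)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t_stat = 0, p_value = 1))
    }
    return(list(
      t_stat = sign(mean(b) - mean(a)) * Inf,
      p_value = .Machine$double.xmin
    ))
  }
  fit <- stats::t.test(b, a, var.equal = (variant == "student"))
  p <- max(unname(fit$p.value), .Machine$double.xmin)
  list(t_stat = unname(fit$statistic), p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1,
#' returned in the input order. Implemented via [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, aligned with `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort_validation("All p-values must lie in (0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify a protein as up, down, or not significant
#'
#' A protein is `up` when its fold change exceeds `fc_up` and the chosen
#' significance value (q by default) is below `alpha`; `down` when the fold
#' change is below `fc_down` under the same significance condition; `ns`
#' otherwise.
#'
#' @param fold_change Raw-scale fold change (treatment over reference), > 0.
#' @param p_value,q_value Raw and BH-adjusted p-values in (0, 1].
#' @param config A [dep_config()].
#' @return Character vector over `{"up", "down", "ns"}` (vectorized).
#' @export
classify_dep <- function(fold_change, p_value, q_value, config = dep_config()) {
  stopifnot(inherits(config, "dep_config"))
  sig <- if (config$significance_on == "q_value") q_value else p_value
  dplyr::case_when(
    fold_change > config$fc_up & sig < config$alpha ~ "up",
    fold_change < config$fc_down & sig < config$alpha ~ "down",
    .default = "ns"
  )
}

#' Run the differential-expression pipeline on an abundance table
#'
#' Per protein: intensities are split by group; non-positive values count as
#' missing; proteins with fewer than `min_valid_per_group` observed values
#' in either group are recorded as `not_tested`. Tested proteins get a
#' two-sample t-test on log2 intensities, a raw-scale fold change
#' (treatment mean over reference mean), BH adjustment across exactly the
#' tested proteins, and an up/down/ns call under the configured thresholds.
#'
#' @param table Abundance tibble: `protein_id` plus one numeric column per
#'   sample (`NA` = missing), as returned by [read_abundance_table()] or
#'   [generate_abundance()].
#' @param groups Tibble with columns `sample_id`, `group` covering every
#'   sample column; exactly two groups.
#' @param config A [dep_config()].
#' @param treatment Which group label is the treatment (numerator of the
#'   fold change). Default: the second group in `groups` file order.
#' @return An object of class `dep_result`: list with `records` (tibble, one
#'   row per protein: `protein_id`, `mean_A`, `mean_B`, `fold_change`,
#'   `log2_fc`, `t_stat`, `p_value`, `q_value`, `status`), counts
#'   `n_up`/`n_down`/`n_ns`/`n_not_tested`, the `config`, and the group
#'   labels. Use [generics::tidy()] / [generics::glance()] /
#'   [ggplot2::autoplot()] on it.
#' @examples
#' sim <- generate_abundance(n_proteins = 50, n_up = 5, n_down = 5, seed = 1)
#' fit <- run_dep(sim$table, sim$groups)
#' glance(fit)
#' @export
run_dep <- function(table, groups, config = dep_config(), treatment = NULL) {
  stopifnot(inherits(config, "dep_config"))
  groups <- check_abundance(table, groups)
  lv <- unique(groups$group)
  if (is.null(treatment)) treatment <- lv[2]
  if (!treatment %in% lv) {
    abort_validation(sprintf("Treatment group '%s' not among groups (%s).",
                             treatment, paste(lv, collapse = ", ")))
  }
  reference <- setdiff(lv, treatment)

  samp_a <- groups$sample_id[groups$group == reference]
  samp_b <- groups$sample_id[groups$group == treatment]
  mat_a <- as.matrix(table[, samp_a, drop = FALSE])
  mat_b <- as.matrix(table[, samp_b, drop = FALSE])
  # label-free convention: a zero intensity means not-quantified
  mat_a[mat_a <= 0] <- NA_real_
  mat_b[mat_b <= 0] <- NA_real_

  n_a <- rowSums(!is.na(mat_a))
  n_b <- rowSums(!is.na(mat_b))
  testable <- n_a >= config$min_valid_per_group & n_b >= config$min_valid_per_group
  if (!any(testable)) {
    abort_validation(paste(
      "No testable protein: every row fails the min-valid-per-group filter.",
      "Lower `min_valid_per_group` or check the missing-value encoding."
    ))
  }

  mean_a <- rowMeans(mat_a, na.rm = TRUE)
  mean_b <- rowMeans(mat_b, na.rm = TRUE)
  fc <- mean_b / mean_a

  tests <- purrr::map(which(testable), function(i) {
    two_sample_t(log2(mat_a[i, ]), log2(mat_b[i, ]), variant = config$t_variant)
  })
  t_stat <- p_value <- q_value <- rep(NA_real_, nrow(table))
  t_stat[testable] <- purrr::map_dbl(tests, "t_stat")
  p_value[testable] <- purrr::map_dbl(tests, "p_value")
  q_value[testable] <- bh_adjust(p_value[testable])

  status <- rep("not_tested", nrow(table))
  status[testable] <- classify_dep(fc[testable], p_value[testable],
                                   q_value[testable], config)

  records <- tibble::tibble(
    protein_id = table$protein_id,
    mean_A = ifelse(is.nan(mean_a), NA_real_, mean_a),
    mean_B = ifelse(is.nan(mean_b), NA_real_, mean_b),
    fold_change = ifelse(is.nan(fc), NA_real_, fc),
    log2_fc = log2(ifelse(is.nan(fc), NA_real_, fc)),
    t_stat = t_stat,
    p_value = p_value,
    q_value = q_value,
    status = status
  )
  structure(
    list(
      records = records,
      n_up = sum(status == "up"),
      n_down = sum(status == "down"),
      n_ns = sum(status == "ns"),
      n_not_tested = sum(status == "not_tested"),
      reference = reference,
      treatment = treatment,
      config = config
    ),
    class = "dep_result"
  )
}

#' @export
print.dep_result <- function(x, ...) {
  cat(sprintf(
    "Differential expression: %s vs %s (reference)\n", x$treatment, x$reference
  ))
  cat(sprintf(
    "  %d proteins: %d up, %d down, %d ns, %d not tested\n",
    nrow(x$records), x$n_up, x$n_down, x$n_ns, x$n_not_tested
  ))
  cat(sprintf(
    "  thresholds: fc > %.2f or < %.2f, %s < %.3g (%s t-test on log2 intensities)\n",
    x$config$fc_up, x$config$fc_down, x$config$significance_on,
    x$config$alpha, x$config$t_variant
  ))
  invisible(x)
}

#' Per-protein records of a differential-expression fit
#'
#' @param x A `dep_result`.
#' @param ... Unused.
#' @return The per-protein tibble (one row per input protein).
#' @exportS3Method generics::tidy
tidy.dep_result <- function(x, ...) {
  x$records
}

#' One-row summary of a differential-expression fit
#'
#' @param x A `dep_result`.
#' @param ... Unused.
#' @return A one-row tibble with the status counts and the configuration.
#' @exportS3Method generics::glance
glance.dep_result <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$records),
    n_up = x$n_up, n_down = x$n_down, n_ns = x$n_ns,
    n_not_tested = x$n_not_tested,
    reference = x$reference, treatment = x$treatment,
    fc_up = x$config$fc_up, fc_down = x$config$fc_down,
    alpha = x$config$alpha, significance_on = x$config$significance_on,
    t_variant = x$config$t_variant
  )
}

#' Volcano plot of a differential-expression fit
#'
#' log2 fold change against -log10 of the configured significance value,
#' colored by up/down/ns status; dashed guides mark the thresholds.
#'
#' @param object A `dep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dep_result <- function(object, ...) {
  sig_col <- object$config$significance_on
  df <- dplyr::filter(object$records, .data$status != "not_tested")
  df$neglog10_sig <- -log10(df[[sig_col]])
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, .data$neglog10_sig,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log2(c(object$config$fc_down,
                                            object$config$fc_up)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#e7548c", down = "#3fa66a",
                                            ns = "grey70")) +
    ggplot2::labs(
      x = sprintf("log2 fold change (%s / %s)", object$treatment, object$reference),
      y = sprintf("-log10 %s", sig_col),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
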