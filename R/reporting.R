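#' Write the volcano-plot substrate table
#'
#' One row per tested protein: `protein_id`, `log2_fc`, `neglog10_sig`
#' (-log10 of the configured significance value), and `status`. Output is
#' byte-stable for identical inputs.
#'
#' @param fit A `dep_result` from [run_dep()].
#' @param path Output TSV path.
#' @return Invisibly, the written tibble.
#' @export
write_volcano_table <- function(fit, path) {
  stopifnot(inherits(fit, "dep_result"))
  sig_col <- fit$config$significance_on
  df <- dplyr::filter(fit$records, .data$status != "not_tested")
  out <- tibble::tibble(
    protein_id = df$protein_id,
    log2_fc = df$log2_fc,
    neglog10_sig = -log10(df[[sig_col]]),
    status = df$status
  )
  write_tsv_stable(out, path)
  invisible(out)
}

#' Write the full per-protein differential-expression table
#'
#' @param fit A `dep_result` from [run_dep()].
#' @param path Output TSV path.
#' @return Invisibly, the records tibble.
#' @export
write_dep_table <- function(fit, path) {
  stopifnot(inherits(fit, "dep_result"))
  write_tsv_stable(fit$records, path)
  invisible(fit$records)
}

#' Write collapsed comparisons as a flat TSV
#'
#' `parts_union` is serialized as semicolon-joined dataset ids; the Simpson
#' column is included when present (see [add_simpson()]).
#'
#' @param collapsed Tibble from [collapse_redundant()] (optionally ranked
#'   and Simpson-scored).
#' @param path Output TSV path.
#' @return Invisibly, the written tibble.
#' @export
write_collapsed_table <- function(collapsed, path) {
  out <- tibble::tibble(
    parts_union = purrr::map_chr(comparison_parts(collapsed), paste,
                                 collapse = ";"),
    n_parts = collapsed$n_parts,
    n_common = collapsed$n_common,
    n_members = collapsed$n_members
  )
  if ("simpson" %in% names(collapsed)) {
    out$simpson <- collapsed$simpson
    out$simpson_variant <- collapsed$simpson_variant
  }
  write_tsv_stable(out, path)
  invisible(out)
}

#' Build an UpSet-style membership matrix for collapsed comparisons
#'
#' Rows are comparisons, columns the `N` registry datasets in registry
#' order, cells 0/1 for membership in `parts_union`, plus `n_common` and
#' (when present) `simpson` columns — the numeric substrate of an UpSet
#' figure.
#'
#' @param collapsed Nonempty tibble from [collapse_redundant()].
#' @param reg The `ev_registry`.
#' @return A tibble: one 0/1 column per dataset id plus `n_parts`,
#'   `n_common`, and `simpson` if available.
#' @export
upset_matrix <- function(collapsed, reg) {
  stopifnot(inherits(reg, "ev_registry"))
  parts <- comparison_parts(collapsed)
  if (length(parts) == 0) {
    abort_validation("No collapsed comparisons to tabulate.")
  }
  memb <- purrr::map(parts, ~ as.integer(reg$id %in% .x))
  mat <- tibble::as_tibble(
    stats::setNames(as.data.frame(do.call(rbind, memb)), reg$id)
  )
  mat$n_parts <- collapsed$n_parts
  mat$n_common <- collapsed$n_common
  if ("simpson" %in% names(collapsed)) mat$simpson <- collapsed$simpson
  mat
}

#' @rdname upset_matrix
#' @param path Output TSV path.
#' @return `write_upset_matrix`: invisibly, the written tibble.
#' @export
write_upset_matrix <- function(collapsed, reg, path) {
  out <- upset_matrix(collapsed, reg)
  write_tsv_stable(out, path)
  invisible(out)
}

#' UpSet-style plot of top-ranked comparisons
#'
#' Bar chart of shared-protein counts for the top-ranked collapsed
#' comparisons, filled by Simpson type diversity when available, over a dot
#' matrix marking the datasets each comparison involves.
#'
#' @param collapsed Tibble from [collapse_redundant()], typically after
#'   [rank_comparisons()] and [add_simpson()].
#' @param reg The `ev_registry`.
#' @param bar `"n_common"` (default) or `"n_parts"` for the bar height.
#' @return A ggplot object.
#' @export
plot_comparisons <- function(collapsed, reg, bar = c("n_common", "n_parts")) {
  bar <- match.arg(bar)
  mat <- upset_matrix(collapsed, reg)
  mat$comparison <- factor(seq_len(nrow(mat)))
  long <- tidyr::pivot_longer(mat, dplyr::all_of(reg$id),
                              names_to = "dataset", values_to = "member")
  long$dataset <- factor(long$dataset, levels = rev(reg$id))
  p_dots <- ggplot2::ggplot(long, ggplot2::aes(.data$comparison, .data$dataset)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$member)), size = 2) +
    ggplot2::scale_colour_manual(values = c(`0` = "grey85", `1` = "#e7548c"),
                                 guide = "none") +
    ggplot2::labs(x = "comparison (ranked)", y = NULL) +
    ggplot2::theme_minimal()
  bars <- ggplot2::ggplot(mat, ggplot2::aes(.data$comparison, .data[[bar]]))
  bars <- if ("simpson" %in% names(mat)) {
    bars + ggplot2::geom_col(ggplot2::aes(fill = .data$simpson)) +
      ggplot2::scale_fill_gradient(low = "#3fa66a", high = "#e7548c",
                                   limits = c(0, 1), name = "Simpson")
  } else {
    bars + ggplot2::geom_col(fill = "#e7548c")
  }
  bars <- bars + ggplot2::labs(x = NULL, y = bar) + ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  patch <- tryCatch(asNamespace("patchwork"), error = function(e) NULL)
  if (!is.null(patch)) {
    patch$wrap_plots(bars, p_dots, ncol = 1, heights = c(2, 3))
  } else {
    p_dots
  }
}

#' Write a run manifest
#'
#' Records tool version, subcommand, the fully resolved configuration, MD5
#' digests of every input file, the list of output files, and timestamps,
#' so a run can be replayed and audited.
#'
#' @param subcommand Name of the pipeline stage.
#' @param config Named list of resolved parameters.
#' @param inputs Character vector of input file paths (digested).
#' @param outputs Character vector of output file paths.
#' @param path Manifest JSON path.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(subcommand, config, inputs, outputs, path) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character())
  }
  manifest <- list(
    tool = "evmeta",
    version = as.character(utils::packageVersion("evmeta")),
    subcommand = subcommand,
    config = config,
    input_digests = digests,
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Deterministic TSV writer: fixed field order, no quoting surprises, "NA"
# for missing — identical inputs give identical bytes.
write_tsv_stable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}
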