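#' Upper-tail hypergeometric probability
#'
#' Exact `P[X >= k]` for `X ~ Hypergeometric(M, K, n)`: drawing `n` proteins
#' without replacement from a universe of `M` of which `K` are annotated,
#' the probability of seeing `k` or more annotated ones. Thin wrapper over
#' [stats::phyper()] with count validation.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Annotation-set size within the universe.
#' @param n Query size within the universe.
#' @param M Universe size.
#' @return The exact upper-tail probability in (0, 1].
#' @export
hypergeometric_upper <- function(k, K, n, M) {
  vals <- c(k = k, K = K, n = n, M = M)
  if (any(vals < 0) || K > M || n > M || k > min(K, n)) {
    abort_validation(sprintf(
      "Inconsistent hypergeometric counts: k=%s, K=%s, n=%s, M=%s (need 0 <= k <= min(K, n) and K, n <= M).",
      k, K, n, M
    ))
  }
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis against annotation sets
#'
#' For every annotation set overlapping the query, computes the overlap
#' within the universe, the fold enrichment `(k/n) / (K/M)`, an exact
#' upper-tail hypergeometric p-value, and a BH q-value across exactly the
#' tested (overlap >= 1) terms. This is a local stand-in for web-service
#' annotation tools: the annotation sets are user inputs and no database is
#' bundled.
#'
#' @param query Protein set of interest (e.g. the up-regulated proteins);
#'   trimmed to the universe with a warning if it extends beyond it.
#' @param universe Background protein set, typically all proteins detected
#'   in the experiment.
#' @param sets Annotation tibble from [read_gene_sets()] (`term_id`,
#'   `term_name`, `proteins` list-column); members are intersected with the
#'   universe before testing.
#' @param alpha Significance level recorded alongside the results
#'   (default 0.05).
#' @return A tibble, one row per tested term, sorted by `q_value` then
#'   `p_value` (ties by `term_id`): `term_id`, `term_name`, `k`, `K`, `n`,
#'   `M`, `fold_enrichment`, `p_value`, `q_value`, `significant`.
#' @export
run_ora <- function(query, universe, sets, alpha = 0.05) {
  universe <- unique(normalize_accession(universe))
  query <- unique(normalize_accession(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    rlang::warn(sprintf(
      "%d query protein(s) outside the universe were trimmed.", length(outside)
    ))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) {
    abort_validation("Query is empty after trimming to the universe.")
  }
  if (!is.data.frame(sets) || !all(c("term_id", "proteins") %in% names(sets)) ||
      nrow(sets) == 0) {
    abort_validation("`sets` must be a nonempty annotation tibble (see read_gene_sets()).")
  }

  M <- length(universe)
  n <- length(query)
  members <- purrr::map(sets$proteins, intersect, universe)
  res <- tibble::tibble(
    term_id = sets$term_id,
    term_name = if ("term_name" %in% names(sets)) sets$term_name else NA_character_,
    k = purrr::map_int(members, ~ length(intersect(.x, query))),
    K = lengths(members),
    n = n,
    M = M
  )
  res <- dplyr::filter(res, .data$k >= 1)
  if (nrow(res) == 0) {
    return(dplyr::mutate(res, fold_enrichment = numeric(),
                         p_value = numeric(), q_value = numeric(),
                         significant = logical()))
  }
  res$fold_enrichment <- (res$k / res$n) / (res$K / res$M)
  res$p_value <- purrr::pmap_dbl(res[c("k", "K", "n", "M")],
                                 function(k, K, n, M) {
                                   hypergeometric_upper(k, K, n, M)
                                 })
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  dplyr::arrange(res, .data$q_value, .data$p_value, .data$term_id)
}
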