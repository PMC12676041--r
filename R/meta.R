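#' Exhaustively enumerate multi-dataset comparisons
#'
#' Enumerates every combination of two or more datasets in the registry as
#' one comparison, identified by the ordered tuple of dataset ids involved
#' and the exact intersection of their protein sets. For `N` datasets this
#' yields `2^N - N - 1` comparisons (all subsets minus the empty set and the
#' `N` singletons), including comparisons whose intersection is empty.
#' Order is deterministic: subset size ascending, then lexicographic by
#' registry position.
#'
#' Intersections are computed once per subset along a depth-first walk of
#' the subset lattice (each subset's membership vector is one `&` away from
#' its parent's), so a 16-dataset registry over a few hundred proteins
#' enumerates in seconds.
#'
#' @param reg An `ev_registry` tibble (see [registry()]).
#' @param max_n Refuse registries larger than this (default 24): the number
#'   of comparisons grows as `2^N`.
#' @return A tibble of class `ev_comparisons`, one row per comparison:
#'   `parts` (list of dataset-id tuples, registry order), `common` (list of
#'   sorted protein-id vectors), `n_parts`, `n_common`.
#' @examples
#' reg <- registry(tibble::tibble(
#'   id = c("a", "b", "c"),
#'   condition_type = c("normoxia", "hypoxia", "hypoxia"),
#'   proteins = list(c("P1", "P2"), c("P2", "P3"), "P2")
#' ))
#' enumerate_comparisons(reg)
#' @export
enumerate_comparisons <- function(reg, max_n = 24) {
  stopifnot(inherits(reg, "ev_registry"))
  n <- nrow(reg)
  if (n < 2) {
    abort_validation("Meta-comparison needs at least 2 datasets in the registry.")
  }
  if (n > max_n) {
    abort_validation(sprintf(
      "Registry has %d datasets; enumerating 2^%d subsets exceeds the cap (max_n = %d).",
      n, n, max_n
    ))
  }
  universe <- sort(unique(unlist(reg$proteins)), method = "radix")
  memb <- matrix(vapply(reg$proteins, function(p) universe %in% p,
                        logical(length(universe))),
                 nrow = length(universe))

  total <- 2L^n - n - 1L
  parts_idx <- vector("list", total)
  common_idx <- vector("list", total)
  count <- 0L
  visit <- function(j_start, idx, cur) {
    for (j in j_start:n) {
      idx2 <- c(idx, j)
      cur2 <- if (is.null(cur)) memb[, j] else cur & memb[, j]
      if (length(idx2) >= 2L) {
        count <<- count + 1L
        parts_idx[[count]] <<- idx2
        common_idx[[count]] <<- which(cur2)
      }
      if (j < n) visit(j + 1L, idx2, cur2)
    }
  }
  visit(1L, integer(0), NULL)
  stopifnot(count == total)

  # depth-first order -> (size ascending, lexicographic by registry position)
  lex <- vapply(parts_idx, function(i) paste(sprintf("%02d", i), collapse = ""),
                character(1))
  ord <- order(lengths(parts_idx), lex, method = "radix")
  parts_idx <- parts_idx[ord]
  common_idx <- common_idx[ord]

  out <- tibble::tibble(
    parts = purrr::map(parts_idx, ~ reg$id[.x]),
    common = purrr::map(common_idx, ~ universe[.x]),
    n_parts = lengths(parts_idx),
    n_common = lengths(common_idx)
  )
  class(out) <- c("ev_comparisons", class(out))
  out
}

#' Restrict comparisons to those involving anchor datasets
#'
#' `mode = "any"` keeps comparisons whose parts intersect the anchors;
#' `mode = "all"` keeps those containing every anchor. Input order is
#' preserved. With `k` anchors out of `N` datasets, `any`-mode keeps
#' `(2^N - N - 1) - (2^(N-k) - (N-k) - 1)` comparisons.
#'
#' @param comparisons Tibble from [enumerate_comparisons()] (needs the
#'   `parts` list-column).
#' @param anchor_ids Nonempty character vector of dataset ids.
#' @param mode `"any"` (default) or `"all"`.
#' @param reg Optional `ev_registry` used to validate `anchor_ids`; when
#'   absent, anchors are checked against the ids appearing in `comparisons`.
#' @return The filtered comparisons tibble.
#' @export
filter_by_anchor <- function(comparisons, anchor_ids,
                             mode = c("any", "all"), reg = NULL) {
  mode <- match.arg(mode)
  parts <- comparison_parts(comparisons)
  if (length(anchor_ids) == 0) {
    abort_validation("`anchor_ids` must be nonempty.")
  }
  known <- if (!is.null(reg)) reg$id else unique(unlist(parts))
  unknown <- setdiff(anchor_ids, known)
  if (length(unknown) > 0) {
    abort_validation(sprintf("Unknown anchor dataset id(s): %s.",
                             paste(unknown, collapse = ", ")))
  }
  keep <- if (mode == "any") {
    purrr::map_lgl(parts, ~ any(.x %in% anchor_ids))
  } else {
    purrr::map_lgl(parts, ~ all(anchor_ids %in% .x))
  }
  comparisons[keep, , drop = FALSE]
}

# A raw comparisons tibble carries `parts`; a collapsed one carries
# `parts_union`. Both are accepted wherever a tuple of dataset ids is needed.
comparison_parts <- function(comparisons) {
  col <- intersect(c("parts", "parts_union"), names(comparisons))[1]
  if (is.na(col)) {
    abort_validation("Expected a `parts` or `parts_union` list-column.")
  }
  comparisons[[col]]
}

#' Collapse comparisons that share an identical common-protein set
#'
#' Two comparisons whose intersections are the same protein set carry the
#' same information; the smaller one is redundant. Comparisons are grouped
#' by exact set equality of `common`, and each group is merged into one
#' record whose `parts_union` is the union of all member part-tuples (kept
#' in registry order). Comparisons with an empty intersection are dropped
#' before grouping by default (`keep_empty = TRUE` retains them as one
#' degenerate group). By construction the intersection over `parts_union`
#' must still equal the shared common set; this soundness invariant is
#' re-verified against the registry and a violation raises an
#' internal-consistency error, since it can only mean corrupted input.
#'
#' @param comparisons Tibble from [enumerate_comparisons()] (possibly
#'   anchor-filtered), or a collapsed tibble (collapse is idempotent).
#' @param reg The `ev_registry` the comparisons were drawn from.
#' @param keep_empty Retain empty-intersection comparisons (default `FALSE`).
#' @return A tibble of class `ev_collapsed`, one row per distinct common
#'   set, in order of first appearance: `parts_union` (list), `common`
#'   (list), `n_parts`, `n_common`, `n_members` (raw comparisons merged).
#' @export
collapse_redundant <- function(comparisons, reg, keep_empty = FALSE) {
  stopifnot(inherits(reg, "ev_registry"))
  parts <- comparison_parts(comparisons)
  common <- comparisons$common
  if (!keep_empty) {
    nonempty <- lengths(common) > 0
    parts <- parts[nonempty]
    common <- common[nonempty]
  }
  if (length(parts) == 0) {
    out <- tibble::tibble(parts_union = list(), common = list(),
                          n_parts = integer(), n_common = integer(),
                          n_members = integer())
    class(out) <- c("ev_collapsed", class(out))
    return(out)
  }
  key <- purrr::map_chr(common, ~ paste(sort(.x, method = "radix"),
                                        collapse = "\x1f"))
  grp <- match(key, unique(key))
  members <- unname(split(seq_along(parts), grp))

  rows <- purrr::map(members, function(ii) {
    ids <- unique(unlist(parts[ii]))
    pu <- reg$id[sort(match(ids, reg$id))]
    if (anyNA(match(ids, reg$id))) {
      abort_validation("Comparison references dataset id(s) absent from the registry.")
    }
    cm <- common[[ii[1]]]
    recomputed <- sort(purrr::reduce(reg$proteins[match(pu, reg$id)], intersect),
                       method = "radix")
    if (!identical(recomputed, sort(cm, method = "radix"))) {
      abort_internal(paste(
        "Collapse soundness violated: the intersection over the merged",
        "dataset tuple differs from the shared common set. The input",
        "comparisons do not come from true intersections over this registry."
      ))
    }
    list(parts_union = pu, common = cm, n_members = length(ii))
  })
  out <- tibble::tibble(
    parts_union = purrr::map(rows, "parts_union"),
    common = purrr::map(rows, "common"),
    n_parts = lengths(purrr::map(rows, "parts_union")),
    n_common = lengths(purrr::map(rows, "common")),
    n_members = purrr::map_int(rows, "n_members")
  )
  class(out) <- c("ev_collapsed", class(out))
  out
}

#' Rank collapsed comparisons
#'
#' Sorts descending by `key` (`n_common`, the number of shared proteins, or
#' `n_parts`, the number of datasets involved), breaking ties by the other
#' key descending and then by the `parts_union` tuple ascending, so the
#' ranking is deterministic across runs. Returns the top `k` records.
#'
#' @param collapsed Tibble from [collapse_redundant()].
#' @param key `"n_common"` (default) or `"n_parts"`.
#' @param k Number of records to return (default 10; capped at the number
#'   available).
#' @return The top-`k` rows of `collapsed`, ranked.
#' @export
rank_comparisons <- function(collapsed, key = c("n_common", "n_parts"), k = 10) {
  key <- match.arg(key)
  if (!is.numeric(k) || k < 1) {
    abort_validation("`k` must be a positive integer.")
  }
  other <- setdiff(c("n_common", "n_parts"), key)
  lex <- purrr::map_chr(comparison_parts(collapsed), paste, collapse = "\x1f")
  ord <- order(-collapsed[[key]], -collapsed[[other]], lex, method = "radix")
  collapsed[ord[seq_len(min(k, nrow(collapsed)))], , drop = FALSE]
}

#' Simpson condition-type diversity of one comparison
#'
#' The probability that two datasets drawn from the comparison share the
#' same condition type. The default without-replacement estimator is
#' `sum_t n_t (n_t - 1) / (n (n - 1))` over the type counts `n_t`
#' (`n = |parts|`): 0 when all types are distinct, 1 when all are equal.
#' The classic with-replacement form `sum_t (n_t / n)^2` is selectable.
#'
#' @param parts Character vector of dataset ids (length >= 2).
#' @param reg The `ev_registry` resolving each id to a condition type.
#' @param variant `"without_replacement"` (default) or `"with_replacement"`.
#' @return A list with `value` (in `[0, 1]`), `variant`, and `type_counts`
#'   (named integer vector of condition-type counts).
#' @examples
#' reg <- registry(tibble::tibble(
#'   id = c("a", "b", "c"),
#'   condition_type = c("hypoxia", "hypoxia", "normoxia"),
#'   proteins = list("P1", "P1", "P1")
#' ))
#' simpson_index(c("a", "b", "c"), reg)$value  # 1/3
#' @export
simpson_index <- function(parts, reg,
                          variant = c("without_replacement", "with_replacement")) {
  variant <- match.arg(variant)
  stopifnot(inherits(reg, "ev_registry"))
  if (length(parts) < 2) {
    abort_validation("Simpson index needs at least 2 datasets.")
  }
  pos <- match(parts, reg$id)
  if (anyNA(pos)) {
    abort_validation(sprintf("Unresolvable dataset id(s): %s.",
                             paste(parts[is.na(pos)], collapse = ", ")))
  }
  types <- reg$condition_type[pos]
  counts <- table(types)
  n <- length(parts)
  value <- if (variant == "without_replacement") {
    sum(counts * (counts - 1)) / (n * (n - 1))
  } else {
    sum((counts / n)^2)
  }
  tc <- as.integer(counts)
  names(tc) <- names(counts)
  list(value = value, variant = variant, type_counts = tc)
}

#' Append a Simpson-index column to collapsed comparisons
#'
#' @param collapsed Tibble from [collapse_redundant()] (or ranked output).
#' @param reg The `ev_registry`.
#' @param variant Passed to [simpson_index()].
#' @return `collapsed` with numeric columns `simpson` and the variant name
#'   recorded in the `simpson_variant` column.
#' @export
add_simpson <- function(collapsed, reg,
                        variant = c("without_replacement", "with_replacement")) {
  variant <- match.arg(variant)
  parts <- comparison_parts(collapsed)
  collapsed$simpson <- purrr::map_dbl(
    parts, ~ simpson_index(.x, reg, variant = variant)$value
  )
  collapsed$simpson_variant <- variant
  collapsed
}

#' Count overlap of a protein set with reference catalogs
#'
#' Counts, per catalog and combined, how many query proteins appear in each
#' reference catalog (for example ExoCarta and Vesiclepedia snapshots):
#' `in_any + in_none = |query|`.
#'
#' @param query Nonempty character vector of protein ids (normalized on
#'   entry).
#' @param catalogs Tibble with columns `name` and list-column `proteins`
#'   (rows from [catalog()], combined with [dplyr::bind_rows()]).
#' @return A list of class `catalog_overlap`: `per_catalog` (tibble with
#'   `catalog`, `n_catalog`, `n_overlap`, `fraction_of_query`), `n_query`,
#'   `in_any`, `in_none`, and `novel` (query proteins in no catalog).
#' @export
compare_catalog <- function(query, catalogs) {
  if (length(query) == 0) {
    abort_validation("`query` must be nonempty.")
  }
  if (!is.data.frame(catalogs) ||
      !all(c("name", "proteins") %in% names(catalogs)) ||
      nrow(catalogs) == 0) {
    abort_validation("`catalogs` must be a nonempty tibble with `name` and `proteins` columns.")
  }
  query <- unique(normalize_accession(query))
  per <- tibble::tibble(
    catalog = catalogs$name,
    n_catalog = lengths(catalogs$proteins),
    n_overlap = purrr::map_int(catalogs$proteins, ~ sum(query %in% .x)),
    fraction_of_query = purrr::map_int(catalogs$proteins,
                                       ~ sum(query %in% .x)) / length(query)
  )
  any_hit <- purrr::reduce(
    purrr::map(catalogs$proteins, ~ query %in% .x), `|`
  )
  structure(
    list(
      per_catalog = per,
      n_query = length(query),
      in_any = sum(any_hit),
      in_none = sum(!any_hit),
      novel = query[!any_hit]
    ),
    class = "catalog_overlap"
  )
}

#' @export
print.catalog_overlap <- function(x, ...) {
  cat(sprintf("Catalog overlap for %d query proteins:\n", x$n_query))
  print(x$per_catalog)
  cat(sprintf("  in any catalog: %d; in none: %d\n", x$in_any, x$in_none))
  invisible(x)
}
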