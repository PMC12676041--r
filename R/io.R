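#' Read a two-condition protein abundance table
#'
#' Reads a TSV whose first column is `protein_id` and whose remaining columns
#' are replicate sample intensities. Label-free intensity zeros usually mean
#' "not quantified", so empty cells, `NA`, `NaN`, and `0` are all recorded as
#' missing by default; set `zeros_are_values = TRUE` to keep zeros as
#' observed intensities. Negative intensities are rejected with their
#' row/column coordinates.
#'
#' @param path Path to the TSV abundance table.
#' @param zeros_are_values Treat `0` as an observed intensity rather than
#'   missing (default `FALSE`).
#' @param strip_isoform Passed to [normalize_accession()].
#' @return A tibble: `protein_id` plus one numeric column per sample, with
#'   `NA` marking missing intensities.
#' @export
read_abundance_table <- function(path, zeros_are_values = FALSE,
                                 strip_isoform = TRUE) {
  if (!file.exists(path)) {
    abort_validation(sprintf("Abundance table not found: %s", path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) {
    abort_validation("Abundance table needs a protein-id column and at least one sample column.")
  }
  ids <- normalize_accession(raw[[1]], strip_isoform = strip_isoform)
  if (anyDuplicated(ids) > 0) {
    abort_validation(sprintf(
      "Duplicate protein id(s) after normalization: %s.",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  samples <- names(raw)[-1]
  if (anyDuplicated(samples) > 0) {
    abort_validation("Duplicate sample column names in abundance table.")
  }
  mat <- lapply(seq_along(samples), function(j) {
    col <- trimws(raw[[j + 1]])
    missing <- is.na(col) | col %in% c("", "NA", "NaN", "na", "nan")
    val <- suppressWarnings(as.numeric(col))
    unparsable <- !missing & is.na(val)
    if (any(unparsable)) {
      abort_validation(sprintf(
        "Non-numeric intensity '%s' at protein '%s', sample '%s'.",
        col[which(unparsable)[1]], ids[which(unparsable)[1]], samples[j]
      ))
    }
    neg <- !is.na(val) & val < 0
    if (any(neg)) {
      abort_validation(sprintf(
        "Negative intensity %s at protein '%s', sample '%s'.",
        format(val[which(neg)[1]]), ids[which(neg)[1]], samples[j]
      ))
    }
    val[missing] <- NA_real_
    if (!zeros_are_values) val[!is.na(val) & val == 0] <- NA_real_
    val
  })
  names(mat) <- samples
  tibble::tibble(protein_id = ids, !!!mat)
}

#' Read a sample-to-group assignment map
#'
#' Two-column TSV (`sample_id`, `group`) assigning every sample column of an
#' abundance table to one of exactly two groups.
#'
#' @param path Path to the group-map TSV.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("Group map not found: %s", path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) {
    abort_validation("Group map needs two columns: sample_id, group.")
  }
  tibble::tibble(sample_id = trimws(raw[[1]]), group = trimws(raw[[2]]))
}

# Shared validation for (table, groups) pairs: exactly two groups, each with
# at least one sample, every sample column assigned.
check_abundance <- function(table, groups) {
  if (!is.data.frame(table) || names(table)[1] != "protein_id") {
    abort_validation("Abundance table must be a data frame whose first column is `protein_id`.")
  }
  samples <- setdiff(names(table), "protein_id")
  if (!is.data.frame(groups) || !all(c("sample_id", "group") %in% names(groups))) {
    abort_validation("`groups` must have columns `sample_id` and `group`.")
  }
  unassigned <- setdiff(samples, groups$sample_id)
  if (length(unassigned) > 0) {
    abort_validation(sprintf(
      "Sample(s) without a group assignment: %s.",
      paste(unassigned, collapse = ", ")
    ))
  }
  groups <- groups[groups$sample_id %in% samples, , drop = FALSE]
  lv <- unique(groups$group)
  if (length(lv) != 2) {
    abort_validation(sprintf(
      "Exactly two groups are required; found %d (%s).",
      length(lv), paste(lv, collapse = ", ")
    ))
  }
  if (any(table(groups$group) < 1)) {
    abort_validation("Each group needs at least one sample.")
  }
  groups
}

#' Read GMT-style annotation sets
#'
#' GMT dialect: tab-separated lines of `set-name`, `description`,
#' `member1`, `member2`, .... Member accessions are normalized; sets that
#' become empty are dropped with a warning; when a set name occurs twice the
#' later definition wins (with a warning).
#'
#' @param path Path to the GMT file.
#' @param strip_isoform Passed to [normalize_accession()].
#' @return A tibble with columns `term_id`, `term_name`, and a list-column
#'   `proteins` of normalized member accessions.
#' @export
read_gene_sets <- function(path, strip_isoform = TRUE) {
  if (!file.exists(path)) {
    abort_validation(sprintf("GMT file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- trimws(lines) != ""
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(tibble::tibble(term_id = character(), term_name = character(),
                          proteins = list()))
  }
  # sentinel keeps trailing empty fields (strsplit drops them), so a
  # member-less "name<tab>desc<tab>" line parses as an empty set
  fields <- purrr::map(strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE),
                       ~ .x[-length(.x)])
  short <- lengths(fields) < 3
  if (any(short)) {
    abort_validation(sprintf(
      "GMT parse error at line %d: fewer than 3 tab-separated fields.",
      lineno[which(short)[1]]
    ))
  }
  out <- tibble::tibble(
    term_id = purrr::map_chr(fields, 1),
    term_name = purrr::map_chr(fields, 2),
    proteins = purrr::map(fields, function(f) {
      members <- trimws(f[-(1:2)])
      members <- members[members != ""]
      if (length(members) == 0) return(character())
      unique(normalize_accession(members, strip_isoform = strip_isoform))
    })
  )
  empty <- lengths(out$proteins) == 0
  if (any(empty)) {
    rlang::warn(sprintf(
      "Dropping %d empty annotation set(s): %s.",
      sum(empty), paste(out$term_id[empty], collapse = ", ")
    ))
    out <- out[!empty, , drop = FALSE]
  }
  dup <- duplicated(out$term_id, fromLast = TRUE)
  if (any(dup)) {
    rlang::warn(sprintf(
      "Duplicate set name(s) in GMT, keeping the later definition: %s.",
      paste(unique(out$term_id[dup]), collapse = ", ")
    ))
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Build a reference catalog of EV proteins
#'
#' A catalog is a named, normalized protein set (for example an ExoCarta or
#' Vesiclepedia snapshot) used by [compare_catalog()] to count how much of a
#' detected proteome has previously been observed in extracellular vesicles.
#'
#' @param name Catalog name (nonempty).
#' @param proteins Character vector of member accessions (nonempty).
#' @param strip_isoform Passed to [normalize_accession()].
#' @return A tibble with columns `name` and list-column `proteins`.
#' @export
catalog <- function(name, proteins, strip_isoform = TRUE) {
  if (!is.character(name) || length(name) != 1 || trimws(name) == "") {
    abort_validation("Catalog `name` must be a nonempty string.")
  }
  p <- unique(normalize_accession(as.character(proteins),
                                  strip_isoform = strip_isoform))
  if (length(p) == 0) {
    abort_validation(sprintf("Catalog '%s' has an empty protein set.", name))
  }
  tibble::tibble(name = name, proteins = list(p))
}
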