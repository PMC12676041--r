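#' Build a dataset registry from per-study protein sets
#'
#' A registry is the unit of the meta-comparison stage: an ordered tibble of
#' protein-set datasets, one row per study dataset, each carrying a
#' condition-type label (`normoxia`, `hypoxia`, `OGD`, `stroke`, or `other`)
#' over which the Simpson diversity index is later taken. Row order is
#' significant and preserved: enumeration order and lexicographic tie-breaks
#' are defined over it.
#'
#' @param datasets A data frame with columns `id`, `condition_type`, and a
#'   list-column `proteins` (character vectors of accessions); optional
#'   columns `label`, `species`, `source_ref` are carried through.
#' @param strip_isoform Passed to [normalize_accession()].
#' @return A tibble of class `ev_registry` with columns `id`, `label`,
#'   `condition_type`, `species`, `source_ref`, `proteins` (list-column of
#'   normalized, de-duplicated accessions), and `n_proteins`.
#' @examples
#' registry(tibble::tibble(
#'   id = c("nx", "hx"),
#'   condition_type = c("normoxia", "hypoxia"),
#'   proteins = list(c("P1", "P2"), c("P2", "P3"))
#' ))
#' @export
registry <- function(datasets, strip_isoform = TRUE) {
  if (!is.data.frame(datasets)) {
    abort_validation("`datasets` must be a data frame (one row per study dataset).")
  }
  needed <- c("id", "condition_type", "proteins")
  missing_cols <- setdiff(needed, names(datasets))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf(
      "Registry is missing required column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  ds <- tibble::as_tibble(datasets)
  for (opt in c("label", "species", "source_ref")) {
    if (is.null(ds[[opt]])) ds[[opt]] <- NA_character_
  }

  id <- as.character(ds$id)
  if (any(is.na(id) | trimws(id) == "")) {
    abort_validation("Every dataset needs a nonempty `id`.")
  }
  if (anyDuplicated(id) > 0) {
    abort_validation(sprintf(
      "Duplicate dataset id(s): %s.",
      paste(unique(id[duplicated(id)]), collapse = ", ")
    ))
  }
  ctype <- as.character(ds$condition_type)
  unknown <- setdiff(ctype, condition_types())
  if (length(unknown) > 0) {
    abort_validation(sprintf(
      "Unknown condition_type(s): %s. Allowed values: %s.",
      paste(unique(unknown), collapse = ", "),
      paste(condition_types(), collapse = ", ")
    ))
  }

  proteins <- purrr::map2(ds$proteins, id, function(p, did) {
    p <- normalize_accession(as.character(p), strip_isoform = strip_isoform)
    up <- unique(p)
    if (length(up) < length(p)) {
      rlang::inform(sprintf(
        "Dataset '%s': collapsed %d duplicate accession(s) after normalization.",
        did, length(p) - length(up)
      ))
    }
    if (length(up) == 0) {
      abort_validation(sprintf("Dataset '%s' has an empty protein set.", did))
    }
    up
  })

  out <- tibble::tibble(
    id = id,
    label = as.character(ds$label),
    condition_type = ctype,
    species = as.character(ds$species),
    source_ref = as.character(ds$source_ref),
    proteins = proteins,
    n_proteins = lengths(proteins)
  )
  class(out) <- c("ev_registry", class(out))
  out
}

#' Read a dataset registry from a JSON file plus protein-list files
#'
#' The registry file is a JSON array of objects with keys `id`, `label`,
#' `condition_type`, `species`, `source_ref`, and `proteins_file` (a path to
#' a plain-text protein list, one accession per line, `#` comments allowed),
#' resolved relative to `list_dir` (default: the registry file's directory).
#'
#' @param path Path to the registry JSON document.
#' @param list_dir Directory against which `proteins_file` paths resolve.
#' @param strip_isoform Passed to [normalize_accession()].
#' @return An `ev_registry` tibble (see [registry()]); iteration order is
#'   the file order.
#' @export
read_registry <- function(path, list_dir = dirname(path), strip_isoform = TRUE) {
  if (!file.exists(path)) {
    abort_validation(sprintf("Registry file not found: %s", path))
  }
  entries <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(entries) || nrow(entries) == 0) {
    abort_validation(sprintf("Registry %s contains no dataset entries.", path))
  }
  if (is.null(entries$proteins_file)) {
    abort_validation("Every registry entry needs a `proteins_file` key.")
  }
  files <- file.path(list_dir, entries$proteins_file)
  absent <- !file.exists(files)
  if (any(absent)) {
    abort_validation(sprintf(
      "Protein-list file(s) not found: %s",
      paste(files[absent], collapse = ", ")
    ))
  }
  entries$proteins <- lapply(files, read_protein_list, normalize = FALSE)
  registry(entries, strip_isoform = strip_isoform)
}

#' Read a plain-text protein list
#'
#' One accession per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @param normalize Pass accessions through [normalize_accession()]
#'   (default `TRUE`).
#' @param strip_isoform Passed to [normalize_accession()].
#' @return Character vector of accessions (order of first appearance;
#'   de-duplicated when `normalize = TRUE`).
#' @export
read_protein_list <- function(path, normalize = TRUE, strip_isoform = TRUE) {
  if (!file.exists(path)) {
    abort_validation(sprintf("Protein list not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  if (!normalize) {
    return(lines)
  }
  unique(normalize_accession(lines, strip_isoform = strip_isoform))
}

#' Write a registry to a JSON document plus per-dataset protein lists
#'
#' Inverse of [read_registry()]: writes `registry.json` and one
#' `<id>.proteins.txt` list per dataset into `dir`.
#'
#' @param reg An `ev_registry` tibble.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the path of the written registry JSON.
#' @export
write_registry <- function(reg, dir) {
  stopifnot(inherits(reg, "ev_registry"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- paste0(reg$id, ".proteins.txt")
  purrr::walk2(reg$proteins, files, function(p, f) {
    writeLines(p, file.path(dir, f))
  })
  meta <- tibble::tibble(
    id = reg$id,
    label = reg$label,
    condition_type = reg$condition_type,
    species = reg$species,
    source_ref = reg$source_ref,
    proteins_file = files
  )
  out <- file.path(dir, "registry.json")
  jsonlite::write_json(meta, out, auto_unbox = FALSE, pretty = TRUE, na = "string")
  invisible(out)
}
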