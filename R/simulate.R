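#' Generate a registry of protein-set datasets with planted structure
#'
#' Simulates the input of the meta-comparison stage: a collection of
#' protein-identifier datasets, each labelled with a condition type, built
#' from (i) a core shared by every dataset, (ii) a block shared by all
#' datasets of the same condition type, and (iii) per-dataset noise proteins
#' drawn uniformly from the remaining universe. The default shape mirrors a
#' 16-dataset collection whose first two datasets are the hypoxia and
#' normoxia anchors of the study being compared.
#'
#' All randomness flows from `seed`; identical arguments reproduce the
#' registry bit for bit.
#'
#' @param n_datasets Number of datasets (default 16).
#' @param universe_size Size of the synthetic protein universe (default 600).
#' @param core_size Proteins shared by every dataset (default 25).
#' @param type_assignment Optional named character vector mapping dataset id
#'   to condition type; default: ids `ds01..dsN` typed by recycling
#'   `hypoxia, normoxia, OGD, stroke` (so the first two datasets are the
#'   hypoxia/normoxia anchors).
#' @param type_block_size Proteins shared within each condition type
#'   (default 40).
#' @param noise_size Per-dataset noise proteins (default 80).
#' @param seed Integer seed (required).
#' @return A list: `registry` (an `ev_registry`) and `truth` (list with
#'   `core_proteins`, `type_block_proteins`, `noise_counts`, `seed`).
#' @examples
#' sim <- generate_registry(n_datasets = 4, seed = 1)
#' sim$registry
#' @export
generate_registry <- function(n_datasets = 16, universe_size = 600,
                              core_size = 25, type_assignment = NULL,
                              type_block_size = 40, noise_size = 80, seed) {
  if (missing(seed)) abort_validation("`seed` is required.")
  if (n_datasets < 2) abort_validation("`n_datasets` must be at least 2.")
  if (is.null(type_assignment)) {
    ids <- sprintf("ds%02d", seq_len(n_datasets))
    type_assignment <- stats::setNames(
      rep(c("hypoxia", "normoxia", "OGD", "stroke"),
          length.out = n_datasets),
      ids
    )
  }
  if (length(type_assignment) != n_datasets) {
    abort_validation("`type_assignment` must name every dataset.")
  }
  types_used <- unique(unname(type_assignment))
  need <- core_size + length(types_used) * type_block_size + noise_size
  if (need > universe_size) {
    abort_validation(sprintf(
      "universe_size = %d cannot hold core (%d) + %d type blocks (%d each) + noise pool (>= %d).",
      universe_size, core_size, length(types_used), type_block_size, noise_size
    ))
  }

  universe <- sprintf("SP%05d", seq_len(universe_size))
  core <- universe[seq_len(core_size)]
  offset <- core_size
  blocks <- stats::setNames(vector("list", length(types_used)), types_used)
  for (ty in types_used) {
    blocks[[ty]] <- universe[offset + seq_len(type_block_size)]
    offset <- offset + type_block_size
  }
  noise_pool <- universe[(offset + 1):universe_size]

  proteins <- withr::with_seed(seed, {
    lapply(unname(type_assignment), function(ty) {
      noise <- sample(noise_pool, noise_size)
      c(core, blocks[[ty]], noise)
    })
  })

  reg <- registry(tibble::tibble(
    id = names(type_assignment),
    label = sprintf("synthetic %s dataset", unname(type_assignment)),
    condition_type = unname(type_assignment),
    species = "synthetic",
    source_ref = "simulated",
    proteins = proteins
  ))
  truth <- list(
    core_proteins = core,
    type_block_proteins = blocks,
    noise_counts = stats::setNames(rep(noise_size, n_datasets),
                                   names(type_assignment)),
    seed = seed
  )
  list(registry = reg, truth = truth)
}

#' Generate a two-condition abundance table with planted effects
#'
#' Simulates the input of the differential-expression stage: per-protein
#' baseline intensities drawn log-normal (the standard model for label-free
#' MS intensities), multiplicative per-observation noise with a stated
#' coefficient of variation, planted up/down proteins shifted by
#' `+/- log2_effect` in the treatment group, and missing cells dropped at
#' `missing_rate` — uniformly by default, or biased toward low intensities
#' (`missing_mode = "intensity"`) to mimic the left-censoring typical of
#' label-free data. The default shape is a 210-protein, 3-vs-3 design with
#' 83 up and 61 down proteins.
#'
#' @param n_proteins Number of proteins (default 210).
#' @param n_up,n_down Planted up-/down-regulated proteins (defaults 83, 61);
#'   `n_up + n_down <= n_proteins`.
#' @param log2_effect Planted absolute log2 effect size (default 2).
#' @param cv Coefficient of variation of the multiplicative noise on the
#'   natural scale (default 0.2).
#' @param n_reps_per_group Replicates per group (default 3; minimum 2).
#' @param missing_rate Fraction of cells dropped (default 0.05; in `[0, 1)`).
#' @param missing_mode `"uniform"` (default) or `"intensity"`
#'   (low-abundance-biased).
#' @param group_labels Reference and treatment group labels, in that order
#'   (default `c("Nx", "Hx")`).
#' @param seed Integer seed (required).
#' @return A list: `table` (abundance tibble, see [read_abundance_table()]),
#'   `groups` (sample-to-group tibble), and `truth` (list with
#'   `dep_ids_up`, `dep_ids_down`, `log2_effect`, `cv`, `missing_rate`,
#'   `seed`).
#' @examples
#' sim <- generate_abundance(n_proteins = 20, n_up = 2, n_down = 2, seed = 7)
#' sim$table
#' @export
generate_abundance <- function(n_proteins = 210, n_up = 83, n_down = 61,
                               log2_effect = 2, cv = 0.2,
                               n_reps_per_group = 3, missing_rate = 0.05,
                               missing_mode = c("uniform", "intensity"),
                               group_labels = c("Nx", "Hx"), seed) {
  missing_mode <- match.arg(missing_mode)
  if (missing(seed)) abort_validation("`seed` is required.")
  if (n_up + n_down > n_proteins) {
    abort_validation("`n_up + n_down` cannot exceed `n_proteins`.")
  }
  if (n_reps_per_group < 2) {
    abort_validation("`n_reps_per_group` must be at least 2.")
  }
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    abort_validation("`missing_rate` must lie in [0, 1).")
  }
  if (cv < 0) abort_validation("`cv` must be nonnegative.")
  if (length(group_labels) != 2 || anyDuplicated(group_labels) > 0) {
    abort_validation("`group_labels` must be two distinct labels.")
  }

  ids <- sprintf("SP%05d", seq_len(n_proteins))
  up_ids <- ids[seq_len(n_up)]
  down_ids <- ids[n_up + seq_len(n_down)]
  reps <- n_reps_per_group
  samples <- c(paste0(group_labels[1], "_", seq_len(reps)),
               paste0(group_labels[2], "_", seq_len(reps)))
  is_treat <- rep(c(FALSE, TRUE), each = reps)

  # multiplicative log-normal noise with E = 1 and the requested CV
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2

  mat <- withr::with_seed(seed, {
    base <- stats::rlnorm(n_proteins, meanlog = log(1e6), sdlog = 1)
    shift <- rep(0, n_proteins)
    shift[ids %in% up_ids] <- log2_effect
    shift[ids %in% down_ids] <- -log2_effect
    m <- matrix(NA_real_, n_proteins, length(samples),
                dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      mult <- if (is_treat[j]) 2^shift else rep(1, n_proteins)
      m[, j] <- base * mult *
        stats::rlnorm(n_proteins, meanlog = meanlog, sdlog = sdlog)
    }
    if (missing_rate > 0) {
      if (missing_mode == "uniform") {
        drop <- matrix(stats::runif(length(m)) < missing_rate,
                       nrow = nrow(m))
      } else {
        # low-abundance bias: drop probability proportional to the
        # reverse intensity rank, scaled to the requested overall rate
        rk <- matrix(rank(-m), nrow = nrow(m))
        pr <- missing_rate * 2 * rk / (length(m) + 1)
        drop <- matrix(stats::runif(length(m)) < pr, nrow = nrow(m))
      }
      m[drop] <- NA_real_
    }
    m
  })

  table <- tibble::tibble(protein_id = ids,
                          !!!as.data.frame(mat, optional = TRUE))
  groups <- tibble::tibble(sample_id = samples,
                           group = rep(group_labels, each = reps))
  truth <- list(dep_ids_up = up_ids, dep_ids_down = down_ids,
                log2_effect = log2_effect, cv = cv,
                missing_rate = missing_rate, seed = seed)
  list(table = table, groups = groups, truth = truth)
}
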