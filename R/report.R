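#' @title Publication-style report writers
#' @description Deterministic file-writing front-ends over the analysis
#'   functions: given input tables (or a config) and an output directory,
#'   each writer produces tidy delimited text that a manuscript or downstream
#'   pipeline can consume byte-identically on re-runs. A thin command-line
#'   wrapper over these functions ships in `inst/scripts/gekkodiet-cli.R`.
#' @name report
NULL

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

load_dataset <- function(specimens_path, prey_path, delim = ",") {
  assemble_dataset(read_specimen_table(specimens_path, delim = delim),
                   read_prey_table(prey_path, delim = delim))
}

#' Abbreviate prey-category labels
#'
#' Three-letter labels for plot axes (first three characters, capitalised,
#' de-duplicated with a numeric suffix), the convention used for importance
#' bar charts in diet papers (Araneae = Ara, Opiliones = Opi, ...).
#'
#' @param categories Character vector of category labels.
#' @return Character vector of unique three-letter abbreviations.
#' @export
abbreviate_categories <- function(categories) {
  ab <- substr(categories, 1, 3)
  substr(ab, 1, 1) <- toupper(substr(ab, 1, 1))
  make.unique(ab, sep = "")
}

#' Write a composition report
#'
#' Builds the composition table of a dataset and writes three files into
#' `out_dir`: `composition.csv` (the publication-style table, rounded to two
#' decimals), `iri_ranking.csv` (categories in IRI order with three-letter
#' abbreviations and ranks) and `composition_log.txt` recording the
#' denominator conventions used. Output is deterministic: re-running on the
#' same inputs reproduces the files byte for byte.
#'
#' @param dataset A `diet_dataset`, or `NULL` to read from paths.
#' @param specimens_path,prey_path Input files (used when `dataset` is NULL).
#' @param out_dir Output directory (created if needed).
#' @param groups,freq_denominator,pi_mode Passed to [composition_table()].
#' @param min_F Passed to [rank_by_iri()] for the ranking file.
#' @param delim Delimiter for input and output files.
#' @return Named character vector of the files written, invisibly.
#' @export
report_composition <- function(dataset = NULL, specimens_path = NULL,
                               prey_path = NULL, out_dir = ".",
                               groups = NULL,
                               freq_denominator = c("sum_of_F", "n_stomachs"),
                               pi_mode = c("exact", "3.14"),
                               min_F = 1, delim = ",") {
  freq_denominator <- match.arg(freq_denominator)
  pi_mode <- match.arg(pi_mode)
  if (is.null(dataset)) {
    dataset <- load_dataset(specimens_path, prey_path, delim = delim)
  }
  ensure_out_dir(out_dir)
  comp <- composition_table(dataset, groups = groups,
                            freq_denominator = freq_denominator,
                            pi_mode = pi_mode)
  files <- c(composition = file.path(out_dir, "composition.csv"),
             ranking = file.path(out_dir, "iri_ranking.csv"),
             log = file.path(out_dir, "composition_log.txt"))
  write_composition(comp, files[["composition"]], delim = delim)
  ranked <- rank_by_iri(comp, min_F = min_F)
  rows <- as_tibble(comp)
  ranking <- tibble(rank = seq_along(ranked), category = ranked,
                    abbreviation = abbreviate_categories(ranked),
                    iri = round_half_up(rows$iri[match(ranked, rows$category)], 2))
  readr::write_delim(ranking, files[["ranking"]], delim = delim, progress = FALSE)
  tot <- attr(comp, "totals")
  writeLines(c(
    sprintf("freq_denominator: %s", freq_denominator),
    sprintf("pi_mode: %s", pi_mode),
    sprintf("n_stomachs: %s", attr(comp, "n_stomachs")),
    sprintf("sum_F: %d", tot[["F"]]),
    sprintf("sum_N: %d", tot[["N"]]),
    sprintf("sum_V_mm3: %.6f", tot[["V"]]),
    sprintf("ranking_min_F: %d", min_F)), files[["log"]])
  invisible(files)
}

#' Write a group-comparison report
#'
#' Runs [compare_groups()] and writes the tidy result table to
#' `comparisons.csv` in `out_dir`.
#'
#' @inheritParams report_composition
#' @inheritParams compare_groups
#' @return Named character vector of the files written, invisibly.
#' @export
report_comparisons <- function(dataset = NULL, specimens_path = NULL,
                               prey_path = NULL, out_dir = ".",
                               grouping = c("sex", "age"),
                               metrics = c("item_length", "item_width",
                                           "item_volume", "count_per_stomach",
                                           "total_volume_per_stomach"),
                               p_adjust = c("none", "holm"), delim = ",") {
  grouping <- match.arg(grouping)
  p_adjust <- match.arg(p_adjust)
  if (is.null(dataset)) {
    dataset <- load_dataset(specimens_path, prey_path, delim = delim)
  }
  ensure_out_dir(out_dir)
  res <- compare_groups(dataset, grouping = grouping, metrics = metrics,
                        p_adjust = p_adjust)
  files <- c(comparisons = file.path(out_dir, "comparisons.csv"))
  readr::write_delim(res, files[["comparisons"]], delim = delim, progress = FALSE)
  invisible(files)
}

#' Write a synthetic dataset to disk
#'
#' Generates a dataset from a `synthetic_config` (or a YAML file describing
#' one) and writes `specimens.csv`, `prey_items.csv` and a `provenance.yml`
#' sidecar recording the seed and a hash of the configuration, so a dataset
#' on disk can always be traced to the exact generator settings.
#'
#' @param config A `synthetic_config`, or a path to a YAML file accepted by
#'   [synthetic_config_from_yaml()].
#' @param out_dir Output directory.
#' @param seed Overrides the config seed when non-NULL.
#' @param delim Output delimiter.
#' @return Named character vector of the files written, invisibly.
#' @export
report_synthetic <- function(config, out_dir = ".", seed = NULL, delim = ",") {
  if (is.character(config)) config <- synthetic_config_from_yaml(config)
  stopifnot(inherits(config, "synthetic_config"))
  seed <- as.integer(seed %||% config$seed)
  ensure_out_dir(out_dir)
  ds <- generate_dataset(config, seed = seed)
  files <- c(specimens = file.path(out_dir, "specimens.csv"),
             prey_items = file.path(out_dir, "prey_items.csv"),
             provenance = file.path(out_dir, "provenance.yml"))
  write_specimen_table(ds, files[["specimens"]], delim = delim)
  write_prey_table(ds, files[["prey_items"]], delim = delim)
  prov <- list(seed = seed,
               config_hash = rlang::hash(config[c(
                 "group_sizes", "morphometrics", "trait_correlations",
                 "prey_count_mean", "prey_count_sd", "categories",
                 "size_targets", "group_effects")]),
               n_specimens = nrow(ds$specimens),
               n_prey_items = nrow(ds$prey_items))
  yaml::write_yaml(prov, files[["provenance"]])
  invisible(files)
}

#' Write a divergence report
#'
#' Computes the pairwise uncorrected p-distance matrix of an aligned FASTA
#' and writes it in both square PHYLIP style (`distances.phy`) and tidy CSV
#' (`distances.csv`), plus `divergence_log.txt` with the maximum divergence
#' and the achieving pair.
#'
#' @param fasta_path Aligned FASTA input.
#' @param out_dir Output directory.
#' @inheritParams p_distance
#' @return Named character vector of the files written, invisibly.
#' @export
report_divergence <- function(fasta_path, out_dir = ".",
                              ambiguity_policy = c("pairwise_delete",
                                                   "mismatch_if_incompatible")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  aln <- read_alignment(fasta_path)
  ensure_out_dir(out_dir)
  dm <- distance_matrix(aln, ambiguity_policy)
  mx <- max_divergence(aln, ambiguity_policy)
  files <- c(phylip = file.path(out_dir, "distances.phy"),
             csv = file.path(out_dir, "distances.csv"),
             log = file.path(out_dir, "divergence_log.txt"))
  write_distance_matrix(dm, files[["phylip"]], format = "phylip")
  write_distance_matrix(dm, files[["csv"]], format = "csv")
  writeLines(c(
    sprintf("alignment_length: %d", aln$alignment_length),
    sprintf("n_sequences: %d", length(aln$ids)),
    sprintf("ambiguity_policy: %s", ambiguity_policy),
    sprintf("max_divergence_percent: %.2f", mx$percent),
    sprintf("max_pair: %s %s", mx$pair[1], mx$pair[2])), files[["log"]])
  invisible(files)
}

#' Read a generator configuration from YAML
#'
#' Accepts a YAML file whose top-level keys mirror the arguments of
#' [synthetic_config()] (`seed`, `group_sizes`, `prey_count_mean`,
#' `prey_count_sd`, `length_mean`, `length_sd`, `width_mean`, `width_sd`,
#' and optionally `group_effects: {length_shift_sd: {female: 1}}`).
#' Unspecified keys keep their defaults.
#'
#' @param path Path to the YAML file.
#' @return A `synthetic_config`.
#' @export
synthetic_config_from_yaml <- function(path) {
  if (!file.exists(path)) {
    stop_gekkodiet(sprintf("Config file not found: %s.", path),
                   "gekkodiet_io_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_gekkodiet(sprintf("Malformed YAML in %s: %s.", path,
                           conditionMessage(e)),
                   "gekkodiet_config_error")
  })
  if (!is.list(raw)) {
    stop_gekkodiet(sprintf("Malformed YAML in %s: expected a mapping.", path),
                   "gekkodiet_config_error")
  }
  args <- list()
  scalar_keys <- c("seed", "prey_count_mean", "prey_count_sd",
                   "length_mean", "length_sd", "width_mean", "width_sd")
  for (key in scalar_keys) if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  if (!is.null(raw$group_sizes)) args$group_sizes <- unlist(raw$group_sizes)
  if (!is.null(raw$group_effects)) {
    args$group_effects <- lapply(raw$group_effects, unlist)
  }
  unknown <- setdiff(names(raw), c(scalar_keys, "group_sizes", "group_effects"))
  if (length(unknown)) {
    stop_gekkodiet(sprintf("Unknown config key(s): %s.",
                           paste(unknown, collapse = ", ")),
                   "gekkodiet_config_error")
  }
  do.call(synthetic_config, args)
}

#' Importance bar chart
#'
#' A ranked bar chart of the IRI per prey category with three-letter
#' category abbreviations on the x axis - the standard one-figure summary of
#' a diet composition table.
#'
#' @param table A `composition_table`.
#' @param min_F Passed to [rank_by_iri()].
#' @return A `ggplot` object.
#' @export
plot_iri <- function(table, min_F = 1) {
  stopifnot(inherits(table, "composition_table"))
  ranked <- rank_by_iri(table, min_F = min_F)
  rows <- as_tibble(table)
  df <- tibble(
    abbreviation = factor(abbreviate_categories(ranked),
                          levels = abbreviate_categories(ranked)),
    iri = rows$iri[match(ranked, rows$category)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abbreviation, y = .data$iri)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Prey category", y = "IRI (%)") +
    ggplot2::theme_minimal()
}
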