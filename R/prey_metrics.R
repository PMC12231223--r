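#' @title Prey volume, diet composition and the Index of Relative Importance
#' @description The quantitative core of a stomach-content study: per-item
#'   volume from the prolate-spheroid approximation, the per-category
#'   composition table (F, %F, N, %N, V, %V and IRI), category rankings, and
#'   descriptive prey-size summaries.
#' @name prey_metrics
NULL

#' Prolate-spheroid prey volume
#'
#' Estimates the volume of an elongated prey item from its maximum length
#' \eqn{L} and maximum width \eqn{W} as a prolate spheroid of revolution:
#' \deqn{V = \frac{4\pi}{3}\,\frac{L}{2}\left(\frac{W}{2}\right)^2}
#' the standard approximation in herpetological diet studies. `pi_mode`
#' selects full floating-point \eqn{\pi} (default) or the two-decimal
#' \eqn{\pi = 3.14} used by the classical field formula; percentages and IRI
#' are invariant to the choice because the constant cancels in ratios.
#'
#' @param length_mm Maximum item length(s), mm; must be > 0.
#' @param width_mm Maximum item width(s), mm; must be > 0.
#' @param pi_mode `"exact"` for full-precision pi, `"3.14"` for the
#'   two-decimal convention.
#' @return Volume(s) in cubic millimetres, strictly increasing in both
#'   dimensions.
#' @examples
#' prey_volume(10, 2)          # 20.944 mm^3
#' prey_volume(10, 2, "3.14")  # 20.933 mm^3
#' @export
prey_volume <- function(length_mm, width_mm, pi_mode = c("exact", "3.14")) {
  pi_mode <- match.arg(pi_mode)
  check_number(length_mm, "length_mm")
  check_number(width_mm, "width_mm")
  if (length(length_mm) != length(width_mm)) {
    stop_gekkodiet("`length_mm` and `width_mm` must have equal length.",
                   "gekkodiet_domain_error")
  }
  pi_val <- if (pi_mode == "exact") pi else 3.14
  (4 * pi_val / 3) * (length_mm / 2) * (width_mm / 2)^2
}

filter_dataset <- function(dataset, groups = NULL) {
  stopifnot(inherits(dataset, "diet_dataset"))
  specimens <- dataset$specimens
  if (!is.null(groups)) {
    bad <- setdiff(groups, diet_groups())
    if (length(bad)) {
      stop_gekkodiet(sprintf("Unknown group(s) in filter: %s.",
                             paste(bad, collapse = ", ")),
                     "gekkodiet_domain_error")
    }
    specimens <- specimens[specimens$group %in% groups, , drop = FALSE]
  }
  items <- dataset$prey_items
  items <- items[items$specimen_id %in% specimens$specimen_id, , drop = FALSE]
  list(specimens = specimens, prey_items = items)
}

item_volumes <- function(items, pi_mode = "exact") {
  v <- items$volume_mm3 %||% rep(NA_real_, nrow(items))
  need <- is.na(v)
  if (any(need)) {
    if (anyNA(items$length_mm[need]) || anyNA(items$width_mm[need])) {
      stop_gekkodiet(
        "Some prey items have no volume and no length/width to compute one.",
        "gekkodiet_validation_error")
    }
    v[need] <- prey_volume(items$length_mm[need], items$width_mm[need],
                           pi_mode = pi_mode)
  }
  v
}

new_composition_table <- function(rows, totals, n_stomachs, freq_denominator) {
  structure(rows,
            totals = totals, n_stomachs = n_stomachs,
            freq_denominator = freq_denominator,
            class = c("composition_table", class(rows)))
}

#' Diet composition table from per-category aggregates
#'
#' Computes the percentage columns and the Index of Relative Importance from
#' already-aggregated per-category counts: `F` (stomachs containing the
#' category), `N` (prey items) and `V` (summed item volume, mm^3). Percentages
#' are taken against column totals, except that `%F` may use the number of
#' stomachs as denominator (`freq_denominator = "n_stomachs"`, the commoner
#' convention in the diet literature) instead of the sum of occurrences
#' (`"sum_of_F"`, the default, which is the convention the bundled
#' C. nigriocularis table uses). The IRI of a category is the arithmetic mean
#' of its three unrounded percentages:
#' \deqn{IRI = (\%F + \%N + \%V)/3}
#' All stored values are unrounded; rounding to two decimals happens only at
#' presentation ([format()], [write_composition()]).
#'
#' @param counts A data frame with columns `category`, `F`, `N`, `V` and
#'   optionally `taxon_class`.
#' @param freq_denominator `"sum_of_F"` or `"n_stomachs"`.
#' @param n_stomachs Number of stomachs analysed; required when
#'   `freq_denominator = "n_stomachs"`.
#' @return A `composition_table`: a tibble with one row per category and
#'   columns `category` (+ `taxon_class` if supplied), `F`, `pct_F`, `N`,
#'   `pct_N`, `V`, `pct_V`, `iri`, carrying the column totals and the
#'   denominator convention as attributes. Rows are ordered by decreasing IRI.
#' @examples
#' composition_from_counts(nigriocularis_composition())
#' @export
composition_from_counts <- function(counts,
                                    freq_denominator = c("sum_of_F", "n_stomachs"),
                                    n_stomachs = NULL) {
  freq_denominator <- match.arg(freq_denominator)
  counts <- as_tibble(counts)
  required <- c("category", "F", "N", "V")
  missing <- setdiff(required, names(counts))
  if (length(missing)) {
    stop_gekkodiet(sprintf("`counts` is missing column(s): %s.",
                           paste(missing, collapse = ", ")),
                   "gekkodiet_schema_error")
  }
  if (nrow(counts) == 0) {
    stop_gekkodiet("Cannot build a composition table from zero categories.",
                   "gekkodiet_domain_error")
  }
  if (anyDuplicated(counts$category)) {
    stop_gekkodiet("Duplicate category rows in `counts`.",
                   "gekkodiet_validation_error")
  }
  if (any(counts$N >= 1 & counts$F < 1)) {
    stop_gekkodiet("A category with items must occur in at least one stomach.",
                   "gekkodiet_validation_error")
  }
  f_den <- switch(freq_denominator,
                  sum_of_F = sum(counts$F),
                  n_stomachs = {
                    if (is.null(n_stomachs)) {
                      stop_gekkodiet(
                        "`n_stomachs` is required when freq_denominator = \"n_stomachs\".",
                        "gekkodiet_domain_error")
                    }
                    n_stomachs
                  })
  rows <- tibble(
    category = counts$category,
    F = counts$F,
    pct_F = 100 * counts$F / f_den,
    N = counts$N,
    pct_N = 100 * counts$N / sum(counts$N),
    V = counts$V,
    pct_V = 100 * counts$V / sum(counts$V))
  rows$iri <- (rows$pct_F + rows$pct_N + rows$pct_V) / 3
  if ("taxon_class" %in% names(counts)) {
    rows <- dplyr::bind_cols(rows[, "category"],
                             tibble(taxon_class = counts$taxon_class),
                             rows[, setdiff(names(rows), "category")])
  }
  ord <- order(-rows$iri, -rows$N, rows$category)
  rows <- rows[ord, , drop = FALSE]
  new_composition_table(
    rows,
    totals = c(F = sum(counts$F), N = sum(counts$N), V = sum(counts$V)),
    n_stomachs = n_stomachs %||% NA_integer_,
    freq_denominator = freq_denominator)
}

#' Diet composition table from a dataset
#'
#' Aggregates a [diet dataset][assemble_dataset()] per prey category - `F`
#' counts distinct stomachs containing at least one item of the category, `N`
#' counts items, `V` sums item volumes (computed with [prey_volume()] where
#' absent) - and derives `%F`, `%N`, `%V` and the IRI via
#' [composition_from_counts()].
#'
#' @param dataset A `diet_dataset`.
#' @param groups Optional character vector of group labels to restrict to
#'   (e.g. `"female"`).
#' @inheritParams composition_from_counts
#' @inheritParams prey_volume
#' @return A `composition_table` (see [composition_from_counts()]).
#' @export
composition_table <- function(dataset, groups = NULL,
                              freq_denominator = c("sum_of_F", "n_stomachs"),
                              pi_mode = c("exact", "3.14")) {
  freq_denominator <- match.arg(freq_denominator)
  pi_mode <- match.arg(pi_mode)
  sel <- filter_dataset(dataset, groups)
  if (nrow(sel$prey_items) == 0) {
    stop_gekkodiet("No prey items left after group filtering.",
                   "gekkodiet_domain_error")
  }
  items <- sel$prey_items
  items$volume_mm3 <- item_volumes(items, pi_mode)
  agg <- dplyr::summarise(
    dplyr::group_by(items, .data$category),
    taxon_class = {
      tc <- unique(stats::na.omit(.data$taxon_class))
      if (length(tc)) tc[[1]] else NA_character_
    },
    F = dplyr::n_distinct(.data$specimen_id),
    N = dplyr::n(),
    V = sum(.data$volume_mm3),
    .groups = "drop")
  composition_from_counts(agg, freq_denominator = freq_denominator,
                          n_stomachs = nrow(sel$specimens))
}

#' @method format composition_table
#' @export
format.composition_table <- function(x, digits = 2, ...) {
  out <- as_tibble(x)
  for (col in c("pct_F", "pct_N", "pct_V", "iri", "V")) {
    out[[col]] <- round_half_up(out[[col]], digits)
  }
  out
}

#' @export
print.composition_table <- function(x, digits = 2, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("<composition_table> %d categories | sum F = %d, sum N = %d, sum V = %.2f mm^3 | %%F denominator: %s\n",
              nrow(x), tot[["F"]], tot[["N"]], tot[["V"]],
              attr(x, "freq_denominator")))
  print(format(x, digits = digits), n = nrow(x))
  invisible(x)
}

#' Rank prey categories by importance
#'
#' Orders categories by non-increasing IRI; ties are broken by descending
#' item count `N`, then alphabetically. `min_F` optionally drops categories
#' found in fewer than that many stomachs before ranking - single-stomach
#' categories are often incidental captures whose volumetric share inflates
#' their IRI, and headline rankings in diet papers typically restrict to
#' recurrent categories (`min_F = 2`).
#'
#' @param table A `composition_table`.
#' @param top_k Optional number of leading categories to return.
#' @param min_F Minimum number of stomachs a category must occur in
#'   (default 1 = strict IRI order over all categories).
#' @return Character vector of category labels.
#' @export
rank_by_iri <- function(table, top_k = NULL, min_F = 1) {
  stopifnot(inherits(table, "composition_table"))
  rows <- as_tibble(table)
  rows <- rows[rows$F >= min_F, , drop = FALSE]
  ord <- order(-rows$iri, -rows$N, rows$category)
  out <- rows$category[ord]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' Descriptive prey-size summary
#'
#' Summarises a prey dimension - per-item length, width or volume, or the
#' per-stomach item count - as n, mean, sample standard deviation (n - 1
#' denominator; 0 when n = 1), minimum and maximum. `count_per_stomach`
#' aggregates items per specimen first; specimens with empty stomachs are
#' excluded unless `include_empty = TRUE` (every stomach in the motivating
#' survey contained food, so exclusion is the default).
#'
#' @param dataset A `diet_dataset`.
#' @param dimension One of `"length"`, `"width"`, `"volume"`,
#'   `"count_per_stomach"`.
#' @param groups Optional group filter as in [composition_table()].
#' @param include_empty Include zero counts for item-less specimens
#'   (`count_per_stomach` only).
#' @inheritParams prey_volume
#' @return A one-row tibble: `dimension`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
size_summary <- function(dataset,
                         dimension = c("length", "width", "volume",
                                       "count_per_stomach"),
                         groups = NULL, include_empty = FALSE,
                         pi_mode = c("exact", "3.14")) {
  dimension <- match.arg(dimension)
  pi_mode <- match.arg(pi_mode)
  sel <- filter_dataset(dataset, groups)
  values <- switch(
    dimension,
    length = sel$prey_items$length_mm,
    width = sel$prey_items$width_mm,
    volume = if (nrow(sel$prey_items)) item_volumes(sel$prey_items, pi_mode) else numeric(),
    count_per_stomach = {
      counts <- table(sel$prey_items$specimen_id)
      n_items <- as.numeric(counts[sel$specimens$specimen_id])
      n_items[is.na(n_items)] <- 0
      if (!include_empty) n_items <- n_items[n_items > 0]
      n_items
    })
  if (length(values) == 0) {
    stop_gekkodiet("Empty selection: no values to summarise.",
                   "gekkodiet_domain_error")
  }
  tibble(dimension = dimension, n = length(values),
         mean = mean(values),
         sd = if (length(values) > 1) stats::sd(values) else 0,
         min = min(values), max = max(values))
}

#' Trophic spectrum per group
#'
#' Counts the number of distinct prey categories consumed by each sex/age
#' group (the breadth of the group's trophic spectrum), or by the whole
#' dataset when `by = "none"`.
#'
#' @param dataset A `diet_dataset`.
#' @param by `"group"` (default) or `"none"`.
#' @return A tibble with columns `group` and `n_categories`.
#' @export
trophic_spectrum <- function(dataset, by = c("group", "none")) {
  by <- match.arg(by)
  stopifnot(inherits(dataset, "diet_dataset"))
  if (by == "none") {
    return(tibble(group = "all",
                  n_categories = length(unique(dataset$prey_items$category))))
  }
  items <- dplyr::left_join(
    dataset$prey_items,
    dataset$specimens[, c("specimen_id", "group")], by = "specimen_id")
  present <- sort(unique(dataset$specimens$group))
  counts <- vapply(present, function(g) {
    length(unique(items$category[items$group == g]))
  }, integer(1), USE.NAMES = FALSE)
  tibble(group = present, n_categories = counts)
}

#' Write a composition table
#'
#' Writes a `composition_table` as delimited text in the column order of a
#' publication table - category (and taxon class), F, %F, N, %N, V, %V, IRI -
#' with percentages and IRI rounded half away from zero to `digits` decimals.
#'
#' @param table A `composition_table`.
#' @param path Output path.
#' @param delim `","` or `"\t"`.
#' @param digits Decimals for percentages, volumes and IRI.
#' @return `path`, invisibly.
#' @export
write_composition <- function(table, path, delim = ",", digits = 2) {
  stopifnot(inherits(table, "composition_table"))
  out <- format(table, digits = digits)
  readr::write_delim(out, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}
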