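#' @title Specimen and prey-item tables
#' @description Readers, writers and validation for the two delimited-text
#'   tables a stomach-flushing survey produces: one row per captured specimen
#'   (id, sex/age group, snout-vent length, mouth width, body mass) and one
#'   row per recovered prey item (owning specimen, prey category, maximum
#'   length and width). Validation is total: malformed input raises a typed
#'   condition, never a silent row drop.
#' @name diet_data
NULL

#' Allowed sex/age group labels
#'
#' Adults are sexed as `male` or `female`; immatures are `subadult` or
#' `juvenile` by snout-vent length. All four labels are legal in any table
#' even when a survey captures no individuals of some class.
#' @export
diet_groups <- function() c("male", "female", "subadult", "juvenile")

specimen_columns <- c("specimen_id", "group", "svl_mm", "mw_mm", "bm_g")
prey_columns <- c("specimen_id", "category", "taxon_class", "length_mm", "width_mm")

resolve_columns <- function(tbl, required, col_map, what) {
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), required)
    if (length(bad)) {
      stop_gekkodiet(sprintf("Unknown column mapping target(s): %s.",
                             paste(bad, collapse = ", ")),
                     "gekkodiet_schema_error")
    }
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(tbl)) {
        names(tbl)[names(tbl) == col_map[[std]]] <- std
      }
    }
  }
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop_gekkodiet(
      sprintf("%s is missing required column(s): %s.", what,
              paste(missing, collapse = ", ")),
      "gekkodiet_schema_error", columns = missing)
  }
  tbl
}

# Parse a character column to double, reporting the physical file line
# (header is line 1, so data row i sits on line i + 1) of the first failures.
parse_measure <- function(x, column, positive = TRUE) {
  x_trim <- trimws(x)
  val <- suppressWarnings(as.numeric(x_trim))
  bad <- which(is.na(val) & !is.na(x_trim) & nzchar(x_trim))
  if (length(bad)) {
    stop_gekkodiet(
      sprintf("Column `%s` has non-numeric value(s) on line(s) %s.",
              column, paste(bad + 1L, collapse = ", ")),
      "gekkodiet_parse_error", lines = bad + 1L)
  }
  bad <- which(is.na(val))
  if (length(bad)) {
    stop_gekkodiet(
      sprintf("Column `%s` has missing value(s) on line(s) %s.",
              column, paste(bad + 1L, collapse = ", ")),
      "gekkodiet_parse_error", lines = bad + 1L)
  }
  if (positive) {
    bad <- which(val <= 0)
    if (length(bad)) {
      stop_gekkodiet(
        sprintf("Column `%s` must be > 0; violated on line(s) %s.",
                column, paste(bad + 1L, collapse = ", ")),
        "gekkodiet_validation_error", lines = bad + 1L)
    }
  }
  val
}

read_raw_delim <- function(path, delim) {
  if (!file.exists(path)) {
    stop_gekkodiet(sprintf("File not found: %s.", path), "gekkodiet_io_error")
  }
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                    locale = readr::locale(decimal_mark = "."),
                    na = character(), trim_ws = TRUE, progress = FALSE,
                    show_col_types = FALSE)
}

#' Read a specimen table
#'
#' Reads a delimited text file with one row per captured individual and the
#' columns `specimen_id`, `group`, `svl_mm`, `mw_mm`, `bm_g` (snout-vent
#' length and mouth width in mm to 0.1 mm, body mass in g to 0.1 g). Rows are
#' validated: measurements must be positive, mouth width must be smaller than
#' snout-vent length, group labels must be one of [diet_groups()], and
#' specimen ids must be unique. Errors name the offending column and physical
#' file line.
#'
#' @param path Path to the delimited file (UTF-8, `.` decimal separator).
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @param col_map Optional named character vector mapping standard column
#'   names to the names used in the file, e.g. `c(svl_mm = "SVL")`.
#' @return A tibble of validated specimens, in file order.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("specimen_id,group,svl_mm,mw_mm,bm_g",
#'              "CT01,male,102.3,20.1,19.9"), path)
#' read_specimen_table(path)
#' @export
read_specimen_table <- function(path, delim = ",", col_map = NULL) {
  tbl <- read_raw_delim(path, delim)
  tbl <- resolve_columns(tbl, specimen_columns, col_map, "Specimen table")
  out <- tibble(
    specimen_id = as.character(tbl$specimen_id),
    group = as.character(tbl$group))
  if (nrow(tbl) == 0) {
    out$svl_mm <- numeric(); out$mw_mm <- numeric(); out$bm_g <- numeric()
    return(out)
  }
  out$svl_mm <- parse_measure(tbl$svl_mm, "svl_mm")
  out$mw_mm <- parse_measure(tbl$mw_mm, "mw_mm")
  out$bm_g <- parse_measure(tbl$bm_g, "bm_g")
  validate_specimens(out)
}

#' Validate a specimen tibble
#'
#' @param specimens A tibble with the specimen columns (see
#'   [read_specimen_table()]).
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_specimens <- function(specimens) {
  specimens <- as_tibble(specimens)
  missing <- setdiff(specimen_columns, names(specimens))
  if (length(missing)) {
    stop_gekkodiet(sprintf("Specimen table is missing required column(s): %s.",
                           paste(missing, collapse = ", ")),
                   "gekkodiet_schema_error", columns = missing)
  }
  bad_group <- setdiff(unique(specimens$group), diet_groups())
  if (length(bad_group)) {
    stop_gekkodiet(sprintf("Unknown group label(s): %s. Allowed: %s.",
                           paste(bad_group, collapse = ", "),
                           paste(diet_groups(), collapse = ", ")),
                   "gekkodiet_validation_error")
  }
  for (col in c("svl_mm", "mw_mm", "bm_g")) {
    check_number(specimens[[col]], col)
  }
  bad <- which(specimens$mw_mm >= specimens$svl_mm)
  if (length(bad)) {
    stop_gekkodiet(
      sprintf("Mouth width must be smaller than snout-vent length; violated for specimen(s): %s.",
              paste(specimens$specimen_id[bad], collapse = ", ")),
      "gekkodiet_validation_error")
  }
  dup <- unique(specimens$specimen_id[duplicated(specimens$specimen_id)])
  if (length(dup)) {
    stop_gekkodiet(sprintf("Duplicate specimen id(s): %s.",
                           paste(dup, collapse = ", ")),
                   "gekkodiet_validation_error")
  }
  specimens
}

#' Read a prey-item table
#'
#' Reads a delimited text file with one row per recovered prey item and the
#' columns `specimen_id`, `category`, `taxon_class`, `length_mm`, `width_mm`
#' (maximum item length and width in mm to 0.1 mm). `taxon_class` (a higher
#' taxonomic label such as "Insecta") may be empty. Category labels are taken
#' verbatim; diet studies routinely mix ranks (order Araneae beside family
#' Blattidae). Items whose width exceeds their length are kept with a warning
#' - curled or telescoped prey can legitimately measure that way, and
#' dropping measured items silently would bias composition. The derived
#' volume column is left uncomputed (see [prey_volume()]).
#'
#' @inheritParams read_specimen_table
#' @return A tibble of validated prey items, in file order, with a
#'   `volume_mm3` column of `NA` to be filled by the composition step.
#' @export
read_prey_table <- function(path, delim = ",", col_map = NULL) {
  tbl <- read_raw_delim(path, delim)
  if (!"taxon_class" %in% names(tbl) &&
      !("taxon_class" %in% names(col_map %||% character()))) {
    tbl$taxon_class <- rep(NA_character_, nrow(tbl))
  }
  tbl <- resolve_columns(tbl, prey_columns, col_map, "Prey table")
  out <- tibble(
    specimen_id = as.character(tbl$specimen_id),
    category = as.character(tbl$category),
    taxon_class = ifelse(nzchar(trimws(tbl$taxon_class)) &
                           !is.na(tbl$taxon_class),
                         as.character(tbl$taxon_class), NA_character_))
  if (nrow(tbl) == 0) {
    out$length_mm <- numeric(); out$width_mm <- numeric()
    out$volume_mm3 <- numeric()
    return(out)
  }
  out$length_mm <- parse_measure(tbl$length_mm, "length_mm")
  out$width_mm <- parse_measure(tbl$width_mm, "width_mm")
  out$volume_mm3 <- if ("volume_mm3" %in% names(tbl)) {
    parse_measure(tbl$volume_mm3, "volume_mm3")
  } else {
    rep(NA_real_, nrow(out))
  }
  validate_prey_items(out)
}

#' Validate a prey-item tibble
#'
#' @param prey_items A tibble with the prey columns (see [read_prey_table()]).
#' @return The validated tibble.
#' @export
validate_prey_items <- function(prey_items) {
  prey_items <- as_tibble(prey_items)
  missing <- setdiff(prey_columns, names(prey_items))
  if (length(missing)) {
    stop_gekkodiet(sprintf("Prey table is missing required column(s): %s.",
                           paste(missing, collapse = ", ")),
                   "gekkodiet_schema_error", columns = missing)
  }
  if (!"volume_mm3" %in% names(prey_items)) {
    prey_items$volume_mm3 <- rep(NA_real_, nrow(prey_items))
  }
  check_number(prey_items$length_mm, "length_mm")
  check_number(prey_items$width_mm, "width_mm")
  v <- prey_items$volume_mm3
  if (any(!is.na(v) & v <= 0)) {
    stop_gekkodiet("`volume_mm3`, when present, must be > 0.",
                   "gekkodiet_validation_error")
  }
  wide <- which(prey_items$width_mm > prey_items$length_mm)
  if (length(wide)) {
    warn(sprintf("%d prey item(s) have width > length (rows %s); kept as measured.",
                 length(wide), paste(utils::head(wide, 10), collapse = ", ")),
         class = "gekkodiet_width_gt_length")
  }
  prey_items
}

#' Assemble a diet dataset
#'
#' Binds a specimen table and a prey-item table into a single validated
#' `diet_dataset`, enforcing referential integrity: every prey item must
#' reference a specimen present in the specimen table.
#'
#' @param specimens Specimen tibble (see [read_specimen_table()]).
#' @param prey_items Prey-item tibble (see [read_prey_table()]).
#' @return An object of class `diet_dataset`: a list with elements
#'   `specimens` and `prey_items`.
#' @export
assemble_dataset <- function(specimens, prey_items) {
  specimens <- validate_specimens(specimens)
  prey_items <- validate_prey_items(prey_items)
  orphans <- setdiff(prey_items$specimen_id, specimens$specimen_id)
  if (length(orphans)) {
    stop_gekkodiet(
      sprintf("Prey item(s) reference unknown specimen id(s): %s.",
              paste(orphans, collapse = ", ")),
      "gekkodiet_validation_error", orphans = orphans)
  }
  structure(list(specimens = specimens, prey_items = prey_items),
            class = "diet_dataset")
}

#' @export
print.diet_dataset <- function(x, ...) {
  counts <- table(factor(x$specimens$group, levels = diet_groups()))
  cat(sprintf("<diet_dataset> %d specimens (%s), %d prey items, %d prey categories\n",
              nrow(x$specimens),
              paste(sprintf("%d %s", counts[counts > 0],
                            names(counts)[counts > 0]), collapse = ", "),
              nrow(x$prey_items), length(unique(x$prey_items$category))))
  invisible(x)
}

#' Write specimen / prey tables
#'
#' Plain delimited-text writers that round-trip with the corresponding
#' readers: lengths are written to 0.1 mm and masses to 0.1 g, the
#' measurement precision of a field caliper and balance.
#'
#' @param x Specimen or prey tibble, or a `diet_dataset`.
#' @param path Output file path.
#' @param delim Field delimiter (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(x, path, delim = ",") {
  if (inherits(x, "diet_dataset")) x <- x$specimens
  x <- as_tibble(x)[, specimen_columns]
  for (col in c("svl_mm", "mw_mm", "bm_g")) x[[col]] <- round(x[[col]], 1)
  readr::write_delim(x, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' @rdname write_specimen_table
#' @export
write_prey_table <- function(x, path, delim = ",") {
  if (inherits(x, "diet_dataset")) x <- x$prey_items
  keep <- c(prey_columns, intersect("volume_mm3", names(x)))
  x <- as_tibble(x)[, keep]
  for (col in c("length_mm", "width_mm")) x[[col]] <- round(x[[col]], 1)
  if (all(is.na(x$volume_mm3))) x$volume_mm3 <- NULL
  readr::write_delim(x, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}

#' Published diet composition of Cyrtodactylus nigriocularis
#'
#' Per-category aggregates from a stomach-flushing survey of 51 black-eyed
#' bent-toed geckos (Cyrtodactylus nigriocularis) at Ba Den Mountain,
#' Tay Ninh Province, Vietnam: the number of stomachs containing the category
#' (`F`), the number of prey items (`N`) and the summed estimated item volume
#' in cubic millimetres (`V`) for each of 22 prey categories (407 items in
#' total). Useful as a worked example for [composition_from_counts()].
#'
#' @return A tibble with columns `category`, `taxon_class`, `F`, `N`, `V`.
#' @examples
#' comp <- composition_from_counts(nigriocularis_composition())
#' rank_by_iri(comp, top_k = 6, min_F = 2)
#' @export
nigriocularis_composition <- function() {
  path <- system.file("extdata", "nigriocularis_composition.csv",
                      package = "gekkodiet", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccidd", progress = FALSE)
}
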