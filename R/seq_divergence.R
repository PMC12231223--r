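#' @title Uncorrected pairwise sequence divergence
#' @description Uncorrected p-distance (proportion of differing sites,
#'   without a substitution-model correction) on an aligned nucleotide
#'   matrix, the conventional quick check that barcoded individuals are
#'   conspecific: within-species COI divergences are typically well under
#'   the few-percent range.
#' @name seq_divergence
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ALLOWED_CHARS <- c(names(IUPAC_SETS), "-")

#' Read an aligned FASTA file
#'
#' Reads a nucleotide FASTA, uppercases, maps U to T, and validates that the
#' file holds a true alignment: at least two records, all of equal length,
#' with an alphabet restricted to the IUPAC nucleotide codes plus the gap
#' character `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `aligned_sequences` object: list with `ids`, `seqs`
#'   (uppercase character strings) and `alignment_length`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    stop_gekkodiet(sprintf("File not found: %s.", path), "gekkodiet_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2) {
    stop_gekkodiet("An alignment needs at least 2 sequences.",
                   "gekkodiet_alignment_error")
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  ids <- names(set) %||% paste0("seq", seq_along(seqs))
  aligned_sequences(ids, seqs)
}

#' Construct an aligned-sequences object
#'
#' @param ids Character vector of sequence labels.
#' @param seqs Character vector of equal-length uppercase sequences.
#' @return An `aligned_sequences` object.
#' @export
aligned_sequences <- function(ids, seqs) {
  seqs <- chartr("U", "T", toupper(seqs))
  lens <- unname(nchar(seqs))
  if (length(unique(lens)) != 1) {
    stop_gekkodiet(
      sprintf("Ragged alignment: sequence lengths %s.",
              paste(unique(lens), collapse = ", ")),
      "gekkodiet_alignment_error")
  }
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% ALLOWED_CHARS)
    if (length(bad)) {
      stop_gekkodiet(
        sprintf("Illegal character '%s' in sequence %s at position %d.",
                chars[bad[1]], ids[i], bad[1]),
        "gekkodiet_parse_error", position = bad[1])
    }
  }
  structure(list(ids = as.character(ids), seqs = unname(seqs),
                 alignment_length = lens[1]),
            class = "aligned_sequences")
}

#' @export
print.aligned_sequences <- function(x, ...) {
  cat(sprintf("<aligned_sequences> %d sequences x %d columns\n",
              length(x$ids), x$alignment_length))
  invisible(x)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among comparable columns. Columns containing
#' a gap in either sequence are always excluded. Under
#' `ambiguity_policy = "pairwise_delete"` (the default, matching the usual
#' convention for uncorrected distances) columns with any ambiguity code
#' (including N) in either sequence are also excluded; under
#' `"mismatch_if_incompatible"` ambiguous columns are kept and count as a
#' mismatch only when the two IUPAC sets share no base.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings (IUPAC + gap).
#' @param ambiguity_policy `"pairwise_delete"` or `"mismatch_if_incompatible"`.
#' @return A list with `distance` (proportion in `[0, 1]`) and
#'   `comparable_sites` (number of columns compared).
#' @examples
#' p_distance("ACGT", "ACGA")$distance  # 0.25
#' @export
p_distance <- function(seq_a, seq_b,
                       ambiguity_policy = c("pairwise_delete",
                                            "mismatch_if_incompatible")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  a <- strsplit(chartr("U", "T", toupper(seq_a)), "", fixed = TRUE)[[1]]
  b <- strsplit(chartr("U", "T", toupper(seq_b)), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) {
    stop_gekkodiet("Sequences must have equal length.",
                   "gekkodiet_alignment_error")
  }
  gap <- a == "-" | b == "-"
  plain <- c("A", "C", "G", "T")
  ambig <- !(a %in% plain) | !(b %in% plain)
  if (ambiguity_policy == "pairwise_delete") {
    keep <- !gap & !ambig
    mism <- a[keep] != b[keep]
  } else {
    keep <- !gap
    ka <- a[keep]; kb <- b[keep]
    mism <- vapply(seq_along(ka), function(i) {
      length(intersect(IUPAC_SETS[[ka[i]]], IUPAC_SETS[[kb[i]]])) == 0
    }, logical(1))
  }
  sites <- sum(keep)
  if (sites == 0) {
    stop_gekkodiet("No comparable sites between the two sequences.",
                   "gekkodiet_degenerate_error")
  }
  list(distance = sum(mism) / sites, comparable_sites = sites)
}

#' Pairwise p-distance matrix
#'
#' All pairwise uncorrected distances of an alignment.
#'
#' @param alignment An `aligned_sequences` object.
#' @inheritParams p_distance
#' @return A `p_distance_matrix`: list with `ids`, symmetric `distances`
#'   (proportions, zero diagonal) and `comparable_sites` matrices.
#' @export
distance_matrix <- function(alignment,
                            ambiguity_policy = c("pairwise_delete",
                                                 "mismatch_if_incompatible")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  stopifnot(inherits(alignment, "aligned_sequences"))
  k <- length(alignment$ids)
  d <- matrix(0, k, k, dimnames = list(alignment$ids, alignment$ids))
  sites <- matrix(alignment$alignment_length, k, k,
                  dimnames = dimnames(d))
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        pd <- p_distance(alignment$seqs[i], alignment$seqs[j],
                         ambiguity_policy)
        d[i, j] <- d[j, i] <- pd$distance
        sites[i, j] <- sites[j, i] <- pd$comparable_sites
      }
    }
  }
  structure(list(ids = alignment$ids, distances = d,
                 comparable_sites = sites),
            class = "p_distance_matrix")
}

#' @export
print.p_distance_matrix <- function(x, ...) {
  cat(sprintf("<p_distance_matrix> %d sequences; max divergence %.2f%%\n",
              length(x$ids), 100 * max(x$distances)))
  invisible(x)
}

#' Maximum pairwise divergence
#'
#' The largest off-diagonal p-distance of an alignment, as a percentage
#' rounded to two decimals, together with the achieving pair (the first in
#' row-major order on ties).
#'
#' @inheritParams distance_matrix
#' @return List with `percent` and `pair` (character vector of two ids).
#' @export
max_divergence <- function(alignment,
                           ambiguity_policy = c("pairwise_delete",
                                                "mismatch_if_incompatible")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  dm <- distance_matrix(alignment, ambiguity_policy)
  k <- length(dm$ids)
  best <- c(1L, 2L); best_d <- -1
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      if (dm$distances[i, j] > best_d) {
        best_d <- dm$distances[i, j]; best <- c(i, j)
      }
    }
  }
  list(percent = round_half_up(100 * best_d, 2),
       pair = dm$ids[best])
}

#' Write a distance matrix
#'
#' Writes a `p_distance_matrix` either as a PHYLIP-style square matrix or as
#' tidy delimited text with one row per pair (`id_a`, `id_b`, `p_distance`,
#' `comparable_sites`).
#'
#' @param x A `p_distance_matrix`.
#' @param path Output path.
#' @param format `"phylip"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(x, path, format = c("phylip", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "p_distance_matrix"))
  if (format == "phylip") {
    k <- length(x$ids)
    lines <- c(sprintf("%5d", k),
               vapply(seq_len(k), function(i) {
                 paste0(formatC(x$ids[i], width = -10),
                        paste(sprintf("%.6f", x$distances[i, ]), collapse = "  "))
               }, character(1)))
    writeLines(lines, path)
  } else {
    k <- length(x$ids)
    pairs <- which(upper.tri(x$distances), arr.ind = TRUE)
    out <- tibble(id_a = x$ids[pairs[, 1]], id_b = x$ids[pairs[, 2]],
                  p_distance = x$distances[pairs],
                  comparable_sites = x$comparable_sites[pairs])
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}
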