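# Small programmatic fixtures shared across test files.

make_specimens <- function(n, group = "female") {
  tibble::tibble(
    specimen_id = sprintf("S%02d", seq_len(n)),
    group = rep_len(group, n),
    svl_mm = 100 + seq_len(n),
    mw_mm = 20 + 0.1 * seq_len(n),
    bm_g = 20 + 0.2 * seq_len(n))
}

make_items <- function(specimen_id, category, length_mm, width_mm,
                       taxon_class = NA_character_) {
  tibble::tibble(
    specimen_id = specimen_id, category = category,
    taxon_class = rep_len(taxon_class, length(specimen_id)),
    length_mm = length_mm, width_mm = width_mm,
    volume_mm3 = NA_real_)
}

# Random tiny dataset: <= 5 stomachs, <= 4 categories, widths <= lengths.
random_small_dataset <- function(seed) {
  withr::with_seed(seed, {
    n_spec <- sample(2:5, 1)
    specimens <- make_specimens(n_spec)
    n_items <- sample(3:20, 1)
    len <- round(stats::runif(n_items, 1, 30), 1)
    wid <- round(len * stats::runif(n_items, 0.1, 1), 1)
    wid <- pmax(pmin(wid, len), 0.1)
    items <- make_items(
      specimen_id = sample(specimens$specimen_id, n_items, replace = TRUE),
      category = sample(c("Araneae", "Blattidae", "Formicidae", "Opiliones"),
                        n_items, replace = TRUE),
      length_mm = len, width_mm = wid)
    assemble_dataset(specimens, items)
  })
}

random_nucleotides <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  draw <- function() paste(sample(alphabet, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

write_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# Mutate k distinct positions of a nucleotide string to a different base.
mutate_sites <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}
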