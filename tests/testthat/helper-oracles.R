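# Independent brute-force oracles used to validate the package's statistics.
# These deliberately use naive loops / full enumeration, not the code paths
# they check.

# All permutations of 1..n (n small), as a list of integer vectors.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Exact null distribution of the Mann-Whitney U for samples (m, n):
# counts[u + 1] = number of the choose(m + n, m) rank assignments with U = u,
# by full enumeration of rank subsets.
enum_u_counts <- function(m, n) {
  ranks <- seq_len(m + n)
  counts <- numeric(m * n + 1)
  sets <- utils::combn(m + n, m)
  for (j in seq_len(ncol(sets))) {
    w <- sum(sets[, j])
    u <- w - m * (m + 1) / 2
    counts[u + 1] <- counts[u + 1] + 1
  }
  counts
}

# Same distribution by the standard counting recurrence
# N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1), memoised. Used where the
# full enumeration is infeasible; itself validated against enum_u_counts on
# small sizes in the test suite.
recurrence_u_counts <- function(m, n) {
  memo <- new.env(parent = emptyenv())
  count1 <- function(u, m, n) {
    if (u < 0 || u > m * n) return(0)
    if (m == 0 || n == 0) return(as.numeric(u == 0))
    key <- paste(u, m, n)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- count1(u - n, m - 1, n) + count1(u, m, n - 1)
    memo[[key]] <- val
    val
  }
  vapply(0:(m * n), count1, numeric(1), m = m, n = n)
}

two_sided_p_from_counts <- function(counts, stat_value) {
  vals <- seq_along(counts) - 1
  total <- sum(counts)
  min(1, 2 * min(sum(counts[vals <= stat_value]),
                 sum(counts[vals >= stat_value])) / total)
}

# Brute-force U statistic: count of (a_i > b_j) pairs, halves for ties.
oracle_u_stat <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Exact two-sided Wilcoxon p for tie-free samples via an enumeration oracle.
oracle_wilcoxon_p <- function(a, b, counts = NULL) {
  m <- length(a); n <- length(b)
  u <- oracle_u_stat(a, b)
  if (is.null(counts)) {
    counts <- if (choose(m + n, m) <= 20000) enum_u_counts(m, n)
              else recurrence_u_counts(m, n)
  }
  two_sided_p_from_counts(counts, u)
}

# Brute-force Kendall tau-b over all pairs, with tie normalisation.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  s <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      s <- s + dx * dy
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
    }
  }
  n0 <- n * (n - 1) / 2
  s / sqrt((n0 - tx) * (n0 - ty))
}

# Exact two-sided Kendall p for tie-free data by enumerating all n!
# permutations of y.
oracle_kendall_p <- function(x, y) {
  n <- length(x)
  s_of <- function(yy) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(yy[j] - yy[i])
    }
    s
  }
  obs <- s_of(y)
  y_sorted <- sort(y)
  svals <- vapply(all_permutations(n), function(p) s_of(y_sorted[p]), numeric(1))
  min(1, 2 * min(mean(svals <= obs), mean(svals >= obs)))
}

# Naive per-column p-distance (pairwise deletion of gaps and ambiguities).
oracle_p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  plain <- c("A", "C", "G", "T")
  sites <- 0; mism <- 0
  for (k in seq_along(a)) {
    if (a[k] %in% plain && b[k] %in% plain) {
      sites <- sites + 1
      if (a[k] != b[k]) mism <- mism + 1
    }
  }
  list(distance = mism / sites, comparable_sites = sites)
}

# Brute-force composition tally: loops over categories and stomachs.
oracle_composition <- function(specimens, items, freq_denominator = "sum_of_F") {
  items$volume_mm3 <- (4 * pi / 3) * (items$length_mm / 2) * (items$width_mm / 2)^2
  cats <- unique(items$category)
  f <- n <- v <- numeric(length(cats))
  for (k in seq_along(cats)) {
    sub <- items[items$category == cats[k], ]
    f[k] <- length(unique(sub$specimen_id))
    n[k] <- nrow(sub)
    v[k] <- sum(sub$volume_mm3)
  }
  f_den <- if (freq_denominator == "sum_of_F") sum(f) else nrow(specimens)
  data.frame(category = cats, F = f, N = n, V = v,
             pct_F = 100 * f / f_den, pct_N = 100 * n / sum(n),
             pct_V = 100 * v / sum(v),
             iri = (100 * f / f_den + 100 * n / sum(n) + 100 * v / sum(v)) / 3)
}
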