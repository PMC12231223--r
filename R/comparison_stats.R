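#' @title Rank-based and parametric comparisons
#' @description The inferential toolkit of a dietary study: Pearson
#'   correlation and ordinary least squares for morphometric relationships,
#'   Kendall's tau-b for body size vs prey volume, and the two-sample
#'   Wilcoxon rank-sum (Mann-Whitney) test for intersexual diet contrasts.
#'   Each function returns a one-row tidy tibble with the statistic, a
#'   two-sided p-value and a `method_detail` string recording whether an
#'   exact or approximate null distribution was used.
#' @name comparison_stats
NULL

check_paired_numeric <- function(x, y, min_n = 2) {
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    stop_gekkodiet("Inputs must be numeric with no missing values.",
                   "gekkodiet_domain_error")
  }
  if (length(x) != length(y)) {
    stop_gekkodiet("`x` and `y` must have equal length.",
                   "gekkodiet_domain_error")
  }
  if (length(x) < min_n) {
    stop_gekkodiet(sprintf("Need at least %d paired observations.", min_n),
                   "gekkodiet_domain_error")
  }
  invisible(NULL)
}

check_nondegenerate <- function(v, name) {
  if (length(unique(v)) < 2) {
    stop_gekkodiet(sprintf("`%s` is constant; the statistic is undefined.", name),
                   "gekkodiet_degenerate_error")
  }
  invisible(NULL)
}

#' Pearson product-moment correlation
#'
#' Correlation between two numeric vectors with the usual two-sided p-value
#' from the t transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return One-row tibble: `statistic_name` (`"r"`), `statistic`, `p_value`,
#'   `n`, `method_detail`.
#' @export
pearson_correlation <- function(x, y) {
  check_paired_numeric(x, y, min_n = 3)
  check_nondegenerate(x, "x"); check_nondegenerate(y, "y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(statistic_name = "r",
         statistic = unname(ct$estimate),
         p_value = ct$p.value,
         n = length(x),
         method_detail = sprintf("two-sided t transform, df = %d", length(x) - 2L))
}

#' Simple linear regression
#'
#' Ordinary least-squares fit of `y` on `x` (via [stats::lm()]), reporting
#' the slope with its two-sided p-value, the intercept and R-squared.
#'
#' @param x Predictor vector (not constant, n >= 3).
#' @param y Response vector.
#' @return One-row tibble: `statistic_name` (`"slope"`), `statistic` (the
#'   slope), `intercept`, `r_squared`, `p_value` (slope /= 0), `n`,
#'   `method_detail`.
#' @export
linear_regression <- function(x, y) {
  check_paired_numeric(x, y, min_n = 3)
  check_nondegenerate(x, "x")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly collinear response; a perfect fit is a
  # legitimate input here (slope p-value is then reported as 0)
  sm <- suppressWarnings(summary(fit))
  slope_row <- stats::coef(sm)["x", ]
  tibble(statistic_name = "slope",
         statistic = unname(slope_row["Estimate"]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = unname(slope_row["Pr(>|t|)"]),
         n = length(x),
         method_detail = "ordinary least squares, two-sided t test on the slope")
}

tie_counts <- function(v) {
  t <- table(v)
  as.numeric(t[t > 1])
}

# Number of permutations of 1..n with each possible inversion count
# (Mahonian numbers), built by polynomial convolution. Gives the exact null
# distribution of Kendall's S for tie-free data: S = choose(n,2) - 2 * inversions.
mahonian_counts <- function(n) {
  counts <- 1
  for (k in 1:(n - 1)) {
    width <- length(counts) + k
    new <- numeric(width)
    for (j in 0:k) new[(j + 1):(j + length(counts))] <-
        new[(j + 1):(j + length(counts))] + counts
    counts <- new
  }
  counts  # index i corresponds to i - 1 inversions
}

kendall_pairs <- function(x, y) {
  n <- length(x)
  concordant <- 0; discordant <- 0
  for (i in 1:(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    s <- sign(dx) * sign(dy)
    concordant <- concordant + sum(s > 0)
    discordant <- discordant + sum(s < 0)
  }
  c(concordant = concordant, discordant = discordant)
}

#' Kendall's tau-b rank correlation
#'
#' Tau-b with tie correction in both margins:
#' \deqn{\tau_b = (C - D)/\sqrt{(n_0 - n_1)(n_0 - n_2)}}
#' where \eqn{C} and \eqn{D} count concordant and discordant pairs,
#' \eqn{n_0 = n(n-1)/2} and \eqn{n_1, n_2} are the tied-pair counts of each
#' margin. The two-sided p-value is exact (full enumeration of the
#' permutation null via the inversion-count distribution) for tie-free data
#' with n <= 10, otherwise a normal approximation with the standard
#' tie-corrected variance of S and a continuity correction of one unit on S.
#'
#' @param x,y Equal-length numeric vectors, n >= 2, neither entirely tied.
#' @return One-row tibble: `statistic_name` (`"tau_b"`), `statistic`,
#'   `p_value`, `n`, `method_detail`.
#' @export
kendall_tau_b <- function(x, y) {
  check_paired_numeric(x, y, min_n = 2)
  check_nondegenerate(x, "x"); check_nondegenerate(y, "y")
  n <- length(x)
  cd <- kendall_pairs(x, y)
  s <- cd[["concordant"]] - cd[["discordant"]]
  n0 <- n * (n - 1) / 2
  tx <- tie_counts(x); ty <- tie_counts(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- s / sqrt((n0 - n1) * (n0 - n2))
  tie_free <- length(tx) == 0 && length(ty) == 0
  if (tie_free && n <= 10) {
    counts <- mahonian_counts(n)
    svals <- n0 - 2 * (seq_along(counts) - 1)   # S for each inversion count
    total <- sum(counts)
    p <- min(1, 2 * min(sum(counts[svals <= s]), sum(counts[svals >= s])) / total)
    detail <- "exact enumeration of the permutation null (tie-free)"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- if (n > 2) {
      sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
        (9 * n * (n - 1) * (n - 2))
    } else 0
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    s_cc <- if (s > 0) s - 1 else if (s < 0) s + 1 else 0
    z <- s_cc / sqrt(var_s)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    detail <- "normal approximation, tie-corrected variance, continuity correction"
  }
  tibble(statistic_name = "tau_b", statistic = unname(tau), p_value = p,
         n = n, method_detail = detail)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-independent-sample location test on ranks. Reports both conventions:
#' the rank-sum \eqn{W} (sum of the midranks of the first sample in the
#' pooled ranking) and the Mann-Whitney \eqn{U = W - n_a(n_a+1)/2}. The
#' two-sided p-value is exact (the full distribution of U over all
#' \eqn{\binom{n_a+n_b}{n_a}} rank assignments) when the data are tie-free
#' and \eqn{n_a n_b \le 400}; otherwise a normal approximation with
#' tie-corrected variance and a 0.5 continuity correction is used.
#'
#' @param a,b Non-empty numeric vectors (independent samples).
#' @return One-row tibble: `statistic_name` (`"W"`), `statistic` (the rank
#'   sum of `a`), `u_statistic`, `p_value`, `n_a`, `n_b`, `method_detail`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b)) {
    stop_gekkodiet("Inputs must be numeric with no missing values.",
                   "gekkodiet_domain_error")
  }
  if (length(a) == 0 || length(b) == 0) {
    stop_gekkodiet("Both samples must be non-empty.", "gekkodiet_domain_error")
  }
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  u <- w - na * (na + 1) / 2
  ties <- tie_counts(pooled)
  tie_free <- length(ties) == 0
  if (tie_free && na * nb <= 400) {
    p <- min(1, 2 * min(stats::pwilcox(u, na, nb),
                        1 - stats::pwilcox(u - 1, na, nb)))
    detail <- "exact distribution of U over all rank assignments (tie-free)"
  } else {
    mu <- na * nb / 2
    var_u <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    cc <- if (u > mu) 0.5 else if (u < mu) -0.5 else 0
    z <- (u - mu - cc) / sqrt(var_u)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    detail <- "normal approximation, tie-corrected variance, continuity correction"
  }
  tibble(statistic_name = "W", statistic = w, u_statistic = u,
         p_value = p, n_a = na, n_b = nb, method_detail = detail)
}

metric_values <- function(sel, metric, pi_mode = "exact") {
  items <- sel$prey_items
  switch(
    metric,
    item_length = items$length_mm,
    item_width = items$width_mm,
    item_volume = if (nrow(items)) item_volumes(items, pi_mode) else numeric(),
    count_per_stomach = {
      counts <- table(items$specimen_id)
      v <- as.numeric(counts[sel$specimens$specimen_id])
      v[!is.na(v)]
    },
    total_volume_per_stomach = {
      if (!nrow(items)) return(numeric())
      vols <- item_volumes(items, pi_mode)
      as.numeric(tapply(vols, items$specimen_id, sum))
    })
}

#' Compare diet metrics between groups
#'
#' Runs a Wilcoxon rank-sum test per requested metric between two sex or age
#' groups. `grouping = "sex"` contrasts males against females;
#' `grouping = "age"` contrasts adults (males plus females) against
#' subadults. Per-item metrics pool items within each group; per-stomach
#' metrics aggregate to one value per specimen first. No multiple-testing
#' adjustment is applied by default (`p_adjust = "holm"` is available).
#'
#' @param dataset A `diet_dataset`.
#' @param grouping `"sex"` or `"age"`.
#' @param metrics Character vector from `item_length`, `item_width`,
#'   `item_volume`, `count_per_stomach`, `total_volume_per_stomach`.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @inheritParams prey_volume
#' @return A tidy tibble with one row per metric: `metric`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `statistic_name`, `statistic`, `u_statistic`,
#'   `p_value`, `method_detail`.
#' @export
compare_groups <- function(dataset, grouping = c("sex", "age"),
                           metrics = c("item_length", "item_width",
                                       "item_volume", "count_per_stomach",
                                       "total_volume_per_stomach"),
                           p_adjust = c("none", "holm"),
                           pi_mode = c("exact", "3.14")) {
  grouping <- match.arg(grouping)
  p_adjust <- match.arg(p_adjust)
  pi_mode <- match.arg(pi_mode)
  allowed <- c("item_length", "item_width", "item_volume",
               "count_per_stomach", "total_volume_per_stomach")
  bad <- setdiff(metrics, allowed)
  if (length(bad)) {
    stop_gekkodiet(sprintf("Unknown metric(s): %s.", paste(bad, collapse = ", ")),
                   "gekkodiet_domain_error")
  }
  sides <- switch(grouping,
                  sex = list(male = "male", female = "female"),
                  age = list(adult = c("male", "female"), subadult = "subadult"))
  labels <- names(sides)
  sels <- lapply(sides, function(g) filter_dataset(dataset, g))
  for (i in seq_along(sels)) {
    if (nrow(sels[[i]]$specimens) == 0) {
      stop_gekkodiet(sprintf("Group `%s` has no specimens.", labels[[i]]),
                     "gekkodiet_validation_error")
    }
  }
  rows <- lapply(metrics, function(m) {
    va <- metric_values(sels[[1]], m, pi_mode)
    vb <- metric_values(sels[[2]], m, pi_mode)
    for (i in which(c(length(va), length(vb)) == 0)) {
      stop_gekkodiet(sprintf("Group `%s` has no data for metric `%s`.",
                             labels[[i]], m),
                     "gekkodiet_validation_error")
    }
    res <- wilcoxon_rank_sum(va, vb)
    dplyr::bind_cols(tibble(metric = m, group_a = labels[[1]],
                            group_b = labels[[2]]), res)
  })
  out <- dplyr::bind_rows(rows)
  if (p_adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}
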