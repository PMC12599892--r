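# Cache of exact Mann-Whitney null distributions, keyed by "n m".
.mwu_cache <- new.env(parent = emptyenv())

# Null counts of the Mann-Whitney statistic U1 (number of (a, b) pairs with
# a > b) over all C(n+m, n) equally likely labelings, for tie-free data.
# Computed as a subset-sum table: the number of n-subsets of ranks 1..N
# with each possible rank sum; U1 = ranksum - n(n+1)/2.
mwu_null_counts <- function(n, m) {
  key <- paste(n, m)
  hit <- get0(key, envir = .mwu_cache)
  if (!is.null(hit)) return(hit)
  N <- n + m
  smax <- sum((m + 1):N)
  ways <- matrix(0, nrow = smax + 1L, ncol = n + 1L)
  ways[1L, 1L] <- 1
  for (j in seq_len(N)) {
    for (k in seq.int(min(n, j), 1L)) {
      ways[(j + 1L):(smax + 1L), k + 1L] <-
        ways[(j + 1L):(smax + 1L), k + 1L] + ways[1L:(smax + 1L - j), k]
    }
  }
  ranksum_counts <- ways[, n + 1L]
  # U1 ranges 0..n*m; ranksum ranges n(n+1)/2 .. smax
  counts <- ranksum_counts[(n * (n + 1L) / 2 + 1L):(smax + 1L)]
  assign(key, counts, envir = .mwu_cache)
  counts
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. With tie-free data and
#' `n + m <= 14` (in `"auto"` mode) the p-value is exact: the null
#' distribution of U over all `choose(n + m, n)` labelings, with the
#' two-sided p defined as `2 * min(P(U1 <= u), P(U1 >= u))` capped at 1.
#' Otherwise a tie-corrected normal approximation with continuity
#' correction is used; ties always force the approximation (mid-ranks,
#' tie-corrected variance). The reported statistic is `U = min(U1, U2)`.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param mode `"auto"` (exact when tie-free and `n + m <= 14`),
#'   `"exact"`, or `"normal"`.
#' @param alpha Significance level for the `significant` flag.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (default `TRUE`).
#' @param contrast Label recorded in the output.
#' @return One-row tibble: `contrast`, `statistic_name` (`"U"`),
#'   `statistic`, `p_value`, `method` (`"exact"` or `"normal_approx"`),
#'   `significant` (`p < alpha`), `alpha`, `n_a`, `n_b`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal"),
                           alpha = 0.05, continuity = TRUE,
                           contrast = "a vs b") {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) {
    abort("both groups must be non-empty.")
  }
  if (anyNA(a) || anyNA(b)) abort("values must be non-missing.")
  n <- length(a); m <- length(b); N <- n + m
  pooled <- c(a, b)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u <- min(u1, n * m - u1)
  has_ties <- anyDuplicated(pooled) > 0L
  want_exact <- switch(mode, exact = TRUE, normal = FALSE,
                       auto = !has_ties && N <= 14L)
  if (want_exact && has_ties) {
    warn("ties present: exact enumeration disabled, using the tie-corrected normal approximation.")
    want_exact <- FALSE
  }
  if (want_exact) {
    counts <- mwu_null_counts(n, m)
    total <- sum(counts)
    k <- as.integer(round(u1)) + 1L
    p_le <- sum(counts[seq_len(k)]) / total
    p_ge <- sum(counts[k:length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * m / 2
    ties <- table(pooled)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      dev <- u1 - mu
      cc <- if (continuity) 0.5 * sign(dev) else 0
      z <- (dev - cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble(
    contrast = contrast, statistic_name = "U", statistic = u,
    p_value = p, method = method, significant = p < alpha, alpha = alpha,
    n_a = n, n_b = m
  )
}

#' Kruskal-Wallis test
#'
#' Rank-based one-way comparison of two or more groups, with mid-ranks and
#' the tie-corrected H statistic. The p-value comes from the chi-square
#' approximation with `k - 1` degrees of freedom; an exact permutation
#' p-value (full enumeration of group assignments) is available for total
#' `n <= 10`. When all pooled values are equal, H is 0 and p is 1.
#'
#' @param samples List of numeric vectors, one per group; at least two
#'   groups of at least two observations each.
#' @param mode `"chi2"` (default) or `"exact"` (total n <= 10 only).
#' @param alpha Significance level for the flag.
#' @param contrast Label recorded in the output.
#' @return One-row tibble in the same schema as [mann_whitney_u()], with
#'   `statistic_name = "H"` and method `"chi2_approx"` or `"exact"`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(samples, mode = c("chi2", "exact"),
                           alpha = 0.05, contrast = "groups") {
  mode <- match.arg(mode)
  if (!is.list(samples) || length(samples) < 2L) {
    abort("`samples` must be a list of at least 2 groups.")
  }
  sizes <- lengths(samples)
  if (any(sizes == 0L)) abort("empty group in `samples`.")
  if (any(sizes < 2L)) abort("each group needs at least 2 observations.")
  pooled <- as.numeric(unlist(samples, use.names = FALSE))
  if (anyNA(pooled)) abort("values must be non-missing.")
  grp <- rep(seq_along(samples), sizes)
  H <- kw_statistic(pooled, grp)
  k <- length(samples)
  if (mode == "exact") {
    if (length(pooled) > 10L) {
      abort("exact permutation enumeration is limited to total n <= 10.")
    }
    p <- kw_exact_p(pooled, sizes, H)
    method <- "exact"
  } else {
    p <- pchisq(H, df = k - 1L, lower.tail = FALSE)
    method <- "chi2_approx"
  }
  tibble(
    contrast = contrast, statistic_name = "H", statistic = H,
    p_value = p, method = method, significant = p < alpha, alpha = alpha,
    n_a = length(pooled), n_b = NA_integer_
  )
}

# Tie-corrected H; 0 when the tie correction degenerates (all values equal).
kw_statistic <- function(pooled, grp) {
  N <- length(pooled)
  r <- rank(pooled)
  rbar <- tapply(r, grp, mean)
  ni <- tabulate(grp)
  h0 <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(0)
  h0 / corr
}

# Exhaustive permutation p-value: enumerate all distinct assignments of the
# pooled observations to groups of the given sizes.
kw_exact_p <- function(pooled, sizes, h_obs) {
  N <- length(pooled)
  count_ge <- 0L
  total <- 0L
  recurse <- function(avail, gi, grp_assign) {
    if (gi > length(sizes)) {
      h <- kw_statistic(pooled, grp_assign)
      total <<- total + 1L
      if (h >= h_obs - 1e-9) count_ge <<- count_ge + 1L
      return(invisible())
    }
    picks <- combn(avail, sizes[gi], simplify = FALSE)
    for (pk in picks) {
      ga <- grp_assign
      ga[pk] <- gi
      recurse(setdiff(avail, pk), gi + 1L, ga)
    }
  }
  recurse(seq_len(N), 1L, integer(N))
  count_ge / total
}

#' Treated-to-control normalization of a study table
#'
#' For every (group, day) cell, the ratio of the treated-group mean to the
#' control-group mean of the metric -- the normalization that puts culture
#' models with different baseline stiffness on a common drug-effect scale.
#' The ratio SD comes from first-order error propagation of the cell SDs:
#' `ratio * sqrt((sd_t / mean_t)^2 + (sd_c / mean_c)^2)`. Day-0 ratios are
#' reported as computed, not rebased to 1. Cells with a missing condition
#' or a non-positive control mean are flagged invalid rather than dropped.
#'
#' @param table Long-format study tibble with columns `group`,
#'   `condition`, `day`, `replicate`, `metric`, `value` (see
#'   [simulate_study_table()]).
#' @param metric Metric to normalize; defaults to the only metric present.
#' @return Tibble per (group, day): cell means/SDs/sizes per condition,
#'   `ratio`, `ratio_sd`, `valid`, `metric`.
#' @export
normalize_treated_to_control <- function(table, metric = NULL) {
  table <- validate_study_table(table)
  metric <- metric %||% unique(table$metric)
  if (length(metric) != 1L) {
    abort("`table` holds several metrics; pick one with `metric = `.")
  }
  tbl <- dplyr::filter(table, .data$metric == !!metric)
  if (nrow(tbl) == 0L) abort(sprintf("no rows for metric '%s'.", metric))
  cells <- tbl |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(),
                     .by = c("group", "day", "condition")) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("mean", "sd", "n"))
  for (col in c("mean_control", "sd_control", "n_control",
                "mean_treated", "sd_treated", "n_treated")) {
    if (!col %in% names(cells)) cells[[col]] <- NA_real_
  }
  cells |>
    dplyr::mutate(
      valid = is.finite(.data$mean_control) & is.finite(.data$mean_treated) &
        .data$mean_control > 0,
      ratio = dplyr::if_else(.data$valid,
                             .data$mean_treated / .data$mean_control,
                             NA_real_),
      ratio_sd = dplyr::if_else(
        .data$valid,
        .data$ratio * sqrt((.data$sd_treated / .data$mean_treated)^2 +
                             (.data$sd_control / .data$mean_control)^2),
        NA_real_),
      metric = !!metric
    ) |>
    dplyr::arrange(.data$group, .data$day)
}

# Schema and invariant checks shared by the study-layer entry points.
validate_study_table <- function(table) {
  tbl <- as_tibble(table)
  need <- c("group", "condition", "day", "replicate", "metric", "value")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0("study table is missing column(s): ",
                 paste(miss, collapse = ", "), "."))
  }
  if (!is.numeric(tbl$value) || !all(is.finite(tbl$value))) {
    abort("`value` must be finite numeric.")
  }
  key <- tbl[, c("group", "condition", "day", "replicate", "metric")]
  if (anyDuplicated(key)) {
    abort("duplicate (group, condition, day, replicate, metric) keys.")
  }
  tbl
}

#' Summarize a longitudinal treated-vs-control study
#'
#' The full statistical report for one metric of a spheroid study:
#' Kruskal-Wallis across days within each (group, condition) series,
#' Mann-Whitney U between control and treated at each (group, day), and
#' the treated/control normalized summary. Raw p-values are reported by
#' default, matching common practice for these small designs; Holm
#' adjustment within each test family is available.
#'
#' @param table Long-format study tibble (see
#'   [simulate_study_table()]).
#' @param metric Metric to analyze; defaults to the only one present.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"holm"`, applied within the KW
#'   family and within the U family separately.
#' @return An object of class `study_report`: tibbles `kw` (per group x
#'   condition), `mwu` (per group x day), `normalized`, plus `alpha` and
#'   `metric`. Design cells with fewer than 2 replicates are excluded with
#'   a warning.
#' @export
summarize_study <- function(table, metric = NULL, alpha = 0.05,
                            p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  table <- validate_study_table(table)
  metric <- metric %||% unique(table$metric)
  if (length(metric) != 1L) {
    abort("`table` holds several metrics; pick one with `metric = `.")
  }
  tbl <- dplyr::filter(table, .data$metric == !!metric)
  small <- tbl |>
    dplyr::summarise(n = dplyr::n(), .by = c("group", "condition", "day")) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(small) > 0L) {
    warn(sprintf("excluding %d design cell(s) with < 2 replicates.",
                 nrow(small)))
    tbl <- dplyr::anti_join(tbl, small, by = c("group", "condition", "day"))
  }
  kw <- tbl |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      groups_by_day <- split(d$value, d$day)
      if (length(groups_by_day) < 2L) return(tibble())
      kruskal_wallis(groups_by_day, alpha = alpha,
                     contrast = sprintf("%s/%s across days %s", key$group,
                                        key$condition,
                                        paste(names(groups_by_day),
                                              collapse = ",")))
    }) |>
    dplyr::ungroup()
  mwu <- tbl |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::group_modify(function(d, key) {
      ctrl <- d$value[d$condition == "control"]
      trt <- d$value[d$condition == "treated"]
      if (length(ctrl) < 2L || length(trt) < 2L) return(tibble())
      mann_whitney_u(ctrl, trt, alpha = alpha,
                     contrast = sprintf("%s day %s: control vs treated",
                                        key$group, key$day))
    }) |>
    dplyr::ungroup()
  if (p_adjust == "holm") {
    kw$p_value <- stats::p.adjust(kw$p_value, method = "holm")
    mwu$p_value <- stats::p.adjust(mwu$p_value, method = "holm")
    kw$significant <- kw$p_value < alpha
    mwu$significant <- mwu$p_value < alpha
  }
  structure(
    list(kw = dplyr::arrange(kw, .data$group, .data$condition),
         mwu = dplyr::arrange(mwu, .data$group, .data$day),
         normalized = normalize_treated_to_control(tbl, metric),
         alpha = alpha, metric = metric, p_adjust = p_adjust),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> metric '%s', alpha %.3g (p adjust: %s)\n",
              x$metric, x$alpha, x$p_adjust))
  cat(sprintf("  %d Kruskal-Wallis series tests (%d significant)\n",
              nrow(x$kw), sum(x$kw$significant)))
  cat(sprintf("  %d control-vs-treated U tests (%d significant)\n",
              nrow(x$mwu), sum(x$mwu$significant)))
  d7 <- dplyr::filter(x$normalized, .data$day == max(.data$day))
  cat("  final-day treated/control ratios: ",
      paste(sprintf("%s %.2f", d7$group, d7$ratio), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn summarize_study All hypothesis tests of the report, one row
#'   per test.
#' @param x A `study_report`.
#' @param ... Unused.
#' @export
tidy.study_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$kw, family = "kruskal_wallis_across_days", .before = 1),
    dplyr::mutate(x$mwu, family = "mwu_control_vs_treated", .before = 1)
  )
}

#' @describeIn summarize_study One-row overview (test counts, significant
#'   counts, final-day ratio range).
#' @export
glance.study_report <- function(x, ...) {
  d7 <- dplyr::filter(x$normalized, .data$day == max(.data$day))
  tibble(
    metric = x$metric, alpha = x$alpha,
    n_kw_tests = nrow(x$kw), n_kw_significant = sum(x$kw$significant),
    n_mwu_tests = nrow(x$mwu), n_mwu_significant = sum(x$mwu$significant),
    min_final_ratio = min(d7$ratio, na.rm = TRUE),
    max_final_ratio = max(d7$ratio, na.rm = TRUE)
  )
}
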