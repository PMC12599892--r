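#' Effect structure for a synthetic longitudinal spheroid study
#'
#' Describes a 3-groups x 2-conditions x 3-time-points design: glioblastoma
#' monoculture (LN229), human-astrocyte monoculture (HA) and co-culture
#' (CO) spheroids, untreated (control) or chemotherapy-treated (treated),
#' measured on days 0, 4 and 7. Each (group, condition) cell has a baseline
#' metric value and per-day multiplicative decline factors; replicates get
#' multiplicative log-normal noise with a stated coefficient of variation.
#'
#' The default factors are synthetic, chosen to mimic the qualitative
#' ordering of a chemosensitivity study: treated glioblastoma monoculture
#' softens strongly, astrocytes are nearly flat under treatment, and the
#' co-culture shows an intermediate (treatment-resistant) decline. They are
#' illustration parameters, not measured values.
#'
#' @param baselines Named numeric vector of day-0 metric values per group.
#' @param factors Tibble with columns `group`, `condition`, `day`, `factor`
#'   giving the multiplicative decline per day; day 0 must have factor 1
#'   (rows for day 0 may be omitted and are filled in as 1). Factors must
#'   lie in (0, 1].
#' @param days Measurement days (default `c(0, 4, 7)`).
#' @param n_replicates Replicates per cell and day (default 9: three
#'   independent experiments in triplicate).
#' @param cv Replicate coefficient of variation (log-normal, mean 1).
#' @param seed RNG seed or NULL.
#' @return A list of class `study_effect_spec`.
#' @examples
#' spec <- study_effect_spec(cv = 0.1)
#' tbl <- simulate_study_table(spec, metric = "wave_speed_mps")
#' @export
study_effect_spec <- function(baselines = c(LN229 = 2.5, HA = 1.8, CO = 2.2),
                              factors = default_decline_factors(),
                              days = c(0, 4, 7),
                              n_replicates = 9L,
                              cv = 0.10,
                              seed = NULL) {
  if (is.null(names(baselines)) || any(!nzchar(names(baselines)))) {
    abort("`baselines` must be a named vector (one value per group).")
  }
  if (any(baselines <= 0)) abort("`baselines` must be positive.")
  check_scalar(n_replicates, "n_replicates", lower = 1)
  check_scalar(cv, "cv", lower = 0)
  factors <- as_tibble(factors)
  need <- c("group", "condition", "day", "factor")
  if (!all(need %in% names(factors))) {
    abort("`factors` needs columns group, condition, day, factor.")
  }
  groups <- names(baselines)
  conditions <- c("control", "treated")
  grid <- tidyr::expand_grid(group = groups, condition = conditions,
                             day = days)
  factors <- dplyr::left_join(grid, factors,
                              by = c("group", "condition", "day"))
  factors$factor[factors$day == 0 & is.na(factors$factor)] <- 1
  if (anyNA(factors$factor)) {
    miss <- factors[is.na(factors$factor), ]
    abort(sprintf("missing decline factor for %s/%s day %s (and %d more).",
                  miss$group[1], miss$condition[1], miss$day[1],
                  nrow(miss) - 1L))
  }
  if (any(factors$factor <= 0 | factors$factor > 1)) {
    abort("decline factors must lie in (0, 1].")
  }
  if (any(factors$factor[factors$day == 0] != 1)) {
    abort("day-0 decline factors must equal 1.")
  }
  structure(
    list(baselines = baselines, factors = factors, days = days,
         groups = groups, conditions = conditions,
         n_replicates = as.integer(n_replicates), cv = cv, seed = seed),
    class = "study_effect_spec"
  )
}

#' @describeIn study_effect_spec Default decline factors: strong treated
#'   decline in LN229, near-flat HA, intermediate co-culture.
#' @export
default_decline_factors <- function() {
  tibble(
    group     = rep(c("LN229", "HA", "CO"), each = 4),
    condition = rep(c("control", "control", "treated", "treated"), times = 3),
    day       = rep(c(4, 7), times = 6),
    factor    = c(0.95, 0.90, 0.70, 0.50,   # LN229
                  0.97, 0.95, 0.96, 0.94,   # HA
                  0.95, 0.90, 0.85, 0.75)   # CO
  )
}

#' Simulate a longitudinal study table
#'
#' Draws one long-format table from a [study_effect_spec()]: one row per
#' (group, condition, day, replicate), with
#' `value = baseline * day_factor * noise` and log-normal noise of mean 1
#' and the spec's coefficient of variation.
#'
#' @param spec A [study_effect_spec()].
#' @param metric Metric name recorded in the `metric` column
#'   (`"wave_speed_mps"` or `"brillouin_shift_ghz"` in the emulated study;
#'   any string is accepted).
#' @return A tibble with columns `group`, `condition`, `day`, `replicate`,
#'   `metric`, `value`; `|groups| * |conditions| * |days| * n_replicates`
#'   rows.
#' @export
simulate_study_table <- function(spec, metric = "wave_speed_mps") {
  stopifnot(inherits(spec, "study_effect_spec"))
  local_seed(spec$seed)
  tbl <- tidyr::expand_grid(
    group = spec$groups, condition = spec$conditions, day = spec$days,
    replicate = seq_len(spec$n_replicates)
  )
  tbl <- dplyr::left_join(tbl, spec$factors,
                          by = c("group", "condition", "day"))
  tbl$baseline <- unname(spec$baselines[tbl$group])
  # log-normal with exact mean 1 and coefficient of variation cv
  if (spec$cv > 0) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    noise <- rlnorm(nrow(tbl), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    noise <- 1
  }
  tbl$metric <- metric
  tbl$value <- tbl$baseline * tbl$factor * noise
  tbl[, c("group", "condition", "day", "replicate", "metric", "value")]
}
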