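# Goodness-of-fit statistics, OLS diagnostics and biennial aggregation for
# comparing simulated against observed series.

#' Goodness-of-fit statistics for a simulated vs observed series
#'
#' Computes, over the non-missing pairs: n, the mean absolute error
#' `MAE = sum(|S_i - M_i|) / n`, the signed mean error `ME = sum(M_i -
#' S_i) / n` (reported separately because published summaries sometimes
#' print the signed form under the MAE label), `RMSE = sqrt(sum((S_i -
#' M_i)^2) / n)`, the coefficient of residual mass `CRM = 1 - sum(S) /
#' sum(M)` and the modelling (Nash-Sutcliffe) efficiency
#' `EF = 1 - sum((S - M)^2) / sum((M - mean(M))^2)`.
#'
#' @param observed Measured values `M_i`.
#' @param simulated Simulated values `S_i`, same length.
#' @return Named list: `n`, `mae`, `me`, `rmse`, `crm`, `ef`.
#' @export
fit_metrics <- function(observed, simulated) {
  stopifnot(length(observed) == length(simulated))
  ok <- !is.na(observed) & !is.na(simulated)
  m <- observed[ok]; s <- simulated[ok]
  n <- length(m)
  if (n < 2) stop("fit_metrics requires at least 2 non-missing pairs")
  if (sum(m) == 0) stop("CRM undefined: sum of observations is zero")
  list(
    n = n,
    mae = mean(abs(s - m)),
    me = mean(m - s),
    rmse = sqrt(mean((s - m)^2)),
    crm = 1 - sum(s) / sum(m),
    ef = 1 - sum((s - m)^2) / sum((m - mean(m))^2)
  )
}

#' OLS regression of simulated on measured values
#'
#' @param observed Measured values (regressor).
#' @param simulated Simulated values (response).
#' @return Named list: `slope`, `intercept`, `r2` (squared Pearson
#'   correlation).
#' @export
linear_regression <- function(observed, simulated) {
  ok <- !is.na(observed) & !is.na(simulated)
  m <- observed[ok]; s <- simulated[ok]
  if (length(m) < 3) stop("linear_regression requires at least 3 pairs")
  if (stats::var(m) == 0) stop("zero variance in the observed values")
  fit <- stats::lm(s ~ m)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = stats::cor(m, s)^2)
}

#' Overlapping biennial means of an annual paired series
#'
#' For each experiment/treatment group, consecutive-year pairs are averaged
#' with overlap: years (y1, y2), (y2, y3), ... A group with k years yields
#' k - 1 biennial records; single-year groups are skipped with a warning.
#' Both the observed and simulated columns are averaged; a biennium is kept
#' only if both years are non-missing.
#'
#' @param pairs Data frame with columns `experiment`, `treatment`, `year`,
#'   `observed`, `simulated`.
#' @return Data frame of the same shape (year = first year of the
#'   biennium).
#' @export
biennial_aggregate <- function(pairs) {
  grp <- interaction(pairs$experiment, pairs$treatment, drop = TRUE)
  out <- lapply(split(pairs, grp), function(d) {
    d <- d[order(d$year), ]
    if (nrow(d) < 2) {
      warning("treatment ", d$treatment[1], " has a single year; skipped")
      return(NULL)
    }
    i <- seq_len(nrow(d) - 1)
    data.frame(experiment = d$experiment[i], treatment = d$treatment[i],
               year = d$year[i],
               observed = (d$observed[i] + d$observed[i + 1]) / 2,
               simulated = (d$simulated[i] + d$simulated[i + 1]) / 2)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!is.na(res$observed) & !is.na(res$simulated), ]
}

#' Evaluate simulated annual outputs against observations
#'
#' Inner-joins the two tables on `experiment`, `treatment` and `year` and
#' emits goodness-of-fit and regression statistics for every shared value
#' column, at the annual scale and (where at least two consecutive years
#' exist) the overlapping-biennial scale. Missing observations are
#' excluded from n, variable by variable.
#'
#' @param sim Data frame with label columns and simulated value columns.
#' @param obs Data frame with the same label and value column names
#'   holding observations (missing as `NA`).
#' @return Data frame: one row per variable x scale with the statistics of
#'   [fit_metrics()] and [linear_regression()].
#' @export
evaluate_run <- function(sim, obs) {
  keys <- c("experiment", "treatment", "year")
  if (!all(keys %in% names(sim)) || !all(keys %in% names(obs))) {
    stop("both tables need experiment, treatment and year columns")
  }
  vars <- setdiff(intersect(names(sim), names(obs)), keys)
  if (length(vars) == 0) stop("no shared value columns to evaluate")
  joined <- merge(obs, sim, by = keys, suffixes = c("_obs", "_sim"))
  if (nrow(joined) == 0) {
    stop("empty join: no matching experiment/treatment/year labels")
  }
  rows <- list()
  for (v in vars) {
    pairs <- data.frame(experiment = joined$experiment,
                        treatment = joined$treatment,
                        year = joined$year,
                        observed = joined[[paste0(v, "_obs")]],
                        simulated = joined[[paste0(v, "_sim")]])
    for (scale in c("annual", "biennial")) {
      pp <- if (scale == "biennial") {
        biennial_aggregate(pairs[!is.na(pairs$observed) &
                                   !is.na(pairs$simulated), ])
      } else pairs
      if (is.null(pp) || sum(!is.na(pp$observed) & !is.na(pp$simulated)) < 3) next
      fm <- fit_metrics(pp$observed, pp$simulated)
      lr <- linear_regression(pp$observed, pp$simulated)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, scale = scale, n = fm$n, mae = fm$mae, me = fm$me,
        rmse = fm$rmse, crm = fm$crm, ef = fm$ef, slope = lr$slope,
        intercept = lr$intercept, r2 = lr$r2)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Load the packaged field-trial fixture
#'
#' Observed and simulated seasonal evapotranspiration and oil yield from
#' two 3-year irrigation experiments (eight treatments, 24 treatment-years;
#' ET observations missing for the first year of Experiment I). Treatment
#' labels follow the published summary table ("FI" is the Experiment I
#' full-irrigation control, "SDI" the Experiment II sustained/continuous
#' deficit treatment).
#'
#' @return Data frame with columns `experiment`, `treatment`, `year`,
#'   `et_obs`, `et_sim`, `yoil_obs`, `yoil_sim` (mm and g m-2; `NA` =
#'   not measured).
#' @export
load_trial_fixture <- function() {
  path <- system.file("extdata", "field_trials_et_yield.csv",
                      package = "olivesim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "*", "NA"))
}
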