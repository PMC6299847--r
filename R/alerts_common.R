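# Shared alert record and trailing-window band machinery used by both the
# clinical (vitals) and habits alerting paths.

alert_cols <- c("day", "category", "rule", "period", "observed",
                "lower", "upper", "direction", "persistent")

#' An empty alert log
#'
#' Alerts share one schema across the pipeline: `day` (civil day),
#' `category` (`clinical` or `habits`), `rule` (e.g. `bp_over`,
#' `spo2_under`, `habits_over`, `weight_24h`), `period` (period label for
#' habits alerts, `NA` for clinical), `observed` value, the `lower`/`upper`
#' thresholds that applied, `direction` (`over`, `under`, `gain`, `loss`)
#' and the `persistent` flag set by [persistence_filter()].
#'
#' @return zero-row alert tibble.
#' @export
empty_alerts <- function() {
  tibble::tibble(
    day = as.Date(character()), category = character(), rule = character(),
    period = character(), observed = numeric(), lower = numeric(),
    upper = numeric(), direction = character(), persistent = logical()
  )
}

new_alerts <- function(day, category, rule, observed, direction,
                       period = NA_character_, lower = NA_real_,
                       upper = NA_real_) {
  if (length(day) == 0) return(empty_alerts())
  tibble::tibble(day = day, category = category, rule = rule,
                 period = as.character(period), observed = observed,
                 lower = lower, upper = upper, direction = direction,
                 persistent = FALSE)
}

#' Trailing-window adaptive band
#'
#' Subject-specific thresholds are the mean plus/minus `k` sample standard
#' deviations of the observations in the trailing `window_days` civil days
#' strictly before each evaluated day, so a deviant day can never widen its
#' own band. Days whose window holds fewer than `min_window_obs`
#' observations are flagged `warmup` and get no band (hence can raise no
#' alert).
#'
#' @param days Date vector of observation days (one value per day).
#' @param values numeric observations aligned with `days`.
#' @param eval_days Date vector of days to compute a band for; defaults to
#'   `days`.
#' @param window_days trailing window length in civil days (default 15).
#' @param k band half-width in standard deviations (default 2).
#' @param min_window_obs minimum observations required in the window
#'   (default 5).
#' @return tibble with `day`, `mean`, `sd`, `lower`, `upper`,
#'   `n_in_window`, `warmup`.
#' @export
trailing_band <- function(days, values, eval_days = days, window_days = 15,
                          k = 2, min_window_obs = 5) {
  stopifnot(length(days) == length(values), window_days >= 1,
            min_window_obs >= 1, k >= 0)
  ord <- order(days)
  days <- days[ord]; values <- values[ord]
  res <- lapply(eval_days, function(d) {
    sel <- days >= (d - window_days) & days <= (d - 1) & !is.na(values)
    v <- values[sel]
    n <- length(v)
    if (n < min_window_obs) {
      tibble::tibble(day = d, mean = NA_real_, sd = NA_real_,
                     lower = NA_real_, upper = NA_real_, n_in_window = n,
                     warmup = TRUE)
    } else {
      m <- mean(v)
      s <- if (n > 1) stats::sd(v) else 0
      tibble::tibble(day = d, mean = m, sd = s, lower = m - k * s,
                     upper = m + k * s, n_in_window = n, warmup = FALSE)
    }
  })
  dplyr::bind_rows(res)
}
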