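# Regression-based response estimation: trait-vs-ca slopes with confidence
# intervals, relative sensitivity at a reference CO2, binned ANOVA,
# two-predictor variance partition, slope RMSE and range summaries.

#' Linear trend of a trait against ambient CO2
#'
#' Ordinary least-squares fit of `y ~ x` with a t-based 95% confidence
#' interval on the slope.
#'
#' @param x predictor (usually ambient CO2, ppm).
#' @param y trait values.
#' @param trait,species optional labels carried in the result.
#' @param conf confidence level for the slope interval.
#' @return list of class `"response_fit"`: `slope`, `intercept`, `ci`
#'   (length-2), `se`, `r2`, `p`, `n`, `trait`, `species`.
#' @export
#' @examples
#' fit_trend(300:400, 2 + 0.14 * (300:400))
fit_trend <- function(x, y, trait = NA_character_, species = "combined",
                      conf = 0.95) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2) stop("degenerate predictor: all x identical")
  if (stats::var(y) == 0) {
    # constant response: slope exactly 0, nothing explained
    out <- list(slope = 0, intercept = y[1], ci = c(0, 0), se = 0, r2 = 0,
                p = 1, n = length(x), trait = trait, species = species)
    class(out) <- "response_fit"
    return(out)
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  ci <- tryCatch(suppressWarnings(stats::confint(fit, "x", level = conf)),
                 error = function(e) c(NA_real_, NA_real_))
  out <- list(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    ci = as.numeric(ci),
    se = sm$coefficients["x", "Std. Error"],
    r2 = sm$r.squared,
    p = sm$coefficients["x", "Pr(>|t|)"],
    n = length(x),
    trait = trait,
    species = species
  )
  class(out) <- "response_fit"
  out
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf(
    "Trend%s%s: slope = %.5g [%.5g, %.5g], r2 = %.3f, p = %.3g, n = %d\n",
    if (!is.na(x$trait)) paste0(" of ", x$trait) else "",
    if (!is.na(x$species)) paste0(" (", x$species, ")") else "",
    x$slope, x$ci[1], x$ci[2], x$r2, x$p, x$n))
  invisible(x)
}

#' Relative sensitivity of a fitted trend
#'
#' Expresses the fitted slope as a percentage change, per `window` ppm of
#' CO2, of the fitted value at a reference CO2:
#' \deqn{100 \cdot \frac{slope \cdot window}{intercept + slope \cdot ref}}
#'
#' @param fit a [fit_trend()] object.
#' @param ref_ca reference CO2, ppm (default 300).
#' @param window CO2 window, ppm (default 100).
#' @return percentage change per window.
#' @export
relative_sensitivity <- function(fit, ref_ca = 300, window = 100) {
  ref_value <- fit$intercept + fit$slope * ref_ca
  if (!is.finite(ref_value) || ref_value == 0) {
    stop("fitted value at the reference CO2 is zero")
  }
  100 * fit$slope * window / ref_value
}

#' One-way ANOVA of a trait across CO2 bins
#'
#' Bins observations into CO2 ranges (default the four 25-ppm ranges
#' 300-325, 326-350, 351-375, 376-400) and tests whether between-bin
#' variation exceeds within-bin variation.
#'
#' @param values trait values (e.g. gsmax).
#' @param ca ambient CO2 per observation, ppm.
#' @param breaks bin edges, ppm.
#' @return list with `F`, `df` (length-2), `p`, `n_per_bin`; when there is no
#'   between-group variance at all, `F = 0` and `p = 1` with a
#'   `"no between-group variance"` note.
#' @export
anova_binned <- function(values, ca, breaks = c(300, 325, 350, 375, 400)) {
  keep <- !is.na(values) & !is.na(ca)
  values <- values[keep]; ca <- ca[keep]
  bins <- cut(ca, breaks = breaks, include.lowest = TRUE)
  counts <- table(bins)
  if (any(counts == 0)) {
    stop("empty CO2 bin(s): ", paste(names(counts)[counts == 0],
                                     collapse = ", "))
  }
  if (stats::var(values) == 0) {
    return(list(F = 0, df = c(length(counts) - 1, length(values) -
                                length(counts)),
                p = 1, n_per_bin = as.integer(counts),
                note = "no between-group variance"))
  }
  fit <- stats::aov(values ~ bins)
  sm <- summary(fit)[[1]]
  list(F = sm$`F value`[1], df = sm$Df, p = sm$`Pr(>F)`[1],
       n_per_bin = as.integer(counts))
}

#' Two-predictor variance partition
#'
#' Partitions the explained variance of `y ~ x1 + x2` between the two
#' predictors by order-averaged incremental r-squared (the two-predictor
#' case of dominance averaging): each predictor's share is the mean of its
#' marginal r-squared and its increment over the other predictor, normalised
#' so the shares sum to 100% of the full-model r-squared.
#'
#' @param y response (e.g. iWUE).
#' @param x1,x2 predictors (e.g. ambient CO2 and mean annual precipitation).
#' @return list with `r2_total` (full model), `share_x1`, `share_x2`
#'   (percentages of the model r-squared, summing to 100).
#' @export
variance_partition <- function(y, x1, x2) {
  keep <- !is.na(y) & !is.na(x1) & !is.na(x2)
  y <- y[keep]; x1 <- x1[keep]; x2 <- x2[keep]
  if (length(y) < 4) stop("need at least 4 observations")
  if (abs(stats::cor(x1, x2)) > 0.999) stop("collinear predictors")
  r2 <- function(fit) summary(fit)$r.squared
  r2_full <- r2(stats::lm(y ~ x1 + x2))
  r2_1 <- r2(stats::lm(y ~ x1))
  r2_2 <- r2(stats::lm(y ~ x2))
  raw1 <- (r2_1 + (r2_full - r2_2)) / 2
  raw2 <- (r2_2 + (r2_full - r2_1)) / 2
  list(r2_total = r2_full,
       share_x1 = 100 * raw1 / (raw1 + raw2),
       share_x2 = 100 * raw2 / (raw1 + raw2))
}

#' Root-mean-square difference between simulated and empirical slopes
#'
#' @param simulated,empirical named numeric vectors of per-species slopes;
#'   the species sets must match (order-insensitive when named).
#' @return RMSE across species.
#' @export
slope_rmse <- function(simulated, empirical) {
  if (!is.null(names(simulated)) && !is.null(names(empirical))) {
    if (!setequal(names(simulated), names(empirical))) {
      stop("mismatched species lists")
    }
    empirical <- empirical[names(simulated)]
  } else if (length(simulated) != length(empirical)) {
    stop("mismatched species lists")
  }
  sqrt(mean((simulated - empirical)^2))
}

#' Range summary of a measurement vector
#'
#' @param values non-empty numeric vector (e.g. per-species delta-13C).
#' @return list with `min`, `max`, `range` (`max - min`).
#' @export
#' @examples
#' range_summary(c(-32.09, -28.05)) # range 4.04
range_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input")
  list(min = min(values), max = max(values),
       range = max(values) - min(values))
}

#' Tidy per-species and combined trend table
#'
#' Fits [fit_trend()] for one trait against ambient CO2, per species and for
#' the pooled data (no species term in the pooled fit), and reports slope,
#' CI, p, r2, n and relative sensitivity in one tidy row each.
#'
#' @param records table holding the trait column, `species`, and `ca`.
#' @param trait name of the trait column.
#' @param ref_ca,window passed to [relative_sensitivity()].
#' @return data.frame, one row per species plus `"combined"`.
#' @export
trend_table <- function(records, trait, ref_ca = 300, window = 100) {
  one <- function(df, label) {
    f <- fit_trend(df$ca, df[[trait]], trait = trait, species = label)
    data.frame(trait = trait, species = label, slope = f$slope,
               intercept = f$intercept, ci_lo = f$ci[1], ci_hi = f$ci[2],
               r2 = f$r2, p = f$p, n = f$n,
               rel_sensitivity = relative_sensitivity(f, ref_ca, window),
               stringsAsFactors = FALSE)
  }
  keep <- !is.na(records[[trait]]) & !is.na(records$ca)
  rec <- records[keep, , drop = FALSE]
  out <- do.call(rbind, c(
    lapply(sort(unique(rec$species)),
           function(sp) one(rec[rec$species == sp, , drop = FALSE], sp)),
    list(one(rec, "combined"))))
  rownames(out) <- NULL
  out
}
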