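#' Major Axis (model II) regression
#'
#' Symmetric line fit for method comparison when both variables carry error:
#' the fitted line is the first principal axis of the 2D scatter. With
#' centered sums of squares `Sxx`, `Syy` and cross-products `Sxy`,
#'
#'   slope = (Syy - Sxx + sqrt((Syy - Sxx)^2 + 4 Sxy^2)) / (2 Sxy)
#'
#' and the intercept passes through the centroid. `r2` is the squared Pearson
#' correlation. A permutation test on the correlation (fixed internal seed,
#' deterministic) provides the p-value.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval) holding the reference (e.g. mean manual)
#'   and test (e.g. automated) measurements; `y` is the automated axis.
#' @param n_perm Number of correlation permutations for the p-value
#'   (`0` skips the test).
#' @return An object of class `major_axis_fit` with fields `slope`,
#'   `intercept`, `r2`, `n`, `p_value` and the fitted data.
#' @examples
#' d <- data.frame(manual = c(1, 2, 3, 4), auto = c(1.1, 1.9, 3.2, 3.9))
#' fit <- major_axis_fit(d, manual, auto)
#' glance(fit)
#' @export
major_axis_fit <- function(data, x, y, n_perm = 9999L) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) stop("major-axis fit needs at least 3 points", call. = FALSE)
  if (stats::var(xv) == 0 || stats::var(yv) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  xm <- mean(xv); ym <- mean(yv)
  sxx <- sum((xv - xm)^2)
  syy <- sum((yv - ym)^2)
  sxy <- sum((xv - xm) * (yv - ym))
  if (sxy == 0) stop("zero covariance: slope undefined", call. = FALSE)
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  r <- cor(xv, yv)
  p <- if (n_perm > 0L) perm_cor_pvalue(xv, yv, n_perm) else NA_real_
  structure(
    list(slope = slope, intercept = ym - slope * xm, r2 = r^2, n = n,
         p_value = p, data = tibble(x = xv, y = yv)),
    class = "major_axis_fit"
  )
}

# two-sided permutation p-value for the correlation, deterministic
perm_cor_pvalue <- function(x, y, n_perm) {
  obs <- abs(cor(x, y))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20160629L)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(cor(x, sample(y))) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' @export
print.major_axis_fit <- function(x, ...) {
  cat("Major Axis (model II) regression, n = ", x$n, "\n",
      "  slope ", round(x$slope, 4), ", intercept ", round(x$intercept, 4),
      ", r2 ", round(x$r2, 4),
      if (!is.na(x$p_value)) paste0(", p ", format.pval(x$p_value)),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy major_axis_fit
#' @export
tidy.major_axis_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @method glance major_axis_fit
#' @export
glance.major_axis_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
         p_value = x$p_value, n = x$n)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot major_axis_fit
#' @export
autoplot.major_axis_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "manual estimate", y = "automated estimate",
      title = sprintf("Major axis fit: slope %.2f, r² %.2f, n = %d",
                      object$slope, object$r2, object$n)
    ) +
    ggplot2::theme_minimal()
}

# exact column schema of the comparison table CSV
.comparison_cols <- c("station", "image_no", "manual_count",
                      "manual_count_sd", "manual_tl_um", "manual_tl_sd_um",
                      "a_count", "a_tl_um", "rec_joined", "rec_events",
                      "fil_obj", "afil_aobj_pct")

#' Read a manual-vs-automated comparison table
#'
#' The CSV schema is
#' `station,image_no,manual_count,manual_count_sd,manual_tl_um,manual_tl_sd_um,a_count,a_tl_um,rec_joined,rec_events,fil_obj,afil_aobj_pct`.
#' Basic invariants (non-negative sds, `rec_joined <= rec_events`,
#' area fraction within 0-100) are checked on read.
#'
#' @param path CSV file path.
#' @return A tibble with the columns above.
#' @export
read_comparison_table <- function(path) {
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(.comparison_cols, names(tab))
  if (length(missing)) {
    stop("comparison table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- tab[.comparison_cols]
  stopifnot(all(tab$manual_count_sd >= 0), all(tab$manual_tl_sd_um >= 0),
            all(tab$rec_joined <= tab$rec_events),
            all(tab$afil_aobj_pct >= 0 & tab$afil_aobj_pct <= 100))
  tab
}

#' Packaged 40-image validation dataset
#'
#' Manual (mean of four operators, with standard deviations) and automated
#' per-FOV filament counts and total lengths for 10 fields of view at each of
#' four sampling stations on three Italian volcanic lakes (Ronciglione and
#' Caprarola on Lake Vico, Albano, Nemi), together with reconnection
#' bookkeeping, filamentous-object counts and filamentous area fractions.
#' The stations span very different background-noise regimes: at Caprarola
#' roughly half of the object area is filamentous, at Nemi barely a quarter.
#'
#' @return A tibble with 40 rows and the [read_comparison_table()] schema.
#' @examples
#' tab <- validation_table()
#' dplyr::count(tab, station)
#' @export
validation_table <- function() {
  path <- system.file("extdata", "validation_table1.csv",
                      package = "cyanotrace", mustWork = TRUE)
  read_comparison_table(path)
}

#' Pooled summaries of a comparison table
#'
#' Computes the pooled reconstruction rate over all rows
#' (`100 * sum(rec_joined) / sum(rec_events)`), and per station the mean
#' filamentous area fraction and the pooled fraction of filamentous objects
#' that are filaments of interest (`100 * sum(a_count) / sum(fil_obj)`).
#' Zero denominators yield `NA`, never 0.
#'
#' @param table A comparison table (see [read_comparison_table()]).
#' @return A list with `overall` (one-row tibble: `reconstruction_pct`) and
#'   `by_station` (tibble: `station`, `mean_afil_aobj_pct`,
#'   `pooled_interest_fraction_pct`).
#' @export
pooled_summaries <- function(table) {
  overall <- tibble(
    reconstruction_pct = if (sum(table$rec_events) == 0) NA_real_ else
      100 * sum(table$rec_joined) / sum(table$rec_events)
  )
  by_station <- table |>
    dplyr::group_by(.data$station) |>
    dplyr::summarise(
      mean_afil_aobj_pct = mean(.data$afil_aobj_pct),
      pooled_interest_fraction_pct =
        ifelse(sum(.data$fil_obj) == 0, NA_real_,
               100 * sum(.data$a_count) / sum(.data$fil_obj)),
      .groups = "drop"
    )
  list(overall = overall, by_station = by_station)
}

#' Major-axis fits for every station and response
#'
#' Fits the model-II regression of the automated estimate on the mean manual
#' estimate for each station, separately for filament abundance
#' (`a_count` vs `manual_count`) and total length (`a_tl_um` vs
#' `manual_tl_um`), using the 10 per-FOV pairs of each station block.
#'
#' @param table A comparison table.
#' @param n_perm Permutations for the p-values (0 to skip).
#' @return A tibble with one row per station x response: `station`,
#'   `response` (`"abundance"` or `"total_length"`), `slope`, `intercept`,
#'   `r2`, `p_value`, `n`.
#' @export
station_fit_suite <- function(table, n_perm = 0L) {
  combos <- expand.grid(station = unique(table$station),
                        response = c("abundance", "total_length"),
                        stringsAsFactors = FALSE)
  rows <- purrr::pmap(combos, function(station, response) {
    d <- table[table$station == station, ]
    fit <- if (response == "abundance") {
      major_axis_fit(d, .data$manual_count, .data$a_count, n_perm = n_perm)
    } else {
      major_axis_fit(d, .data$manual_tl_um, .data$a_tl_um, n_perm = n_perm)
    }
    dplyr::mutate(glance(fit), station = station, response = response)
  })
  dplyr::bind_rows(rows)[, c("station", "response", "slope", "intercept",
                             "r2", "p_value", "n")]
}

#' Slope range and minimum r-squared of a fit suite
#'
#' Rounds each slope to two decimals (the reporting convention for these
#' statistics) and returns the minimum and maximum together with the minimum
#' unrounded r-squared.
#'
#' @param fits Output of [station_fit_suite()], possibly filtered to a subset
#'   of stations.
#' @return One-row tibble: `min_slope`, `max_slope`, `min_r2`, `n_fits`.
#' @export
summarize_fit_suite <- function(fits) {
  tibble(
    min_slope = min(round(fits$slope, 2)),
    max_slope = max(round(fits$slope, 2)),
    min_r2 = min(fits$r2),
    n_fits = nrow(fits)
  )
}
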