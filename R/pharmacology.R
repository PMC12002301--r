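# Quantification of receptor-assay and organ-pharmacology data:
# per-experiment luminescence normalization, four-parameter logistic
# EC50 fitting, contraction normalization against a reference agonist,
# stomach-area time courses, and the two-sample comparison used for the
# feeding-behavior assay.

#' Normalize luminescence responses within experiments
#'
#' Each response is expressed as a percentage of the maximal response
#' observed in its own experiment (`100 * value / max(experiment)`),
#' matching the per-experiment normalization used for receptor-assay
#' dose-response curves.
#'
#' @param table `data.frame` with columns `experiment` and `response`.
#' @return the table with an added `response_pct` column.
#' @export
normalize_luminescence <- function(table) {
  stopifnot(all(c("experiment", "response") %in% names(table)))
  maxima <- tapply(table$response, table$experiment, max)
  if (any(maxima <= 0))
    stop("experiment(s) with no positive response: ",
         paste(names(maxima)[maxima <= 0], collapse = ", "))
  table$response_pct <- as.numeric(
    100 * table$response / maxima[as.character(table$experiment)])
  table
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `resp = bottom + (top - bottom) / (1 + 10^(hill * (log_ec50 - log10(conc))))`
#' on all replicate points jointly. Initialization is multi-start:
#' bottom/top from the response range, `log_ec50` at the concentration
#' nearest half-range, Hill slope in \{0.5, 1, 2\} with ±1 log jitter on
#' `log_ec50`; the best residual sum of squares wins. Optimization uses
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#'
#' @param conc molar concentrations (> 0).
#' @param resp responses (same length).
#' @return list of class `dose_response_fit` with `bottom`, `top`,
#'   `log_ec50`, `ec50`, `hill`, `rss`, `n_points`.
#' @export
fit_4pl <- function(conc, resp) {
  stopifnot(length(conc) == length(resp), all(conc > 0))
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations")
  if (stats::var(resp) == 0) stop("degenerate: no response variation")
  lc <- log10(conc)
  df <- data.frame(lc = lc, resp = resp)
  half <- (min(resp) + max(resp)) / 2
  lc0 <- lc[which.min(abs(resp - half))]
  starts <- list()
  for (h in c(0.5, 1, 2)) starts[[length(starts) + 1L]] <-
    c(bottom = min(resp), top = max(resp), log_ec50 = lc0, hill = h)
  starts[[length(starts) + 1L]] <-
    c(bottom = min(resp), top = max(resp), log_ec50 = lc0 - 1, hill = 1)
  starts[[length(starts) + 1L]] <-
    c(bottom = min(resp), top = max(resp), log_ec50 = lc0 + 1, hill = 1)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ bottom + (top - bottom) / (1 + 10^(hill * (log_ec50 - lc))),
        data = df, start = as.list(s),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("4PL fit failed from all starts")
  p <- stats::coef(best$fit)
  if (p[["top"]] < p[["bottom"]]) {  # canonical orientation
    tmp <- p[["top"]]; p[["top"]] <- p[["bottom"]]; p[["bottom"]] <- tmp
    p[["hill"]] <- -p[["hill"]]
  }
  structure(list(bottom = unname(p["bottom"]), top = unname(p["top"]),
                 log_ec50 = unname(p["log_ec50"]),
                 ec50 = 10^unname(p["log_ec50"]),
                 hill = unname(p["hill"]), rss = best$rss,
                 n_points = length(resp)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit (n = %d): EC50 = %.3g M (log10 = %.3f), hill = %.2f,\n  bottom = %.2f, top = %.2f, rss = %.4g\n",
    x$n_points, x$ec50, x$log_ec50, x$hill, x$bottom, x$top, x$rss))
  invisible(x)
}

#' Normalize contraction amplitudes to a reference agonist
#'
#' Each amplitude is expressed as a percentage of the reference-agonist
#' contraction recorded in the same preparation
#' (`100 * amplitude / reference_amplitude`; the reference defines 100%).
#' For the cumulative (no-wash) protocol the per-dose values are reported
#' as measured and flagged when the series is non-monotone.
#'
#' @param records `data.frame` with columns `prep_id`, `concentration`,
#'   `amplitude`, `reference_amplitude`, and optionally `protocol`
#'   (`"washed"`/`"cumulative"`).
#' @return list with `records` (input plus `pct` column and, for
#'   cumulative preps, `non_monotone`), and `summary` (per-concentration
#'   `mean`, `sem`, `n`).
#' @export
normalize_contraction <- function(records) {
  need <- c("prep_id", "concentration", "amplitude", "reference_amplitude")
  stopifnot(all(need %in% names(records)))
  bad <- is.na(records$reference_amplitude) | records$reference_amplitude <= 0
  if (any(bad))
    stop("missing/invalid reference amplitude for prep(s): ",
         paste(unique(records$prep_id[bad]), collapse = ", "))
  stopifnot(all(records$amplitude >= 0))
  records$pct <- 100 * records$amplitude / records$reference_amplitude
  if ("protocol" %in% names(records)) {
    records$non_monotone <- FALSE
    for (p in unique(records$prep_id[records$protocol == "cumulative"])) {
      sel <- records$prep_id == p & records$protocol == "cumulative"
      ser <- records[sel, ]
      ser <- ser[order(ser$concentration), ]
      if (any(diff(ser$pct) < 0))
        records$non_monotone[sel] <- TRUE
    }
  }
  agg <- split(records$pct, records$concentration)
  summary <- data.frame(
    concentration = as.numeric(names(agg)),
    mean = vapply(agg, mean, 0),
    sem = vapply(agg, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_, 0),
    n = vapply(agg, length, 0L), row.names = NULL)
  summary <- summary[order(summary$concentration), ]
  list(records = records, summary = summary)
}

#' Normalize an organ-area time course to the pre-injection area
#'
#' Each area is expressed as a percentage of the same animal's area at
#' the final pre-injection time point (`t_inject`), then summarized as
#' mean ± SEM per group and time point.
#'
#' @param areas `data.frame` with columns `animal`, `group`, `time`,
#'   `area`.
#' @param t_inject time of the pre-injection reference measurement.
#' @return list with `records` (plus `pct`) and `summary` (per
#'   `group` x `time`: `mean`, `sem`, `n`).
#' @export
area_timecourse <- function(areas, t_inject = 0) {
  stopifnot(all(c("animal", "group", "time", "area") %in% names(areas)))
  ref <- areas[areas$time == t_inject, ]
  if (!nrow(ref)) stop("no measurements at t_inject = ", t_inject)
  key <- paste(areas$animal, areas$group)
  rkey <- paste(ref$animal, ref$group)
  r <- ref$area[match(key, rkey)]
  if (anyNA(r)) stop("animal(s) missing the pre-injection measurement")
  if (any(r <= 0)) stop("non-positive pre-injection area")
  areas$pct <- 100 * areas$area / r
  agg <- split(areas$pct, list(areas$group, areas$time), drop = TRUE)
  parts <- strsplit(names(agg), "\\.(?=[^.]*$)", perl = TRUE)
  summary <- data.frame(
    group = vapply(parts, `[`, "", 1L),
    time = as.numeric(vapply(parts, `[`, "", 2L)),
    mean = vapply(agg, mean, 0),
    sem = vapply(agg, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_, 0),
    n = vapply(agg, length, 0L), row.names = NULL)
  summary <- summary[order(summary$group, summary$time), ]
  list(records = areas, summary = summary)
}

#' Two-sample comparison (Student's t-test)
#'
#' Classical pooled-variance two-tailed Student's t-test via
#' [stats::t.test()]; Welch's form is available behind `welch = TRUE`.
#' Degenerate inputs (zero pooled variance) are handled explicitly:
#' equal means give p = 1, unequal means give p = 0 with a flag.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @param welch use Welch's unequal-variance form.
#' @return list with `t`, `df`, `p`, and `degenerate` flag.
#' @export
compare_groups <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1,
                  degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}
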