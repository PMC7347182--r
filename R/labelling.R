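# Period labelling: turn event timestamps t1/t2/t3 into the P0-P4 periods
# and attach a label to every 1-Hz feature row.

#' Compute the period boundaries of one test
#'
#' The two self-report anchored intervals are halved (integer-second floor)
#' to form four pain-intensity strata, and a 30-s pre-stimulus baseline is
#' added:
#' \describe{
#'   \item{P0}{`[t0, t1)` with `t0 = t1 - 30` - baseline}
#'   \item{P1}{`[t1, t1split]` with `t1split = t1 + floor((t2 - t1) / 2)`}
#'   \item{P2}{`(t1split, t2)`}
#'   \item{P3}{`[t2, t2split]` with `t2split = t2 + floor((t3 - t2) / 2)`}
#'   \item{P4}{`(t2split, t3]`}
#' }
#'
#' @param t1,t2,t3 Stimulus start, pain threshold and pain tolerance in
#'   seconds from recording start; must satisfy `t1 < t2 < t3`.
#' @param test_id Optional identifier used in error messages.
#' @return A list of class `period_boundaries` with elements `t0`, `t1`,
#'   `t1split`, `t2`, `t2split`, `t3`.
#' @examples
#' compute_periods(0, 10, 20)
#' @export
compute_periods <- function(t1, t2, t3, test_id = NULL) {
  if (!(t1 < t2 && t2 < t3))
    stop("invalid event ordering (need t1 < t2 < t3)",
         if (!is.null(test_id)) paste0(" in test ", test_id) else "")
  structure(list(t0 = t1 - 30,
                 t1 = t1,
                 t1split = t1 + floor((t2 - t1) / 2),
                 t2 = t2,
                 t2split = t2 + floor((t3 - t2) / 2),
                 t3 = t3),
            class = "period_boundaries")
}

#' @export
print.period_boundaries <- function(x, ...) {
  cat(sprintf(
    "<periods: P0=[%g,%g) P1=[%g,%g] P2=(%g,%g) P3=[%g,%g] P4=(%g,%g]>\n",
    x$t0, x$t1, x$t1, x$t1split, x$t1split, x$t2, x$t2, x$t2split,
    x$t2split, x$t3))
  invisible(x)
}

#' Label feature rows by period
#'
#' Assigns each 1-Hz row, identified by its window-start time, to the period
#' whose interval contains it, honouring the exact open/closed endpoints of
#' the period definitions. Times before `t0` or after `t3` fall outside all
#' periods and are returned as `NA` (to be dropped).
#'
#' @param feature_times Numeric vector of window-start times (seconds from
#'   recording start).
#' @param boundaries A [compute_periods()] object.
#' @return An ordered factor with levels `P0 < P1 < P2 < P3 < P4` (`NA` for
#'   out-of-range times).
#' @examples
#' b <- compute_periods(0, 10, 20)
#' label_rows(c(0, 5, 6, 10, 15, 16, 20), b)
#' @export
label_rows <- function(feature_times, boundaries) {
  b <- boundaries
  lab <- rep(NA_character_, length(feature_times))
  tt <- feature_times
  lab[tt >= b$t0 & tt < b$t1] <- "P0"
  lab[tt >= b$t1 & tt <= b$t1split] <- "P1"
  lab[tt > b$t1split & tt < b$t2] <- "P2"
  lab[tt >= b$t2 & tt <= b$t2split] <- "P3"
  lab[tt > b$t2split & tt <= b$t3] <- "P4"
  factor(lab, levels = PERIODS, ordered = TRUE)
}

#' Label and standardize a cohort feature table
#'
#' Attaches period labels to every row, drops rows outside `[t0, t3]`,
#' excludes tests lacking at least one row in each of P1-P4 (logged with a
#' message; none arise under the default generator, whose 8-s duration floor
#' guarantees every period at least two rows), and finally z-scores each
#' feature per test over all retained rows, baseline included.
#'
#' @param features Unstandardized cohort feature table from
#'   [cohort_features()] (or equivalently formatted real data).
#' @param manifest Cohort manifest holding `test_id`, `t1`, `t2`, `t3`.
#' @return A tibble of standardized labelled rows with a `period` column;
#'   the per-test standardization constants are attached as attribute
#'   `"scaling"` and the per-test boundaries as attribute `"boundaries"`.
#' @export
label_features <- function(features, manifest) {
  stopifnot(all(features$test_id %in% manifest$test_id))
  feature_cols <- intersect(FEATURES, names(features))
  pieces <- split(features, features$test_id)
  bounds <- list()
  scaling <- list()
  out <- lapply(names(pieces), function(tid) {
    rows <- pieces[[tid]]
    meta <- manifest[manifest$test_id == tid, ]
    b <- compute_periods(meta$t1, meta$t2, meta$t3, test_id = tid)
    bounds[[tid]] <<- b
    rows$period <- label_rows(rows$time_s, b)
    rows <- rows[!is.na(rows$period), , drop = FALSE]
    pain_counts <- table(factor(rows$period, levels = PERIODS))[-1]
    if (any(pain_counts == 0)) {
      message("excluding test ", tid, ": empty pain period(s) ",
              paste(names(pain_counts)[pain_counts == 0], collapse = ", "))
      return(NULL)
    }
    z <- zscore_standardize(rows, feature_cols)
    scaling[[tid]] <<- list(center = z$center, scale = z$scale)
    z$rows
  })
  res <- dplyr::bind_rows(out)
  attr(res, "boundaries") <- bounds
  attr(res, "scaling") <- scaling
  res
}

#' Period duration summary
#'
#' Mean and SD of each period's length, over all tests and per stimulus type
#' (a numeric companion to the usual bar-chart view of how recording time
#' distributes over P0-P4).
#'
#' @param manifest Cohort manifest (included tests are used).
#' @return A tibble with `group` (`All`, `heat`, `electrical`), `period`,
#'   `mean_s`, `sd_s`.
#' @export
period_duration_summary <- function(manifest) {
  m <- manifest[manifest$included %||% TRUE, , drop = FALSE]
  durs <- lapply(seq_len(nrow(m)), function(i) {
    b <- compute_periods(m$t1[i], m$t2[i], m$t3[i], m$test_id[i])
    tibble::tibble(stimulus_type = m$stimulus_type[i], period = PERIODS,
                   length_s = c(b$t1 - b$t0, b$t1split - b$t1,
                                b$t2 - b$t1split, b$t2split - b$t2,
                                b$t3 - b$t2split))
  })
  durs <- dplyr::bind_rows(durs)
  all <- dplyr::summarise(dplyr::group_by(durs, .data$period),
                          mean_s = mean(.data$length_s),
                          sd_s = sd(.data$length_s), .groups = "drop")
  all$group <- "All"
  by_stim <- dplyr::summarise(
    dplyr::group_by(durs, group = .data$stimulus_type, .data$period),
    mean_s = mean(.data$length_s), sd_s = sd(.data$length_s),
    .groups = "drop")
  dplyr::bind_rows(all, by_stim)[, c("group", "period", "mean_s", "sd_s")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
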