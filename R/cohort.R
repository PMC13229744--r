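# Cohort-level statistics: correlations between gradient metrics and
# conventional indices, paired reproducibility, and target-volume
# subgroup summaries.

#' Pearson and Spearman correlation with two-sided p-values
#'
#' Pearson p-values use the t-distribution transform; Spearman p-values
#' use the exact null distribution for n <= 30 (falling back to the
#' asymptotic approximation when ties prevent it) and the large-sample
#' approximation above.
#'
#' @param x,y paired numeric vectors, length >= 3, no missing values.
#' @return `list(pearson_r =, pearson_p =, spearman_rho =, spearman_p =,
#'   n =)`; a constant series yields `NA` coefficients with a warning and
#'   `attr(, "degenerate") = TRUE`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            !anyNA(x), !anyNA(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series: correlation undefined")
    return(structure(list(pearson_r = NA_real_, pearson_p = NA_real_,
                          spearman_rho = NA_real_, spearman_p = NA_real_,
                          n = length(x)),
                     degenerate = TRUE))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = length(x) <= 30L))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}

#' Mean absolute percentage difference between paired series
#'
#' `mean_i( |a_i - b_i| / ((a_i + b_i)/2) * 100 )`: the symmetric
#' percentage difference used for paired reproducibility analysis.
#' Pairs with zero mean are excluded with a warning.
#'
#' @param a,b paired positive numeric vectors.
#' @return percentage difference (symmetric in `a`, `b`, invariant to a
#'   common rescaling of both series).
#' @export
mapd <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  m <- (a + b) / 2
  bad <- m == 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) with zero mean excluded")
    a <- a[!bad]; b <- b[!bad]; m <- m[!bad]
  }
  if (length(a) == 0L) stop("no pairs with positive mean")
  mean(abs(a - b) / m) * 100
}

#' Subgroup summary by target volume
#'
#' Stratifies case records into bands `[-Inf, b1), [b1, b2), ...,
#' [bk, Inf)` (boundary values belong to the upper band) and reports
#' mean, SD and n of each metric per band.
#'
#' @param records data frame of per-case metrics (see [cohort_analyze()]).
#' @param volume_breaks strictly increasing break points on the grouping
#'   column (default `c(1, 3)`, the classic < 1 cc / 1-3 cc / >= 3 cc
#'   SRS bands when the column is in cc).
#' @param by name of the grouping column (default `"tv_cc"`).
#' @param metrics metric columns to summarise; defaults to all numeric
#'   columns except the grouping column.
#' @return a data frame with one row per (band, metric): `group`, `n`,
#'   `metric`, `mean`, `sd`.
#' @export
subgroup_summary <- function(records, volume_breaks = c(1, 3),
                             by = "tv_cc", metrics = NULL) {
  stopifnot(is.data.frame(records), by %in% names(records),
            all(diff(volume_breaks) > 0))
  if (is.null(metrics)) {
    metrics <- names(records)[vapply(records, is.numeric, logical(1))]
    metrics <- setdiff(metrics, by)
  }
  breaks <- c(-Inf, volume_breaks, Inf)
  labels <- character(length(breaks) - 1L)
  for (i in seq_along(labels)) {
    labels[i] <- if (i == 1L) {
      paste0("<", volume_breaks[1])
    } else if (i == length(labels)) {
      paste0(">=", volume_breaks[length(volume_breaks)])
    } else {
      paste0(volume_breaks[i - 1L], "-", volume_breaks[i])
    }
  }
  band <- cut(records[[by]], breaks = breaks, labels = labels,
              right = FALSE)
  out <- do.call(rbind, lapply(levels(band), function(g) {
    rows <- records[band == g, , drop = FALSE]
    if (nrow(rows) == 0L) {
      return(data.frame(group = g, n = 0L, metric = NA_character_,
                        mean = NA_real_, sd = NA_real_))
    }
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(group = g, n = nrow(rows), metric = m,
                 mean = mean(rows[[m]]), sd = stats::sd(rows[[m]]))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Batch analysis of a case cohort
#'
#' Runs [dgc_analyze()] for every case in a manifest and assembles the
#' per-case metric records. A failing case is skipped with a warning,
#' never aborting the batch.
#'
#' @param manifest a data frame (or path to a CSV) with columns
#'   `case_id`, `dose`, `struct`, and optionally `plan` (file paths).
#' @param out_dir optional directory for the cohort CSVs (`cases.csv`
#'   and `subgroups.csv`).
#' @param ... further arguments passed to [dgc_analyze()]
#'   (`step`, `low_frac`, `surface_method`, ...).
#' @return a data frame of case records (one row per analysed case):
#'   `case_id`, `tv_mm3`, `tv_cc`, `rx_gy`, `ddgi_at_rx_mm`,
#'   `min_ddgi_mm`, `cdgi_50_mm`, `paddick_ci`, `gi`, `r50`,
#'   `grid_spacing_mm`, `delta_d_gy`, `grade`; failed case ids in
#'   `attr(, "failed")`.
#' @export
cohort_analyze <- function(manifest, out_dir = NULL, ...) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(all(c("case_id", "dose", "struct") %in% names(manifest)))
  if (nrow(manifest) == 0L) stop("empty cohort manifest")
  failed <- character()
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    plan <- if ("plan" %in% names(rec) && nzchar(rec$plan %||% "")) {
      rec$plan
    } else NULL
    res <- tryCatch(
      dgc_analyze(rec$dose, rec$struct, plan = plan, ...),
      error = function(e) {
        warning("case ", rec$case_id, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) {
      failed <<- c(failed, as.character(rec$case_id))
      return(NULL)
    }
    data.frame(case_id = rec$case_id,
               tv_mm3 = res$indices$tv_mm3,
               tv_cc = res$indices$tv_mm3 / 1000,
               rx_gy = res$plan_info$rx_gy,
               ddgi_at_rx_mm = res$indices$ddgi_at_rx_mm,
               min_ddgi_mm = res$indices$min_ddgi_mm,
               cdgi_50_mm = res$indices$cdgi_50_mm,
               paddick_ci = res$indices$paddick_ci,
               gi = res$indices$gi,
               r50 = res$indices$r50,
               grid_spacing_mm = max(res$meta$spacing),
               delta_d_gy = res$meta$delta_d,
               grade = res$grading$grade)
  })
  records <- do.call(rbind, rows)
  if (is.null(records)) stop("every case in the cohort failed")
  attr(records, "failed") <- failed
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "cases.csv"),
                     row.names = FALSE)
    utils::write.csv(subgroup_summary(records),
                     file.path(out_dir, "subgroups.csv"), row.names = FALSE)
  }
  records
}
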