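#' Intraclass correlation coefficient ICC(2,1)
#'
#' Repeatability of repeated measurements on the same subjects: the two-way
#' random-effects, absolute-agreement, single-measurement ICC. Subjects (eye
#' x area x slab cells) are rows; the k repeated acquisitions are columns and
#' are treated as exchangeable "raters". From the two-way ANOVA mean squares
#' (MSR between subjects, MSC between acquisitions, MSE residual):
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' with the 95% confidence interval from the F-distribution method of
#' McGraw & Wong.
#'
#' @param m Numeric matrix or data frame, subjects x repeated measurements;
#'   no missing cells, at least 2 subjects and 2 columns.
#' @param conf_level Confidence level for the interval.
#' @return An `icc_result` list: `icc`, `model`, `ci95`, `n_subjects`, `k`,
#'   and the mean squares. Supports [tidy()][generics::tidy] and `glance()`.
#' @examples
#' m <- matrix(rnorm(20, rep(1:5, each = 4)), 5, 4, byrow = TRUE)
#' icc(m)
#' @export
icc <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("measurement matrix has missing cells", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  stopifnot(n >= 2, k >= 2)
  if (var(as.vector(m)) == 0) {
    stop("ICC undefined: zero total variance", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
    outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  # McGraw & Wong (1996) interval for ICC(A,1)
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(
    list(
      icc = est, model = "two_way_random_absolute_single",
      ci95 = c(lo = lo, hi = hi), conf_level = conf_level,
      n_subjects = n, k = k, msr = msr, msc = msc, mse = mse
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) = %.4f  [%.0f%% CI %.4f, %.4f]  (n = %d subjects, k = %d)\n",
    x$icc, 100 * x$conf_level, x$ci95[1], x$ci95[2], x$n_subjects, x$k
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname icc
#' @param x An `icc_result`.
#' @param ... Unused.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$icc, model = x$model,
    conf.low = unname(x$ci95[1]), conf.high = unname(x$ci95[2]),
    n_subjects = x$n_subjects, k = x$k
  )
}

#' @rdname icc
#' @export
glance.icc_result <- function(x, ...) tidy.icc_result(x)

#' Simulate a measurement matrix with a known true ICC
#'
#' Draws from the two-way random-effects model
#' `y_ij = mu + subject_i + column_j + error_ij` with variance components set
#' so that the population ICC(2,1) equals `rho`. Used to validate ICC
#' recovery.
#'
#' @param n_subjects,k Matrix dimensions.
#' @param rho True ICC in \[0, 1).
#' @param sigma_col SD of the column (acquisition) effect.
#' @param total_var Total variance scale.
#' @return A `n_subjects x k` matrix.
#' @export
simulate_icc_matrix <- function(n_subjects, k, rho, sigma_col = 0,
                                total_var = 1) {
  var_col <- sigma_col^2
  var_subj <- rho * (total_var + var_col)
  var_err <- total_var - var_subj
  stopifnot(var_err > 0)
  subj <- rnorm(n_subjects, 0, sqrt(var_subj))
  cols <- rnorm(k, 0, sigma_col)
  outer(subj, rep(1, k)) + outer(rep(1, n_subjects), cols) +
    matrix(rnorm(n_subjects * k, 0, sqrt(var_err)), n_subjects, k)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the two-sided p-value comes
#' from the t approximation `t = rho sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A one-row tibble with `rho`, `statistic`, `p.value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0 || var(y) == 0) {
    stop("Spearman correlation undefined for a constant vector",
      call. = FALSE
    )
  }
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    t_stat <- sign(rho) * Inf
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), n - 2)
  }
  tibble::tibble(rho = rho, statistic = t_stat, p.value = p, n = n)
}

#' Compare two groups of measurements with a t-test
#'
#' Welch's t-test for independent groups (no equal-variance assumption) or a
#' paired t-test. Two-sided. A paired comparison whose differences are all
#' identical is handled as an exact shift: t = 0, p = 1 when the shift is
#' zero, otherwise p = 0.
#'
#' @param a,b Numeric vectors (equal length if `paired`).
#' @param paired Paired comparison?
#' @return A one-row tibble with `statistic`, `p.value`, `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `method`.
#' @export
compare_means <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired) stopifnot(length(a) == length(b))
  base <- tibble::tibble(
    mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
    method = ifelse(paired, "paired t-test", "Welch t-test")
  )
  if (paired && sd(a - b) <= 1e-10 * max(1, abs(mean(a - b)))) {
    shift <- mean(a - b)
    return(dplyr::mutate(base,
      statistic = ifelse(shift == 0, 0, sign(shift) * Inf),
      p.value = ifelse(shift == 0, 1, 0), .before = 1
    ))
  }
  if (!paired && sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(dplyr::mutate(base, statistic = 0, p.value = 1, .before = 1))
    }
    return(dplyr::mutate(base,
      statistic = sign(mean(a) - mean(b)) * Inf,
      p.value = 0, .before = 1
    ))
  }
  tt <- t.test(a, b, paired = paired)
  dplyr::mutate(base,
    statistic = unname(tt$statistic), p.value = tt$p.value,
    .before = 1
  )
}

#' Agreement between two binary graders
#'
#' The agreement rate is the number of identical answers divided by the total
#' number of answers; the Pearson correlation of the two 0/1 vectors is
#' reported alongside (`NA` when either grader is constant).
#'
#' @param g1,g2 Binary (0/1 or logical) vectors of equal length.
#' @return A one-row tibble with `pearson_r`, `agreement_rate`, `n`.
#' @export
grader_agreement <- function(g1, g2) {
  stopifnot(length(g1) == length(g2), length(g1) >= 1)
  g1 <- as.numeric(g1)
  g2 <- as.numeric(g2)
  r <- if (length(g1) >= 2 && sd(g1) > 0 && sd(g2) > 0) {
    cor(g1, g2)
  } else {
    NA_real_
  }
  tibble::tibble(
    pearson_r = r, agreement_rate = mean(g1 == g2), n = length(g1)
  )
}

#' Repeatability report over a measurement cohort
#'
#' Computes one ICC per (eye, scan area, slab) cell from a tidy table of
#' repeated vessel-density measurements, then summarises and compares ICCs
#' across strata (group, scan area, slab) and correlates VD with the
#' acquisition quality index per slab when available.
#'
#' Each cell's measurement matrix has the repeated acquisitions as columns.
#' When the table carries a `box_id` column (per-box VD, the usual case), the
#' grid boxes are the subject rows, so every cell yields its own ICC; with
#' only one VD value per image, cells are pooled per (scan area, slab, group)
#' and eyes become the subject rows.
#'
#' @param vd_tbl Tidy tibble with columns `eye_id`, `scan_area`, `slab`,
#'   `group`, `acquisition`, `vd`, optionally `box_id` and `quality_index`.
#' @return A list of tibbles: `icc_by_cell`, `icc_summary` (mean, sd and
#'   median ICC per stratum level), `comparisons` (Welch t-tests between the
#'   two levels of each stratum with exactly two levels), and
#'   `quality_correlation` (Spearman rho of quality index vs VD per slab, when
#'   the column is present).
#' @export
repeatability_report <- function(vd_tbl) {
  needed <- c("eye_id", "scan_area", "slab", "group", "acquisition", "vd")
  stopifnot(all(needed %in% names(vd_tbl)))
  icc_of <- function(d, subject_col) {
    m <- d |>
      dplyr::select(dplyr::all_of(c(subject_col, "acquisition", "vd"))) |>
      tidyr::pivot_wider(
        names_from = "acquisition", values_from = "vd"
      ) |>
      dplyr::select(-dplyr::all_of(subject_col)) |>
      as.matrix()
    if (nrow(m) < 2 || anyNA(m) || var(as.vector(m)) == 0) {
      return(tibble::tibble(icc = NA_real_, n_subjects = nrow(m)))
    }
    fit <- icc(m)
    tibble::tibble(icc = fit$icc, n_subjects = fit$n_subjects)
  }
  if ("box_id" %in% names(vd_tbl)) {
    icc_cells <- vd_tbl |>
      dplyr::group_by(
        .data$eye_id, .data$scan_area, .data$slab, .data$group
      ) |>
      dplyr::group_modify(~ icc_of(.x, "box_id")) |>
      dplyr::ungroup()
  } else {
    icc_cells <- vd_tbl |>
      dplyr::group_by(.data$scan_area, .data$slab, .data$group) |>
      dplyr::group_modify(~ icc_of(.x, "eye_id")) |>
      dplyr::ungroup()
  }
  strata <- list(
    group = "group", scan_area = "scan_area", slab = "slab"
  )
  summarise_by <- function(col) {
    icc_cells |>
      dplyr::group_by(dplyr::across(dplyr::all_of(col))) |>
      dplyr::summarise(
        mean_icc = mean(.data$icc, na.rm = TRUE),
        sd_icc = sd(.data$icc, na.rm = TRUE),
        median_icc = median(.data$icc, na.rm = TRUE),
        n = sum(!is.na(.data$icc)), .groups = "drop"
      ) |>
      dplyr::mutate(stratum = col, .before = 1) |>
      dplyr::rename(level = dplyr::all_of(col))
  }
  icc_summary <- dplyr::bind_rows(lapply(
    unname(unlist(strata)),
    summarise_by
  ))
  compare_stratum <- function(col) {
    lv <- unique(icc_cells[[col]])
    if (length(lv) != 2) return(NULL)
    a <- icc_cells$icc[icc_cells[[col]] == lv[1]]
    b <- icc_cells$icc[icc_cells[[col]] == lv[2]]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    dplyr::mutate(compare_means(a, b),
      stratum = col, level_a = as.character(lv[1]),
      level_b = as.character(lv[2]), .before = 1
    )
  }
  comparisons <- dplyr::bind_rows(
    purrr::compact(lapply(unname(unlist(strata)), compare_stratum))
  )
  quality_correlation <- NULL
  if ("quality_index" %in% names(vd_tbl) &&
    any(!is.na(vd_tbl$quality_index))) {
    per_image <- vd_tbl |>
      dplyr::filter(!is.na(.data$quality_index)) |>
      dplyr::group_by(
        .data$eye_id, .data$scan_area, .data$slab, .data$acquisition
      ) |>
      dplyr::summarise(
        vd = mean(.data$vd), quality_index = mean(.data$quality_index),
        .groups = "drop"
      )
    quality_correlation <- per_image |>
      dplyr::group_by(.data$slab) |>
      dplyr::group_modify(~ spearman_cor(.x$quality_index, .x$vd)) |>
      dplyr::ungroup()
  }
  list(
    icc_by_cell = icc_cells, icc_summary = icc_summary,
    comparisons = comparisons, quality_correlation = quality_correlation
  )
}
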