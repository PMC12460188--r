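#' Fisher z-transform
#'
#' Maps bounded correlation-like values through `atanh` onto an unbounded
#' scale suitable for parametric testing. Values are clipped to
#' `+-(1 - 1e-7)` first so the transform stays finite.
#'
#' @param values Numeric values with magnitude below 1 (baseline-corrected
#'   coherence terms in this pipeline).
#' @return Transformed values; strictly increasing, odd.
#' @examples
#' fisher_z(0.5) # 0.5493
#' @export
fisher_z <- function(values) {
  if (any(!is.finite(values))) {
    abort("`values` must be finite.", class = "dyadcoh_domain_error")
  }
  atanh(pmin(pmax(values, -1 + 1e-7), 1 - 1e-7))
}

#' Remove outliers by IQR fence, then moment criteria
#'
#' Two-stage removal used before the per-ROI repeated-measures ANOVA. Stage
#' one removes values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Stage two
#' iteratively removes the single most extreme remaining value (largest
#' absolute deviation from the current median) until the sample skewness and
#' excess kurtosis are below their critical magnitudes, or only the floor
#' fraction of values remains. Moments are the classical g1 / g2 statistics
#' (excess kurtosis, normal = 0).
#'
#' @param values Numeric vector (>= 5 values).
#' @param skew_crit,kurt_crit Critical absolute skewness and excess kurtosis.
#' @param floor_frac Minimum fraction of the original sample that must remain.
#' @return A list: `kept` (surviving values), `kept_idx` (their original
#'   positions), `log` (tibble of removals with `index`, `value`, `reason`).
#' @export
remove_outliers <- function(values, skew_crit = 1, kurt_crit = 2,
                            floor_frac = 0.7) {
  if (length(values) < 5) {
    abort("need at least 5 values for outlier screening.", class = "dyadcoh_domain_error")
  }
  idx <- seq_along(values)
  q <- quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fence <- values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
  log <- tibble(
    index = idx[fence], value = values[fence],
    reason = rep("iqr_fence", sum(fence))
  )
  keep <- !fence
  floor_n <- ceiling(floor_frac * length(values))
  moments_ok <- function(v) {
    if (length(v) < 5 || stats::sd(v) == 0) return(TRUE)
    abs(e1071::skewness(v, type = 1)) < skew_crit &&
      abs(e1071::kurtosis(v, type = 1)) < kurt_crit
  }
  while (sum(keep) > floor_n && !moments_ok(values[keep])) {
    v <- values[keep]
    worst <- which(keep)[which.max(abs(v - median(v)))]
    keep[worst] <- FALSE
    log <- bind_rows(log, tibble(
      index = worst, value = values[worst], reason = "moment_criteria"
    ))
  }
  list(kept = values[keep], kept_idx = idx[keep], log = log)
}

#' One-way repeated-measures ANOVA with sphericity diagnostics
#'
#' Within-subject ANOVA across k conditions: partitions the total sum of
#' squares into condition, subject and error components, with
#' `F = MS_cond / MS_error` on `(k - 1, (n - 1)(k - 1))` degrees of freedom.
#' Sphericity is checked with Mauchly's W (chi-square approximation on the
#' covariance of orthonormal condition contrasts); when Mauchly's p falls
#' below `mauchly_alpha`, both degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon estimated from the same contrast covariance.
#'
#' @param data Tibble with columns `dyad_id` (subject), `condition`, `value`;
#'   only complete cases (subjects observed in every condition) enter.
#' @param mauchly_alpha Mauchly p-value threshold that triggers the
#'   Greenhouse-Geisser correction.
#' @return An `rm_anova` object: list with `F`, `df_effect`, `df_error`
#'   (possibly epsilon-corrected), `epsilon`, `mauchly_w`, `mauchly_p`,
#'   `p_value`, `gg_applied`, the SS decomposition (`ss_condition`,
#'   `ss_subject`, `ss_error`, `ss_total`), `n_subjects`, `k`, `means`, and
#'   `degenerate` (zero error variance flag).
#' @export
rm_anova <- function(data, mauchly_alpha = 0.05) {
  stopifnot(all(c("dyad_id", "condition", "value") %in% names(data)))
  wide <- data %>%
    pivot_wider(
      id_cols = "dyad_id", names_from = "condition", values_from = "value"
    )
  Y <- as.matrix(wide[, -1])
  Y <- Y[complete.cases(Y), , drop = FALSE]
  n <- nrow(Y)
  k <- ncol(Y)
  if (n < 5) {
    abort("need at least 5 complete cases.", class = "dyadcoh_domain_error")
  }
  grand <- mean(Y)
  ss_total <- sum((Y - grand)^2)
  ss_subject <- k * sum((rowMeans(Y) - grand)^2)
  ss_condition <- n * sum((colMeans(Y) - grand)^2)
  ss_error <- ss_total - ss_subject - ss_condition
  df_e <- k - 1
  df_r <- (n - 1) * (k - 1)
  ms_cond <- ss_condition / df_e
  ms_err <- ss_error / df_r
  degenerate <- ms_err <= .Machine$double.eps * max(1, ms_cond)
  Fstat <- if (degenerate) Inf else ms_cond / ms_err

  # orthonormal contrasts of the k conditions
  C <- qr.Q(qr(stats::contr.helmert(k)))
  S <- stats::cov(Y %*% C)
  tr <- sum(diag(S))
  W <- det(S) / (tr / (k - 1))^(k - 1)
  W <- min(max(W, 0), 1)
  f_corr <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
  chi2 <- -(n - 1) * f_corr * log(max(W, .Machine$double.xmin))
  df_m <- k * (k - 1) / 2 - 1
  mauchly_p <- pchisq(chi2, df_m, lower.tail = FALSE)
  eps <- tr^2 / ((k - 1) * sum(S^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)

  gg <- !degenerate && is.finite(mauchly_p) && mauchly_p < mauchly_alpha
  df_e_used <- if (gg) eps * df_e else df_e
  df_r_used <- if (gg) eps * df_r else df_r
  p <- if (degenerate) 0 else pf(Fstat, df_e_used, df_r_used, lower.tail = FALSE)

  structure(
    list(
      F = Fstat, df_effect = df_e_used, df_error = df_r_used,
      epsilon = eps, mauchly_w = W, mauchly_p = mauchly_p,
      p_value = p, gg_applied = gg,
      ss_condition = ss_condition, ss_subject = ss_subject,
      ss_error = ss_error, ss_total = ss_total,
      n_subjects = n, k = k,
      means = colMeans(Y), conditions = colnames(Y),
      degenerate = degenerate
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g%s\n",
    x$df_effect, x$df_error, x$F, x$p_value,
    if (x$gg_applied) sprintf(" (GG eps = %.3f)", x$epsilon) else ""
  ))
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(
    term = "condition", statistic = x$F, df = x$df_effect,
    df_error = x$df_error, p.value = x$p_value
  )
}

#' @rdname rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(
    statistic = x$F, p.value = x$p_value, epsilon = x$epsilon,
    mauchly.w = x$mauchly_w, mauchly.p = x$mauchly_p,
    gg.applied = x$gg_applied, n = x$n_subjects, k = x$k,
    degenerate = x$degenerate
  )
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard step-up procedure: with m ordered p-values, reject the largest i
#' with `p(i) <= i q / m` and all smaller. Adjusted values are the monotone
#' BH q-values of [stats::p.adjust()]; the rejection mask equals
#' `q_value <= q`.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param q Target false-discovery rate.
#' @return A tibble with `p`, `q_value`, `reject` (empty for empty input).
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(tibble(p = double(), q_value = double(), reject = logical()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "dyadcoh_domain_error")
  }
  adj <- p.adjust(p, method = "BH")
  tibble(p = p, q_value = adj, reject = !is.na(adj) & adj <= q)
}

#' Post hoc paired contrasts against the cooperation condition
#'
#' For each omnibus-significant ROI, runs two-tailed paired t-tests for the
#' three conceptually interpretable contrasts - cooperation minus solo,
#' cooperation minus communication, cooperation minus competition - and
#' applies Benjamini-Hochberg correction across the whole post hoc family
#' (all contrasts x all significant ROIs jointly; set
#' `family = "per_contrast"` to correct within each contrast instead).
#'
#' @param data Tibble `dyad_id`, `condition`, `roi`, `value` (transformed,
#'   outlier-screened cell values).
#' @param significant_rois ROIs whose omnibus test survived FDR control.
#' @param q Target false-discovery rate for the post hoc family.
#' @param family `"joint"` or `"per_contrast"` correction family.
#' @return Tibble with `roi`, `contrast`, `estimate` (mean paired
#'   difference), `t`, `df`, `p`, `q_value`, `significant`, `direction`.
#'   Contrasts with fewer than 3 complete pairs are skipped.
#' @export
posthoc_cooperation_tests <- function(data, significant_rois, q = 0.05,
                                      family = c("joint", "per_contrast")) {
  family <- match.arg(family)
  others <- c("solo", "communication", "competition")
  rows <- list()
  for (roi in significant_rois) {
    d <- dplyr::filter(data, .data$roi == !!roi)
    coop <- d %>% dplyr::filter(.data$condition == "cooperation")
    for (other in others) {
      oth <- d %>% dplyr::filter(.data$condition == !!other)
      paired <- inner_join(
        coop[, c("dyad_id", "value")], oth[, c("dyad_id", "value")],
        by = "dyad_id", suffix = c("_coop", "_other")
      )
      if (nrow(paired) < 3) next
      diffs <- paired$value_coop - paired$value_other
      if (stats::sd(diffs) == 0) {
        tt <- list(
          statistic = if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf,
          parameter = nrow(paired) - 1,
          p.value = if (mean(diffs) == 0) 1 else 0
        )
      } else {
        ht <- t.test(diffs)
        tt <- list(
          statistic = unname(ht$statistic),
          parameter = unname(ht$parameter), p.value = ht$p.value
        )
      }
      rows[[length(rows) + 1]] <- tibble(
        roi = roi, contrast = paste0("coop-", other),
        estimate = mean(diffs), t = tt$statistic, df = tt$parameter,
        p = tt$p.value
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      roi = integer(), contrast = character(), estimate = double(),
      t = double(), df = double(), p = double(), q_value = double(),
      significant = logical(), direction = integer()
    ))
  }
  out <- list_rbind(rows)
  if (family == "joint") {
    adj <- fdr_bh(out$p, q)
    out$q_value <- adj$q_value
    out$significant <- adj$reject
  } else {
    out <- out %>%
      group_by(.data$contrast) %>%
      mutate(
        q_value = p.adjust(.data$p, "BH"),
        significant = .data$q_value <= q
      ) %>%
      ungroup()
  }
  out$direction <- as.integer(sign(out$estimate))
  out
}

#' Per-ROI omnibus and post hoc inference on corrected coherence
#'
#' The full statistical stage: Fisher z-transforms the baseline-corrected
#' coherence terms, screens outliers per ROI x condition, fits the
#' repeated-measures ANOVA per ROI on complete cases, controls the omnibus
#' tests at FDR `q` across ROIs, and runs the cooperation post hoc contrasts
#' for significant ROIs.
#'
#' @param corrected Corrected coherence table (`dyad_id`, `condition`, `roi`,
#'   `value`).
#' @param q Target false-discovery rate.
#' @param transform Apply the Fisher z-transform first? (`"atanh"`, the
#'   procedure's definition; `"atanh_sqrt"` transforms signed square roots;
#'   `"none"`.)
#' @param skew_crit,kurt_crit,floor_frac Outlier-screening parameters, see
#'   [remove_outliers()].
#' @param mauchly_alpha Sphericity threshold, see [rm_anova()].
#' @param posthoc_family Post hoc FDR family, see
#'   [posthoc_cooperation_tests()].
#' @return A `roi_stats` list: `omnibus` (one row per ROI with F, dfs,
#'   epsilon, Mauchly statistics, p, q, significance), `posthoc`,
#'   `removals` (outlier log), `cells` (the screened, transformed values
#'   used), `q`.
#' @export
roi_stats <- function(corrected, q = 0.05,
                      transform = c("atanh", "atanh_sqrt", "none"),
                      skew_crit = 1, kurt_crit = 2, floor_frac = 0.7,
                      mauchly_alpha = 0.05,
                      posthoc_family = c("joint", "per_contrast")) {
  transform <- match.arg(transform)
  posthoc_family <- match.arg(posthoc_family)
  z <- corrected %>% mutate(value = switch(transform,
    atanh = fisher_z(.data$value),
    atanh_sqrt = sign(.data$value) * fisher_z(sqrt(abs(.data$value))),
    none = .data$value
  ))

  screened <- list()
  removals <- list()
  for (roi in sort(unique(z$roi))) {
    for (cond in unique(z$condition)) {
      cell <- z %>% dplyr::filter(.data$roi == !!roi, .data$condition == !!cond)
      if (nrow(cell) < 5) {
        screened[[length(screened) + 1]] <- cell
        next
      }
      scr <- remove_outliers(cell$value, skew_crit, kurt_crit, floor_frac)
      screened[[length(screened) + 1]] <- cell[scr$kept_idx, ]
      if (nrow(scr$log) > 0) {
        removals[[length(removals) + 1]] <- scr$log %>%
          mutate(
            roi = roi, condition = cond,
            dyad_id = cell$dyad_id[.data$index]
          )
      }
    }
  }
  cells <- list_rbind(screened)
  removal_log <- if (length(removals)) list_rbind(removals) else
    tibble(
      index = integer(), value = double(), reason = character(),
      roi = integer(), condition = character(), dyad_id = integer()
    )

  omnibus <- list_rbind(lapply(sort(unique(cells$roi)), function(roi) {
    d <- dplyr::filter(cells, .data$roi == !!roi)
    n_complete <- d %>%
      dplyr::count(.data$dyad_id) %>%
      dplyr::filter(.data$n == length(unique(cells$condition))) %>%
      nrow()
    if (n_complete < 5) {
      return(tibble(
        roi = roi, F = NA_real_, df_effect = NA_real_, df_error = NA_real_,
        epsilon = NA_real_, mauchly_w = NA_real_, mauchly_p = NA_real_,
        p = NA_real_, n = n_complete, excluded = TRUE
      ))
    }
    a <- rm_anova(d, mauchly_alpha)
    tibble(
      roi = roi, F = a$F, df_effect = a$df_effect, df_error = a$df_error,
      epsilon = a$epsilon, mauchly_w = a$mauchly_w, mauchly_p = a$mauchly_p,
      p = a$p_value, n = a$n_subjects, excluded = FALSE
    )
  }))
  tested <- !is.na(omnibus$p)
  omnibus$q_value <- NA_real_
  omnibus$significant <- FALSE
  if (any(tested)) {
    adj <- fdr_bh(omnibus$p[tested], q)
    omnibus$q_value[tested] <- adj$q_value
    omnibus$significant[tested] <- adj$reject
  }

  posthoc <- posthoc_cooperation_tests(
    cells, omnibus$roi[omnibus$significant], q, posthoc_family
  )

  structure(
    list(
      omnibus = omnibus, posthoc = posthoc, removals = removal_log,
      cells = cells, q = q
    ),
    class = "roi_stats"
  )
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf(
    "<roi_stats> %d ROIs tested, %d significant at FDR q <= %g; %d post hoc rows\n",
    sum(!x$omnibus$excluded), sum(x$omnibus$significant), x$q, nrow(x$posthoc)
  ))
  invisible(x)
}

#' @rdname roi_stats
#' @param x A `roi_stats` object.
#' @param ... Unused.
#' @method tidy roi_stats
#' @export
tidy.roi_stats <- function(x, ...) x$omnibus

#' @rdname roi_stats
#' @method glance roi_stats
#' @export
glance.roi_stats <- function(x, ...) {
  tibble(
    n_rois = nrow(x$omnibus), n_tested = sum(!x$omnibus$excluded),
    n_significant = sum(x$omnibus$significant),
    n_posthoc_significant = sum(x$posthoc$significant),
    n_outliers_removed = nrow(x$removals), q = x$q
  )
}

#' Plot per-ROI omnibus results
#'
#' Bar chart of the omnibus F statistic per ROI, significant ROIs
#' highlighted.
#'
#' @param stats A `roi_stats` object.
#' @return A ggplot object.
#' @export
plot_roi_stats <- function(stats) {
  df <- stats$omnibus %>% dplyr::filter(!.data$excluded)
  ggplot(df, aes(x = factor(.data$roi), y = .data$F, fill = .data$significant)) +
    ggplot2::geom_col() +
    labs(x = "ROI", y = "F", fill = sprintf("q <= %g", stats$q)) +
    theme_minimal()
}
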