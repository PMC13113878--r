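#' @title Statistical layer: outlier removal, group tests, summaries
#' @description The comparisons used on per-ROI metrics and blot
#'   densitometry: ROUT outlier removal at a user FDR, Kruskal-Wallis with
#'   Dunn's post hoc z tests, Welch's unequal-variance t, Brown-Forsythe
#'   and Welch ANOVA, the two-sample Kolmogorov-Smirnov test, and blot
#'   normalization. Group tests that base R provides are delegated to it;
#'   ROUT, Dunn's z and the Brown-Forsythe F* are implemented here.
#' @name sg_stats
#' @keywords internal
NULL

#' Grouped per-ROI (or per-blot) values
#'
#' @param groups Named list of non-empty numeric vectors, one per
#'   condition group. Each element is one technical replicate (one ROI or
#'   one blot lane).
#' @param experiment_n Optional named integer vector: number of
#'   independent experiments per group (the N of the N-vs-n bookkeeping;
#'   group sizes are the n).
#' @return Object of class `grouped_data`.
#' @export
grouped_data <- function(groups, experiment_n = NULL) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    stop("'groups' must be a named list of numeric vectors")
  }
  if (!all(vapply(groups, function(g) is.numeric(g) && length(g) > 0, TRUE))) {
    stop("every group must be a non-empty numeric vector")
  }
  structure(list(groups = lapply(groups, as.numeric),
                 group_n = vapply(groups, length, 0L),
                 experiment_n = experiment_n),
            class = "grouped_data")
}

as_grouped_data <- function(x) {
  if (inherits(x, "grouped_data")) x else grouped_data(x)
}

#' @export
print.grouped_data <- function(x, ...) {
  cat(sprintf("<grouped_data> %d groups: %s\n", length(x$groups),
              paste(sprintf("%s (n=%d)", names(x$groups), x$group_n),
                    collapse = ", ")))
  invisible(x)
}

# robust scale: 68.27th percentile of |residuals| with a small-sample
# degrees-of-freedom correction (one fitted parameter)
robust_sd <- function(res) {
  n <- length(res)
  as.numeric(stats::quantile(abs(res), 0.6827, type = 7)) * n / (n - 1)
}

#' ROUT outlier identification (one-sample)
#'
#' Robust-regression-and-outlier-removal for a location fit: the centre is
#' estimated by iteratively reweighted least squares with Lorentzian
#' weights `1 / (1 + (r / s)^2)`, the robust residual SD `s` is the
#' 68.27th percentile of the absolute residuals (with an `n/(n-1)` df
#' correction), per-point t ratios `|r| / s` are converted to two-sided p
#' values on `n - 1` df, and a false-discovery-rate step-up at rate `Q`
#' is applied scanning from the most extreme residual. Flags are
#' invariant to affine rescaling of the data.
#'
#' @param values Numeric vector, at least 5 values (fewer cannot support
#'   the robust scale estimate).
#' @param Q Desired maximum false-discovery rate, in percent (default 1).
#' @return Logical vector of outlier flags, with attributes `t_ratio`,
#'   `rsdr` and `center`.
#' @examples
#' rout_outliers(c(rnorm(9, 10, 0.1), 100))
#' @export
rout_outliers <- function(values, Q = 1) {
  stopifnot(is.numeric(values), is.numeric(Q), Q > 0, Q < 100)
  n <- length(values)
  if (n < 5) stop("ROUT needs at least 5 values for a robust scale estimate")
  m <- stats::median(values)
  s <- robust_sd(values - m)
  if (s > 0) {
    for (it in 1:100) {
      r <- values - m
      w <- 1 / (1 + (r / s)^2)
      m_new <- sum(w * values) / sum(w)
      s_new <- robust_sd(values - m_new)
      conv <- abs(m_new - m) <= 1e-12 * max(1, abs(m))
      m <- m_new
      if (s_new > 0) s <- s_new
      if (conv) break
    }
  }
  res <- values - m
  out <- logical(n)
  if (s == 0 || all(res == 0)) {
    return(structure(out, t_ratio = rep(0, n), rsdr = s, center = m))
  }
  t_ratio <- abs(res) / s
  p <- 2 * stats::pt(-t_ratio, df = n - 1)
  # FDR step-up: order by decreasing |residual| (increasing p)
  ord <- order(p)
  q <- Q / 100
  thresh <- q * seq_len(n) / n
  below <- p[ord] <= thresh
  if (any(below)) out[ord[seq_len(max(which(below)))]] <- TRUE
  structure(out, t_ratio = t_ratio, rsdr = s, center = m)
}

# apply ROUT per group; returns cleaned grouped_data + removed indices
apply_rout <- function(data, Q) {
  removed <- lapply(data$groups, function(g) {
    if (length(g) >= 5) which(rout_outliers(g, Q)) else integer()
  })
  cleaned <- mapply(function(g, idx) if (length(idx)) g[-idx] else g,
                    data$groups, removed, SIMPLIFY = FALSE)
  if (any(vapply(cleaned, length, 0L) == 0L)) {
    stop("a group is empty after outlier removal")
  }
  list(data = grouped_data(cleaned, data$experiment_n), removed = removed)
}

group_summaries <- function(data) {
  g <- data$groups
  shap <- vapply(g, function(v) {
    if (length(v) >= 3 && length(v) <= 5000 && stats::sd(v) > 0) {
      stats::shapiro.test(v)$p.value
    } else NA_real_
  }, 0)
  data.frame(group = names(g), n = vapply(g, length, 0L),
             mean = vapply(g, mean, 0),
             sem = vapply(g, function(v) stats::sd(v) / sqrt(length(v)), 0),
             shapiro_p = shap, row.names = NULL)
}

new_test_report <- function(test_name, statistic, parameter = NULL,
                            p_value = NULL, comparisons = NULL,
                            summaries = NULL, outliers_removed = NULL,
                            details = list()) {
  structure(list(test_name = test_name, statistic = statistic,
                 parameter = parameter, p_value = p_value,
                 comparisons = comparisons, summaries = summaries,
                 outliers_removed = outliers_removed, details = details),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s\n", x$test_name))
  if (length(x$statistic)) {
    cat("  ", paste(sprintf("%s = %.6g", names(x$statistic), x$statistic),
                    collapse = ", "), "\n", sep = "")
  }
  if (length(x$p_value)) {
    cat("  ", paste(sprintf("p(%s) = %.4g", names(x$p_value) %||% "",
                            x$p_value), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat("  comparisons:\n")
    print(x$comparisons, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$summaries)) {
    cat("  group mean +/- SEM:\n")
    print(x$summaries, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

all_values_equal <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  length(unique(v)) == 1L
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Rank-based H test (tie-corrected, via [stats::kruskal.test()]) followed
#' by Dunn's z tests on mean ranks with a Bonferroni-family adjustment
#' over the compared pairs. The comparison set is either all pairs
#' (default) or each group versus a control group. Identical values across
#' all groups give H = 0 and p = 1 rather than an error.
#'
#' @param data A [grouped_data] (or a named list of numeric vectors), at
#'   least 2 groups with at least 2 values each.
#' @param comparisons `"all"` pairs or `"vs_control"`.
#' @param control Control group name for `comparisons = "vs_control"`
#'   (default: the first group).
#' @param rout_q If non-`NULL`, apply per-group ROUT outlier removal at
#'   this Q (percent) before testing.
#' @return A `test_report` with the H statistic, its chi-square p value,
#'   one row per comparison (z, raw and adjusted p) and per-group
#'   mean +/- SEM summaries.
#' @examples
#' kruskal_wallis_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
kruskal_wallis_dunn <- function(data, comparisons = c("all", "vs_control"),
                                control = NULL, rout_q = NULL) {
  data <- as_grouped_data(data)
  comparisons <- match.arg(comparisons)
  removed <- NULL
  if (!is.null(rout_q)) {
    cl <- apply_rout(data, rout_q)
    data <- cl$data; removed <- cl$removed
  }
  g <- data$groups
  if (length(g) < 2 || any(vapply(g, length, 0L) < 2)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  nm <- names(g)
  pairs <- if (comparisons == "all") {
    utils::combn(nm, 2, simplify = FALSE)
  } else {
    control <- control %||% nm[1]
    if (!control %in% nm) stop("unknown control group: ", control)
    lapply(setdiff(nm, control), function(o) c(control, o))
  }

  if (all_values_equal(g)) {
    comp <- data.frame(group1 = vapply(pairs, `[`, "", 1),
                       group2 = vapply(pairs, `[`, "", 2),
                       z = 0, p_raw = 1, p_adj = 1)
    return(new_test_report("Kruskal-Wallis / Dunn", c(H = 0),
                           c(df = length(g) - 1), c(kruskal_wallis = 1),
                           comp, group_summaries(data), removed))
  }

  values <- unlist(g, use.names = FALSE)
  fac <- factor(rep(nm, vapply(g, length, 0L)), levels = nm)
  kw <- stats::kruskal.test(values, fac)

  # Dunn's z on mean ranks with the tie-corrected variance
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, fac, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sig2 <- N * (N + 1) / 12 - tie_term
  n_i <- vapply(g, length, 0L)
  m <- length(pairs)
  comp <- do.call(rbind, lapply(pairs, function(pr) {
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(sig2 * (1 / n_i[[pr[1]]] + 1 / n_i[[pr[2]]]))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = pr[1], group2 = pr[2], z = z, p_raw = p,
               p_adj = min(1, p * m))
  }))
  new_test_report("Kruskal-Wallis / Dunn",
                  c(H = unname(kw$statistic)),
                  c(df = unname(kw$parameter)),
                  c(kruskal_wallis = kw$p.value),
                  comp, group_summaries(data), removed,
                  details = list(comparisons = comparisons,
                                 adjustment = "Bonferroni (Dunn)"))
}

#' Welch's unequal-variance t test
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param rout_q Optional per-sample ROUT Q (percent) applied first.
#' @return A `test_report` with the t statistic, Welch-Satterthwaite df
#'   and p value. Two constant samples with equal means give t = 0,
#'   p = 1; with different means, p = 0.
#' @export
welch_t <- function(a, b, rout_q = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  removed <- NULL
  if (!is.null(rout_q)) {
    cl <- apply_rout(grouped_data(list(a = a, b = b)), rout_q)
    a <- cl$data$groups$a; b <- cl$data$groups$b; removed <- cl$removed
  }
  data <- grouped_data(list(a = a, b = b))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(new_test_report("Welch's t",
                           c(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf),
                           c(df = length(a) + length(b) - 2),
                           c(welch = if (eq) 1 else 0),
                           summaries = group_summaries(data),
                           outliers_removed = removed))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  new_test_report("Welch's t", c(t = unname(tt$statistic)),
                  c(df = unname(tt$parameter)), c(welch = tt$p.value),
                  summaries = group_summaries(data),
                  outliers_removed = removed)
}

#' Brown-Forsythe and Welch ANOVA
#'
#' Both heteroscedasticity-robust one-way ANOVA statistics: Welch's W
#' (via [stats::oneway.test()] with `var.equal = FALSE`) and the
#' Brown-Forsythe F*, which keeps the ordinary between-group sum of
#' squares but replaces the denominator with `sum((1 - n_i/N) s_i^2)` and
#' uses Satterthwaite degrees of freedom.
#'
#' @param data A [grouped_data] or named list; at least 3 groups with at
#'   least 2 values each.
#' @param rout_q Optional per-group ROUT Q (percent) applied first.
#' @return A `test_report` with both statistics and p values
#'   (`brown_forsythe`, `welch`).
#' @export
brown_forsythe_welch_anova <- function(data, rout_q = NULL) {
  data <- as_grouped_data(data)
  removed <- NULL
  if (!is.null(rout_q)) {
    cl <- apply_rout(data, rout_q)
    data <- cl$data; removed <- cl$removed
  }
  g <- data$groups
  if (length(g) < 3) stop("need >= 3 groups")
  if (any(vapply(g, length, 0L) < 2)) stop("every group needs >= 2 values")

  if (all_values_equal(g)) {
    return(new_test_report("Brown-Forsythe / Welch ANOVA",
                           c(F_star = 0, W = 0), NULL,
                           c(brown_forsythe = 1, welch = 1),
                           summaries = group_summaries(data),
                           outliers_removed = removed))
  }

  n_i <- vapply(g, length, 0)
  N <- sum(n_i)
  mean_i <- vapply(g, mean, 0)
  var_i <- vapply(g, stats::var, 0)
  grand <- sum(n_i * mean_i) / N
  k <- length(g)

  # Brown-Forsythe F*
  num <- sum(n_i * (mean_i - grand)^2)
  den_terms <- (1 - n_i / N) * var_i
  den <- sum(den_terms)
  if (den == 0) {
    f_star <- if (num == 0) 0 else Inf
    p_bf <- if (num == 0) 1 else 0
  } else {
    f_star <- num / den
    c_i <- den_terms / den
    df2 <- 1 / sum(c_i^2 / (n_i - 1))
    p_bf <- stats::pf(f_star, k - 1, df2, lower.tail = FALSE)
  }

  # Welch's W
  if (any(var_i == 0)) {
    w <- NA_real_; p_w <- NA_real_
  } else {
    values <- unlist(g, use.names = FALSE)
    fac <- factor(rep(names(g), n_i), levels = names(g))
    ow <- stats::oneway.test(values ~ fac, var.equal = FALSE)
    w <- unname(ow$statistic); p_w <- ow$p.value
  }

  new_test_report("Brown-Forsythe / Welch ANOVA",
                  c(F_star = f_star, W = w), NULL,
                  c(brown_forsythe = p_bf, welch = p_w),
                  summaries = group_summaries(data),
                  outliers_removed = removed)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param a,b Non-empty numeric samples.
#' @param exact Passed to [stats::ks.test()]; the default chooses the
#'   exact p for small tie-free samples and the asymptotic one otherwise.
#' @return A `test_report` with the D statistic and p value.
#' @export
ks_two_sample <- function(a, b, exact = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 1, length(b) >= 1)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  new_test_report("Kolmogorov-Smirnov (two-sample)",
                  c(D = unname(kt$statistic)), NULL, c(ks = kt$p.value),
                  summaries = group_summaries(grouped_data(list(a = a, b = b))))
}

#' Immunoblot band normalization
#'
#' Densitometry fold change: the band of interest is first normalized to
#' its loading control (beta-Actin or GAPDH) and then to the corresponding
#' vehicle-control lane.
#'
#' @param band,loading_control Treated-lane band and loading-control
#'   intensities (> 0).
#' @param vehicle_band,vehicle_control Vehicle-lane intensities (> 0).
#' @return Fold change `(band/loading_control) / (vehicle_band/vehicle_control)`.
#' @examples
#' normalize_blot(7, 1, 1, 1)  # 7-fold
#' @export
normalize_blot <- function(band, loading_control, vehicle_band, vehicle_control) {
  if (any(c(band, loading_control, vehicle_band, vehicle_control) <= 0)) {
    stop("all band and control intensities must be positive")
  }
  (band / loading_control) / (vehicle_band / vehicle_control)
}
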