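#' Coefficient of variation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; used to
#' quantify the within-session stability of serial instant D/P and Kt
#' determinations.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return CV, percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Paired Student's t test
#'
#' Thin wrapper around [stats::t.test()] (paired, two-tailed) returning
#' a flat result; a zero-variance difference vector is flagged as
#' degenerate instead of erroring.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return List with `t`, `df`, `p` and logical `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = length(d) - 1, p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors (n >= 3, non-degenerate variance).
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

#' Ordinary least-squares linear fit
#'
#' Wraps [stats::lm()]; returns slope, intercept and Pearson r, the
#' quantities reported for instant-vs-balance agreement.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return List with `slope`, `intercept`, `r`.
#' @export
linear_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = pearson_r(x, y))
}

#' One-way ANOVA
#'
#' Standard between/within decomposition via [stats::aov()].
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2 and
#'   at least one with positive variance overall).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::sd(y) == 0) return(list(F = 0, df1 = length(groups) - 1,
                                     df2 = length(y) - length(groups), p = 1))
  a <- summary(stats::aov(y ~ g))[[1]]
  list(F = a[["F value"]][1], df1 = a[["Df"]][1], df2 = a[["Df"]][2],
       p = a[["Pr(>F)"]][1])
}

#' Scheffe post-hoc pairwise comparisons
#'
#' After a one-way ANOVA, pair (i, j) differs at level `alpha` iff
#' `(m_i - m_j)^2 > (k - 1) F_crit(alpha; k-1, N-k) MSE (1/n_i + 1/n_j)`.
#'
#' @param groups List of numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per pair: `group_i`, `group_j`,
#'   `diff`, `crit` (critical difference) and logical `significant`.
#' @export
scheffe_posthoc <- function(groups, alpha = 0.05) {
  k <- length(groups)
  stopifnot(k >= 2, all(lengths(groups) >= 2))
  n <- lengths(groups)
  N <- sum(n)
  m <- vapply(groups, mean, 0)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / (N - k)
  fcrit <- stats::qf(1 - alpha, k - 1, N - k)
  nms <- names(groups)
  if (is.null(nms)) nms <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group_i = nms[pairs[1, ]], group_j = nms[pairs[2, ]],
    diff = m[pairs[1, ]] - m[pairs[2, ]],
    crit = sqrt((k - 1) * fcrit * mse * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]])),
    stringsAsFactors = FALSE
  )
  out$significant <- out$diff^2 > out$crit^2
  rownames(out) <- NULL
  out
}

# Metrics compared instant-vs-balance by paired t within a report.
.paired_metric_map <- list(
  dp = c("dp_inst_mean", "dp_bal"),
  kt = c("kt_inst_l", "kt_bal_l"),
  kt_cor = c("kt_cor_l", "kt_bal_l"),
  q = c("q_inst_mg", "q_bal_mg")
)

#' Build a cohort summary report
#'
#' Summarizes per-session metric rows (from [session_metrics()], and
#' optionally [urea_kinetics()]) by modality arm and solute: mean, SD
#' and n of every metric; paired t tests of the instant-route columns
#' against their balance counterparts within each arm x solute cell;
#' one-way ANOVA (with Scheffe post-hoc) across arms for each
#' solute x metric.  Per-session values are computed first and only
#' then averaged — inputs are never pooled before the metric is formed.
#'
#' @param metrics Data frame from [session_metrics()] rows.
#' @param urea Optional data frame from [urea_kinetics()] rows.
#' @return Object of class `cohort_report`: list with data frames
#'   `summary` (arm, solute, metric, mean, sd, n), `paired` (arm,
#'   solute, comparison, t, df, p), `anova` (solute, metric, F, df1,
#'   df2, p) and `scheffe` (solute, metric, pairwise rows).
#' @export
build_report <- function(metrics, urea = NULL) {
  stopifnot(nrow(metrics) > 0)
  num_cols <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  cells <- split(metrics, list(metrics$modality, metrics$solute), drop = TRUE)
  summ <- do.call(rbind, lapply(cells, function(cell) {
    do.call(rbind, lapply(num_cols, function(cn) {
      v <- cell[[cn]][!is.na(cell[[cn]])]
      data.frame(arm = cell$modality[1], solute = cell$solute[1],
                 metric = cn, mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  paired <- do.call(rbind, lapply(cells, function(cell) {
    do.call(rbind, lapply(names(.paired_metric_map), function(cmp) {
      cols <- .paired_metric_map[[cmp]]
      ok <- !is.na(cell[[cols[1]]]) & !is.na(cell[[cols[2]]])
      if (sum(ok) < 2) return(NULL)
      tt <- paired_t_test(cell[[cols[1]]][ok], cell[[cols[2]]][ok])
      data.frame(arm = cell$modality[1], solute = cell$solute[1],
                 comparison = paste(cols, collapse = " vs "),
                 t = tt$t, df = tt$df, p = tt$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  anova_metrics <- c("dp_inst_mean", "dp_bal", "kt_inst_l", "kt_bal_l",
                     "frac_kt_bal", "frac_kt_inst", "wkt_bal_l")
  an <- NULL; sch <- NULL
  for (s in unique(metrics$solute)) {
    ms <- metrics[metrics$solute == s, ]
    for (cn in intersect(anova_metrics, num_cols)) {
      groups <- split(ms[[cn]][!is.na(ms[[cn]])],
                      ms$modality[!is.na(ms[[cn]])])
      groups <- groups[lengths(groups) >= 2]
      if (length(groups) < 2) next
      av <- one_way_anova(groups)
      an <- rbind(an, data.frame(solute = s, metric = cn, F = av$F,
                                 df1 = av$df1, df2 = av$df2, p = av$p,
                                 stringsAsFactors = FALSE))
      sp <- scheffe_posthoc(groups)
      sp$solute <- s; sp$metric <- cn
      sch <- rbind(sch, sp)
    }
  }
  if (!is.null(urea) && nrow(urea) >= 1) {
    ucells <- split(urea, urea$modality, drop = TRUE)
    # kt_bal_l is already summarized from the metrics rows
    unum <- setdiff(names(urea)[vapply(urea, is.numeric, TRUE)], "kt_bal_l")
    usumm <- do.call(rbind, lapply(ucells, function(cell) {
      do.call(rbind, lapply(unum, function(cn) {
        v <- cell[[cn]][!is.na(cell[[cn]])]
        data.frame(arm = cell$modality[1], solute = "urea", metric = cn,
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                   n = length(v), stringsAsFactors = FALSE)
      }))
    }))
    summ <- rbind(summ, usumm)
  }
  rownames(summ) <- NULL
  if (!is.null(paired)) rownames(paired) <- NULL
  structure(list(summary = summ, paired = paired, anova = an,
                 scheffe = sch), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  arms <- unique(x$summary$arm)
  cat("  arms:", paste(arms, collapse = ", "), "\n")
  key <- x$summary[x$summary$metric %in% c("kt_bal_l", "kt_inst_l"), ]
  for (a in arms) {
    ka <- key[key$arm == a, ]
    cat(sprintf("  %s:\n", a))
    for (s in unique(ka$solute)) {
      kb <- ka[ka$solute == s & ka$metric == "kt_bal_l", ]
      ki <- ka[ka$solute == s & ka$metric == "kt_inst_l", ]
      cat(sprintf("    %-11s Kt_bal %6.1f±%.1f L   Kt_inst %6.1f±%.1f L (n=%d)\n",
                  s, kb$mean, ifelse(is.na(kb$sd), 0, kb$sd),
                  ki$mean, ifelse(is.na(ki$sd), 0, ki$sd), kb$n))
    }
  }
  invisible(x)
}
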