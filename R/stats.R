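#' Endpoint prevalence summary
#'
#' Events, denominator and percentage (one decimal, halves rounded away from
#' zero, the convention used in the published counts: 93/213 -> 43.7).
#'
#' @param events event count, or a cohort data.frame when `endpoint` is given.
#' @param n denominator (ignored when a data.frame is supplied).
#' @param endpoint endpoint column name when `events` is a data.frame.
#' @return One-row data.frame: `endpoint`, `n`, `events`, `percent`.
#' @export
#' @examples
#' summarize_endpoint(93, 213) # 43.7
summarize_endpoint <- function(events, n = NULL, endpoint = NA_character_) {
  if (is.data.frame(events)) {
    tab <- events
    if (!endpoint %in% names(tab)) stop("no endpoint column '", endpoint, "'")
    x <- tab[[endpoint]]
    x <- x[!is.na(x)]
    n <- length(x)
    events <- sum(x)
  }
  if (n < 1) stop("n must be >= 1")
  if (events > n) stop("events cannot exceed n")
  data.frame(endpoint = endpoint, n = as.integer(n), events = as.integer(events),
             percent = round_half_up(100 * events / n, 1),
             stringsAsFactors = FALSE)
}

#' Normality-gated two-group comparison
#'
#' Applies the Shapiro-Wilk test at alpha = 0.05 in each group; if neither
#' rejects, groups are compared by the equal-variance Student's t-test (Welch
#' behind the `welch` flag), otherwise by the two-sided Mann-Whitney U test.
#' Group medians and IQRs are reported regardless of the test used.
#'
#' @param values numeric vector.
#' @param groups binary grouping vector (two levels), same length.
#' @param welch use the Welch t-form when the t-branch is taken.
#' @return One-row data.frame of class `vt_group_test`: `test_used`,
#'   per-group `median`/`q25`/`q75`, `p_value`, `flag`.
#' @export
group_compare <- function(values, groups, welch = FALSE) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  g <- unique(groups)
  if (length(g) != 2L) stop("exactly two groups required")
  x <- values[groups == g[1]]
  y <- values[groups == g[2]]
  if (length(x) < 3L || length(y) < 3L)
    stop("each group needs at least 3 non-missing values")
  flag <- NA_character_
  if (sd(x) == 0 && sd(y) == 0) {
    return(group_test_row("degenerate", x, y, g, p = 1, flag = "zero variance in both groups"))
  }
  normal <- function(v) {
    if (sd(v) == 0) return(FALSE)
    shapiro.test(v)$p.value > 0.05
  }
  if (normal(x) && normal(y)) {
    p <- t.test(x, y, var.equal = !welch)$p.value
    test <- if (welch) "welch_t" else "student_t"
  } else {
    p <- wilcox.test(x, y, exact = FALSE)$p.value
    test <- "mann_whitney_u"
  }
  group_test_row(test, x, y, g, p, flag)
}

group_test_row <- function(test, x, y, g, p, flag) {
  qs <- function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  qx <- qs(x); qy <- qs(y)
  structure(data.frame(
    test_used = test,
    group1 = as.character(g[1]), n1 = length(x),
    median1 = qx[2], q25_1 = qx[1], q75_1 = qx[3],
    group2 = as.character(g[2]), n2 = length(y),
    median2 = qy[2], q25_2 = qy[1], q75_2 = qy[3],
    p_value = p, flag = flag, stringsAsFactors = FALSE),
    class = c("vt_group_test", "data.frame"))
}

adjusters_for <- function(endpoint) {
  base <- c("onset_to_puncture_min", "ivt")
  if (identical(endpoint, "excellent_outcome")) c(base, "age_years", "baseline_mrs")
  else base
}

is_ti_feature <- function(feature) grepl("_ti$", feature)

#' Covariate-adjusted logistic regression for one feature-endpoint pair
#'
#' Fits `endpoint ~ feature + onset_to_puncture_min + ivt` by maximum
#' likelihood (plus `age_years` and `baseline_mrs` when the endpoint is
#' `excellent_outcome`), on complete cases. Tortuosity-index features are
#' multiplied by 10 before fitting, so their adjusted odds ratio reads as the
#' multiplicative odds change per 0.1 TI increment. Reports the Wald 95% CI
#' `exp(beta +/- 1.96 se)` and Wald p-value; a profile-likelihood CI is
#' available behind `profile_ci`.
#'
#' @param table cohort data.frame (see [simulate_cohort()] for columns).
#' @param feature feature column name.
#' @param endpoint binary endpoint column name.
#' @param extra_adjusters additional adjuster columns, appended to the
#'   endpoint-based defaults.
#' @param profile_ci use profile-likelihood instead of Wald intervals.
#' @return An object of class `vt_aor`: one-row data.frame with `feature`,
#'   `endpoint`, `aor`, `ci_low`, `ci_high`, `p_value`, `adjusters`,
#'   `scaling_note`, `n_used`, `converged`.
#' @export
fit_adjusted_logistic <- function(table, feature, endpoint,
                                  extra_adjusters = NULL, profile_ci = FALSE) {
  stopifnot(feature %in% names(table), endpoint %in% names(table))
  adj <- unique(c(adjusters_for(endpoint), extra_adjusters))
  adj <- intersect(adj, names(table))
  cols <- c(endpoint, feature, adj)
  dat <- table[stats::complete.cases(table[, cols]), cols]
  y <- dat[[endpoint]]
  if (!all(y %in% 0:1)) stop("endpoint must be binary 0/1")
  if (length(unique(y)) < 2L) stop("endpoint has a single class; model undefined")
  p_pred <- 1 + length(adj)
  if (nrow(dat) < 10 + 5 * p_pred)
    stop(sprintf("too few complete cases (%d) for %d predictors", nrow(dat), p_pred))
  scaled <- is_ti_feature(feature)
  xname <- feature
  if (scaled) {
    dat[[feature]] <- 10 * dat[[feature]]
  }
  form <- stats::as.formula(paste(endpoint, "~",
                                  paste(c(xname, adj), collapse = " + ")))
  fit <- suppressWarnings(glm(form, data = dat, family = binomial()))
  sm <- summary(fit)$coefficients
  beta <- sm[xname, "Estimate"]
  se <- sm[xname, "Std. Error"]
  # detect quasi-separation: runaway coefficient or exploding SE
  converged <- fit$converged && is.finite(se) && se < 50 && abs(beta) < 50
  if (converged) {
    if (profile_ci) {
      ci <- suppressMessages(suppressWarnings(exp(stats::confint(fit, xname))))
      lo <- ci[1]; hi <- ci[2]
    } else {
      lo <- exp(beta - 1.96 * se)
      hi <- exp(beta + 1.96 * se)
    }
    pv <- sm[xname, "Pr(>|z|)"]
  } else {
    lo <- hi <- pv <- NA_real_
  }
  structure(data.frame(
    feature = feature, endpoint = endpoint,
    aor = exp(beta), ci_low = lo, ci_high = hi, p_value = pv,
    adjusters = paste(adj, collapse = "+"),
    scaling_note = if (scaled) "feature x10 (aOR per 0.1 TI)" else "unscaled",
    n_used = nrow(dat), converged = converged,
    stringsAsFactors = FALSE), class = c("vt_aor", "data.frame"))
}

#' @export
print.vt_aor <- function(x, ...) {
  cat(sprintf("aOR %s ~ %s: %.2f [95%%CI %.2f-%.2f], p = %.3g (n = %d%s)\n",
              x$endpoint, x$feature, x$aor, x$ci_low, x$ci_high, x$p_value,
              x$n_used, if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations with two-sided p-values. Constant
#' columns yield `NA` with a flag.
#'
#' @param table cohort data.frame.
#' @param features columns to correlate (default: the six features).
#' @return A `vt_cormat` list with matrices `r` and `p` and a `flags` vector.
#' @export
correlation_matrix <- function(table, features = feature_columns) {
  stopifnot(all(features %in% names(table)))
  k <- length(features)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(features, features))
  diag(r) <- 1; diag(p) <- 0
  flags <- character(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- table[[features[i]]]; y <- table[[features[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) { flags <- c(flags, sprintf("%s-%s: <3 pairs", features[i], features[j])); next }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      flags <- c(flags, sprintf("%s-%s: constant column", features[i], features[j]))
      next
    }
    ct <- cor.test(x[ok], y[ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, flags = flags), class = "vt_cormat")
}

#' @export
print.vt_cormat <- function(x, ...) {
  cat("Pearson correlation matrix (R):\n")
  print(round(x$r, 3))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Full cohort analysis
#'
#' Runs, for every feature x endpoint pair, the unadjusted normality-gated
#' group comparison and the covariate-adjusted logistic regression; plus
#' per-endpoint prevalence summaries and the feature correlation matrix. No
#' multiple-testing correction is applied (raw p at alpha 0.05). Per-cell
#' failures are recorded and do not abort the run.
#'
#' @param table cohort data.frame.
#' @param features feature columns (default: the six descriptors).
#' @param endpoints endpoint columns (default: the eight endpoints).
#' @param profile_ci,welch flags passed through to the cell analyses.
#' @return A `vt_analysis` bundle: data.frames `adjusted`, `group_tests`,
#'   `endpoint_summaries`, the `correlations` matrix object, and `failures`.
#' @export
run_full_analysis <- function(table, features = feature_columns,
                              endpoints = intersect(endpoint_columns, names(table)),
                              profile_ci = FALSE, welch = FALSE) {
  adjusted <- list(); gtests <- list(); failures <- list()
  for (ep in endpoints) for (f in features) {
    key <- paste(f, ep, sep = ":")
    res <- tryCatch(fit_adjusted_logistic(table, f, ep, profile_ci = profile_ci),
                    error = function(e) e)
    if (inherits(res, "error")) failures[[paste0("aor:", key)]] <- conditionMessage(res)
    else adjusted[[key]] <- as.data.frame(res)
    gt <- tryCatch({
      cbind(data.frame(feature = f, endpoint = ep, stringsAsFactors = FALSE),
            as.data.frame(group_compare(table[[f]], table[[ep]], welch = welch)))
    }, error = function(e) e)
    if (inherits(gt, "error")) failures[[paste0("group:", key)]] <- conditionMessage(gt)
    else gtests[[key]] <- gt
  }
  summaries <- do.call(rbind, lapply(endpoints, function(ep)
    summarize_endpoint(table, endpoint = ep)))
  structure(list(
    adjusted = do.call(rbind, c(adjusted, list(make.row.names = FALSE))),
    group_tests = do.call(rbind, c(gtests, list(make.row.names = FALSE))),
    endpoint_summaries = summaries,
    correlations = correlation_matrix(table, features),
    failures = failures
  ), class = "vt_analysis")
}

#' @export
print.vt_analysis <- function(x, ...) {
  cat(sprintf("<vt_analysis: %d adjusted models, %d group tests, %d endpoints, %d failures>\n",
              NROW(x$adjusted), NROW(x$group_tests),
              NROW(x$endpoint_summaries), length(x$failures)))
  sig <- x$adjusted[!is.na(x$adjusted$p_value) & x$adjusted$p_value < 0.05, ]
  if (nrow(sig)) {
    cat("significant adjusted associations (p < 0.05):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s ~ %s: aOR %.2f [%.2f-%.2f], p = %.3f\n",
                  sig$endpoint[i], sig$feature[i], sig$aor[i],
                  sig$ci_low[i], sig$ci_high[i], sig$p_value[i]))
  }
  invisible(x)
}

#' Write a full-analysis bundle to disk
#'
#' Flat CSVs (`adjusted_results.csv`, `group_tests.csv`, `correlations.csv`,
#' `endpoint_summaries.csv`) plus the whole bundle as `results.json`.
#'
#' @param bundle a `vt_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(bundle, dir) {
  stopifnot(inherits(bundle, "vt_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$adjusted, file.path(dir, "adjusted_results.csv"), row.names = FALSE)
  write.csv(bundle$group_tests, file.path(dir, "group_tests.csv"), row.names = FALSE)
  write.csv(bundle$endpoint_summaries, file.path(dir, "endpoint_summaries.csv"),
            row.names = FALSE)
  cm <- as.data.frame(as.table(bundle$correlations$r))
  names(cm) <- c("feature_a", "feature_b", "r")
  cm$p <- as.vector(bundle$correlations$p)
  write.csv(cm, file.path(dir, "correlations.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(adjusted = bundle$adjusted, group_tests = bundle$group_tests,
         endpoint_summaries = bundle$endpoint_summaries,
         correlations = list(r = bundle$correlations$r, p = bundle$correlations$p),
         failures = bundle$failures),
    file.path(dir, "results.json"), dataframe = "rows", matrix = "rowmajor",
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
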