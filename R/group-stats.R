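#' Classify abdominal obesity from waist-hip ratio
#'
#' Sex-specific waist-hip ratio (WHR) rule: males with WHR strictly above
#' 0.9 and females strictly above 0.85 are classified as abdominal obesity;
#' everyone else as non-abdominal. Boundary values are non-abdominal.
#'
#' @param sex Character vector; accepted tokens `male`/`female`/`M`/`F`
#'   (case-insensitive).
#' @param whr Positive waist-hip ratios, same length as `sex`.
#' @return Character vector of `"abdominal"` / `"non_abdominal"`.
#' @export
#' @examples
#' classify_whr(c("male", "female", "M"), c(0.98, 0.79, 0.90))
classify_whr <- function(sex, whr) {
  sex <- normalize_sex(sex)
  if (length(sex) != length(whr)) stop_invalid("`sex` and `whr` lengths differ")
  if (any(!is.finite(whr)) || any(whr <= 0)) stop_invalid("`whr` must be positive")
  cutoff <- ifelse(sex == "male", 0.9, 0.85)
  ifelse(whr > cutoff, "abdominal", "non_abdominal")
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- dplyr::case_match(s, c("m", "male") ~ "male", c("f", "female") ~ "female")
  if (anyNA(out)) {
    stop_invalid(sprintf("unknown sex token(s): %s",
                         paste(unique(sex[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Standard step-up adjustment: with p-values sorted ascending,
#' q_(i) = min over j >= i of m p_(j) / j, capped at 1. Rejection uses the
#' strict rule q < alpha.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param alpha Significance level in (0, 1).
#' @return A list with `q` (adjusted values) and `reject` (logical flags).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) stop_invalid("`pvalues` must be non-empty")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop_invalid("p-values must lie in (0, 1]")
  }
  check_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  if (alpha >= 1) stop_invalid("`alpha` must be < 1")
  q <- p.adjust(pvalues, method = "BH")
  list(q = q, reject = q < alpha)
}

#' Permutation test for group differences in degree centrality
#'
#' Per node, the observed statistic is the difference in group mean DC
#' (group 1 minus group 2). The null distribution is built by randomly
#' reassigning subjects to groups (preserving group sizes); the two-sided
#' p-value is (1 + #\{|null| >= |observed|\}) / (1 + n_perm), so p is never
#' exactly zero. P-values are then corrected across nodes with
#' Benjamini-Hochberg FDR.
#'
#' @param dc Numeric matrix or data frame of DC values, subjects in rows,
#'   nodes in columns. Nodes containing missing values are dropped with a
#'   warning.
#' @param labels Group label per subject (exactly two distinct groups).
#' @param n_perm Number of permutations (default 5000).
#' @param alpha FDR level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return A `permutation_result`: tibble with columns `node`,
#'   `observed_diff`, `p`, `q`, `significant`; test settings are attached
#'   as attributes.
#' @export
permutation_test_dc <- function(dc, labels, n_perm = 5000L, alpha = 0.05,
                                seed = 1L) {
  x <- as.matrix(as.data.frame(dc))
  if (!is.numeric(x)) stop_invalid("`dc` must be numeric")
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop_invalid("`labels` length must match rows of `dc`")
  groups <- sort(unique(labels), decreasing = TRUE) # abdominal before non_abdominal
  if ("abdominal" %in% groups) groups <- c("abdominal", setdiff(groups, "abdominal"))
  if (length(groups) != 2L) {
    stop_invalid(sprintf("need exactly 2 groups, got %d", length(groups)))
  }
  if (min(table(labels)) < 2L) stop_invalid("need at least 2 subjects per group")
  keep <- !apply(x, 2L, anyNA)
  if (!all(keep)) {
    warn(sprintf("dropping %d node(s) with missing DC values", sum(!keep)))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) stop_invalid("no nodes left after dropping missing values")
  nodes <- colnames(x)
  if (is.null(nodes)) nodes <- default_labels(ncol(x))

  g1 <- labels == groups[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  tot <- colSums(x)
  obs <- colSums(x[g1, , drop = FALSE]) / n1 - colSums(x[!g1, , drop = FALSE]) / n2
  set.seed(stage_seed(seed, "permutation"))
  exceed <- numeric(ncol(x))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    s1 <- colSums(x[idx, , drop = FALSE])
    d <- s1 / n1 - (tot - s1) / n2
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  p <- (1 + exceed) / (1 + n_perm)
  fdr <- bh_fdr(p, alpha)
  out <- tibble::tibble(node = nodes, observed_diff = unname(obs),
                        p = unname(p), q = fdr$q, significant = fdr$reject)
  attr(out, "groups") <- groups
  attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha
  attr(out, "n") <- c(n1, n2)
  class(out) <- c("permutation_result", class(out))
  out
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("node", "observed_diff", "p", "q", "significant")])
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x), n_significant = sum(x$significant),
                 n_perm = attr(x, "n_perm"), alpha = attr(x, "alpha"),
                 n_group1 = attr(x, "n")[1], n_group2 = attr(x, "n")[2])
}

#' Plot permutation-test results
#'
#' Observed group differences per node, filled by FDR significance.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$node, y = .data$observed_diff,
                                       fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "group difference in DC",
                  fill = sprintf("q < %.2g", attr(object, "alpha"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' Pearson chi-square statistic without continuity correction, 1 degree of
#' freedom, as used for sex-by-group comparisons in demographic tables.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(69, 47, 83, 75), 2))
chi_square_independence <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L)) {
    stop_invalid("`table` must be a 2x2 matrix")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop_invalid("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_degenerate("all table margins must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Two-sample t-test from summary statistics
#'
#' Reconstructs the two-sided two-sample t-test from group means, standard
#' deviations and sizes, as needed to check printed demographic tables.
#'
#' @param mean1,sd1,n1 Group 1 summaries.
#' @param mean2,sd2,n2 Group 2 summaries.
#' @param variant `"pooled"` (equal variances) or `"welch"`.
#' @return List with `t`, `df`, `p_value`.
#' @export
#' @examples
#' t_test_from_summaries(31.37, 5.01, 152, 29.84, 4.40, 122)
t_test_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  for (v in list(c(sd1, "sd1"), c(sd2, "sd2"))) {
    check_scalar_number(as.numeric(v[1]), v[2], min = 0, strict_min = TRUE)
  }
  n1 <- check_count(n1, "n1", min = 2L)
  n2 <- check_count(n2, "n2", min = 2L)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Demographic group comparisons
#'
#' Table-1-style tests on a subject table: chi-square (no continuity
#' correction) for the sex ratio and two-sample t-tests (pooled by
#' default) for age, BMI, WHR (per sex) and the four EDE-Q subscales.
#'
#' @param subjects Subject tibble with columns `sex`, `age`, `bmi`, `whr`,
#'   `group`, `edeq_r`, `edeq_e`, `edeq_s`, `edeq_w`.
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @return Tibble with one row per comparison: `parameter`, group means,
#'   `statistic`, `p_value`.
#' @export
demographic_tests <- function(subjects, variant = "pooled") {
  g1 <- subjects[subjects$group == "abdominal", ]
  g2 <- subjects[subjects$group == "non_abdominal", ]
  cont <- function(name, col, d1 = g1, d2 = g2) {
    x1 <- d1[[col]]; x2 <- d2[[col]]
    tt <- t_test_from_summaries(mean(x1), sd(x1), length(x1),
                                mean(x2), sd(x2), length(x2), variant)
    tibble::tibble(parameter = name, mean_abdominal = mean(x1),
                   mean_non_abdominal = mean(x2), statistic = tt$t,
                   p_value = tt$p_value)
  }
  sex_tab <- rbind(table(factor(g1$sex, c("male", "female"))),
                   table(factor(g2$sex, c("male", "female"))))
  cs <- chi_square_independence(sex_tab)
  dplyr::bind_rows(
    cont("age", "age"),
    tibble::tibble(parameter = "sex", mean_abdominal = NA, mean_non_abdominal = NA,
                   statistic = cs$statistic, p_value = cs$p_value),
    cont("bmi", "bmi"),
    cont("whr_male", "whr", g1[g1$sex == "male", ], g2[g2$sex == "male", ]),
    cont("whr_female", "whr", g1[g1$sex == "female", ], g2[g2$sex == "female", ]),
    cont("edeq_r", "edeq_r"), cont("edeq_e", "edeq_e"),
    cont("edeq_s", "edeq_s"), cont("edeq_w", "edeq_w")
  )
}

#' Regress eating-disorder scores on degree centrality
#'
#' Ordinary least squares EDE-Q ~ DC(+ DC2 + ...) + age + intercept: the
#' brain-behaviour model with age as a covariate. With several DC columns
#' this is the multimodal variant combining structural and functional
#' centralities.
#'
#' @param edeq Numeric response vector (one EDE-Q subscale).
#' @param dc_predictors Numeric vector, matrix or data frame of per-subject
#'   DC predictors.
#' @param age Numeric age covariate.
#' @return An `edeq_regression` object; see [tidy.edeq_regression()] and
#'   [glance.edeq_regression()].
#' @export
fit_edeq_regression <- function(edeq, dc_predictors, age) {
  bare <- is.null(dim(dc_predictors))
  dcd <- as.data.frame(dc_predictors)
  if (bare || (ncol(dcd) == 1L && is.null(colnames(dc_predictors)))) {
    names(dcd) <- "dc"
  }
  if (!all(vapply(dcd, is.numeric, logical(1)))) {
    stop_invalid("DC predictors must be numeric")
  }
  n <- length(edeq)
  if (nrow(dcd) != n || length(age) != n) {
    stop_invalid("`edeq`, `dc_predictors` and `age` must have equal lengths")
  }
  if (n < ncol(dcd) + 3L) {
    stop_invalid(sprintf("need at least %d observations for %d predictor(s)",
                         ncol(dcd) + 3L, ncol(dcd)))
  }
  df <- cbind(data.frame(.edeq = edeq), dcd, data.frame(age = age))
  df <- df[complete.cases(df), , drop = FALSE]
  mm <- as.matrix(cbind(`(Intercept)` = 1, df[, -1, drop = FALSE]))
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    stop_invalid(sprintf("collinear predictor(s): %s", paste(dropped, collapse = ", ")))
  }
  fit <- lm(.edeq ~ ., data = df)
  structure(list(fit = fit, n = nrow(df), predictors = names(dcd)),
            class = "edeq_regression")
}

#' @export
print.edeq_regression <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<edeq_regression: %d obs, R^2 = %.4f, model p = %.4g>\n",
              x$n, g$r_squared, g$p_model))
  invisible(x)
}

#' Coefficient table for an EDE-Q regression
#'
#' @param x An `edeq_regression`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.edeq_regression <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                 std_error = unname(co[, 2]), statistic = unname(co[, 3]),
                 p_value = unname(co[, 4]))
}

#' Model-level summary for an EDE-Q regression
#'
#' @param x An `edeq_regression`.
#' @param ... Unused.
#' @return One-row tibble with `r_squared`, `adj_r_squared`, `p_model`
#'   (overall F-test) and `n`.
#' @export
glance.edeq_regression <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  p_model <- if (is.null(f)) NA_real_ else unname(pf(f[1], f[2], f[3], lower.tail = FALSE))
  tibble::tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
                 p_model = p_model, n = x$n)
}

#' FDR correction across a family of regressions
#'
#' Benjamini-Hochberg adjustment applied jointly across all rows of a
#' regression-results table — the full family of identified
#' regions/networks crossed with the four EDE-Q subscales.
#'
#' @param results Tibble with one row per (region/network, scale) model.
#' @param p_col Name of the p-value column to correct (default
#'   `"p_model"`).
#' @param alpha FDR level.
#' @return `results` with columns `q` and `significant` appended.
#' @export
correct_regression_family <- function(results, p_col = "p_model", alpha = 0.05) {
  if (!p_col %in% names(results)) {
    stop_invalid(sprintf("column `%s` not found in results", p_col))
  }
  fdr <- bh_fdr(results[[p_col]], alpha)
  results$q <- fdr$q
  results$significant <- fdr$reject
  results
}
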