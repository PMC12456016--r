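#' Negative log10 transform of a p-value
#'
#' `-log10(p)`, which grows as the p-value shrinks; 0 at p = 1, 1.301 at
#' p = 0.05, 3 at p = 0.001.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return `-log10(p)`.
#' @export
neglog10 <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  -log10(p)
}

#' Fold change in a p-value due to contamination
#'
#' The ratio of the contaminated to the clean p-value. Values between 0 and
#' 1 mean the p-value decreased under contamination; values above 1 mean it
#' increased.
#'
#' @param p_contaminated,p_clean P-values from the contaminated and clean
#'   analyses; `p_clean` must be positive.
#' @return `p_contaminated / p_clean`.
#' @export
p_fold_change <- function(p_contaminated, p_clean) {
  if (any(p_clean <= 0)) stop("`p_clean` must be > 0")
  p_contaminated / p_clean
}

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, length >= 3 (at most 5000 values are used;
#'   longer inputs are subsampled deterministically).
#' @return Shapiro-Wilk p-value.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 finite values")
  if (stats::sd(values) == 0) stop("degenerate input: constant values")
  if (length(values) > 5000) {
    values <- values[round(seq(1, length(values), length.out = 5000))]
  }
  stats::shapiro.test(values)$p.value
}

#' Pearson correlation between a design parameter and an outcome
#'
#' Runs a Shapiro-Wilk normality check on the outcome first (attached to the
#' result, with a warning on failure at 0.05 -- the correlation itself is
#' still Pearson, never switched silently), then [stats::cor.test()].
#'
#' @param records Data frame of outcome records.
#' @param x_parameter,y_outcome Column names of the predictor and outcome.
#' @return List of class `correlation_result`: `r`, `p_value`, `n`,
#'   `normality_p`, plus the variable names.
#' @export
correlate <- function(records, x_parameter, y_outcome) {
  x <- records[[x_parameter]]
  y <- records[[y_outcome]]
  if (is.null(x) || is.null(y)) stop("unknown column name")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete records")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant variable")
  }
  norm_p <- tryCatch(normality_check(y), error = function(e) NA_real_)
  if (is.finite(norm_p) && norm_p < 0.05) {
    warning(sprintf("outcome `%s` fails normality (Shapiro-Wilk p = %.3g)",
                    y_outcome, norm_p))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), normality_p = norm_p,
                 x_parameter = x_parameter, y_outcome = y_outcome),
            class = "correlation_result")
}

#' Contaminant count needed to reach an impact criterion
#'
#' Fits ordinary least squares `response = a + b * level` to (contaminant
#' level, response) points and solves for the level at which the fitted line
#' reaches 2 -- either a twofold p-value change (`fold_change_2`) or a
#' change of two significant taxa (`delta_sig_2`). The threshold is
#' `n_star = (2 - a) / b`; it is 0 when the intercept already exceeds the
#' criterion and undefined (NA) when the slope is not positive.
#'
#' @param levels Numeric vector of contaminant levels (>= 2 distinct).
#' @param response Numeric vector: fold changes or `|delta n_significant|`.
#' @param criterion `"fold_change_2"` or `"delta_sig_2"` (label only; the
#'   criterion value is 2 in both cases).
#' @return List of class `threshold_estimate`: `criterion`, `slope`,
#'   `intercept`, `n_star` (NA when undefined).
#' @export
threshold_for_criterion <- function(levels, response,
                                    criterion = c("fold_change_2", "delta_sig_2")) {
  criterion <- match.arg(criterion)
  ok <- is.finite(levels) & is.finite(response)
  levels <- levels[ok]
  response <- response[ok]
  if (length(unique(levels)) < 2) {
    stop("need at least 2 distinct contaminant levels")
  }
  fit <- stats::lm(response ~ levels)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  b_tol <- 1e-10 * max(1, abs(a)) # a numerically zero slope is "no slope"
  n_star <- if (a >= 2) 0 else if (b <= b_tol) NA_real_ else (2 - a) / b
  structure(list(criterion = criterion, slope = b, intercept = a,
                 n_star = n_star, n_points = length(levels)),
            class = "threshold_estimate")
}

#' Categorise false positives induced by contamination
#'
#' A false positive is a taxon significant (q <= alpha) in the contaminated
#' analysis that is either an injected contaminant, or a non-contaminant
#' taxon that was not significant in the clean analysis. The latter are
#' split by their clean q-value into `borderline` (clean q in (0.05, 0.1])
#' and `random` (clean q > 0.1).
#'
#' @param da_clean `da_result` from the matrix without injected rows.
#' @param da_cont `da_result` from the contaminated matrix (same method).
#' @param contaminant_ids Character vector of injected taxon identifiers.
#' @return List of class `fp_breakdown`: per-category counts
#'   (`contaminant`, `borderline`, `random`), `n_false_positive`,
#'   `n_significant` (total significant in the contaminated analysis) and
#'   `fp_proportion` (0 when nothing is significant).
#' @export
classify_false_positives <- function(da_clean, da_cont, contaminant_ids) {
  if (!inherits(da_clean, "da_result") || !inherits(da_cont, "da_result")) {
    stop("expected `da_result` inputs")
  }
  if (!identical(attr(da_clean, "method"), attr(da_cont, "method"))) {
    stop("clean and contaminated results must come from the same method")
  }
  if (any(contaminant_ids %in% da_clean$taxon_id)) {
    stop("clean analysis must not contain injected contaminant taxa")
  }
  sig_cont <- da_cont$taxon_id[da_cont$significant]
  is_contam <- sig_cont %in% contaminant_ids

  clean_q <- stats::setNames(da_clean$q, da_clean$taxon_id)
  noncontam_sig <- sig_cont[!is_contam]
  q0 <- clean_q[noncontam_sig]
  if (any(is.na(q0))) stop("contaminated result contains unknown taxa")
  newly_sig <- noncontam_sig[q0 > 0.05]
  q_new <- q0[q0 > 0.05]

  counts <- c(
    contaminant = sum(is_contam),
    borderline = sum(q_new <= 0.1),
    random = sum(q_new > 0.1)
  )
  n_fp <- sum(counts)
  n_sig <- length(sig_cont)
  structure(list(counts = counts,
                 n_false_positive = n_fp,
                 n_significant = n_sig,
                 fp_proportion = if (n_sig == 0) 0 else n_fp / n_sig),
            class = "fp_breakdown")
}

#' Two-way ANOVA on false-positive proportions
#'
#' Fixed-effects two-way ANOVA (main effects and interaction) of a
#' false-positive proportion against the differential-abundance method and
#' the false-positive category, via [stats::aov()].
#'
#' @param breakdowns Data frame with one row per observation.
#' @param value_col Name of the numeric response column (default
#'   `"proportion"`).
#' @param method_col,category_col Names of the two factor columns.
#' @return Data frame with one row per model term: `term`, `df`, `sum_sq`,
#'   `mean_sq`, `F`, `p`.
#' @export
fp_anova <- function(breakdowns, value_col = "proportion",
                     method_col = "method", category_col = "category") {
  for (cl in c(value_col, method_col, category_col)) {
    if (is.null(breakdowns[[cl]])) stop(sprintf("missing column `%s`", cl))
  }
  dat <- data.frame(
    y = breakdowns[[value_col]],
    method = droplevels(as.factor(breakdowns[[method_col]])),
    category = droplevels(as.factor(breakdowns[[category_col]]))
  )
  if (nlevels(dat$method) < 2 || nlevels(dat$category) < 2) {
    stop("need at least 2 levels per factor")
  }
  if (any(table(dat$method, dat$category) == 0)) {
    stop("empty factor cells")
  }
  fit <- stats::aov(y ~ method * category, data = dat)
  tab <- summary(fit)[[1]]
  data.frame(term = trimws(rownames(tab)),
             df = tab[["Df"]],
             sum_sq = tab[["Sum Sq"]],
             mean_sq = tab[["Mean Sq"]],
             F = tab[["F value"]],
             p = tab[["Pr(>F)"]],
             row.names = NULL, stringsAsFactors = FALSE)
}
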