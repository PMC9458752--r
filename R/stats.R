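# Group statistics as applied to these data: two-sample t (from raw values or
# from printed mean/SEM/n summaries), two-sample Kolmogorov-Smirnov,
# (repeated-measures) two-way ANOVA, Sidak adjustment, the 2.5-SD outlier
# rule, and the Mann-Whitney U test.

.asSummary <- function(x) {
  if (is(x, "GroupSummary")) return(x)
  x <- as.numeric(x)
  if (length(x) < 2L) stop("at least 2 values per group required")
  groupSummary(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}

#' Two-sample t test from raw values or printed summaries
#'
#' Accepts each group either as a numeric vector of raw values or as a
#' [GroupSummary-class] (mean, SEM, n), reconstructing sd = SEM * sqrt(n) in
#' summary mode; the two modes agree exactly when the summaries are computed
#' from the raw values. The default is the pooled-variance Student t
#' (df = n1 + n2 - 2, the integer df convention of the source figures);
#' Welch is available. p values are two-sided.
#'
#' @param a,b numeric vectors or [GroupSummary-class] objects.
#' @param method "pooled" (default) or "welch".
#' @return A [TestResult-class].
#' @examples
#' tTestGroups(groupSummary(165.4, 1.24, 8), groupSummary(136.0, 1.21, 7))
#' @export
tTestGroups <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  a <- .asSummary(a); b <- .asSummary(b)
  s1sq <- (a@sem * sqrt(a@n))^2
  s2sq <- (b@sem * sqrt(b@n))^2
  n1 <- a@n; n2 <- b@n
  if (method == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    lab <- "Two-sample t (pooled)"
  } else {
    se <- sqrt(s1sq / n1 + s2sq / n2)
    df <- se^4 / ((s1sq / n1)^2 / (n1 - 1) + (s2sq / n2)^2 / (n2 - 1))
    lab <- "Welch two-sample t"
  }
  t <- (a@mean - b@mean) / se
  testResult(t, df, 2 * stats::pt(-abs(t), df), lab)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_x - ECDF_y|, with the p value from [stats::ks.test()]
#' (exact for small untied samples, asymptotic otherwise).
#'
#' @param x,y numeric samples (>= 1 value each).
#' @param exact passed to [stats::ks.test()] (default NULL = its small-sample
#'   rule).
#' @return A [TestResult-class]; df is NA.
#' @examples
#' ksTwoSample(c(1, 2), c(1.5, 2.5))  # D = 0.5
#' @export
ksTwoSample <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  testResult(unname(kt$statistic), NA_real_, kt$p.value,
             "Two-sample Kolmogorov-Smirnov")
}

#' Two-way ANOVA with optional repeated measures
#'
#' Main effects and interaction for a two-factor design: a between-subjects
#' factor (e.g. genotype) crossed with a within-subject factor (e.g. current
#' step). With \code{subject} supplied, the between factor is tested against
#' the subject-within-group error stratum (repeated-measures ANOVA); without
#' it, an ordinary two-way ANOVA on all observations. Designs must be
#' complete and crossed per subject.
#'
#' @param values numeric response.
#' @param groupFactor between-subjects factor.
#' @param withinFactor within-subject (or second crossed) factor.
#' @param subject subject identifiers, or NULL for ordinary two-way ANOVA.
#' @return A list of [TestResult-class]: \code{group}, \code{within},
#'   \code{interaction}. Degenerate designs with a zero error term yield an
#'   infinite F and p = 0.
#' @examples
#' d <- expand.grid(g = c("WT", "KO"), s = 1:3, rep = 1:2)
#' twoWayAnova(rnorm(nrow(d)), d$g, d$s)
#' @export
twoWayAnova <- function(values, groupFactor, withinFactor, subject = NULL) {
  g <- factor(groupFactor)
  w <- factor(withinFactor)
  if (length(values) != length(g) || length(values) != length(w))
    stop("values and factors must have equal length")
  if (!is.null(subject)) {
    s <- factor(subject)
    tab <- table(s, w)
    if (any(tab != 1))
      stop("unsupported design: each subject needs exactly one value per ",
           "within-factor level (listwise-complete crossed design required)")
    if (any(rowSums(table(s, g) > 0) != 1))
      stop("unsupported design: each subject must belong to one group")
    d <- data.frame(y = values, g = g, w = w, s = s)
    fit <- stats::aov(y ~ g * w + Error(s), data = d)
    st <- summary(fit)
    between <- st[["Error: s"]][[1]]
    within <- st[["Error: Within"]][[1]]
    gRow <- match("g", trimws(rownames(between)))
    gErr <- match("Residuals", trimws(rownames(between)))
    res <- list(
      group = .anovaRow(between, gRow, gErr, "RM two-way ANOVA: group"),
      within = .anovaRow(within, match("w", trimws(rownames(within))),
                         match("Residuals", trimws(rownames(within))),
                         "RM two-way ANOVA: within"),
      interaction = .anovaRow(within,
                              match("g:w", trimws(rownames(within))),
                              match("Residuals", trimws(rownames(within))),
                              "RM two-way ANOVA: interaction"))
  } else {
    if (any(table(g, w) == 0)) stop("unsupported design: empty cells")
    d <- data.frame(y = values, g = g, w = w)
    hasRep <- any(table(g, w) > 1)
    oneLevel <- nlevels(w) < 2L  # collapsed within factor: one-way ANOVA
    form <- if (oneLevel) y ~ g else if (hasRep) y ~ g * w else y ~ g + w
    fit <- stats::aov(form, data = d)
    st <- summary(fit)[[1]]
    rn <- trimws(rownames(st))
    err <- match("Residuals", rn)
    res <- list(
      group = .anovaRow(st, match("g", rn), err, "Two-way ANOVA: group"),
      within = .anovaRow(st, match("w", rn), err, "Two-way ANOVA: within"),
      interaction = if (hasRep && !oneLevel)
        .anovaRow(st, match("g:w", rn), err, "Two-way ANOVA: interaction")
      else testResult(NA_real_, NA_real_, NA_real_,
                      "Two-way ANOVA: interaction (no replicates)"))
  }
  res
}

.anovaRow <- function(tab, row, errRow, label) {
  if (is.na(row)) return(testResult(NA_real_, NA_real_, NA_real_, label))
  msErr <- tab[errRow, "Mean Sq"]
  ms <- tab[row, "Mean Sq"]
  f <- ms / msErr
  df1 <- tab[row, "Df"]; df2 <- tab[errRow, "Df"]
  # an error term that is zero up to floating-point residue means the effect
  # sits on a noiseless stratum: flag an infinite F rather than a huge one
  if (!is.finite(f) || (ms > 0 && msErr < 1e-12 * ms)) {
    return(testResult(Inf, df1, 0, paste0(label, " (zero error term)")))
  }
  testResult(f, df1, stats::pf(f, df1, df2, lower.tail = FALSE), label)
}

#' Sidak multiple-comparison adjustment
#'
#' p_adj = 1 - (1 - p)^m, clipped to \[0, 1\].
#'
#' @param p p values in \[0, 1\].
#' @param m number of comparisons (default \code{length(p)}).
#' @return Adjusted p values.
#' @examples
#' sidakAdjust(0.01, m = 5)  # ~0.049
#' @export
sidakAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p values must be in [0, 1]")
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' A priori outlier filter (2.5 SD)
#'
#' Single-pass removal of values more than 2.5 standard deviations from the
#' mean, both computed once from the full sample (the criterion is a priori,
#' not iterated). Zero-variance samples yield no removals.
#'
#' @param values numeric vector (>= 3 values).
#' @param sdLimit z-score cutoff (default 2.5).
#' @return A list with \code{kept} (values retained) and \code{removed}
#'   (integer indices removed, possibly empty).
#' @examples
#' outlierFilter(c(rep(0, 9), 100))$removed  # 10
#' @export
outlierFilter <- function(values, sdLimit = 2.5) {
  if (length(values) < 3L) stop("at least 3 values required")
  s <- stats::sd(values)
  if (s == 0) return(list(kept = values, removed = integer(0)))
  z <- abs(values - mean(values)) / s
  removed <- which(z > sdLimit)
  list(kept = if (length(removed)) values[-removed] else values,
       removed = removed)
}

#' Mann-Whitney U test
#'
#' Nonparametric two-sample comparison. The U statistic equals the number of
#' (x, y) pairs with x < y (plus half-ties). Exact p by enumeration (via
#' [stats::wilcox.test()]) when the combined sample is small (n1 + n2 <= 10)
#' and untied; otherwise the tie-corrected normal approximation.
#'
#' @param x,y numeric samples (>= 1 value each).
#' @return A [TestResult-class] with U as the statistic; df is NA.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- (length(x) + length(y)) <= 10 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  testResult(unname(wt$statistic), NA_real_, wt$p.value, "Mann-Whitney U")
}
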