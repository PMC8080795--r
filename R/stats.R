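#' Group summary (n, mean, SD)
#'
#' Printed per-group summaries — the form in which published tables
#' report results — are first-class inputs to the summary-based tests.
#'
#' @param n group size (>= 2).
#' @param mean sample mean.
#' @param sd sample standard deviation (>= 0).
#' @return an object of class \code{GroupSummary}.
#' @export
groupSummary <- function(n, mean, sd) {
  if (!is.numeric(n) || n < 2) stop("group size n must be >= 2")
  if (!is.numeric(sd) || sd < 0) stop("sd must be >= 0")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "GroupSummary")
}

#' @export
print.GroupSummary <- function(x, ...) {
  cat(sprintf("GroupSummary: n = %d, mean = %g, sd = %g\n", x$n, x$mean, x$sd))
  invisible(x)
}

.asGroupSummary <- function(x) {
  if (inherits(x, "GroupSummary")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(groupSummary(x[1], x[2], x[3]))
  stop("expected a GroupSummary or a numeric (n, mean, sd) triple")
}

#' Pooled two-sample Student t test from group summaries
#'
#' The equal-variance (pooled) Student t test computed directly from
#' per-group (n, mean, SD), so tests can be reproduced from published
#' tables.  The statistic is signed as \code{(mean2 - mean1)} in the
#' caller's argument order; the p-value is two-sided from the central t
#' distribution with \code{n1 + n2 - 2} degrees of freedom.
#'
#' @param g1,g2 [groupSummary()] objects (or numeric (n, mean, sd)
#'   triples).
#' @return list of class \code{ttestSummary}: \code{t}, \code{df},
#'   \code{p}, \code{pooledSD}.
#' @examples
#' tTestFromSummary(groupSummary(15, 1.162, 0.076),
#'                  groupSummary(45, 1.253, 0.067))
#' @seealso [tTestPooled()] for raw data.
#' @export
tTestFromSummary <- function(g1, g2) {
  g1 <- .asGroupSummary(g1); g2 <- .asGroupSummary(g2)
  df <- g1$n + g2$n - 2L
  sp <- sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df)
  se <- sp * sqrt(1 / g1$n + 1 / g2$n)
  tstat <- if (se == 0) {
    if (g1$mean == g2$mean) 0 else stop("zero pooled SD with unequal means: t is undefined")
  } else (g2$mean - g1$mean) / se
  structure(list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
                 pooledSD = sp),
            class = "ttestSummary")
}

#' @export
print.ttestSummary <- function(x, ...) {
  cat(sprintf("Pooled two-sample t: t = %.4f, df = %d, p = %.4g (pooled SD %.4g)\n",
              x$t, x$df, x$p, x$pooledSD))
  invisible(x)
}

#' Pooled two-sample Student t test from raw data
#'
#' Computes per-group summaries and delegates to [tTestFromSummary()];
#' the statistic is signed as \code{mean(y) - mean(x)}.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return see [tTestFromSummary()].
#' @export
tTestPooled <- function(x, y) {
  tTestFromSummary(groupSummary(length(x), mean(x), stats::sd(x)),
                   groupSummary(length(y), mean(y), stats::sd(y)))
}

#' Chi-square test of independence
#'
#' Pearson's chi-square on an R x C contingency table with expected
#' counts from the product of the margins; no continuity correction.
#' Rows or columns whose margin is zero carry no information and are
#' dropped with a warning before testing.
#'
#' @param observed numeric matrix of counts (>= 2 rows and columns after
#'   dropping empty margins).
#' @return list of class \code{chisqResult}: \code{chi2}, \code{df},
#'   \code{p}, \code{expected}, \code{observed}.
#' @examples
#' chiSquareIndependence(rbind(FAP = c(12, 3, 0), control = c(34, 9, 2)))
#' @export
chiSquareIndependence <- function(observed) {
  observed <- as.matrix(observed)
  if (length(observed) == 0L || sum(observed) <= 0)
    stop("empty contingency table")
  if (any(observed < 0)) stop("counts must be >= 0")
  keepR <- rowSums(observed) > 0
  keepC <- colSums(observed) > 0
  if (!all(keepR) || !all(keepC)) {
    warning("dropping ", sum(!keepR), " empty row(s) and ",
            sum(!keepC), " empty column(s) from the contingency table")
    observed <- observed[keepR, keepC, drop = FALSE]
  }
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("the contingency table must have at least 2 non-empty rows and columns")
  ht <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  structure(list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, expected = ht$expected, observed = observed),
            class = "chisqResult")
}

#' @export
print.chisqResult <- function(x, ...) {
  cat(sprintf("Chi-square independence: chi2 = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Cohen's d between two groups from summaries
#'
#' Standardized mean difference. The default denominator is the
#' root-mean-square of the two SDs, sqrt((s1^2 + s2^2)/2) — the
#' two-group convention used by the G*Power tool — so published post hoc
#' powers reproduce; the pooled-SD variant is also available.
#'
#' @param g1,g2 [groupSummary()] objects (or (n, mean, sd) triples).
#' @param method "rms" (default) or "pooled".
#' @return nonnegative effect size d.
#' @export
cohensD <- function(g1, g2, method = c("rms", "pooled")) {
  g1 <- .asGroupSummary(g1); g2 <- .asGroupSummary(g2)
  method <- match.arg(method)
  denom <- switch(method,
    rms = sqrt((g1$sd^2 + g2$sd^2) / 2),
    pooled = sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2))
  )
  if (denom == 0) stop("both SDs are zero: effect size is undefined")
  abs(g1$mean - g2$mean) / denom
}

#' Post hoc power of a two-sided two-sample t test
#'
#' Achieved power at the observed effect size via the noncentral t
#' distribution: noncentrality delta = d * sqrt(n1 n2 / (n1 + n2)),
#' critical value the upper alpha/2 quantile of the central t with
#' n1 + n2 - 2 df, and power P(T' > t_crit) + P(T' < -t_crit).
#'
#' @param d nonnegative effect size (see [cohensD()]).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided significance level, in (0, 1); default 0.05.
#' @return list of class \code{powerResult}: \code{d},
#'   \code{noncentrality}, \code{criticalT}, \code{df}, \code{power}.
#' @examples
#' d <- cohensD(groupSummary(15, 1.162, 0.076), groupSummary(45, 1.253, 0.067))
#' posthocPowerT(d, 15, 45)$power  # ~0.987
#' @export
posthocPowerT <- function(d, n1, n2, alpha = 0.05) {
  if (!is.numeric(d) || d < 0) stop("effect size d must be >= 0")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  pow <- stats::pt(tcrit, df, ncp, lower.tail = FALSE) + stats::pt(-tcrit, df, ncp)
  structure(list(d = d, noncentrality = ncp, criticalT = tcrit,
                 df = df, power = pow),
            class = "powerResult")
}

#' @export
print.powerResult <- function(x, ...) {
  cat(sprintf("Post hoc power: d = %.3f, ncp = %.3f, t_crit = %.3f (df %d), power = %.1f%%\n",
              x$d, x$noncentrality, x$criticalT, x$df, 100 * x$power))
  invisible(x)
}

.validRatings <- function(ratings) {
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("at least 2 subjects are required")
  if (ncol(x) < 2L) stop("at least 2 raters/items are required")
  if (anyNA(x)) stop("the ratings matrix must be complete (no missing cells)")
  x
}

## two-way mean squares of a complete subjects x raters grid
.ratingsMS <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  ssr <- k * sum((rowMeans(x) - gm)^2)          # subjects
  ssc <- n * sum((colMeans(x) - gm)^2)          # raters
  sse <- sum((x - outer(rowMeans(x), colMeans(x), `+`) + gm)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation coefficient (two-way models)
#'
#' ICC from the two-way (subjects x raters) ANOVA decomposition, in the
#' Shrout--Fleiss parameterization, with a 95% confidence interval from
#' F-distribution bounds.  "twoWayRandomAbsolute" is ICC(2,1)/ICC(2,k)
#' (raters random, absolute agreement); "twoWayMixedConsistency" is
#' ICC(3,1)/ICC(3,k) (raters fixed, consistency).
#'
#' @param ratings complete numeric matrix, subjects in rows, raters in
#'   columns (>= 2 of each).
#' @param model "twoWayRandomAbsolute" (default) or
#'   "twoWayMixedConsistency".
#' @param unit "single" (default) or "average" measures.
#' @param conf confidence level (default 0.95).
#' @return list of class \code{iccResult}: \code{icc}, \code{lower},
#'   \code{upper}, \code{model}, \code{unit}, \code{n}, \code{k}.
#' @export
iccReliability <- function(ratings,
                           model = c("twoWayRandomAbsolute", "twoWayMixedConsistency"),
                           unit = c("single", "average"),
                           conf = 0.95) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  x <- .validRatings(ratings)
  ms <- .ratingsMS(x)
  n <- ms$n; k <- ms$k
  a <- 1 - conf
  sb <- function(r) r * k / (1 + (k - 1) * r)  # Spearman-Brown step-up

  if (ms$msr == 0 && ms$mse == 0)
    stop("ratings have no variance at all: ICC is undefined")

  if (model == "twoWayMixedConsistency") {
    icc1 <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    if (ms$mse == 0) {
      lo <- hi <- 1
    } else {
      Fobs <- ms$msr / ms$mse
      v <- (n - 1) * (k - 1)
      FL <- Fobs / stats::qf(1 - a / 2, n - 1, v)
      FU <- Fobs * stats::qf(1 - a / 2, v, n - 1)
      lo <- (FL - 1) / (FL + k - 1)
      hi <- (FU - 1) / (FU + k - 1)
    }
  } else {
    icc1 <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    if (ms$mse == 0 && ms$msc == 0) {
      lo <- hi <- 1
    } else {
      ## Satterthwaite df for the ICC(2,1) interval (Shrout & Fleiss)
      Fj <- ms$msc / ms$mse
      num <- (k - 1) * (n - 1) *
        (k * icc1 * Fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
      den <- (n - 1) * k^2 * icc1^2 * Fj^2 +
        (n * (1 + (k - 1) * icc1) - k * icc1)^2
      v <- num / den
      FU <- stats::qf(1 - a / 2, n - 1, v)
      FL <- stats::qf(1 - a / 2, v, n - 1)
      lo <- n * (ms$msr - FU * ms$mse) /
        (FU * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
      hi <- n * (FL * ms$msr - ms$mse) /
        (k * ms$msc + (k * n - k - n) * ms$mse + n * FL * ms$msr)
    }
  }
  if (unit == "average") {
    icc1 <- sb(icc1); lo <- sb(lo); hi <- sb(hi)
  }
  structure(list(icc = icc1, lower = lo, upper = hi, model = model,
                 unit = unit, n = n, k = k, conf = conf),
            class = "iccResult")
}

#' @export
print.iccResult <- function(x, ...) {
  cat(sprintf("ICC (%s, %s): %.4f [%.4f, %.4f] (%d subjects, %d raters)\n",
              x$model, x$unit, x$icc, x$lower, x$upper, x$n, x$k))
  invisible(x)
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of item sums).
#'
#' @param ratings complete numeric matrix, subjects x items (>= 2 items).
#' @return alpha (a single number; 1 for perfectly replicated columns).
#' @export
cronbachAlpha <- function(ratings) {
  x <- .validRatings(ratings)
  k <- ncol(x)
  vt <- stats::var(rowSums(x))
  if (vt == 0) stop("zero total-score variance: alpha is undefined")
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vt)
}

#' Mann-Whitney U test
#'
#' Wilcoxon rank-sum with midrank handling of ties; the null
#' distribution is enumerated exactly for small untied samples (both
#' n <= 20) and otherwise approximated normally with the tie-corrected
#' variance.  Two-sided.
#'
#' @param x,y numeric samples (non-empty).
#' @return list of class \code{mannWhitneyResult}: \code{U} (number of
#'   (x, y) pairs with x < y, counting ties as 1/2), \code{p},
#'   \code{exact}.
#' @export
mannWhitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 20L && length(y) <= 20L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(y, x, exact = exact, correct = FALSE)
  )
  structure(list(U = unname(ht$statistic), p = ht$p.value, exact = exact),
            class = "mannWhitneyResult")
}

#' @export
print.mannWhitneyResult <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, p = %.4g (%s)\n",
              x$U, x$p, if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' Two-factor ANOVA with interaction (Type II sums of squares)
#'
#' Fits \code{value ~ A * B} and tests both main effects and the
#' interaction against the residual mean square, using Type II sums of
#' squares so unbalanced designs (such as an uneven sex x group layout)
#' are handled order-invariantly.
#'
#' @param values numeric outcomes.
#' @param factorA,factorB parallel factors (>= 2 levels each).
#' @return data.frame with one row per term (A, B, A:B, Residuals) and
#'   columns \code{term}, \code{sumsq}, \code{df}, \code{F}, \code{p}.
#' @export
twoWayAnova <- function(values, factorA, factorB) {
  A <- factor(factorA); B <- factor(factorB)
  if (length(values) != length(A) || length(values) != length(B))
    stop("values and both factors must have the same length")
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("each factor must have at least 2 levels")
  fit <- stats::lm(values ~ A * B)
  if (stats::df.residual(fit) < 1L)
    stop("no residual degrees of freedom: the interaction model needs ",
         "more than one observation per cell")
  aa <- car::Anova(fit, type = 2)
  terms <- rownames(aa)
  terms[terms == "A"] <- "factorA"
  terms[terms == "B"] <- "factorB"
  terms[terms == "A:B"] <- "factorA:factorB"
  data.frame(term = terms, sumsq = aa[["Sum Sq"]], df = aa[["Df"]],
             F = aa[["F value"]], p = aa[["Pr(>F)"]],
             row.names = NULL)
}
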