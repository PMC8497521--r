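#' Ordinary least squares with a stable orthogonal decomposition
#'
#' Thin wrapper around the QR path of [stats::lm.fit()] returning
#' estimates, standard errors and the coefficient covariance. Rank
#' deficiency is reported together with the offending columns.
#'
#' @param y response vector.
#' @param X design matrix (include an intercept column if wanted).
#' @return a LinearModelFit list: `coefficients`, `se`, `sigma2` (residual
#'   variance), `df` (`n - rank`), `cov` (coefficient covariance),
#'   `residuals`, `rank`.
#' @export
olsFit <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  fit <- lm.fit(X, y)
  r <- fit$rank
  if (r < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop(sprintf("rank-deficient design: aliased column(s) %s",
                 paste(bad, collapse = ", ")))
  }
  if (n <= r) stop("need more observations than parameters")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - r)
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R[seq_len(r), seq_len(r), drop = FALSE])
  ## undo the QR pivoting
  piv <- fit$qr$pivot[seq_len(r)]
  cov <- matrix(NA_real_, r, r)
  cov[piv, piv] <- XtXinv * sigma2
  dimnames(cov) <- list(colnames(X), colnames(X))
  list(coefficients = fit$coefficients, se = sqrt(diag(cov)),
       sigma2 = sigma2, df = n - r, cov = cov,
       residuals = fit$residuals, rank = r)
}

#' Two-way fixed-effects ANOVA with Type-II sums of squares
#'
#' Main-effect F tests for two crossed factors from nested OLS fits:
#' the sum of squares for each factor is the drop in residual sum of
#' squares when it is added to the model already containing the other
#' factor (Type II), tested against the residual mean square of the
#' additive (or interaction) model. When a factor has fewer than two
#' levels the analysis drops to one-way with a warning. Tukey HSD
#' pairwise comparisons are available for the post-hoc path.
#'
#' @param y response values.
#' @param a,b factors.
#' @param names labels for the two factors in the output.
#' @param interaction include the `a:b` interaction term.
#' @param tukey also return Tukey HSD pairwise comparisons.
#' @return data.frame with one row per term: `term`, `df`, `sumSq`,
#'   `meanSq`, `F`, `p`; residual row last. When `tukey = TRUE`, the HSD
#'   tables are attached as attribute `"tukey"`.
#' @export
twoWayAnova <- function(y, a, b, names = c("A", "B"), interaction = FALSE,
                        tukey = FALSE) {
  a <- factor(a); b <- factor(b)
  stopifnot(length(y) == length(a), length(y) == length(b))
  if (nlevels(a) < 2L && nlevels(b) < 2L)
    stop("both factors are constant: degenerate design")
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    warning("a factor has a single level: dropping to one-way ANOVA")
    f <- if (nlevels(a) >= 2L) a else b
    nm <- if (nlevels(a) >= 2L) names[1] else names[2]
    full <- lm(y ~ f)
    an <- anova(full)
    out <- data.frame(term = c(nm, "residual"), df = an$Df,
                      sumSq = an$`Sum Sq`, meanSq = an$`Mean Sq`,
                      F = an$`F value`, p = an$`Pr(>F)`)
    return(out)
  }
  full <- if (interaction) lm(y ~ a * b) else lm(y ~ a + b)
  rssFull <- sum(resid(full)^2)
  dfFull <- df.residual(full)
  if (dfFull < 1L) stop("no residual degrees of freedom")
  msRes <- rssFull / dfFull
  ## Type II: each factor adjusted for the other (main effects only)
  additive <- if (interaction) lm(y ~ a + b) else full
  rssAdd <- sum(resid(additive)^2)
  ssA <- sum(resid(lm(y ~ b))^2) - rssAdd
  ssB <- sum(resid(lm(y ~ a))^2) - rssAdd
  dfA <- nlevels(a) - 1L
  dfB <- nlevels(b) - 1L
  ## a zero sum of squares means the factor explains nothing: F = 0, p = 1
  ## by convention, even when the residual mean square is also zero
  fRow <- function(term, ss, dfTerm) {
    Fv <- if (ss <= .Machine$double.eps * max(1, rssFull)) 0
          else (ss / dfTerm) / msRes
    data.frame(term = term, df = dfTerm, sumSq = ss, meanSq = ss / dfTerm,
               F = Fv,
               p = if (Fv == 0) 1 else pf(Fv, dfTerm, dfFull, lower.tail = FALSE))
  }
  rows <- list(fRow(names[1], ssA, dfA), fRow(names[2], ssB, dfB))
  if (interaction)
    rows <- c(rows, list(fRow(paste0(names[1], ":", names[2]),
                              rssAdd - rssFull, dfA * dfB)))
  out <- rbind(do.call(rbind, rows),
               data.frame(term = "residual", df = dfFull, sumSq = rssFull,
                          meanSq = msRes, F = NA_real_, p = NA_real_))
  if (tukey) {
    av <- if (interaction) aov(y ~ a * b) else aov(y ~ a + b)
    attr(out, "tukey") <- TukeyHSD(av)
  }
  out
}

#' Random-intercept linear mixed model by REML
#'
#' Fits `y ~ X + (1 | group)` by restricted maximum likelihood via
#' [lme4::lmer()]. At the boundary (between-group variance 0) the fixed
#' effects collapse to the OLS estimates. P-values for fixed effects use
#' a normal approximation on estimate/SE.
#'
#' @param y response vector.
#' @param X design matrix of fixed effects *without* intercept column (an
#'   intercept is always included), or `NULL` for intercept-only.
#' @param group grouping factor for the random intercept.
#' @return a RandomInterceptFit list: `fixef` (data.frame: term, estimate,
#'   se, z, p), `varGroup`, `varResidual`, `nGroups`, `converged`, `fit`.
#' @export
remlRandomIntercept <- function(y, X, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (is.null(X)) {
    dat <- data.frame(.y = y, .g = group)
    form <- .y ~ 1 + (1 | .g)
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    dat <- data.frame(.y = y, X, .g = group)
    form <- as.formula(paste(".y ~", paste(colnames(X), collapse = " + "),
                             "+ (1 | .g)"))
  }
  fit <- lme4::lmer(form, data = dat, REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- fe / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  list(fixef = data.frame(term = names(fe), estimate = unname(fe),
                          se = unname(se), z = unname(z),
                          p = unname(2 * pnorm(-abs(z)))),
       varGroup = vc$vcov[vc$grp == ".g"],
       varResidual = vc$vcov[vc$grp == "Residual"],
       nGroups = nlevels(group), converged = conv, fit = fit)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials (`>= 1`).
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @examples
#' wilsonInterval(5, 10)
#' @export
wilsonInterval <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}
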