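#' Linear discriminant check for persistence bias
#'
#' Tests whether the species that persist at the low feeding level differ
#' systematically in their (z-scored) energy-budget input parameters from
#' those that persist only at the high level. With two groups the
#' discriminant analysis yields a single axis; Wilks' lambda
#' `1 / (1 + theta)` (theta the discriminant eigenvalue) near 1 indicates
#' no separation, i.e. no trait bias in which species drop out. The exact
#' two-group F transform `F = ((1 - W) / W) * (n - p - 1) / p` on
#' `(p, n - p - 1)` degrees of freedom is reported.
#'
#' @param params_matrix numeric matrix of DEB input parameters, rows =
#'   species (will be z-scored).
#' @param groups two-level factor (or vector) of persistence groupings.
#' @return List with `wilks_lambda`, `F`, `df1`, `df2`, `p`, and the
#'   fitted `MASS::lda` object.
#' @export
lda_persistence_check <- function(params_matrix, groups) {
  X <- scale(as.matrix(params_matrix))
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs at least 2 members")
  n <- nrow(X); p <- ncol(X)
  fit <- tryCatch(MASS::lda(X, grouping = g),
                  error = function(e)
                    stop("singular pooled covariance; remove collinear ",
                         "predictors: ", conditionMessage(e)))
  # Wilks' lambda from the between/within decomposition
  Wmat <- matrix(0, p, p)
  Bmat <- matrix(0, p, p)
  gm <- colMeans(X)
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    ci <- scale(Xi, scale = FALSE)
    Wmat <- Wmat + crossprod(ci)
    Bmat <- Bmat + nrow(Xi) * tcrossprod(colMeans(Xi) - gm)
  }
  theta <- max(Re(eigen(solve(Wmat, Bmat), only.values = TRUE)$values))
  W <- 1 / (1 + theta)
  df1 <- p
  df2 <- n - p - 1
  Fstat <- ((1 - W) / W) * df2 / df1
  list(wilks_lambda = W, F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE), lda = fit)
}

#' Linear model of population performance on PC scores
#'
#' Ordinary least squares of a performance measure (population growth rate
#' `lambda` or damping ratio `xi`) on the two retained axis scores and
#' their interaction.
#'
#' @param response numeric response, one value per population.
#' @param scores matrix or data.frame with two columns of axis scores.
#' @return List with `coefficients` (estimate, SE, t, p per term),
#'   `adj_r_squared` (flagged with attribute `"negative"` when < 0), and
#'   the `lm` fit.
#' @export
performance_lm <- function(response, scores) {
  scores <- as.data.frame(scores)
  if (ncol(scores) < 2) stop("need two axis-score columns")
  d <- data.frame(y = response, PC1 = scores[[1]], PC2 = scores[[2]])
  d <- d[stats::complete.cases(d), ]
  fit <- stats::lm(y ~ PC1 * PC2, data = d)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient model matrix")
  sm <- summary(fit)
  adj <- sm$adj.r.squared
  if (is.finite(adj) && adj < 0) attr(adj, "negative") <- TRUE
  list(coefficients = stats::coef(sm), adj_r_squared = adj,
       sigma = sm$sigma, df_residual = fit$df.residual, fit = fit)
}

#' Mixed model of axis scores on a habitat predictor
#'
#' Gaussian linear mixed-effect model with a species random intercept,
#' used because many species contribute two populations (one per feeding
#' level). Reports the fixed-effect F test (Satterthwaite degrees of
#' freedom) and the Nakagawa variance-partition marginal R2 (fixed
#' effects only) and conditional R2 (fixed plus random effects). Falls
#' back to ordinary least squares, with a warning, when the random-effect
#' variance is singular.
#'
#' @param response numeric axis scores per population.
#' @param predictor numeric (e.g. temperature-at-depth) or factor
#'   (e.g. clade) fixed effect.
#' @param species grouping factor for the random intercept.
#' @return List with `F`, `df1`, `df2`, `p`, `marginal_r2`,
#'   `conditional_r2`, and the fit.
#' @export
habitat_mixed_model <- function(response, predictor, species) {
  d <- data.frame(y = response, x = predictor, sp = factor(species))
  d <- d[stats::complete.cases(d), ]
  fit <- suppressMessages(lmerTest::lmer(y ~ x + (1 | sp), data = d,
                                         control = lme4::lmerControl(
                                           check.conv.singular =
                                             lme4::.makeCC(action = "ignore",
                                                           tol = 1e-4))))
  if (lme4::isSingular(fit, tol = 1e-4)) {
    warning("singular random-effect variance; falling back to OLS")
    ols <- stats::lm(y ~ x, data = d)
    an <- stats::anova(ols)
    sm <- summary(ols)
    return(list(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                p = an$`Pr(>F)`[1], marginal_r2 = sm$r.squared,
                conditional_r2 = sm$r.squared, fit = ols, singular = TRUE))
  }
  an <- stats::anova(fit)   # lmerTest: Satterthwaite F test
  vf <- stats::var(stats::predict(fit, re.form = NA))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vr <- sum(vc$vcov[vc$grp != "Residual"])
  ve <- vc$vcov[vc$grp == "Residual"]
  tot <- vf + vr + ve
  list(F = an$`F value`[1], df1 = an$NumDF[1], df2 = an$DenDF[1],
       p = an$`Pr(>F)`[1],
       marginal_r2 = vf / tot, conditional_r2 = (vf + vr) / tot,
       fit = fit, singular = FALSE)
}

#' Ordinal regression of IUCN status on axis scores
#'
#' Proportional-odds logistic regression of the ordered IUCN category
#' (LC < NT < VU < EN < CR; Data Deficient records must be excluded
#' beforehand) on the two axis scores and their interaction. Reports
#' McFadden's pseudo-R2 `1 - residual deviance / null deviance`.
#'
#' @param scores matrix or data.frame with two columns of axis scores.
#' @param iucn ordered factor (or character vector with the standard
#'   category codes).
#' @return List with `coefficients`, `mcfadden_r2`, `deviance`,
#'   `null_deviance`, and the `MASS::polr` fit.
#' @export
iucn_ordinal <- function(scores, iucn) {
  scores <- as.data.frame(scores)
  lev <- c("LC", "NT", "VU", "EN", "CR")
  if (!is.ordered(iucn)) {
    iucn <- as.character(iucn)
    if ("DD" %in% iucn) stop("exclude Data Deficient (DD) records first")
    iucn <- factor(iucn, levels = lev, ordered = TRUE)
  }
  iucn <- droplevels(iucn)
  if (nlevels(iucn) < 3) stop("need at least 3 ordered categories present")
  d <- data.frame(iucn = iucn, PC1 = scores[[1]], PC2 = scores[[2]])
  d <- d[stats::complete.cases(d), ]
  fit <- MASS::polr(iucn ~ PC1 * PC2, data = d, Hess = TRUE)
  null_fit <- MASS::polr(iucn ~ 1, data = d)
  sm <- summary(fit)
  ct <- sm$coefficients[rownames(sm$coefficients) %in%
                          c("PC1", "PC2", "PC1:PC2"), , drop = FALSE]
  pvals <- 2 * stats::pnorm(abs(ct[, "t value"]), lower.tail = FALSE)
  list(coefficients = cbind(ct, `p value` = pvals),
       mcfadden_r2 = 1 - stats::deviance(fit) / stats::deviance(null_fit),
       deviance = stats::deviance(fit),
       null_deviance = stats::deviance(null_fit), fit = fit)
}
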