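# Statistical battery for the movement sense test: normality gating,
# group ANOVA with Bonferroni post-hoc, ROC, Pearson correlation with NDI,
# and test-retest reliability (paired t, ICC(2,k), SEM, MDC).

.OUTCOME_VARS <- c("acuity_pct", "speed_mm_s", "time_s", "norm_acuity_au")

#' Normality gate with Ln transform
#'
#' Shapiro-Wilk test; when the hypothesis of normality is rejected at
#' `alpha` and all values are strictly positive, the natural-log transform
#' is applied (the transformed values are returned for downstream analysis;
#' descriptive tables stay on the raw scale).
#'
#' @param values numeric vector, n >= 3, finite.
#' @param alpha significance level for the gate (default 0.05).
#' @param variable optional variable name carried into the report.
#' @return list with `variable`, `W`, `p_value`, `decision` ("normal" or
#'   "ln_transformed") and `values` (Ln-transformed when gated).
#' @export
shapiroGate <- function(values, alpha = 0.05, variable = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 3 || any(!is.finite(values)))
    .err("invalidInputError", "need >= 3 finite values")
  if (stats::sd(values) == 0)
    .err("degenerateSampleError", "constant input: normality test undefined")
  sw <- stats::shapiro.test(values)
  if (sw$p.value < alpha) {
    if (any(values <= 0))
      .err("transformInfeasibleError",
           "Ln transform requested for non-positive values")
    list(variable = variable, W = unname(sw$statistic), p_value = sw$p.value,
         decision = "ln_transformed", values = log(values))
  } else {
    list(variable = variable, W = unname(sw$statistic), p_value = sw$p.value,
         decision = "normal", values = values)
  }
}

#' One-way group ANOVA with Bonferroni post-hoc
#'
#' Fixed-effects one-way ANOVA across the three groups, followed by pairwise
#' pooled-variance t tests with Bonferroni adjustment (factor = number of
#' pairs, 3 for three groups, capped at 1). Effect size is eta squared
#' (between-group SS over total SS).
#'
#' @param values numeric outcome (already normality-gated if needed).
#' @param groups factor/character of group labels, each group n >= 2.
#' @return list with `F`, `p`, `df`, `eta_squared`, and `posthoc`
#'   (data.frame: group1, group2, p_raw, p_adj).
#' @export
groupAnova <- function(values, groups) {
  groups <- factor(groups)
  n <- table(groups)
  if (any(n < 2))
    .err("insufficientDataError",
         paste("groups with n < 2:", paste(names(n)[n < 2], collapse = ", ")))
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fval <- an[1, "F value"]
  pval <- an[1, "Pr(>F)"]
  eta2 <- an[1, "Sum Sq"] / sum(an[, "Sum Sq"])
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        p_raw = NA_real_, p_adj = NA_real_)
  for (j in seq_len(m)) {
    sel <- groups %in% pairs[, j]
    tt <- stats::t.test(values[sel & groups == pairs[1, j]],
                        values[sel & groups == pairs[2, j]],
                        var.equal = TRUE)
    posthoc$p_raw[j] <- tt$p.value
  }
  posthoc$p_adj <- pmin(1, m * posthoc$p_raw)
  list(F = Fval, p = pval, df = unname(an[, "Df"]),
       eta_squared = eta2, posthoc = posthoc)
}

#' ROC analysis via the rank-sum formulation
#'
#' AUC is computed from the Mann-Whitney U statistic on mid-ranks (ties count
#' one half); its p value uses the normal approximation to U with the
#' standard tie correction. At the supplied cutoff, sensitivity is the
#' fraction of cases on the case side and 1-specificity the fraction of
#' controls on the case side. `direction = "low"` declares that low scores
#' indicate cases (true for NormAcuity: patients score lower), so "case side"
#' means score below the cutoff.
#'
#' @param scores numeric scores.
#' @param labels logical (TRUE = case) or a factor/character vector where
#'   `caseLabel` marks cases.
#' @param direction "low" if low scores indicate cases, "high" otherwise.
#' @param cutoff decision threshold on the score scale (default 2.5, the
#'   NormAcuity cutoff used clinically).
#' @param caseLabel label marking cases when `labels` is not logical.
#' @return list with `auc`, `auc_p`, `cutoff`, `sensitivity`,
#'   `one_minus_specificity`, `n_case`, `n_control`.
#' @export
rocAnalysis <- function(scores, labels, direction = c("low", "high"),
                        cutoff = 2.5, caseLabel = NULL) {
  direction <- match.arg(direction)
  if (!is.logical(labels)) {
    if (is.null(caseLabel))
      .err("invalidLabelsError", "supply logical labels or a caseLabel")
    labels <- labels == caseLabel
  }
  if (!any(labels) || all(labels))
    .err("invalidLabelsError", "both classes must be present")
  if (any(is.na(scores)) || any(is.na(labels)))
    .err("invalidInputError", "scores and labels must be complete")
  s <- if (direction == "low") -scores else scores
  n1 <- sum(labels)          # cases
  n2 <- sum(!labels)         # controls
  r <- rank(s)               # mid-ranks handle ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  # normal approximation to U with tie correction
  U <- auc * n1 * n2
  N <- n1 + n2
  tie <- table(s)
  tieTerm <- sum(tie^3 - tie)
  varU <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  aucP <- if (varU > 0) 2 * stats::pnorm(-abs((U - n1 * n2 / 2) / sqrt(varU))) else NA_real_
  caseSide <- if (direction == "low") scores < cutoff else scores > cutoff
  list(auc = auc, auc_p = aucP, cutoff = cutoff,
       sensitivity = mean(caseSide[labels]),
       one_minus_specificity = mean(caseSide[!labels]),
       n_case = n1, n_control = n2)
}

#' Pearson correlation between NDI and a movement sense variable
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `r`, `p` (two-sided, t-based) and `n`.
#' @export
pearsonWithNdi <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) .err("insufficientDataError", "need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .err("degenerateSampleError", "zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Paired t test for systematic test-retest bias
#'
#' Detects adaptation/learning effects between occasions 1 and 2.
#'
#' @param test1,test2 paired numeric vectors, n >= 2.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
pairedBiasTest <- function(test1, test2) {
  if (length(test1) != length(test2) || length(test1) < 2)
    .err("insufficientDataError", "need paired vectors of length >= 2")
  d <- test2 - test1
  if (stats::sd(d) == 0 && mean(d) != 0)
    .err("degenerateSampleError",
         "zero-variance nonzero differences: t statistic is infinite")
  if (stats::sd(d) == 0)
    return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0))
  tt <- stats::t.test(test2, test1, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d))
}

#' ICC(2,k): two-way random effects, absolute agreement, average measures
#'
#' Point estimate from the mean squares of the two-way decomposition
#' (rows = subjects, columns = occasions):
#' ICC = (MSR - MSE) / (MSR + (MSC - MSE)/n). The 95% CI uses the F-based
#' interval for the single-measure absolute-agreement coefficient followed by
#' the Spearman-Brown step-up to k measures; bounds are clipped to [-1, 1].
#' The interpretation label uses the conventional bands: < 0.5 poor,
#' 0.5-0.75 moderate, 0.75-0.9 good, > 0.9 excellent.
#'
#' @param measurements numeric matrix, subjects x occasions (complete,
#'   >= 3 subjects, >= 2 occasions).
#' @param conf confidence level for the interval (default 0.95).
#' @return list with `icc`, `ci95` (length-2), `interpretation`, and the
#'   mean squares `MSR`, `MSC`, `MSE`.
#' @export
icc2k <- function(measurements, conf = 0.95) {
  m <- as.matrix(measurements)
  if (any(is.na(m))) .err("incompleteMatrixError", "missing cells in the matrix")
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2)
    .err("insufficientDataError", "need >= 3 subjects and >= 2 occasions")
  grand <- mean(m)
  if (stats::sd(as.vector(m)) == 0)
    .err("degenerateSampleError", "zero total variance")
  rowM <- rowMeans(m); colM <- colMeans(m)
  SSR <- k * sum((rowM - grand)^2)
  SSC <- n * sum((colM - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (MSC - MSE) / n)

  # F-based CI for ICC(A,1) (McGraw-Wong), then Spearman-Brown step-up
  alpha <- 1 - conf
  if (MSE <= 0 && MSC <= 0) {   # duplicated occasions: perfect agreement
    return(list(icc = 1, ci95 = c(1, 1), interpretation = "perfect",
                MSR = MSR, MSC = MSC, MSE = MSE))
  }
  r1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  a <- k * r1 / (n * (1 - r1))
  b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  u1 <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  stepUp <- function(r) k * r / (1 + (k - 1) * r)
  ci <- sort(c(stepUp(l1), stepUp(u1)))
  ci <- pmin(1, pmax(-1, ci))
  list(icc = icc, ci95 = ci, interpretation = iccInterpretation(icc),
       MSR = MSR, MSC = MSC, MSE = MSE)
}

#' @rdname icc2k
#' @param icc an ICC value.
#' @export
iccInterpretation <- function(icc) {
  if (icc >= 1) "perfect"
  else if (icc > 0.9) "excellent"
  else if (icc >= 0.75) "good"
  else if (icc >= 0.5) "moderate"
  else "poor"
}

#' Standard error of measurement from test-retest differences
#'
#' SEM = SD(test2 - test1) / sqrt(2) (sample SD, n-1 denominator), computed
#' on untransformed data. Quantifies the random error between trials.
#'
#' @param test1,test2 paired numeric vectors, n >= 2.
#' @return SEM in the units of the variable.
#' @export
semFromDiff <- function(test1, test2) {
  if (length(test1) != length(test2) || length(test1) < 2)
    .err("insufficientDataError", "need paired vectors of length >= 2")
  stats::sd(test2 - test1) / sqrt(2)
}

#' Minimal detectable change from the SEM
#'
#' MDC = SEM x 1.96 x sqrt(2): the smallest change exceeding measurement
#' noise with 95% confidence.
#'
#' @param sem non-negative SEM.
#' @return MDC in the units of the variable.
#' @export
mdcFromSem <- function(sem) {
  if (any(sem < 0)) .err("invalidInputError", "sem must be non-negative")
  sem * 1.96 * sqrt(2)
}

# ---- report assembly -------------------------------------------------------

#' Validity report: group comparison, ROC and NDI correlations
#'
#' For each outcome variable: normality is gated on the pooled group-mean
#' residuals (Ln transform applied to the raw values when rejected), a
#' one-way ANOVA with Bonferroni post-hoc is run on the (possibly
#' transformed) data, and descriptive group means +/- SD are reported
#' untransformed. ROC analyses (cases = pooled patients, and each patient
#' group separately, vs controls) are run on the variables in
#' `rocVariables`; Pearson correlations with NDI are computed per patient
#' group.
#'
#' @param outcomes data.frame with columns `subject_id`, `group` (CON, INP,
#'   TNP), the four outcome variables, and `ndi_pct` (NA for CON).
#' @param alpha normality-gate significance level.
#' @param rocVariables variables to submit to ROC (default NormAcuity).
#' @param cutoff ROC cutoff on the raw score scale.
#' @return object of class `ValidityReport`: per-variable list with
#'   `descriptives`, `normality`, `anova`, plus `roc` and `ndi_correlations`
#'   blocks.
#' @export
validityReport <- function(outcomes, alpha = 0.05,
                           rocVariables = "norm_acuity_au", cutoff = 2.5) {
  if (!"group" %in% names(outcomes))
    .err("invalidInputError", "outcomes must have a 'group' column")
  groups <- factor(outcomes$group, levels = c("CON", "INP", "TNP"))
  if (nlevels(droplevels(groups)) < 2)
    .err("invalidInputError", "need at least two groups")
  perVar <- list()
  for (v in intersect(.OUTCOME_VARS, names(outcomes))) {
    x <- outcomes[[v]]
    resid <- x - stats::ave(x, groups)
    sw <- stats::shapiro.test(resid)
    xa <- x
    decision <- "normal"
    if (sw$p.value < alpha && all(x > 0)) {
      xa <- log(x)
      decision <- "ln_transformed"
    }
    desc <- do.call(rbind, lapply(split(x, groups), function(g)
      data.frame(n = length(g), mean = mean(g), sd = stats::sd(g))))
    desc$group <- rownames(desc)
    perVar[[v]] <- list(
      descriptives = desc[, c("group", "n", "mean", "sd")],
      normality = list(W = unname(sw$statistic), p_value = sw$p.value,
                       decision = decision),
      anova = groupAnova(xa, groups))
  }
  roc <- list()
  isPat <- outcomes$group %in% c("INP", "TNP")
  for (v in intersect(rocVariables, names(outcomes))) {
    roc[[v]] <- list(
      NP_vs_CON = rocAnalysis(outcomes[[v]], isPat, "low", cutoff),
      INP_vs_CON = with(subset(outcomes, group %in% c("INP", "CON")),
        rocAnalysis(get(v), group == "INP", "low", cutoff)),
      TNP_vs_CON = with(subset(outcomes, group %in% c("TNP", "CON")),
        rocAnalysis(get(v), group == "TNP", "low", cutoff)))
  }
  ndi <- list()
  if ("ndi_pct" %in% names(outcomes)) {
    for (g in intersect(c("INP", "TNP"), unique(outcomes$group))) {
      sub <- outcomes[outcomes$group == g, ]
      ndi[[g]] <- lapply(intersect(.OUTCOME_VARS, names(outcomes)),
                         function(v) c(list(variable = v),
                                       pearsonWithNdi(sub$ndi_pct, sub[[v]])))
      names(ndi[[g]]) <- intersect(.OUTCOME_VARS, names(outcomes))
    }
  }
  structure(list(variables = perVar, roc = roc, ndi_correlations = ndi,
                 alpha = alpha, cutoff = cutoff),
            class = "ValidityReport")
}

#' Reliability report: paired t, ICC(2,k), SEM and MDC per variable
#'
#' Occasion tables are matched on `subject_id`. Normality is gated on the
#' pooled two-occasion values; the paired t test and ICC run on Ln data when
#' gated, while descriptives, SEM and MDC stay untransformed (SEM is defined
#' on the raw scale).
#'
#' @param occ1,occ2 data.frames with `subject_id` and the outcome variables,
#'   one row per subject, occasions 1 and 2.
#' @param alpha normality-gate level.
#' @return object of class `ReliabilityReport`: per-variable list with
#'   `mean1`, `sd1`, `mean2`, `sd2`, `paired_p`, `icc`, `icc_ci95`,
#'   `interpretation`, `sem`, `mdc`.
#' @export
reliabilityReport <- function(occ1, occ2, alpha = 0.05) {
  ids <- intersect(occ1$subject_id, occ2$subject_id)
  if (length(ids) < 3)
    .err("insufficientDataError", "need >= 3 subjects present at both occasions")
  a <- occ1[match(ids, occ1$subject_id), ]
  b <- occ2[match(ids, occ2$subject_id), ]
  perVar <- list()
  for (v in intersect(.OUTCOME_VARS, names(a))) {
    x1 <- a[[v]]; x2 <- b[[v]]
    pooled <- c(x1, x2)
    sw <- stats::shapiro.test(pooled)
    useLn <- sw$p.value < alpha && all(pooled > 0)
    y1 <- if (useLn) log(x1) else x1
    y2 <- if (useLn) log(x2) else x2
    icc <- icc2k(cbind(y1, y2))
    sem <- semFromDiff(x1, x2)
    perVar[[v]] <- list(
      mean1 = mean(x1), sd1 = stats::sd(x1),
      mean2 = mean(x2), sd2 = stats::sd(x2),
      ln_transformed = useLn,
      paired_p = pairedBiasTest(y1, y2)$p,
      icc = icc$icc, icc_ci95 = icc$ci95,
      interpretation = icc$interpretation,
      sem = sem, mdc = mdcFromSem(sem))
  }
  structure(list(variables = perVar, n = length(ids), alpha = alpha),
            class = "ReliabilityReport")
}

#' @export
print.ValidityReport <- function(x, ...) {
  cat("Validity report (group comparison / ROC / NDI correlation)\n")
  for (v in names(x$variables)) {
    a <- x$variables[[v]]$anova
    cat(sprintf("  %-15s F=%.3f p=%.4f eta2=%.3f [%s]\n", v, a$F, a$p,
                a$eta_squared, x$variables[[v]]$normality$decision))
  }
  for (v in names(x$roc)) {
    r <- x$roc[[v]]$NP_vs_CON
    cat(sprintf("  ROC %s (NP vs CON): AUC=%.2f p=%.3f, cutoff %.2f: sens=%.2f 1-spec=%.2f\n",
                v, r$auc, r$auc_p, r$cutoff, r$sensitivity,
                r$one_minus_specificity))
  }
  invisible(x)
}

#' @export
print.ReliabilityReport <- function(x, ...) {
  cat(sprintf("Reliability report (n = %d subjects, 2 occasions)\n", x$n))
  for (v in names(x$variables)) {
    r <- x$variables[[v]]
    cat(sprintf("  %-15s ICC=%.3f (%.3f-%.3f, %s)  SEM=%.2f MDC=%.2f  paired p=%.4f\n",
                v, r$icc, r$icc_ci95[1], r$icc_ci95[2], r$interpretation,
                r$sem, r$mdc, r$paired_p))
  }
  invisible(x)
}
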