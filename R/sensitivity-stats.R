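#' Temperature sensitivity of SOS for one site
#'
#' S_T is the slope of the linear regression of normalized SOS anomalies
#' on normalized previous-growing-season predictor anomalies for one site
#' record. Because both sides are z-scored, the slope equals the Pearson
#' correlation of the raw paired series; the back-transformed slope in
#' days per degree C is `slope_norm * SD(SOS) / SD(T_GS)`. Negative S_T
#' means warming in the previous season advances the next spring.
#'
#' @param pairs data.frame from [anomaly_pairs()] (needs `sos_anom`,
#'   `predictor_anom`, `sos_raw`, `predictor_raw`; >= 3 complete rows).
#' @param site_id,species labels carried into the output row.
#' @return one-row data.frame: `site_id, species, slope_norm,
#'   slope_days_per_C, p_value, n_years`.
#' @export
st_regression <- function(pairs, site_id = NA_character_,
                          species = NA_character_) {
  cc <- pairs[is.finite(pairs$sos_anom) & is.finite(pairs$predictor_anom), ,
              drop = FALSE]
  if (nrow(cc) < 3)
    stop("empty-input: need >= 3 complete anomaly pairs", call. = FALSE)
  if (sd(cc$predictor_anom) == 0)
    return(data.frame(site_id = site_id, species = species,
                      slope_norm = NA_real_, slope_days_per_C = NA_real_,
                      p_value = NA_real_, n_years = nrow(cc)))
  fit <- lm(sos_anom ~ predictor_anom, data = cc)
  sm <- summary(fit)$coefficients
  slope <- sm["predictor_anom", "Estimate"]
  data.frame(site_id = site_id, species = species, slope_norm = slope,
             slope_days_per_C = slope * sd(cc$sos_raw) / sd(cc$predictor_raw),
             p_value = sm["predictor_anom", "Pr(>|t|)"], n_years = nrow(cc))
}

#' Mean and t-based 95% confidence interval of site-level slopes
#'
#' Pools site-level regression slopes; the relationship is called
#' significant when the confidence interval excludes zero.
#'
#' @param slopes numeric vector of site-level slopes (>= 3 non-missing).
#' @param conf confidence level (default 0.95).
#' @return list `mean, ci_low, ci_high, n, significant`.
#' @export
slope_ci <- function(slopes, conf = 0.95) {
  s <- slopes[is.finite(slopes)]
  stopifnot(length(s) >= 3)
  m <- mean(s)
  se <- sd(s) / sqrt(length(s))
  tq <- qt(1 - (1 - conf) / 2, df = length(s) - 1)
  ci <- c(m - tq * se, m + tq * se)
  list(mean = m, ci_low = ci[1], ci_high = ci[2], n = length(s),
       significant = ci[1] > 0 || ci[2] < 0)
}

#' Partial correlation with significance test
#'
#' Correlation between `x` and `y` after removing the linear effect of
#' the control variables from both, computed from the inverse of the
#' joint correlation matrix (equivalent to correlating the two residual
#' vectors). Two-sided p-value from the t distribution with
#' `df = n - 2 - n_controls`.
#'
#' @param x,y numeric vectors.
#' @param controls data.frame/matrix of control variables (`NULL` or
#'   zero columns reduces to the Pearson correlation).
#' @return list `r_partial, p_value, df, n, controls`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls) || NCOL(controls) == 0) {
    n <- sum(is.finite(x) & is.finite(y))
    r <- cor(x, y, use = "complete.obs")
    return(pc_result(r, n, 0L, character(0)))
  }
  controls <- as.data.frame(controls)
  cc <- stats::complete.cases(x, y, controls)
  X <- cbind(x = x[cc], y = y[cc], controls[cc, , drop = FALSE])
  consts <- vapply(X, function(v) sd(v) == 0, logical(1))
  if (any(consts[-(1:2)]))
    stop("collinearity: constant control column(s): ",
         paste(names(X)[-(1:2)][consts[-(1:2)]], collapse = ", "), call. = FALSE)
  qrC <- qr(scale(as.matrix(controls[cc, , drop = FALSE])))
  if (qrC$rank < NCOL(controls)) {
    bad <- colnames(controls)[-qrC$pivot[seq_len(qrC$rank)]]
    stop("collinearity: rank-deficient controls: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  R <- cor(X)
  P <- solve(R)
  r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  pc_result(r, nrow(X), NCOL(controls), colnames(controls))
}

pc_result <- function(r, n, k, controls) {
  df <- n - 2L - k
  stopifnot(df > 0)
  tstat <- r * sqrt(df / (1 - r^2))
  list(r_partial = r, p_value = 2 * pt(-abs(tstat), df), df = df, n = n,
       controls = controls)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Tests whether group means (e.g. S_T by species or vegetation type)
#' differ: one-way ANOVA F test, all pairwise Tukey honestly-significant-
#' difference p-values from the studentized range distribution, and a
#' compact letter display in which groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length (>= 2 groups with
#'   >= 2 values each).
#' @param alpha significance level for the letter display (default 0.05).
#' @return list `anova_F, anova_p, tukey` (data.frame pair/diff/p_adj),
#'   `letters` (named character vector per group).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  fit <- aov(values ~ groups)
  ft <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  letters <- compact_letter_display(levels(groups), pairs, alpha)
  list(anova_F = ft["groups", "F value"], anova_p = ft["groups", "Pr(>F)"],
       tukey = pairs, letters = letters)
}

# insert-and-absorb compact letter display over a pairwise significance
# matrix; ties broken by group (input) order
compact_letter_display <- function(group_names, pairs, alpha = 0.05) {
  g <- length(group_names)
  sig <- matrix(FALSE, g, g, dimnames = list(group_names, group_names))
  ab <- strsplit(pairs$pair, "-", fixed = TRUE)
  for (i in seq_len(nrow(pairs))) {
    a <- ab[[i]][1]; b <- ab[[i]][2]
    if (pairs$p_adj[i] < alpha) sig[a, b] <- sig[b, a] <- TRUE
  }
  # columns of `cols` are candidate letters (logical membership vectors)
  cols <- matrix(TRUE, nrow = g, ncol = 1, dimnames = list(group_names, NULL))
  for (a in seq_len(g)) for (b in seq_len(g)) {
    if (b <= a || !sig[a, b]) next
    both <- which(cols[a, ] & cols[b, ])
    for (cl in both) {
      without_a <- cols[, cl]; without_a[a] <- FALSE
      without_b <- cols[, cl]; without_b[b] <- FALSE
      cols[, cl] <- without_a
      cols <- cbind(cols, without_b)
    }
    # absorb: drop columns whose membership is a subset of another's
    keep <- rep(TRUE, ncol(cols))
    for (ci in seq_len(ncol(cols))) for (cj in seq_len(ncol(cols))) {
      if (ci == cj || !keep[ci]) next
      if (all(cols[, ci] <= cols[, cj]) && (any(cols[, ci] < cols[, cj]) || ci > cj))
        keep[ci] <- FALSE
    }
    cols <- cols[, keep, drop = FALSE]
  }
  out <- apply(cols, 1, function(m) paste(letters[which(m)], collapse = ""))
  setNames(out, group_names)
}
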