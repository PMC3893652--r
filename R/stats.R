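#' Build a table of trial records
#'
#' A trial record couples one video trial's design cell (species, stimulus
#' condition) with the estimated embedding dimensionality and the two
#' observer CBM scores. Censored dimensionalities carry the value
#' `d_max + 1`.
#'
#' @param species character/factor of species labels.
#' @param condition integer stimulus count per trial, each in {0, 1, 2}.
#' @param dimensionality integer dimensionalities (>= 1).
#' @param cbm_a,cbm_b integer observer scores in 1..12.
#' @param trial_id optional identifiers (default 1..n).
#' @return data.frame of class `trial_table`.
#' @export
trial_table <- function(species, condition, dimensionality, cbm_a, cbm_b,
                        trial_id = NULL) {
  n <- length(species)
  if (is.null(trial_id)) trial_id <- seq_len(n)
  if (!all(condition %in% 0:2)) stop("condition must be 0, 1, or 2 stimuli")
  if (any(dimensionality < 1)) stop("dimensionality must be >= 1")
  for (s in list(cbm_a, cbm_b)) {
    if (any(s < 1 | s > 12)) stop("CBM scores must lie in 1..12")
  }
  out <- data.frame(trial_id = trial_id, species = as.character(species),
                    condition = as.integer(condition),
                    dimensionality = as.integer(dimensionality),
                    cbm_a = as.integer(cbm_a), cbm_b = as.integer(cbm_b),
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Select the most reliable trials per design cell
#'
#' Within every species x condition cell, keeps the `k` trials with the
#' smallest absolute disagreement between the two observers,
#' `|cbm_a - cbm_b|`; ties are broken by `trial_id` order. This mirrors the
#' protocol of rating ten replicate trials per cell and retaining the three
#' with minimum inter-observer variation for comparison with the embedding
#' analysis.
#'
#' @param trials a data.frame with columns `species`, `condition`, `trial_id`,
#'   `cbm_a`, `cbm_b` (e.g. a [trial_table()]).
#' @param k trials to keep per cell (default 3).
#' @return The selected rows, ordered by species, condition, trial_id.
#' @export
select_reliable_trials <- function(trials, k = 3L) {
  check_scalar(k, "k")
  needed <- c("species", "condition", "trial_id", "cbm_a", "cbm_b")
  if (!all(needed %in% names(trials))) {
    stop("trials must have columns: ", paste(needed, collapse = ", "))
  }
  cells <- split(seq_len(nrow(trials)),
                 list(trials$species, trials$condition), drop = TRUE)
  keep <- integer(0)
  for (cell in names(cells)) {
    idx <- cells[[cell]]
    if (length(idx) < k) {
      stop("cell '", cell, "' has only ", length(idx), " trials (need ", k, ")")
    }
    delta <- abs(trials$cbm_a[idx] - trials$cbm_b[idx])
    ord <- idx[order(delta, match(trials$trial_id[idx], trials$trial_id))]
    keep <- c(keep, ord[seq_len(k)])
  }
  out <- trials[keep, , drop = FALSE]
  out <- out[order(out$species, out$condition, match(out$trial_id, trials$trial_id)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with t-test
#'
#' Correlation between two measurement series (e.g. embedding dimensionality
#' and mean observer CBM across trials), with significance assessed by the
#' t statistic `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (two-sided).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, neither constant.
#' @return List with `r`, `r_squared`, `t`, `df`, `p`.
#' @export
correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  r <- cor(x, y)
  df <- n - 2L
  t <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t), df)
  list(r = r, r_squared = r^2, t = t, df = df, p = p)
}

# Shared extraction of an aov fit into the package's ANOVA result structure.
summarize_aov <- function(fit, data, factors, response) {
  # anova.lm warns on all-identical responses; that case is defined here (F = 0)
  tab <- suppressWarnings(anova(fit))
  res_row <- nrow(tab)
  mse <- tab[res_row, "Mean Sq"]
  df_den <- tab[res_row, "Df"]
  constant_response <- length(unique(data[[response]])) == 1L
  effects <- lapply(factors, function(f) {
    Fv <- tab[f, "F value"]; p <- tab[f, "Pr(>F)"]
    # no between-group variation: define F = 0 rather than the 0/0 of anova()
    if (constant_response || tab[f, "Sum Sq"] <= 0) { Fv <- 0; p <- 1 }
    list(factor = f, F = Fv, df_num = tab[f, "Df"], df_den = df_den, p = p)
  })
  names(effects) <- factors
  group_means <- lapply(factors, function(f) {
    tapply(data[[response]], data[[f]], mean)
  })
  names(group_means) <- factors
  structure(list(effects = effects, group_means = group_means, mse = mse,
                 df_den = df_den, response = response, table = tab,
                 data = data),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  for (e in x$effects) {
    cat(sprintf("%s: F(%d,%d) = %.3g, p = %.4g\n",
                e$factor, e$df_num, e$df_den, e$F, e$p))
  }
  invisible(x)
}

#' Two-way analysis of variance on trial dimensionalities
#'
#' Fits `response ~ species + condition` (main effects; add the interaction
#' with `interaction = TRUE`) on a trial table and reports the F statistic,
#' degrees of freedom and p-value of each main effect, the per-level group
#' means, and the pooled error mean square used by the protected post-hoc
#' comparisons.
#'
#' @param trials a [trial_table()] (or data.frame with the same columns).
#' @param response response column, default `"dimensionality"`.
#' @param interaction include the species:condition interaction term.
#' @return Object of class `anova_result`.
#' @export
two_way_anova <- function(trials, response = "dimensionality",
                          interaction = FALSE) {
  df <- as.data.frame(trials)
  df$species <- factor(df$species)
  df$condition <- factor(df$condition)
  if (nlevels(df$species) < 2 || nlevels(df$condition) < 2) {
    stop("need at least 2 levels of species and condition")
  }
  counts <- table(df$species, df$condition)
  if (any(counts == 0)) stop("empty design cells: ",
                             paste(which(counts == 0), collapse = ", "))
  form <- if (interaction) {
    stats::as.formula(paste(response, "~ species * condition"))
  } else {
    stats::as.formula(paste(response, "~ species + condition"))
  }
  fit <- aov(form, data = df)
  summarize_aov(fit, df, c("species", "condition"), response)
}

#' One-way analysis of variance
#'
#' Fits `response ~ factor` on a trial table (typically dimensionality
#' against stimulus condition within one species).
#'
#' @param trials data.frame of trials.
#' @param factor grouping column, default `"condition"`.
#' @param response response column, default `"dimensionality"`.
#' @return Object of class `anova_result`.
#' @export
one_way_anova <- function(trials, factor = "condition",
                          response = "dimensionality") {
  df <- as.data.frame(trials)
  df[[factor]] <- base::factor(df[[factor]])
  if (nlevels(df[[factor]]) < 2) stop("need at least 2 factor levels")
  form <- stats::as.formula(paste(response, "~", factor))
  fit <- aov(form, data = df)
  summarize_aov(fit, df, factor, response)
}

#' Fisher's protected least significant difference post-hoc comparisons
#'
#' Pairwise comparisons of factor-level means using the parent ANOVA's pooled
#' error mean square and its degrees of freedom:
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))`. The comparisons are
#' *protected*: they are only carried out when the parent main effect is
#' significant at `alpha`; otherwise an empty table is returned with the gate
#' reason attached (attribute `"gate"`), matching the convention of reporting
#' no post-hoc tests after a non-significant omnibus F.
#'
#' @param anova an [one_way_anova()]/[two_way_anova()] result.
#' @param factor which factor's levels to compare (defaults to the first).
#' @param alpha significance gate for the parent effect and the pairwise
#'   flags.
#' @return data.frame of class `posthoc_table` with columns `level_i`,
#'   `level_j`, `diff`, `t`, `p`, `significant`; zero rows when gated.
#' @export
fisher_plsd <- function(anova, factor = NULL, alpha = 0.05) {
  stopifnot(inherits(anova, "anova_result"))
  if (is.null(factor)) factor <- names(anova$effects)[1]
  if (!factor %in% names(anova$effects)) {
    stop("factor '", factor, "' not in the ANOVA")
  }
  eff <- anova$effects[[factor]]
  empty <- data.frame(level_i = character(0), level_j = character(0),
                      diff = numeric(0), t = numeric(0), p = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (!is.finite(eff$p) || eff$p >= alpha) {
    attr(empty, "gate") <- sprintf(
      "parent effect '%s' not significant (p = %.3g >= %.2f); post-hoc tests withheld",
      factor, eff$p, alpha)
    class(empty) <- c("posthoc_table", "data.frame")
    return(empty)
  }
  data <- anova$data
  levs <- levels(data[[factor]])
  means <- tapply(data[[anova$response]], data[[factor]], mean)
  ns <- tapply(data[[anova$response]], data[[factor]], length)
  pairs <- combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dmean <- means[[i]] - means[[j]]
    se <- sqrt(anova$mse * (1 / ns[[i]] + 1 / ns[[j]]))
    t <- if (se == 0) 0 else dmean / se
    p <- if (se == 0 && dmean == 0) 1 else 2 * pt(-abs(t), anova$df_den)
    data.frame(level_i = i, level_j = j, diff = dmean, t = t, p = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "gate") <- NA_character_
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Bar chart of mean dimensionality by group
#'
#' Means with one-standard-error bars, in the style of the summary figures
#' of dimensionality by species and condition.
#'
#' @param trials data.frame of trials.
#' @param by grouping column.
#' @param response response column.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_dimensionality_means <- function(trials, by = "species",
                                      response = "dimensionality", ...) {
  m <- tapply(trials[[response]], trials[[by]], mean)
  se <- tapply(trials[[response]], trials[[by]],
               function(v) sd(v) / sqrt(length(v)))
  bp <- graphics::barplot(m, ylim = c(0, max(m + se) * 1.15),
                          ylab = paste("mean", response), ...)
  graphics::arrows(bp, m - se, bp, m + se, angle = 90, code = 3, length = 0.05)
  invisible(list(means = m, se = se))
}
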