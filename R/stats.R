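#' Two-group comparison with the study's test battery
#'
#' Wraps the standard two-tailed tests used for group comparisons: unpaired t
#' with or without Welch's correction, exact/approximate Mann-Whitney,
#' paired t, and Wilcoxon signed rank. Nonparametric tests use the exact null
#' distribution when the combined sample size is at most 12 and the data are
#' tie-free, and the normal approximation with tie correction otherwise.
#'
#' @param values_a,values_b Numeric vectors (aligned order for paired modes).
#' @param mode One of "unpaired-t", "welch-t", "mann-whitney", "paired-t",
#'   "wilcoxon".
#' @return A one-row data.frame of class `group_comparison`: `test`,
#'   `statistic`, `df` (NA for rank tests), `p`, `n_a`, `n_b`.
#' @export
compare_two_groups <- function(values_a, values_b,
                               mode = c("unpaired-t", "welch-t",
                                        "mann-whitney", "paired-t",
                                        "wilcoxon")) {
  mode <- match.arg(mode)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (mode %in% c("paired-t", "wilcoxon") && length(a) != length(b))
    stop("paired modes require equal-length, aligned samples")

  res <- switch(mode,
    "unpaired-t" = stats::t.test(a, b, var.equal = TRUE),
    "welch-t" = stats::t.test(a, b, var.equal = FALSE),
    "paired-t" = stats::t.test(a, b, paired = TRUE),
    "mann-whitney" = {
      exact <- (length(a) + length(b)) <= 12 &&
        !any(duplicated(c(a, b)))
      suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                          correct = !exact))
    },
    "wilcoxon" = {
      d <- a - b
      exact <- length(d) <= 12 && !any(duplicated(abs(d))) && !any(d == 0)
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                          exact = exact, correct = !exact))
    })
  out <- data.frame(test = mode,
                    statistic = unname(res$statistic),
                    df = if (is.null(res$parameter)) NA_real_ else
                      unname(res$parameter),
                    p = res$p.value,
                    n_a = length(a), n_b = length(b))
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Repeated-measures one-way ANOVA on a complete subject-by-condition table
#'
#' Decomposes the total sum of squares into condition, subject, and residual
#' strata; `F = MS_condition / MS_residual`. Incomplete tables are rejected:
#' exclude subjects with missing cells before calling (a mixed-effects
#' analysis is out of scope).
#'
#' @param table Numeric matrix, subjects in rows, conditions in columns.
#' @return An `anova_table` data.frame: per effect `effect`, `df`, `SS`,
#'   `MS`, `F`, `p`.
#' @export
rm_one_way_anova <- function(table) {
  m <- as.matrix(table)
  if (any(is.na(m)))
    stop(paste("table has missing cells; exclude incomplete subjects",
               "(mixed-effects models are not implemented)"))
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and conditions")
  long <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), times = ncol(m))),
    condition = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  fit <- stats::aov(y ~ condition + Error(subject), data = long)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  tab <- data.frame(
    effect = c("condition", "subject", "residual"),
    df = c(within["condition", "Df"], between["Residuals", "Df"],
           within["Residuals", "Df"]),
    SS = c(within["condition", "Sum Sq"], between["Residuals", "Sum Sq"],
           within["Residuals", "Sum Sq"]),
    MS = c(within["condition", "Mean Sq"], between["Residuals", "Mean Sq"],
           within["Residuals", "Mean Sq"]),
    F = c(within["condition", "F value"], NA, NA),
    p = c(within["condition", "Pr(>F)"], NA, NA))
  class(tab) <- c("anova_table", "data.frame")
  tab
}

# Greenhouse-Geisser epsilon from a pooled within-group covariance matrix of
# the k within-subject levels (Box's computational formula). Bounded to
# [1/(k-1), 1].
gg_epsilon <- function(S) {
  k <- ncol(S)
  if (k < 3) return(1)  # sphericity holds trivially for k = 2
  sbar <- mean(S)
  dbar <- mean(diag(S))
  rbar <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rbar^2) + k^2 * sbar^2)
  if (den <= 0) return(1)
  max(1 / (k - 1), min(1, num / den))
}

#' Mixed-design (repeated-measures two-way) ANOVA
#'
#' One between-subject factor (group) and one within-subject factor (e.g.
#' current level), the design used to compare firing responses across
#' increasing current injections between groups. Subjects missing any
#' within-factor level are dropped with a warning (complete-case analysis).
#' The between stratum tests group against subject-within-group error; the
#' within stratum tests the within factor and its interaction with group
#' against the within-subject error. Because repeated measures over many
#' levels rarely satisfy sphericity, within-stratum effects additionally
#' carry Greenhouse-Geisser corrected p values (`p_gg`, with the epsilon in
#' `eps_gg`): both numerator and denominator degrees of freedom are
#' multiplied by the epsilon estimated from the pooled within-group
#' covariance of the level measurements.
#'
#' @param data Data.frame with columns `subject`, `group`, `within`, `y`.
#' @return An `anova_table` data.frame with attribute `n_dropped`.
#' @export
rm_two_way_anova <- function(data) {
  need <- c("subject", "group", "within", "y")
  if (!all(need %in% names(data)))
    stop("`data` needs columns subject, group, within, y")
  d <- data
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$within <- factor(d$within)
  # complete cases over the shared within grid
  lv <- levels(d$within)
  ok_subj <- vapply(split(d, d$subject, drop = TRUE), function(s)
    all(lv %in% s$within) && !any(is.na(s$y)), logical(1))
  n_dropped <- sum(!ok_subj)
  if (n_dropped > 0) {
    warning(sprintf("%d subject(s) dropped for missing levels", n_dropped))
    d <- d[d$subject %in% names(ok_subj)[ok_subj], , drop = FALSE]
    d$subject <- droplevels(d$subject)
  }
  if (nlevels(d$subject) < 3) stop("too few complete subjects")
  fit <- stats::aov(y ~ group * within + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn <- function(tb, key) {
    i <- match(key, trimws(rownames(tb)))
    tb[i, , drop = FALSE]
  }
  grab <- function(tb, key) {
    r <- rn(tb, key)
    c(df = r[1, "Df"], SS = r[1, "Sum Sq"], MS = r[1, "Mean Sq"],
      F = r[1, "F value"], p = r[1, "Pr(>F)"])
  }
  g <- grab(between, "group"); ge <- grab(between, "Residuals")
  w <- grab(within, "within"); gw <- grab(within, "group:within")
  we <- grab(within, "Residuals")

  # pooled within-group covariance of the subject-by-level matrix
  wide <- stats::xtabs(y ~ subject + within, data = d)
  grp_of <- d$group[match(rownames(wide), d$subject)]
  pooled <- 0; wsum <- 0
  for (gl in levels(d$group)) {
    m <- wide[grp_of == gl, , drop = FALSE]
    if (nrow(m) >= 2) {
      pooled <- pooled + (nrow(m) - 1) * stats::cov(m)
      wsum <- wsum + (nrow(m) - 1)
    }
  }
  eps <- if (wsum > 0) gg_epsilon(pooled / wsum) else 1
  p_gg_w <- stats::pf(w["F"], eps * w["df"], eps * we["df"],
                      lower.tail = FALSE)
  p_gg_gw <- stats::pf(gw["F"], eps * gw["df"], eps * we["df"],
                       lower.tail = FALSE)

  tab <- data.frame(
    effect = c("group", "subjects_within_group", "within",
               "within_x_group", "within_error"),
    stratum = c("between", "between", "within", "within", "within"),
    df = c(g["df"], ge["df"], w["df"], gw["df"], we["df"]),
    SS = c(g["SS"], ge["SS"], w["SS"], gw["SS"], we["SS"]),
    MS = c(g["MS"], ge["MS"], w["MS"], gw["MS"], we["MS"]),
    F = c(g["F"], NA, w["F"], gw["F"], NA),
    p = c(g["p"], NA, w["p"], gw["p"], NA),
    eps_gg = c(NA, NA, eps, eps, NA),
    p_gg = c(g["p"], NA, p_gg_w, p_gg_gw, NA))
  attr(tab, "n_dropped") <- n_dropped
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Balanced two-way ANOVA with replicates
#'
#' Standard crossed two-factor analysis (e.g. injury condition by
#' satellite-microglia association for cfos positivity). Unbalanced designs
#' are rejected rather than silently choosing a sums-of-squares type.
#'
#' @param data Data.frame with columns `A`, `B`, `y`.
#' @return An `anova_table` data.frame.
#' @export
two_way_anova <- function(data) {
  need <- c("A", "B", "y")
  if (!all(need %in% names(data))) stop("`data` needs columns A, B, y")
  d <- data
  d$A <- factor(d$A); d$B <- factor(d$B)
  cell_n <- table(d$A, d$B)
  if (length(unique(as.vector(cell_n))) != 1 || any(cell_n == 0))
    stop("design is unbalanced; this analysis requires equal cell counts")
  fit <- stats::aov(y ~ A * B, data = d)
  s <- summary(fit)[[1]]
  key <- trimws(rownames(s))
  pick <- function(k, col) s[match(k, key), col]
  tab <- data.frame(
    effect = c("A", "B", "A_x_B", "residual"),
    df = vapply(c("A", "B", "A:B", "Residuals"), pick, numeric(1),
                col = "Df"),
    SS = vapply(c("A", "B", "A:B", "Residuals"), pick, numeric(1),
                col = "Sum Sq"),
    MS = vapply(c("A", "B", "A:B", "Residuals"), pick, numeric(1),
                col = "Mean Sq"),
    F = vapply(c("A", "B", "A:B", "Residuals"), pick, numeric(1),
               col = "F value"),
    p = vapply(c("A", "B", "A:B", "Residuals"), pick, numeric(1),
               col = "Pr(>F)"))
  rownames(tab) <- NULL
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values, `p_i* = min_{j >= i} (m * p_(j) / j)` capped at
#' 1, computed separately within each post-hoc family; the original order is
#' restored.
#'
#' @param p Numeric vector of raw p values in \[0, 1\].
#' @param family Optional vector of family labels (one per p value).
#' @return Adjusted p values in the input order.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  if (is.null(family)) family <- rep(1L, length(p))
  if (length(family) != length(p))
    stop("`family` must match `p` in length")
  out <- numeric(length(p))
  for (f in unique(family)) {
    i <- which(family == f)
    out[i] <- stats::p.adjust(p[i], method = "BH")
  }
  out
}
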