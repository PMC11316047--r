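#' ROUT outlier removal (single-group location model)
#'
#' Robust outlier detection controlled by a false discovery rate Q. The
#' robust centre is the median; the robust scale is the RSDR, the 68.27th
#' percentile of the absolute residuals with the small-sample correction
#' `n / (n - 1)`. Each point gets a t-like statistic `|residual| / RSDR` with
#' `n - 1` degrees of freedom and a two-sided p-value; points are screened
#' from the most extreme inward with a Benjamini-Hochberg-style boundary at
#' rate Q, and flagged points are removed.
#'
#' @param values numeric vector (n >= 3 for any removal to occur).
#' @param q false discovery rate Q (default 0.01, the method's convention).
#' @return List: `kept` (values retained), `flagged` (indices into `values`
#'   of removed points), `rsdr`, `p` (per-point p-values in input order).
#' @examples
#' rout_outliers(c(1, 2, 3, 4, 100))$flagged
#' @export
rout_outliers <- function(values, q = 0.01) {
  stopifnot(is.numeric(values), q > 0, q < 1)
  n <- length(values)
  if (n < 3L) {
    warning("ROUT needs n >= 3; no outliers removed")
    return(list(kept = values, flagged = integer(0), rsdr = NA_real_,
                p = rep(NA_real_, n)))
  }
  res <- values - median(values)
  rsdr <- unname(quantile(abs(res), 0.6827, type = 7)) * n / (n - 1)
  if (rsdr <= 0) {
    return(list(kept = values, flagged = integer(0), rsdr = rsdr,
                p = rep(1, n)))
  }
  tstat <- abs(res) / rsdr
  p <- 2 * pt(-tstat, df = n - 1)
  ord <- order(p)                       # most extreme first
  flagged <- integer(0)
  for (i in seq_len(n)) {
    if (p[ord[i]] <= q * i / n) flagged <- c(flagged, ord[i]) else break
  }
  list(kept = if (length(flagged)) values[-flagged] else values,
       flagged = sort(flagged), rsdr = rsdr, p = p)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper returning the W statistic and p-value; constant samples (for
#' which the test is undefined) are reported as non-normal with `W = NA`.
#'
#' @param values numeric vector with 3 <= n <= 5000.
#' @return List: `W`, `p`, `normal` (p >= alpha), `alpha`.
#' @param alpha significance level for the normality decision.
#' @export
normality <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(values)) == 0) {
    return(list(W = NA_real_, p = 0, normal = FALSE, alpha = alpha))
  }
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value,
       normal = sw$p.value >= alpha, alpha = alpha)
}

# Dunn's test: pairwise rank-based z comparisons after Kruskal-Wallis, with
# mid-ranks, tie-corrected variance, and Holm adjustment
dunn_posthoc <- function(values, groups, adjust = "holm") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p_raw[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
             p_unadjusted = p_raw, p_adjusted = p.adjust(p_raw, adjust))
}

# Dunnett comparisons against a control group via the multivariate-t
# formulation (multcomp); returns adjusted p per treatment-vs-control pair
dunnett_posthoc <- function(values, groups, control) {
  groups <- stats::relevel(factor(groups), ref = control)
  dat <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = dat)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl, test = multcomp::adjusted("single-step"))
  cmp <- names(sm$test$coefficients)
  treat <- sub(" - .*$", "", cmp)
  raw <- 2 * pt(-abs(sm$test$tstat), df = fit$df.residual)
  data.frame(group1 = treat, group2 = control,
             t = unname(sm$test$tstat),
             p_unadjusted = unname(raw),
             p_adjusted = unname(as.numeric(sm$test$pvalues)))
}

#' Normality-gated group comparison with optional ROUT outlier removal
#'
#' The published decision tree: outliers are removed per group with the ROUT
#' method; every group is tested for normality with Shapiro-Wilk. If all
#' groups are Gaussian, two groups are compared with an unpaired two-sided
#' Student's t test and three or more with ordinary one-way ANOVA, followed by
#' Dunnett's post hoc test when a control group is named (all conditions vs
#' control) or Tukey's otherwise (all pairs). If any group fails normality,
#' two groups are compared with the Mann-Whitney test and three or more with
#' a Kruskal-Wallis test followed by Dunn's multiple comparisons (Holm
#' adjustment). The report records every branch taken.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 3
#'   after outlier removal).
#' @param control optional name of the control group (selects Dunnett).
#' @param alpha significance level (default 0.05).
#' @param rout_q ROUT false discovery rate; `NULL` disables outlier removal.
#' @param welch use the Welch t test instead of the pooled-variance Student
#'   t test (default FALSE).
#' @return A list of class `StatReport`: `groups` (cleaned samples),
#'   `outliers_removed` (per group indices + Q), `normality` (per-group W and
#'   p), `all_normal`, `test_used`, `statistic`, `p`, `posthoc` (pairwise
#'   adjusted p, or NULL), `alpha`.
#' @export
compare_groups <- function(groups, control = NULL, alpha = 0.05,
                           rout_q = 0.01, welch = FALSE) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)) ||
      any(!nzchar(names(groups)))) {
    stop("'groups' must be a named list with at least two groups")
  }
  if (!is.null(control) && !control %in% names(groups)) {
    stop("control group '", control, "' not found")
  }
  outliers <- list()
  cleaned <- groups
  if (!is.null(rout_q)) {
    for (g in names(groups)) {
      ro <- rout_outliers(groups[[g]], q = rout_q)
      cleaned[[g]] <- ro$kept
      outliers[[g]] <- ro$flagged
    }
  }
  small <- names(cleaned)[vapply(cleaned, length, integer(1)) < 3L]
  if (length(small)) {
    stop("groups with n < 3 after outlier removal: ", paste(small, collapse = ", "))
  }
  norm <- lapply(cleaned, normality, alpha = alpha)
  all_normal <- all(vapply(norm, `[[`, logical(1), "normal"))
  k <- length(cleaned)
  values <- unlist(cleaned, use.names = FALSE)
  glab <- factor(rep(names(cleaned), lengths(cleaned)), levels = names(cleaned))

  posthoc <- NULL
  if (all_normal) {
    if (k == 2L) {
      ht <- t.test(cleaned[[1L]], cleaned[[2L]], var.equal = !welch)
      test_used <- if (welch) "welch_t" else "t"
      statistic <- unname(ht$statistic); pval <- ht$p.value
    } else {
      fit <- aov(values ~ glab)
      an <- summary(fit)[[1L]]
      statistic <- an[["F value"]][1L]; pval <- an[["Pr(>F)"]][1L]
      if (!is.null(control)) {
        test_used <- "anova_dunnett"
        posthoc <- dunnett_posthoc(values, glab, control)
      } else {
        test_used <- "anova_tukey"
        tk <- TukeyHSD(fit)$glab
        nm <- strsplit(rownames(tk), "-", fixed = TRUE)
        posthoc <- data.frame(group1 = vapply(nm, `[`, "", 1L),
                              group2 = vapply(nm, `[`, "", 2L),
                              diff = tk[, "diff"],
                              p_adjusted = tk[, "p adj"],
                              row.names = NULL)
      }
    }
  } else {
    if (k == 2L) {
      ht <- suppressWarnings(wilcox.test(cleaned[[1L]], cleaned[[2L]]))
      test_used <- "mann_whitney"
      statistic <- unname(ht$statistic); pval <- ht$p.value
    } else {
      ht <- kruskal.test(values, glab)
      test_used <- "kruskal_dunn"
      statistic <- unname(ht$statistic); pval <- ht$p.value
      posthoc <- dunn_posthoc(values, glab)
      if (!is.null(control)) {
        posthoc <- posthoc[posthoc$group1 == control | posthoc$group2 == control, ]
        rownames(posthoc) <- NULL
      }
    }
  }
  structure(list(groups = cleaned,
                 outliers_removed = list(indices = outliers, q = rout_q),
                 normality = norm, all_normal = all_normal,
                 test_used = test_used, statistic = statistic, p = pval,
                 posthoc = posthoc, control = control, alpha = alpha),
            class = "StatReport")
}

#' @export
print.StatReport <- function(x, ...) {
  cat("StatReport:", x$test_used, "- statistic", signif(x$statistic, 5),
      ", p =", format.pval(x$p, digits = 4), "\n")
  n_out <- sum(lengths(x$outliers_removed$indices))
  if (n_out) cat("  outliers removed (ROUT Q =", x$outliers_removed$q, "):", n_out, "\n")
  cat("  normality:", if (x$all_normal) "all groups Gaussian" else "non-Gaussian branch", "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc comparisons:\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Per-replicate normalisation to the control mean
#'
#' Divides every observation by the mean of the control-group observations of
#' its own biological replicate, removing between-experiment scale
#' variability. Every replicate must contain control observations.
#'
#' @param values numeric vector.
#' @param replicate replicate labels, same length.
#' @param group group labels, same length.
#' @param control name of the control group.
#' @return Numeric vector of normalised values (control mean = 1 within each
#'   replicate).
#' @export
normalize_per_replicate <- function(values, replicate, group, control) {
  stopifnot(length(values) == length(replicate), length(values) == length(group))
  out <- numeric(length(values))
  for (r in unique(replicate)) {
    sel <- replicate == r
    ctrl <- values[sel & group == control]
    if (!length(ctrl)) stop("replicate '", r, "' has no control observations")
    m <- mean(ctrl)
    if (!is.finite(m) || m == 0) stop("replicate '", r, "' has a non-positive control mean")
    out[sel] <- values[sel] / m
  }
  out
}
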