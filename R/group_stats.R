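#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA on a complete balanced design, the
#' group-level test applied to per-subject working-point metrics (e.g. best
#' r_PLV per structural variant x noise level). Reports, per effect: the F
#' statistic and degrees of freedom, generalized eta squared, the
#' Greenhouse-Geisser epsilon, Mauchly's sphericity p-value, and the p-value
#' (GG-corrected whenever Mauchly's test rejects at 0.05; epsilon is reported
#' always). Normality of the within-cell residuals is checked with Shapiro's
#' test. F statistics come from the univariate aov decomposition; epsilon and
#' Mauchly's test come from an independent multivariate fit via [car::Anova()].
#'
#' @param values numeric response (one observation per subject x a x b cell).
#' @param subject_ids subject identifier per observation.
#' @param factor_a,factor_b within-subject factor levels per observation.
#' @return list of class `rm_anova`: `effects` (data.frame with columns
#'   effect, F, df1, df2, ges, eps, mauchly_p, p_uncorrected, p, corrected),
#'   `shapiro_p`, `n_subjects`.
#' @export
rm_anova_2way <- function(values, subject_ids, factor_a, factor_b) {
  d <- data.frame(y = values, s = factor(subject_ids), a = factor(factor_a),
                  b = factor(factor_b))
  if (anyNA(d)) stop("missing values in the design")
  tab <- table(d$s, d$a, d$b)
  if (any(tab != 1))
    stop("design must be complete and balanced: one observation per cell")
  if (nlevels(d$s) < 3) stop("need at least 3 subjects")

  # univariate route: sums of squares from aov
  fit <- stats::aov(y ~ a * b + Error(s / (a * b)), data = d)
  sm <- summary(fit)
  get_stratum <- function(name) {
    st <- sm[[paste0("Error: ", name)]][[1]]
    st
  }
  strata <- list(a = get_stratum("s:a"), b = get_stratum("s:b"),
                 `a:b` = get_stratum("s:a:b"))
  ss_subj <- sm[["Error: s"]][[1]]["Residuals", "Sum Sq"]
  ss_err_all <- ss_subj + sum(vapply(strata, function(st)
    st["Residuals", "Sum Sq"], numeric(1)))

  # multivariate route: GG epsilon + Mauchly via car on the wide response,
  # with the wide matrix built explicitly to control column order
  cells <- expand.grid(a = levels(d$a), b = levels(d$b))
  Y <- sapply(seq_len(nrow(cells)), function(k)
    d$y[d$a == cells$a[k] & d$b == cells$b[k]][order(
      d$s[d$a == cells$a[k] & d$b == cells$b[k]])])
  mlm <- stats::lm(Y ~ 1)
  av <- car::Anova(mlm, idata = cells, idesign = ~ a * b, type = "III")
  # car warns when HF epsilon exceeds 1 or a stratum is singular; the table
  # below carries the relevant diagnostics already
  avs <- suppressWarnings(summary(av, multivariate = FALSE))
  ggtab <- avs$pval.adjustments
  sph <- avs$sphericity.tests

  eff_names <- c(a = "a", b = "b", `a:b` = "a:b")
  rows <- lapply(names(eff_names), function(e) {
    st <- strata[[e]]
    eff_row <- rownames(st)[1]
    F_val <- st[eff_row, "F value"]
    df1 <- st[eff_row, "Df"]
    df2 <- st["Residuals", "Df"]
    p_unc <- st[eff_row, "Pr(>F)"]
    ges <- st[eff_row, "Sum Sq"] / (st[eff_row, "Sum Sq"] + ss_err_all)
    if (!is.null(ggtab) && e %in% rownames(ggtab)) {
      eps <- unname(ggtab[e, "GG eps"])
      p_gg <- unname(ggtab[e, "Pr(>F[GG])"])
      m_p <- unname(sph[e, "p-value"])
    } else {
      # factors with 2 levels have no sphericity question: epsilon = 1
      eps <- 1
      p_gg <- p_unc
      m_p <- NA_real_
    }
    corrected <- !is.na(m_p) && m_p < 0.05
    data.frame(effect = e, F = F_val, df1 = df1, df2 = df2, ges = ges,
               eps = eps, mauchly_p = m_p, p_uncorrected = p_unc,
               p = if (corrected) p_gg else p_unc, corrected = corrected,
               stringsAsFactors = FALSE)
  })
  eff <- do.call(rbind, rows)
  rownames(eff) <- NULL
  resid_cell <- d$y - stats::ave(d$y, d$a, d$b)
  structure(list(effects = eff,
                 shapiro_p = stats::shapiro.test(resid_cell)$p.value,
                 n_subjects = nlevels(d$s)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (%d subjects)\n", x$n_subjects))
  for (i in seq_len(nrow(x$effects))) {
    e <- x$effects[i, ]
    cat(sprintf("  %s: F(%g, %g) = %.2f, ges = %.3g, eps = %.2f, p = %.3g%s\n",
                e$effect, e$df1, e$df2, e$F, e$ges, e$eps, e$p,
                if (e$corrected) " (GG-corrected)" else ""))
  }
  cat(sprintf("  Shapiro on cell residuals: p = %.3g\n", x$shapiro_p))
  invisible(x)
}

#' Paired Wilcoxon tests with BH correction and effect sizes
#'
#' Signed-rank tests on a family of paired comparisons, with Cohen's d on the
#' paired differences (mean of differences / sd of differences) and
#' Benjamini-Hochberg adjustment across the family. Comparisons with all-zero
#' differences are flagged degenerate (no test is possible).
#'
#' @param pairs_list named list; each element is a list or data.frame with
#'   equal-length paired samples `x` and `y` (n >= 5).
#' @return data.frame: comparison, n, W (sum of positive ranks of x - y),
#'   cohens_d, p, p_adjusted, degenerate.
#' @export
paired_wilcoxon_fdr <- function(pairs_list) {
  if (is.null(names(pairs_list)) || any(names(pairs_list) == ""))
    names(pairs_list) <- paste0("comparison_", seq_along(pairs_list))
  rows <- lapply(names(pairs_list), function(nm) {
    pr <- pairs_list[[nm]]
    x <- pr$x; y <- pr$y
    if (length(x) != length(y)) stop(nm, ": paired samples differ in length")
    if (length(x) < 5) stop(nm, ": need at least 5 pairs")
    dif <- x - y
    if (all(dif == 0) || stats::sd(dif) == 0)
      return(data.frame(comparison = nm, n = length(x), W = NA_real_,
                        cohens_d = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    data.frame(comparison = nm, n = length(x), W = unname(wt$statistic),
               cohens_d = mean(dif) / stats::sd(dif), p = wt$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[c("comparison", "n", "W", "cohens_d", "p", "p_adjusted", "degenerate")]
}
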