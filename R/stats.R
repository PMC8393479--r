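#' Aggregate section values to one case-level value
#'
#' Cases enter every statistic as the arithmetic mean of their (up to three)
#' section values at a given cord level.
#'
#' @param values numeric vector of section values (>= 1, non-missing values
#'   are averaged).
#' @return list with `value` (mean) and `n` (sections used).
#' @export
aggregate_case <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no section values to aggregate")
  list(value = mean(values), n = length(values))
}

#' Two-sided single-outlier Grubbs test
#'
#' One pass only (no iteration): the point with the largest studentized
#' deviation `G = max |x - mean| / sd` is flagged iff `G` exceeds the
#' t-based critical value at `alpha`. Ties in deviation are broken by first
#' index. Zero-variance input flags nothing.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha test level (default 0.2, a deliberately permissive screen).
#' @return list with `index` (integer or `NA` if none), `G`, `critical`.
#' @export
grubbs_outlier <- function(values, alpha = 0.2) {
  n <- length(values)
  if (n < 3) stop("Grubbs test requires at least 3 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    return(list(index = NA_integer_, G = 0, critical = NA_real_))
  }
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tc <- qt(1 - alpha / (2 * n), n - 2)
  critical <- (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2))
  list(
    index = if (G > critical) which.max(dev) else NA_integer_,
    G = G, critical = critical
  )
}

test_result <- function(test, statistic, p, method, extra = list()) {
  structure(c(list(test = test, statistic = statistic, p = p,
                   method = method), extra), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (%s)\n", x$test, x$statistic,
              x$p, x$method))
  invisible(x)
}

#' Two-sided Mann-Whitney test
#'
#' Exact enumeration of the U distribution when there are no ties and the
#' smaller sample has at most 8 observations; tie-corrected normal
#' approximation (no continuity correction) otherwise. The method used is
#' recorded in the result.
#'
#' @param a,b numeric samples (each n >= 1).
#' @return a `test_result` with the U statistic of `a`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  test_result("mann_whitney", unname(wt$statistic), wt$p.value,
              if (exact) "exact enumeration"
              else "tie-corrected normal approximation")
}

#' Welch two-sample t-test
#'
#' @param a,b numeric samples (each n >= 2).
#' @return a `test_result` with Welch-Satterthwaite degrees of freedom in
#'   `df`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  tt <- t.test(a, b, var.equal = FALSE)
  test_result("welch_t", unname(tt$statistic), tt$p.value,
              "Welch-Satterthwaite", list(df = unname(tt$parameter)))
}

#' Pearson correlation with least-squares regression line
#'
#' @param x,y numeric vectors (n >= 3 for the t-based p).
#' @return a `test_result` with `r`, `slope`, `intercept`.
#' @export
pearson_linreg <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0) stop("x has zero variance; regression undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  fit <- lm(y ~ x)
  test_result("pearson_linreg", unname(ct$statistic), ct$p.value,
              "t-based two-sided",
              list(r = unname(ct$estimate),
                   slope = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1])))
}

sidak_adjust <- function(p, m = length(p)) pmin(1, 1 - (1 - p)^m)

#' Two-way ANOVA with Sidak or Tukey post-tests
#'
#' Between-subjects designs are fitted by least squares with sum-to-zero
#' contrasts and tested with Type III sums of squares (matching the
#' behaviour of mainstream biostatistics software on unbalanced designs,
#' e.g. a 4-control vs 13-ALS by 3-level layout). Post-test families:
#' `sidak` compares `factor1` groups within each `factor2` level, jointly
#' Sidak-adjusted (`1 - (1 - p)^m` over the m planned comparisons); `tukey`
#' compares `factor2` levels within each `factor1` group via the studentized
#' range. With `repeated = "both"` a complete within-subject design is
#' required and fitted as a subject-blocked ANOVA; Sidak post-tests are then
#' paired t-tests on subject differences.
#'
#' @param data data.frame in long format.
#' @param value name of the response column.
#' @param factor1,factor2 names of the two factor columns.
#' @param posthoc `"sidak"`, `"tukey"` or `"both"` (default).
#' @param repeated `"none"` (between subjects) or `"both"` (both factors
#'   within subject).
#' @param subject subject column name, required when `repeated = "both"`.
#' @return list with `anova` (term table), `posthoc` (data.frame:
#'   `family`, `by`, `comparison`, `estimate`, `p_raw`, `p_adj`), `method`.
#' @export
two_way_anova <- function(data, value, factor1, factor2,
                          posthoc = c("both", "sidak", "tukey"),
                          repeated = c("none", "both"), subject = NULL) {
  posthoc <- match.arg(posthoc)
  repeated <- match.arg(repeated)
  d <- data.frame(
    y = data[[value]],
    f1 = factor(data[[factor1]]),
    f2 = factor(data[[factor2]])
  )
  if (nlevels(d$f1) < 2 || nlevels(d$f2) < 2) {
    stop("each factor needs at least 2 levels")
  }
  if (repeated == "both") {
    if (is.null(subject)) stop("repeated designs need a subject column")
    d$subject <- factor(data[[subject]])
    counts <- table(d$subject, d$f1, d$f2)
    if (any(counts != 1)) {
      stop("repeated-measures design must be complete ",
           "(one observation per subject per cell)")
    }
    fit <- aov(y ~ f1 * f2 + Error(subject / (f1 * f2)), data = d)
    sm <- summary(fit)
    rows <- do.call(rbind, lapply(sm, function(stratum) {
      tb <- stratum[[1]]
      data.frame(term = trimws(rownames(tb)), df = tb$Df,
                 ss = tb$`Sum Sq`, F = tb$`F value`, p = tb$`Pr(>F)`)
    }))
    rownames(rows) <- NULL
    an <- rows[!rows$term %in% "Residuals", , drop = FALSE]
    ph <- NULL
    if (posthoc %in% c("both", "sidak")) {
      ph <- rm_sidak_posthoc(d, factor1, factor2)
    }
    return(list(anova = an, posthoc = ph,
                method = "repeated-measures two-way ANOVA (both factors)"))
  }
  cells <- table(d$f1, d$f2)
  if (any(cells == 0)) {
    warning("empty cell(s) in between-subjects design; ",
            "only estimable contrasts are reported")
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(y ~ f1 * f2, data = d)
  a3 <- car::Anova(fit, type = 3)
  an <- data.frame(
    term = rownames(a3), ss = a3$`Sum Sq`, df = a3$Df,
    F = a3$`F value`, p = a3$`Pr(>F)`
  )
  an <- an[!an$term %in% c("(Intercept)", "Residuals"), , drop = FALSE]
  an$term <- c("f1" = factor1, "f2" = factor2,
               "f1:f2" = paste0(factor1, ":", factor2))[an$term]
  rownames(an) <- NULL
  ph_list <- list()
  if (posthoc %in% c("both", "sidak")) {
    emm <- emmeans::emmeans(fit, as.formula("~ f1 | f2"))
    ct <- summary(emmeans::contrast(emm, "pairwise"), adjust = "none")
    ph_list$sidak <- data.frame(
      family = "sidak", by = as.character(ct$f2),
      comparison = as.character(ct$contrast), estimate = ct$estimate,
      p_raw = ct$p.value, p_adj = sidak_adjust(ct$p.value)
    )
  }
  if (posthoc %in% c("both", "tukey")) {
    emm <- emmeans::emmeans(fit, as.formula("~ f2 | f1"))
    ct <- summary(emmeans::contrast(emm, "pairwise"), adjust = "tukey")
    ph_list$tukey <- data.frame(
      family = "tukey", by = as.character(ct$f1),
      comparison = as.character(ct$contrast), estimate = ct$estimate,
      p_raw = NA_real_, p_adj = ct$p.value
    )
  }
  ph <- do.call(rbind, ph_list)
  if (!is.null(ph)) rownames(ph) <- NULL
  list(anova = an, posthoc = ph,
       method = "two-way ANOVA, Type III SS, sum-to-zero contrasts")
}

# Sidak-adjusted paired t contrasts of f1 within each f2 level, for the
# repeated-measures branch.
rm_sidak_posthoc <- function(d, factor1, factor2) {
  out <- list()
  l1 <- levels(d$f1)
  pairs1 <- utils::combn(l1, 2, simplify = FALSE)
  for (lv in levels(d$f2)) {
    for (pr in pairs1) {
      da <- d[d$f2 == lv & d$f1 == pr[1], ]
      db <- d[d$f2 == lv & d$f1 == pr[2], ]
      da <- da[order(da$subject), ]; db <- db[order(db$subject), ]
      diffs <- da$y - db$y
      tt <- t.test(diffs)
      out[[length(out) + 1L]] <- data.frame(
        family = "sidak", by = lv,
        comparison = paste(pr[1], "-", pr[2]),
        estimate = mean(diffs), p_raw = tt$p.value, p_adj = NA_real_
      )
    }
  }
  ph <- do.call(rbind, out)
  ph$p_adj <- sidak_adjust(ph$p_raw)
  ph
}

#' One-way ANOVA with Tukey post-test
#'
#' Used for comparisons across cord levels within a single cohort.
#'
#' @param data data.frame.
#' @param value,factor1 column names.
#' @return list with `anova`, `posthoc`, `method`.
#' @export
one_way_anova <- function(data, value, factor1) {
  d <- data.frame(y = data[[value]], f1 = factor(data[[factor1]]))
  fit <- lm(y ~ f1, data = d)
  a <- anova(fit)
  an <- data.frame(term = factor1, ss = a$`Sum Sq`[1], df = a$Df[1],
                   F = a$`F value`[1], p = a$`Pr(>F)`[1])
  emm <- emmeans::emmeans(fit, ~f1)
  ct <- summary(emmeans::contrast(emm, "pairwise"), adjust = "tukey")
  ph <- data.frame(family = "tukey", by = NA_character_,
                   comparison = as.character(ct$contrast),
                   estimate = ct$estimate, p_raw = NA_real_,
                   p_adj = ct$p.value)
  list(anova = an, posthoc = ph, method = "one-way ANOVA, Tukey post-test")
}
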