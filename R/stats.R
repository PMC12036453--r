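# Nonparametric statistical battery: assumption gating, Kruskal-Wallis with
# post hoc pairwise tests, aligned rank transform factorial ANOVA, rank-sum
# tests, Bland-Altman agreement, absolute-agreement ICC, and Bonferroni
# correction. Midranks are used everywhere; tie corrections are applied to
# the Kruskal-Wallis statistic and the rank-sum normal approximation.

#' Shapiro-Wilk and Bartlett assumption gate
#'
#' @param groups list of numeric vectors, each of length >= 3.
#' @return list with `shapiro_p` (per group), `bartlett_p`, and
#'   `nonparametric` (TRUE when any p < alpha).
#' @param alpha gate significance level.
#' @export
gate_assumptions <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  lens <- vapply(groups, length, 1L)
  if (any(lens < 3L)) stop("each group needs >= 3 values")
  if (any(vapply(groups, function(g) stats::sd(g) == 0, logical(1L))))
    stop("constant group: normality undefined")
  sw <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, numeric(1L))
  bt <- stats::bartlett.test(groups)$p.value
  list(shapiro_p = sw, bartlett_p = bt,
       nonparametric = any(c(sw, bt) < alpha))
}

#' @noRd
midranks <- function(x) rank(x, ties.method = "average")

#' Kruskal-Wallis rank-sum omnibus test
#'
#' H on midranks with the standard tie correction and the chi-square
#' approximation on k - 1 degrees of freedom. All-identical data give
#' H = 0, p = 1.
#'
#' @param groups list of >= 2 numeric vectors (>= 3 for the usual design).
#' @return a `stat_result` list: `test`, `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  if (n < 5L) stop("total n must be >= 5")
  r <- midranks(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  H <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H / corr
    p <- stats::pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(test = "kruskal_wallis", statistic = c(H = H),
                 df = length(groups) - 1L, p_value = p),
            class = "stat_result")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided; exact null distribution for combined n <= 20 without ties,
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return a `stat_result` with statistic `W` (Mann-Whitney U of `x`).
#' @export
ranksum <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  n1 <- length(x); n2 <- length(y)
  r <- midranks(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
  ties <- table(c(x, y))
  exact <- (n1 + n2) <= 20L && !any(ties > 1L)
  if (exact) {
    # two-sided: double the smaller tail of the exact U distribution
    p <- min(1, 2 * min(stats::pwilcox(W, n1, n2),
                        stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)))
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(test = "ranksum", statistic = c(W = W),
                 df = c(n1 = n1, n2 = n2), p_value = p),
            class = "stat_result")
}

#' Post hoc pairwise comparisons after an omnibus test
#'
#' Default `"ranksum_bonferroni"`: a two-sample rank-sum test per pair with
#' Bonferroni correction over the number of pairs. `"tukey_on_ranks"`
#' applies Tukey's HSD to the global midranks (one-way ANOVA on ranks,
#' studentized-range p-values) — the parametric post hoc sometimes quoted
#' after a rank omnibus.
#'
#' @param groups named list of numeric vectors.
#' @param method `"ranksum_bonferroni"` or `"tukey_on_ranks"`.
#' @return data frame with columns `pair`, `statistic`, `p`, `adjusted_p`.
#' @export
posthoc_pairwise <- function(groups,
                             method = c("ranksum_bonferroni", "tukey_on_ranks")) {
  method <- match.arg(method)
  k <- length(groups)
  stopifnot(k >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  if (method == "ranksum_bonferroni") {
    rows <- lapply(seq_len(m), function(j) {
      i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
      a <- groups[[i1]]; b <- groups[[i2]]
      if (stats::sd(c(a, b)) == 0) {
        st <- c(W = length(a) * length(b) / 2); p <- 1
      } else {
        rs <- ranksum(a, b)
        st <- rs$statistic; p <- rs$p_value
      }
      data.frame(pair = paste(names(groups)[c(i1, i2)], collapse = "-"),
                 statistic = unname(st), p = p)
    })
    out <- do.call(rbind, rows)
    out$adjusted_p <- bonferroni(out$p, m)
  } else {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(seq_len(k), lengths(groups))
    r <- midranks(x)
    ni <- tabulate(g)
    n <- length(x)
    mbar <- tapply(r, g, mean)
    sse <- sum((r - mbar[g])^2)
    df_e <- n - k
    mse <- sse / df_e
    rows <- lapply(seq_len(m), function(j) {
      i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
      se <- sqrt(mse / 2 * (1 / ni[i1] + 1 / ni[i2]))
      q <- if (se > 0) abs(mbar[i1] - mbar[i2]) / se else 0
      p <- if (se > 0) stats::ptukey(q, k, df_e, lower.tail = FALSE) else 1
      data.frame(pair = paste(names(groups)[c(i1, i2)], collapse = "-"),
                 statistic = unname(q), p = p)
    })
    out <- do.call(rbind, rows)
    out$adjusted_p <- out$p   # Tukey's HSD is already familywise
  }
  out
}

#' Aligned rank transform two-way factorial ANOVA
#'
#' For each effect (A, B, A:B) the responses are aligned with cell-means
#' estimates — the response minus every estimated effect except the one
#' under test, i.e. residual plus that effect's own estimate — then
#' midranked, and a standard balanced two-way factorial ANOVA is run on the
#' ranks; only the F for the aligned-for effect is reported. Aligned
#' responses sum to zero for every effect (checked internally). Cells are
#' treated as independent (no repeated-measures error structure), matching
#' crossed designs with one observation set per cell; the design must be
#' balanced (equal cell counts).
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factors (or coercible) of the same length.
#' @return list of three `stat_result`s named `A`, `B`, `A:B`, each with
#'   `statistic` (F), `df` = (effect df, error df), `p_value`.
#' @export
art_anova <- function(values, factor_a, factor_b) {
  a <- as.factor(factor_a)
  b <- as.factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need >= 2 levels")
  tab <- table(a, b)
  if (any(tab == 0L)) {
    bad <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop("empty cell: ", levels(a)[bad[1L]], " x ", levels(b)[bad[2L]])
  }
  if (length(unique(as.vector(tab))) != 1L)
    stop("art_anova requires a balanced design (equal cell counts)")
  if (tab[1L] < 2L) stop("need >= 2 observations per cell")
  y <- as.numeric(values)
  mu <- mean(y)
  m_ab <- tapply(y, list(a, b), mean)
  m_a <- rowMeans(m_ab)
  m_b <- colMeans(m_ab)
  ia <- as.integer(a); ib <- as.integer(b)
  cell <- m_ab[cbind(ia, ib)]
  eff_a <- m_a[ia] - mu
  eff_b <- m_b[ib] - mu
  eff_ab <- cell - m_a[ia] - m_b[ib] + mu
  resid <- y - cell
  aligned <- list("A" = resid + eff_a, "B" = resid + eff_b,
                  "A:B" = resid + eff_ab)
  for (nm in names(aligned))
    if (abs(sum(aligned[[nm]])) > 1e-9 * max(1, sum(abs(y))))
      stop("internal error: aligned responses for ", nm, " do not sum to zero")
  out <- lapply(names(aligned), function(nm) {
    r <- midranks(aligned[[nm]])
    f <- balanced_two_way_f(r, ia, ib, nlevels(a), nlevels(b))
    stat <- switch(nm, "A" = f$FA, "B" = f$FB, "A:B" = f$FAB)
    df1 <- switch(nm, "A" = f$dfA, "B" = f$dfB, "A:B" = f$dfAB)
    structure(list(test = paste0("art_", nm), statistic = c(F = stat),
                   df = c(df1, f$dfE),
                   p_value = if (is.na(stat)) NA_real_ else
                     stats::pf(stat, df1, f$dfE, lower.tail = FALSE)),
              class = "stat_result")
  })
  names(out) <- names(aligned)
  out
}

#' Balanced two-way factorial ANOVA from cell means
#' @noRd
balanced_two_way_f <- function(y, ia, ib, na_, nb_) {
  n <- length(y)
  r <- n / (na_ * nb_)
  mu <- mean(y)
  m_ab <- tapply(y, list(ia, ib), mean)
  m_a <- rowMeans(m_ab)
  m_b <- colMeans(m_ab)
  ss_a <- r * nb_ * sum((m_a - mu)^2)
  ss_b <- r * na_ * sum((m_b - mu)^2)
  dev <- m_ab - outer(m_a, rep(1, nb_)) - outer(rep(1, na_), m_b) + mu
  ss_ab <- r * sum(dev^2)
  ss_e <- sum((y - m_ab[cbind(ia, ib)])^2)
  df_a <- na_ - 1L; df_b <- nb_ - 1L
  df_ab <- df_a * df_b
  df_e <- n - na_ * nb_
  ms_e <- ss_e / df_e
  fr <- function(ss, df) if (ms_e > 0) (ss / df) / ms_e else NA_real_
  list(FA = fr(ss_a, df_a), FB = fr(ss_b, df_b), FAB = fr(ss_ab, df_ab),
       dfA = df_a, dfB = df_b, dfAB = df_ab, dfE = df_e)
}

#' Bland-Altman agreement analysis
#'
#' Differences `m1 - m2` against pair means: bias, 1.96-SD limits of
#' agreement, and the slope of differences on means as the
#' proportional-bias probe. Plot coordinates are returned for export.
#'
#' @param m1,m2 paired numeric vectors (>= 3 pairs).
#' @return an `agreement_result` list: `bias`, `loa_low`, `loa_high`,
#'   `slope`, `plot_data` (data frame `mean`, `difference`).
#' @export
bland_altman <- function(m1, m2) {
  stopifnot(length(m1) == length(m2), length(m1) >= 3L)
  d <- m1 - m2
  mn <- (m1 + m2) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  slope <- if (stats::var(mn) > 0) stats::cov(mn, d) / stats::var(mn) else 0
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, slope = slope,
                 plot_data = data.frame(mean = mn, difference = d)),
            class = "agreement_result")
}

#' Two-way absolute-agreement single-measure ICC
#'
#' ICC(A,1): with subject mean square `MSR`, rater mean square `MSC` and
#' error mean square `MSE` from the two-way decomposition of an n x k
#' subject-by-rater table,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param rater_a,rater_b paired scores from the two raters (>= 3 pairs).
#' @return an `agreement_result` list with `icc`, the mean squares, and
#'   `undefined` flag (zero between-subject variance).
#' @export
icc_agreement <- function(rater_a, rater_b) {
  stopifnot(length(rater_a) == length(rater_b), length(rater_a) >= 3L)
  x <- cbind(rater_a, rater_b)
  n <- nrow(x); k <- 2L
  mu <- mean(x)
  sm <- rowMeans(x)
  rm_ <- colMeans(x)
  ss_r <- k * sum((sm - mu)^2)
  ss_c <- n * sum((rm_ - mu)^2)
  ss_e <- sum((x - outer(sm, rep(1, k)) - outer(rep(1, n), rm_) + mu)^2)
  msr <- ss_r / (n - 1L)
  msc <- ss_c / (k - 1L)
  mse <- ss_e / ((n - 1L) * (k - 1L))
  denom <- msr + (k - 1L) * mse + k * (msc - mse) / n
  undefined <- msr <= 0 || denom <= 0
  icc <- if (undefined) NA_real_ else (msr - mse) / denom
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse,
                 undefined = undefined),
            class = "agreement_result")
}

#' Bonferroni correction
#'
#' @param p numeric vector of p-values.
#' @param m number of comparisons (defaults to `length(p)`; must be at
#'   least that).
#' @return adjusted p-values `min(1, p * m)`, in input order.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be >= number of p-values")
  pmin(1, p * m)
}

#' Group summary table (mean, SD, CV, n)
#'
#' Summarizes a long table into per-group mean, n-1 SD, coefficient of
#' variation and n, with formatted `mean +/- SD` strings alongside the
#' numeric columns. Groups of size 1 get a missing SD; empty groups are
#' omitted with a warning.
#'
#' @param table data frame holding `value` plus grouping columns.
#' @param by character vector of grouping column names.
#' @param value name of the value column.
#' @param digits digits for the formatted string.
#' @return data frame with one row per group.
#' @export
build_summary <- function(table, by = c("species", "tissue"),
                          value = "value", digits = 3L) {
  stopifnot(all(by %in% names(table)), value %in% names(table))
  key <- interaction(table[by], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(lv) {
    d <- table[key == lv, , drop = FALSE]
    v <- d[[value]][is.finite(d[[value]])]
    if (length(v) == 0L) {
      warning("empty group omitted: ", gsub("\r", " / ", lv))
      return(NULL)
    }
    g <- strsplit(lv, "\r", fixed = TRUE)[[1L]]
    out <- as.data.frame(as.list(g), col.names = by,
                         stringsAsFactors = FALSE)
    out$n <- length(v)
    out$mean <- mean(v)
    out$sd <- if (length(v) > 1L) stats::sd(v) else NA_real_
    out$cv_pct <- if (length(v) > 1L && mean(v) != 0) 100 * out$sd / out$mean
                  else NA_real_
    out$label <- if (is.na(out$sd)) signif(out$mean, digits) else
      paste0(signif(out$mean, digits), " ± ", signif(out$sd, digits))
    out
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, df = (%s), p = %.4g\n", x$test,
              names(x$statistic)[1L], x$statistic[1L],
              paste(x$df, collapse = ", "), x$p_value))
  invisible(x)
}
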