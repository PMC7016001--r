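#' Grade-wise comparison of a qMRI summary variable
#'
#' Kruskal-Wallis omnibus test (tie-corrected) across the degeneration
#' subgroups, followed by Dunn's pairwise post-hoc comparisons in the
#' fixed reporting order I vs II, I vs >=III, II vs >=III. The pairwise z
#' statistics use the tie-corrected pooled rank variance and Dunn's own
#' familywise (Bonferroni) adjustment over the three comparisons; no
#' further correction is applied.
#'
#' The omnibus p-value is by default the asymptotic chi-square value; a
#' Monte-Carlo permutation p-value for the same H statistic is available
#' with `p_method = "permutation"` (label reshuffling, `n_perm` draws).
#'
#' @param values numeric vector
#' @param groups factor of group labels, same length
#' @param alpha significance level (0.005 in the analysis plan)
#' @param p_method `"asymptotic"` or `"permutation"`
#' @param n_perm permutation count
#' @return object of class `test_result`
#' @export
compare_grades <- function(values, groups, alpha = 0.005,
                           p_method = c("asymptotic", "permutation"),
                           n_perm = 10000) {
  p_method <- match.arg(p_method)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(factor(groups[keep]))
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    message("degenerate groups; Kruskal-Wallis result missing")
    return(test_result("Kruskal-Wallis", NA_real_, NA_real_, NULL, alpha,
                       p_method))
  }
  if (stats::sd(values) == 0) {
    # every observation tied: no evidence of any group difference
    ph <- data.frame(comparison = paste(utils::combn(levels(groups), 2)[1, ],
                                        "vs",
                                        utils::combn(levels(groups), 2)[2, ]),
                     z = 0, p_adj = 1, significant = FALSE)
    return(test_result("Kruskal-Wallis", 0, 1, ph, alpha, p_method))
  }
  kw <- stats::kruskal.test(values, groups)
  p <- unname(kw$p.value)
  if (p_method == "permutation")
    p <- perm_p_kruskal(values, groups, unname(kw$statistic), n_perm)
  ph <- dunn_kruskal(values, groups, alpha)
  test_result("Kruskal-Wallis", unname(kw$statistic), p, ph, alpha, p_method)
}

#' Longitudinal comparison across loading states
#'
#' Friedman test over complete per-sample triplets (samples are blocks,
#' loading states are treatments), followed by Dunn's post-hoc pairwise
#' comparisons reported in the fixed order delta0 vs delta1, delta0 vs
#' delta2, delta1 vs delta2. Samples with a missing value in any state
#' are dropped with a message.
#'
#' @param y numeric matrix, rows = samples, columns = loading states in
#'   order (delta0, delta1, delta2, ...)
#' @inheritParams compare_grades
#' @return object of class `test_result`
#' @export
compare_loading <- function(y, alpha = 0.005,
                            p_method = c("asymptotic", "permutation"),
                            n_perm = 10000) {
  p_method <- match.arg(p_method)
  y <- as.matrix(y)
  if (is.null(colnames(y)))
    colnames(y) <- paste0("delta", seq_len(ncol(y)) - 1L)
  complete <- stats::complete.cases(y)
  if (any(!complete))
    message(sprintf("dropping %d sample(s) with incomplete loading series",
                    sum(!complete)))
  y <- y[complete, , drop = FALSE]
  if (nrow(y) < 2L || ncol(y) < 2L) {
    message("too few complete series; Friedman result missing")
    return(test_result("Friedman", NA_real_, NA_real_, NULL, alpha, p_method))
  }
  fr <- stats::friedman.test(y)
  stat <- unname(fr$statistic)
  p <- unname(fr$p.value)
  if (is.nan(stat)) { stat <- 0; p <- 1 }  # all within-block values tied
  if (p_method == "permutation") p <- perm_p_friedman(y, stat, n_perm)
  ph <- dunn_friedman(y, alpha)
  test_result("Friedman", stat, p, ph, alpha, p_method)
}

#' Compare response-to-loading Delta statistics
#'
#' Screens each Delta sample for normality with the D'Agostino-Pearson
#' omnibus test, compares Delta1 vs Delta2 with an unpaired two-sample
#' Student's t-test (pooled variance), and - when subgroup labels are
#' given - runs one-way ANOVAs of each Delta across the degeneration
#' subgroups.
#'
#' @param delta1,delta2 per-sample Delta values (percent)
#' @param group optional factor of degeneration subgroups
#' @param alpha significance level
#' @return list with `t_test`, `anova_delta1`, `anova_delta2` (each a
#'   `test_result` or NULL) and `normality_p` (named K-squared p-values)
#' @export
compare_deltas <- function(delta1, delta2, group = NULL, alpha = 0.005) {
  norm_p <- c(delta1 = tryCatch(dagostino_pearson(delta1)$p.value,
                                error = function(e) NA_real_),
              delta2 = tryCatch(dagostino_pearson(delta2)$p.value,
                                error = function(e) NA_real_))
  tt <- if (sum(!is.na(delta1)) >= 3 && sum(!is.na(delta2)) >= 3) {
    ht <- stats::t.test(delta1, delta2, var.equal = TRUE)
    test_result("unpaired t", unname(ht$statistic), unname(ht$p.value),
                NULL, alpha, "asymptotic")
  } else {
    message("fewer than 3 observations per Delta; t-test missing")
    test_result("unpaired t", NA_real_, NA_real_, NULL, alpha, "asymptotic")
  }
  av <- function(d) {
    if (is.null(group)) return(NULL)
    g <- droplevels(factor(group))
    ok <- !is.na(d)
    if (length(levels(g)) < 2L || any(table(g[ok]) < 3L)) {
      message("fewer than 3 observations per subgroup cell; ANOVA missing")
      return(test_result("one-way ANOVA", NA_real_, NA_real_, NULL, alpha,
                         "asymptotic"))
    }
    fit <- stats::aov(d ~ g)
    s <- summary(fit)[[1]]
    test_result("one-way ANOVA", s[["F value"]][1], s[["Pr(>F)"]][1],
                NULL, alpha, "asymptotic")
  }
  list(t_test = tt, anova_delta1 = av(delta1), anova_delta2 = av(delta2),
       normality_p = norm_p)
}

#' Repeated-measures ANOVA of mask pixel counts across loading
#'
#' @param counts numeric matrix, rows = samples, columns = loading states
#' @param alpha significance level
#' @return a `test_result` (F statistic of the within-sample load effect)
#' @export
compare_pixel_counts <- function(counts, alpha = 0.005) {
  counts <- as.matrix(counts)
  n <- nrow(counts); k <- ncol(counts)
  df <- data.frame(count = as.vector(counts),
                   load = factor(rep(seq_len(k), each = n)),
                   sample = factor(rep(seq_len(n), k)))
  fit <- stats::aov(count ~ load + Error(sample / load), data = df)
  s <- summary(fit)[["Error: sample:load"]][[1]]
  test_result("repeated-measures ANOVA", s[["F value"]][1],
              s[["Pr(>F)"]][1], NULL, alpha, "asymptotic")
}

#' Spearman correlation between qMRI summaries and Elastic Modulus
#'
#' Tie-aware Spearman rank correlation; constant input yields a missing
#' result rather than an error.
#'
#' @param qmri per-sample qMRI ROI medians (ms)
#' @param em per-sample Elastic Modulus values (MPa)
#' @return list with `rho`, `p.value`, `n`
#' @export
correlate_qmri_biomech <- function(qmri, em) {
  keep <- !is.na(qmri) & !is.na(em)
  qmri <- qmri[keep]; em <- em[keep]
  if (length(qmri) < 5L) stop("need at least 5 paired samples")
  if (stats::sd(qmri) == 0 || stats::sd(em) == 0) {
    message("constant input; Spearman correlation missing")
    return(list(rho = NA_real_, p.value = NA_real_, n = length(qmri)))
  }
  ct <- suppressWarnings(stats::cor.test(qmri, em, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p.value = unname(ct$p.value),
       n = length(qmri))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample-skewness and sample-kurtosis z scores
#' into K-squared = z1^2 + z2^2, referred to a chi-square distribution
#' with 2 degrees of freedom.
#'
#' @param x numeric vector, n >= 8
#' @return list with `statistic` (K-squared) and `p.value`
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  # skewness z (D'Agostino)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z (Anscombe-Glynn)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2,
                                               lower.tail = FALSE))
}

test_result <- function(test, statistic, p_value, posthoc, alpha, p_method) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 posthoc = posthoc, alpha = alpha, p_method = p_method,
                 significant = isTRUE(p_value <= alpha)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s)%s\n", x$test,
              x$statistic, x$p_value, x$p_method,
              if (isTRUE(x$significant)) " *" else ""))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc (Dunn):",
        paste(sprintf("%s %s", x$posthoc$comparison,
                      ifelse(x$posthoc$significant, "*", "ns")),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- internals ------------------------------------------------------------

kw_statistic <- function(r, groups, tie_corr, n) {
  sums <- tapply(r, groups, sum)
  sizes <- tabulate(groups)
  h <- 12 / (n * (n + 1)) * sum(sums^2 / sizes) - 3 * (n + 1)
  h / tie_corr
}

perm_p_kruskal <- function(values, groups, observed, n_perm) {
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  g <- as.integer(groups)
  count <- 0L
  for (b in seq_len(n_perm)) {
    h <- kw_statistic(r, sample(g), tie_corr, n)
    if (h >= observed - 1e-12) count <- count + 1L
  }
  (count + 1) / (n_perm + 1)
}

perm_p_friedman <- function(y, observed, n_perm) {
  n <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1, rank))
  count <- 0L
  for (b in seq_len(n_perm)) {
    rp <- t(apply(r, 1, sample))
    stat <- friedman_statistic(rp, n, k)
    if (stat >= observed - 1e-12) count <- count + 1L
  }
  (count + 1) / (n_perm + 1)
}

friedman_statistic <- function(r, n, k) {
  # tie-corrected Friedman chi-square from a matrix of within-block ranks
  cs <- colSums(r)
  num <- (k - 1) * sum((cs - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (den == 0) return(0)
  num / den
}

dunn_kruskal <- function(values, groups, alpha) {
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  mean_r <- tapply(r, groups, mean)
  sizes <- table(groups)
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- (mean_r[[a]] - mean_r[[b]]) / se
    p <- min(2 * stats::pnorm(-abs(z)) * ncol(pairs), 1)
    data.frame(comparison = paste(a, "vs", b), z = z, p_adj = p,
               significant = p <= alpha)
  })
  do.call(rbind, res)
}

dunn_friedman <- function(y, alpha) {
  n <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1, rank))
  mean_r <- colMeans(r)
  # tie correction over blocks
  tie_sum <- sum(apply(y, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  var0 <- k * (k + 1) / (6 * n)
  se <- sqrt(var0 * (1 - tie_sum / (n * k * (k^2 - 1))))
  labs <- colnames(y)
  pairs <- utils::combn(seq_len(k), 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    z <- if (se == 0) 0 else (mean_r[a] - mean_r[b]) / se
    p <- min(2 * stats::pnorm(-abs(z)) * m, 1)
    data.frame(comparison = paste(labs[a], "vs", labs[b]), z = z,
               p_adj = p, significant = p <= alpha)
  })
  do.call(rbind, res)
}
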