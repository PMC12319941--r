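#' Paired t-test
#'
#' Classical paired t on two equal-length vectors (or a one-sample test of
#' `x` against a constant `y`). One-tailed tests halve the two-tailed p on
#' the predicted side. When every pairwise difference is exactly zero the
#' test is the trivial t = 0; a degenerate nonzero constant difference (zero
#' variance) is an error.
#'
#' @param x,y Paired observations.
#' @param tails 1 or 2.
#' @param direction For one-tailed tests, `"greater"` (x > y predicted) or
#'   `"less"`.
#' @return An object of class `navaff_ttest` with fields `t`, `df`, `p`,
#'   `tails`, `direction`, `n`, `mean_diff`; see [tidy.navaff_ttest()].
#' @examples
#' paired_t(c(2, 3, 5, 4), c(1, 1, 2, 1), tails = 1, direction = "greater")
#' @export
paired_t <- function(x, y, tails = 2, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3)
    stop("paired t-test requires at least 3 pairs", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      res <- list(t = 0, df = length(d) - 1,
                  p = if (tails == 2) 1 else 0.5)
    } else {
      stop("zero variance of paired differences", call. = FALSE)
    }
  } else {
    alt <- if (tails == 2) "two.sided" else direction
    tt <- stats::t.test(x, y, paired = TRUE, alternative = alt)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(c(res, list(tails = tails, direction = direction,
                        n = length(d), mean_diff = mean(d))),
            class = "navaff_ttest")
}

#' @export
print.navaff_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test (%d-tailed%s): t(%g) = %.3f, p = %.4g\n",
              x$tails, if (x$tails == 1) paste0(", ", x$direction) else "",
              x$df, x$t, x$p))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for test results
#'
#' @param x A `navaff_ttest` or `rm_anova` object.
#' @param ... Unused.
#' @return A tibble: one row per statistic (`tidy`) or a one-row model
#'   summary (`glance`).
#' @export
tidy.navaff_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$mean_diff, statistic = x$t, df = x$df,
                 p.value = x$p, tails = x$tails, direction = x$direction)
}

#' @rdname tidy.navaff_ttest
#' @export
glance.navaff_ttest <- function(x, ...) {
  tibble::tibble(n = x$n, method = "paired t-test", tails = x$tails)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor for a k-level within-subject factor,
#' computed from the sample covariance of the condition-level data:
#' `epsilon = tr(S~)^2 / ((k - 1) * tr(S~^2))` where `S~` is the
#' double-centered covariance. Two-level factors are spherical by
#' construction (`epsilon = 1` exactly).
#'
#' @param x Either a k x k covariance matrix of the within-subject levels,
#'   or an n-subjects x k data matrix (covariance taken internally).
#' @return Epsilon in `(1/(k-1), 1]`.
#' @export
gg_epsilon <- function(x) {
  x <- as.matrix(x)
  S <- if (nrow(x) == ncol(x) && isSymmetric(unname(x), tol = 1e-8)) x
       else stats::cov(x)
  k <- ncol(S)
  if (k < 2) stop("epsilon requires a factor with at least 2 levels",
                  call. = FALSE)
  Cn <- diag(k) - 1 / k
  St <- Cn %*% S %*% Cn
  tr1 <- sum(diag(St))
  tr2 <- sum(St * St)
  if (tr2 <= .Machine$double.eps) return(1)
  min(1, tr1^2 / ((k - 1) * tr2))
}

# Normalized Helmert contrast matrix (k x (k-1)) with orthonormal columns,
# each orthogonal to the unit vector.
helmert_orth <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), `/`)
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Both factors within-subject, one observation per subject x cell
#' (complete, balanced). Effects are tested by projecting each subject's
#' cell vector onto orthonormal effect contrasts; each effect's error term
#' is its own subject-by-effect interaction, and its Greenhouse-Geisser
#' epsilon comes from the covariance of the contrast scores. Both
#' uncorrected and corrected df/p are reported.
#'
#' @param data Data frame with one row per subject x cell.
#' @param dv,subject,a,b Column names of the response, subject id, and the
#'   two within-subject factors.
#' @return An object of class `rm_anova`: a tibble with one row per effect
#'   (`a`, `b`, `a:b`) and columns `F`, `df1`, `df2`, `epsilon_gg`,
#'   `df1_gg`, `df2_gg`, `p`, `p_gg`.
#' @export
rm_anova_2way <- function(data, dv = "value", subject = "subject",
                          a = "a", b = "b") {
  d <- data[, c(subject, a, b, dv)]
  names(d) <- c(".subject", ".a", ".b", ".value")
  for (col in c(".subject", ".a", ".b"))
    d[[col]] <- if (is.factor(d[[col]])) droplevels(d[[col]]) else d[[col]]
  la <- sort(unique(d$.a))
  lb <- sort(unique(d$.b))
  subs <- sort(unique(d$.subject))
  n <- length(subs)
  ka <- length(la)
  kb <- length(lb)
  if (n < 3) stop("repeated-measures ANOVA requires at least 3 subjects",
                  call. = FALSE)
  tab <- table(d$.subject, d$.a, d$.b)
  if (any(tab != 1))
    stop(paste("unbalanced or incomplete within-subject table; drop",
               "incomplete subjects before calling rm_anova_2way()"),
         call. = FALSE)
  d <- d[order(match(d$.subject, subs), match(d$.a, la), match(d$.b, lb)), ]
  Y <- matrix(d$.value, nrow = n, byrow = TRUE)  # cells ordered a slow, b fast
  Ca <- helmert_orth(ka)
  Cb <- helmert_orth(kb)
  ua <- matrix(1 / sqrt(ka), ka, 1)
  ub <- matrix(1 / sqrt(kb), kb, 1)
  effects <- list(
    list(name = a, M = kronecker(Ca, ub)),
    list(name = b, M = kronecker(ua, Cb)),
    list(name = paste(a, b, sep = ":"), M = kronecker(Ca, Cb))
  )
  rows <- purrr::map(effects, function(e) {
    sc <- Y %*% e$M
    dfe <- ncol(sc)
    m <- colMeans(sc)
    ss_eff <- n * sum(m^2)
    ss_err <- sum(sweep(sc, 2, m)^2)
    if (ss_eff <= 1e-12 * max(1, ss_err)) {
      F <- 0
    } else if (ss_err <= .Machine$double.eps) {
      F <- Inf
    } else {
      F <- (ss_eff / dfe) / (ss_err / (dfe * (n - 1)))
    }
    Sg <- stats::cov(sc)
    tr2 <- sum(Sg * Sg)
    eps <- if (tr2 <= .Machine$double.eps) 1
           else min(1, sum(diag(Sg))^2 / (dfe * tr2))
    df2 <- dfe * (n - 1)
    tibble::tibble(effect = e$name, F = F, df1 = dfe, df2 = df2,
                   epsilon_gg = eps, df1_gg = eps * dfe, df2_gg = eps * df2,
                   p = stats::pf(F, dfe, df2, lower.tail = FALSE),
                   p_gg = stats::pf(F, eps * dfe, eps * df2,
                                    lower.tail = FALSE))
  })
  structure(dplyr::bind_rows(rows), n = n, factors = c(a, b),
            class = c("rm_anova", "tbl_df", "tbl", "data.frame"))
}

#' Post hoc 2 x 2 interaction contrast
#'
#' Restricts the data to two levels of each factor and tests the
#' interaction; with both factors at 2 levels this is equivalent to a paired
#' t-test on the per-subject double difference (F = t^2).
#'
#' @inheritParams rm_anova_2way
#' @param levels_a,levels_b Optional pair of levels to keep for each factor
#'   (defaults to all, which must then be 2).
#' @return A one-row `rm_anova` tibble for the interaction effect.
#' @export
interaction_contrast_2x2 <- function(data, dv = "value", subject = "subject",
                                     a = "a", b = "b",
                                     levels_a = NULL, levels_b = NULL) {
  if (!is.null(levels_a)) data <- data[data[[a]] %in% levels_a, ]
  if (!is.null(levels_b)) data <- data[data[[b]] %in% levels_b, ]
  if (length(unique(data[[a]])) != 2 || length(unique(data[[b]])) != 2)
    stop("interaction contrast requires exactly 2 levels of each factor",
         call. = FALSE)
  res <- rm_anova_2way(data, dv = dv, subject = subject, a = a, b = b)
  out <- res[res$effect == paste(a, b, sep = ":"), ]
  structure(out, n = attr(res, "n"), factors = attr(res, "factors"),
            class = class(res))
}

#' @rdname tidy.navaff_ttest
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.navaff_ttest
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"),
                 factors = paste(attr(x, "factors"), collapse = " x "),
                 n_effects = nrow(x))
}

#' Power of the paired t-test
#'
#' Exact power from the noncentral t distribution: with `n` pairs,
#' standardized effect size `d` and level `alpha`, the test statistic has
#' `n - 1` df and noncentrality `d * sqrt(n)`. Two-tailed power counts both
#' rejection regions.
#'
#' @param n Number of pairs (>= 2).
#' @param d Standardized paired effect size (Cohen's d, >= 0).
#' @param alpha Significance level in (0, 1).
#' @param tails 1 or 2.
#' @return Power (probability of rejection).
#' @examples
#' power_paired_t(16, 0.8) # planned power for a large effect
#' @export
power_paired_t <- function(n, d, alpha = 0.05, tails = 2) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  stopifnot(n >= 2, d >= 0, tails %in% c(1, 2))
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}
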