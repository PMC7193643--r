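# orthonormal basis of the column span of X (tolerance-ranked SVD)
span_basis <- function(X) {
  if (is.null(X) || ncol(X) == 0L) return(matrix(0, nrow(X), 0L))
  s <- svd(X)
  keep <- s$d > max(dim(X)) * .Machine$double.eps * s$d[1]
  s$u[, keep, drop = FALSE]
}

proj_ss <- function(Q, Y) if (ncol(Q) == 0L) 0 else sum(crossprod(Q, Y)^2)

#' Permutational multivariate analysis of (co)variance
#'
#' Distance-based MANOVA/MANCOVA on Euclidean distances computed from the
#' raw response(s), i.e. the Gower-centred inner-product partitioning that
#' reduces to classical sums of squares for Euclidean geometry. Each term
#' is tested conditionally on all other terms: its sum of squares is the
#' increment in explained SS when the term's columns are added to the
#' design holding everything else, and the pseudo-F uses the full-model
#' residual mean square as denominator. Significance comes from
#' permutation of residuals under the reduced model (the design without
#' the tested term; Freedman-Lane): reduced-model residual rows are
#' permuted, added back to the reduced-model fit, and the pseudo-F
#' recomputed, with
#' `p = (1 + #(F* >= F)) / (n_permutations + 1)`.
#'
#' List the covariate first in the formula so the printed table mirrors a
#' covariate-first layout; with the conditional SS used here the order
#' does not change the tests. Nested factors are written with the usual
#' `outer / inner` (or `outer + outer:inner`) formula idiom.
#'
#' @param data Data frame with one row per observation.
#' @param formula Model formula; multiple responses via
#'   `cbind(y1, y2, ...) ~ ...`.
#' @param n_permutations Number of random permutations (default 999, so
#'   the smallest attainable p is 0.001).
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `perm_mancova`; see [tidy.perm_mancova()].
#' @export
perm_mancova <- function(data, formula, n_permutations = 999, seed = NULL) {
  if (n_permutations < 1) stop_ts("`n_permutations` must be >= 1")
  mf <- stats::model.frame(formula, data)
  Y <- as.matrix(stats::model.response(mf))
  storage.mode(Y) <- "double"
  tt <- stats::terms(formula, data = data)
  labels <- attr(tt, "term.labels")
  if (length(labels) == 0L) stop_ts("the design has no terms to test")
  X <- stats::model.matrix(tt, mf)
  asgn <- attr(X, "assign")
  n <- nrow(Y)

  Qfull <- span_basis(X)
  rank_full <- ncol(Qfull)
  df_res <- n - rank_full
  if (df_res < 1) stop_ts("no residual degrees of freedom")
  ss_res <- sum(Y^2) - proj_ss(Qfull, Y)
  ss_total <- sum(sweep(Y, 2, colMeans(Y))^2)

  degenerate <- ss_total <= 1e-10 * n
  if (degenerate)
    message("responses carry no variation; pseudo-F undefined, p = 1")

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  if (!is.null(seed)) {
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }

  res <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    Qred <- span_basis(X[, asgn != k, drop = FALSE])
    df_k <- rank_full - ncol(Qred)
    if (df_k < 1)
      stop_ts("term `", labels[k],
              "` is aliased with the rest of the design (0 df)")
    ss_k <- proj_ss(Qfull, Y) - proj_ss(Qred, Y)
    if (degenerate) {
      res[[k]] <- tibble::tibble(term = labels[k], df = df_k, sum_sq = 0,
                                 pseudo_F = NA_real_, p_perm = 1)
      next
    }
    f_obs <- (ss_k / df_k) / (ss_res / df_res)
    fitted_red <- Qred %*% crossprod(Qred, Y)
    E <- Y - fitted_red
    n_ge <- 0L
    for (b in seq_len(n_permutations)) {
      Yb <- fitted_red + E[sample.int(n), , drop = FALSE]
      ss_k_b <- proj_ss(Qfull, Yb) - proj_ss(Qred, Yb)
      ss_res_b <- sum(Yb^2) - proj_ss(Qfull, Yb)
      f_b <- (ss_k_b / df_k) / (ss_res_b / df_res)
      if (f_b >= f_obs - 1e-12) n_ge <- n_ge + 1L
    }
    res[[k]] <- tibble::tibble(term = labels[k], df = df_k, sum_sq = ss_k,
                               pseudo_F = f_obs,
                               p_perm = (n_ge + 1) / (n_permutations + 1))
  }
  table <- dplyr::bind_rows(res)
  n_unique <- if (n <= 170) factorial(n) else Inf
  if (n_unique < 100)
    warning("only ", n_unique, " unique permutations are possible; ",
            "permutation p-values are coarse", call. = FALSE)
  structure(list(table = table,
                 residual = tibble::tibble(term = "Residual", df = df_res,
                                           sum_sq = ss_res),
                 total = tibble::tibble(term = "Total", df = n - 1,
                                        sum_sq = ss_total),
                 n_obs = n, n_responses = ncol(Y),
                 n_permutations = n_permutations,
                 n_unique_permutations = n_unique,
                 scheme = paste("permutation of residuals under the",
                                "reduced model (Freedman-Lane);",
                                "denominator: full-model residual mean",
                                "square"),
                 seed = seed),
            class = "perm_mancova")
}

#' @export
print.perm_mancova <- function(x, ...) {
  cat("Permutational MANCOVA (Euclidean distances, ",
      x$n_permutations, " permutations)\n", sep = "")
  cat("Scheme: ", x$scheme, "\n\n", sep = "")
  print(as.data.frame(dplyr::bind_rows(
    x$table, x$residual, x$total)), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a permutational MANCOVA
#'
#' @param x A [perm_mancova()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per tested term (`term`, `df`, `sum_sq`,
#'   `pseudo_F`, `p_perm`); `glance()`: one-row model summary.
#' @export
tidy.perm_mancova <- function(x, ...) x$table

#' @rdname tidy.perm_mancova
#' @export
glance.perm_mancova <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_responses = x$n_responses,
                 df_residual = x$residual$df,
                 n_permutations = x$n_permutations,
                 n_unique_permutations = x$n_unique_permutations)
}

#' Friedman rank test for complete blocks
#'
#' Rank-based comparison of `k >= 3` related treatments over complete
#' blocks (tie-corrected chi-square approximation). The degenerate case of
#' no within-block variation returns statistic 0, p = 1.
#'
#' @param data Long-format data frame.
#' @param response,treatment,block Columns (bare names) holding the value,
#'   the treatment level, and the block id.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_blocks`,
#'   `n_treatments`.
#' @export
friedman_test <- function(data, response, treatment, block) {
  y <- dplyr::pull(data, {{ response }})
  g <- factor(dplyr::pull(data, {{ treatment }}))
  b <- factor(dplyr::pull(data, {{ block }}))
  k <- nlevels(g)
  if (k < 3) stop_ts("Friedman test needs at least 3 treatments")
  counts <- table(b, g)
  if (any(counts != 1L))
    stop_ts("incomplete blocks: every block must contain every treatment ",
            "exactly once")
  spread <- tapply(y, b, function(v) diff(range(v)))
  if (all(spread == 0)) {
    return(tibble::tibble(statistic = 0, df = k - 1, p_value = 1,
                          n_blocks = nlevels(b), n_treatments = k))
  }
  ft <- stats::friedman.test(y, g, b)
  tibble::tibble(statistic = unname(ft$statistic),
                 df = unname(ft$parameter),
                 p_value = ft$p.value,
                 n_blocks = nlevels(b), n_treatments = k)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (with their count reported). The p-value is exact for up to
#' `exact_max` non-zero pairs and a normal approximation with continuity
#' correction beyond that.
#'
#' @param x Numeric vector of differences, or first member of each pair.
#' @param y Optional second member; differences are `x - y`.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return One-row tibble: `statistic` (V), `p_value`, `n_used`,
#'   `n_zero_dropped`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nz <- d != 0
  n_dropped <- sum(!nz)
  d <- d[nz]
  if (length(d) == 0L) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(tibble::tibble(statistic = NA_real_, p_value = 1, n_used = 0L,
                          n_zero_dropped = n_dropped,
                          method = "degenerate"))
  }
  exact <- length(d) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_used = length(d), n_zero_dropped = n_dropped,
                 method = if (exact) "exact" else
                   "normal approximation with continuity correction")
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a family of `m` comparisons (`m` may exceed
#' the number of p-values supplied).
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < length(p)) stop_ts("`m` must be at least length(p)")
  stats::p.adjust(p, method = "bonferroni", n = m)
}
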