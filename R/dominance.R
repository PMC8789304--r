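# Chi-square machinery for subgenome-biased retention and auto- vs
# allotetraploidy classification.

#' Chi-square upper-tail probability
#'
#' Survival function of the chi-square distribution, computed through the
#' regularized upper incomplete gamma function.
#'
#' @param x statistic (>= 0).
#' @param df degrees of freedom (> 0).
#' @return `P(X >= x)`.
#' @export
chisq_sf <- function(x, df) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop("x must be numeric and >= 0")
  }
  if (!is.numeric(df) || any(df <= 0)) stop("df must be > 0")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' F-distribution upper-tail probability
#'
#' Survival function of the F distribution, computed through the
#' regularized incomplete beta function.
#'
#' @param x statistic (>= 0).
#' @param d1,d2 numerator and denominator degrees of freedom (> 0).
#' @return `P(F >= x)`.
#' @export
f_sf <- function(x, d1, d2) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop("x must be numeric and >= 0")
  }
  if (!is.numeric(d1) || any(d1 <= 0) || !is.numeric(d2) || any(d2 <= 0)) {
    stop("degrees of freedom must be > 0")
  }
  stats::pf(x, d1, d2, lower.tail = FALSE)
}

#' Chi-square goodness-of-fit test
#'
#' Pearson's statistic `sum((O - E)^2 / E)` with `df = k - 1`; the expected
#' vector is rescaled to the observed total.
#'
#' @param observed vector of counts.
#' @param expected vector of strictly positive expectations (any scale).
#' @return a `mirna_test` with statistic, df, p-value, and the
#'   observed/expected vectors.
#' @export
chisq_gof <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have the same length")
  }
  if (length(observed) < 2L) stop("need at least two categories")
  if (any(observed < 0)) stop("observed counts must be >= 0")
  if (any(expected <= 0)) {
    stop("expected values must all be > 0; pool sparse categories first")
  }
  expected <- expected * sum(observed) / sum(expected)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  new_mirna_test(stat, df, chisq_sf(stat, df), "chi-square goodness-of-fit",
                 observed = observed, expected = expected)
}

# Pool a four-slot column-total vector into the requested two-way contrast.
pool_slots <- function(totals, contrast = c("alpha_beta", "one_two")) {
  contrast <- match.arg(contrast)
  missing <- setdiff(SUBGENOME_SLOTS, names(totals))
  if (length(missing)) {
    stop("retention table lacks subgenome slots: ",
         paste(missing, collapse = ", "))
  }
  if (contrast == "alpha_beta") {
    c(alpha = unname(totals["1a"] + totals["2a"]),
      beta = unname(totals["1b"] + totals["2b"]))
  } else {
    c(one = unname(totals["1a"] + totals["1b"]),
      two = unname(totals["2a"] + totals["2b"]))
  }
}

table_totals <- function(table) {
  if (is.matrix(table)) colSums(table) else table
}

#' Test for subgenome-biased retention
#'
#' Pools the four subgenome columns of a retention table into the requested
#' contrast (alpha = 1a+2a vs beta = 1b+2b, or 1 = 1a+1b vs 2 = 2a+2b) and
#' tests the pooled unit counts against equality with a chi-square
#' goodness-of-fit test (df = 1). Under allotetraploidy the alpha-beta
#' contrast is expected to reject; under autotetraploidy neither should.
#'
#' @param table a retention matrix (multiplicity x slot) or named vector of
#'   per-slot totals covering `1a, 2a, 1b, 2b`.
#' @param contrast `"alpha_beta"` or `"one_two"`.
#' @return a `mirna_test`.
#' @export
subgenome_bias_test <- function(table, contrast = c("alpha_beta", "one_two")) {
  contrast <- match.arg(contrast)
  obs <- pool_slots(table_totals(table), contrast)
  res <- chisq_gof(obs, c(1, 1))
  res$test_name <- paste0("subgenome bias (",
                          if (contrast == "alpha_beta") "alpha vs beta"
                          else "1 vs 2", ")")
  res
}

#' Classify a WGD as auto- or allotetraploidy
#'
#' Calls the event allotetraploid iff the relevant retention contrast
#' rejects equality at `alpha_level`; the dominant subgenome is the pooled
#' side with the larger count. A non-significant contrast yields an "auto"
#' call (symmetric loss, no dominant subgenome).
#'
#' @param table retention matrix or per-slot totals (see
#'   [subgenome_bias_test()]).
#' @param alpha_level significance level.
#' @param contrast pooled contrast tested (default alpha vs beta, the
#'   second-WGD contrast).
#' @return a list of class `mode_call`: `call` (`"auto"`/`"allo"`),
#'   `dominant_subgenome` (`NA` for auto calls), `alpha_level`, and the
#'   supporting `mirna_test`.
#' @export
classify_wgd_mode <- function(table, alpha_level = 0.05,
                              contrast = c("alpha_beta", "one_two")) {
  contrast <- match.arg(contrast)
  test <- subgenome_bias_test(table, contrast)
  allo <- test$p_value < alpha_level
  dominant <- if (allo) names(test$observed)[which.max(test$observed)] else NA
  structure(
    list(call = if (allo) "allo" else "auto",
         dominant_subgenome = dominant,
         alpha_level = alpha_level, test = test),
    class = "mode_call"
  )
}

#' @export
print.mode_call <- function(x, ...) {
  cat(sprintf("WGD mode call: %s%s (p = %.4g at alpha = %g)\n", x$call,
              if (!is.na(x$dominant_subgenome)) {
                paste0(", dominant subgenome ", x$dominant_subgenome)
              } else "",
              x$test$p_value, x$alpha_level))
  invisible(x)
}

#' Test for continued subgenome-biased loss after an LCA
#'
#' Tests whether post-LCA losses are distributed across the four subgenome
#' slots in proportion to how many units each slot held in the LCA
#' (chi-square goodness-of-fit, df = 3). A rejection with excess beta
#' losses indicates that fractionation bias persists long after the
#' allotetraploidy event.
#'
#' @param losses named per-slot loss tallies (see
#'   [continued_loss_counts()]).
#' @param lca_counts named per-slot unit counts at the LCA.
#' @return a `mirna_test`.
#' @export
continued_loss_test <- function(losses, lca_counts) {
  if (is.null(names(losses)) || is.null(names(lca_counts))) {
    stop("losses and lca_counts must be named by subgenome slot")
  }
  lca_counts <- lca_counts[names(losses)]
  if (anyNA(lca_counts)) stop("lca_counts must cover every slot in losses")
  zero <- lca_counts == 0
  if (any(zero & losses > 0)) {
    stop("nonzero losses on a slot with zero LCA count: ",
         paste(names(losses)[zero & losses > 0], collapse = ", "))
  }
  if (any(zero)) {
    losses <- losses[!zero]
    lca_counts <- lca_counts[!zero]
  }
  res <- chisq_gof(losses, lca_counts)
  res$test_name <- "continued post-LCA loss bias"
  res
}
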