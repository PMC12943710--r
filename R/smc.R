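#' Z-score standardization
#'
#' Centers to mean 0 and scales to sample SD 1 (denominator n - 1).
#'
#' @param values numeric vector (>= 2 finite values).
#' @param name variable name used in error messages.
#' @return standardized vector.
#' @export
zscore <- function(values, name = deparse(substitute(values))) {
  if (length(values) < 2) stop("need >= 2 values to standardize '", name, "'")
  if (any(!is.finite(values))) stop("non-finite values in '", name, "'")
  s <- sd(values)
  if (s == 0) stop("zero variance in '", name, "': cannot z-score")
  (values - mean(values)) / s
}

#' Soil multi-nutrient cycling (SMC) index and its statistics
#'
#' The SMC index is the per-sample mean of the z-scores of exactly seven
#' nutrient variables: SOC, NO3, NH4, TN, TP, AP and AK. Standardization is
#' performed jointly across all samples (both stand types and ages) so
#' group contrasts are meaningful. Group differences are tested with the
#' Wilcoxon rank-sum test and covariate relationships (SMC ~ pH, SMC ~ SWC)
#' with ordinary least squares.
#'
#' @param frame metadata `data.frame` with the seven nutrient columns plus
#'   `stand_type`, `stand_age`, `pH` and `SWC` (see [read_metadata]).
#' @return an object of class `smc_result`: list with `smc` (named
#'   per-sample index), `group_means`, `wilcoxon` (per contrast), and `ols`
#'   (per covariate).
#' @export
smc_index <- function(frame) {
  vars <- c("SOC", "NO3", "NH4", "TN", "TP", "AP", "AK")
  miss <- setdiff(vars, names(frame))
  if (length(miss)) stop("missing SMC variable(s): ",
                         paste(miss, collapse = ", "))
  complete <- rowSums(!is.finite(as.matrix(frame[, vars]))) == 0
  if (any(!complete)) {
    warning("excluding sample(s) with missing soil values from SMC: ",
            paste(frame$sample_id[!complete], collapse = ", "))
    frame <- frame[complete, , drop = FALSE]
  }
  z <- vapply(vars, function(v) zscore(frame[[v]], v), numeric(nrow(frame)))
  smc <- rowMeans(z)
  names(smc) <- frame$sample_id %||% rownames(frame)

  out <- list(smc = smc, variables = vars)
  if (!is.null(frame$stand_type)) {
    g <- as.character(frame$stand_type)
    out$group_means <- tapply(smc, g, mean)
    out$wilcoxon <- list(
      stand_type = wilcoxon_rank_sum(smc[g == "P"], smc[g == "M"]))
    if (!is.null(frame$stand_age)) {
      a <- as.character(frame$stand_age)
      lv <- sort(unique(a))
      if (length(lv) == 2)
        out$wilcoxon$stand_age <-
          wilcoxon_rank_sum(smc[a == lv[1]], smc[a == lv[2]])
    }
  }
  out$ols <- list()
  for (v in c("pH", "SWC"))
    if (!is.null(frame[[v]])) out$ols[[v]] <- ols_fit(frame[[v]], smc)
  structure(out, class = "smc_result")
}

#' @export
print.smc_result <- function(x, ...) {
  cat("SMC index over", length(x$smc), "samples (mean",
      format(mean(x$smc), digits = 3), ")\n")
  if (!is.null(x$group_means)) {
    cat("group means:",
        paste(names(x$group_means), format(x$group_means, digits = 3),
              sep = " = ", collapse = ", "), "\n")
    cat("Wilcoxon (P vs M): W =", x$wilcoxon$stand_type$W,
        ", p =", format(x$wilcoxon$stand_type$p, digits = 3), "\n")
  }
  for (v in names(x$ols))
    cat(sprintf("OLS SMC ~ %s: slope %.3f, R2 %.3f, p %.3g\n", v,
                x$ols[[v]]$slope, x$ols[[v]]$r_squared, x$ols[[v]]$p))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p by enumeration when `nA + nB <= 12` and there are no
#' ties; otherwise the normal approximation with tie correction (no
#' continuity correction).
#'
#' @param x,y numeric samples for the two groups (each non-empty).
#' @return list with `W` (rank-sum statistic of `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  list(W = unname(wt$statistic), p = min(1, wt$p.value), exact = exact)
}

#' Simple ordinary least squares fit
#'
#' Closed-form one-predictor least squares with `R^2 = 1 - SSE/SST` and the
#' two-sided p-value of the slope t-statistic.
#'
#' @param x predictor values (non-degenerate, `n >= 3`).
#' @param y response values.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need n >= 3 for OLS")
  if (sd(x) == 0) stop("degenerate predictor (zero variance)")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]), n = n)
}
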