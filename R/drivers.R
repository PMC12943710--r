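#' Random-forest predictor importance with permutation significance
#'
#' Fits a regression forest and reports each predictor's %IncMSE (percent
#' increase in out-of-bag MSE when that predictor is permuted). Predictor
#' significance is assessed by refitting the forest with the *response*
#' permuted `n_perm` times and comparing the observed importance to the
#' null distribution:
#' `p = (1 + #(null >= obs)) / (1 + n_perm)`.
#'
#' @param x data.frame or matrix of predictors (n >= 10 rows, finite).
#' @param y numeric response (non-constant).
#' @param n_trees trees per forest (default 1000).
#' @param n_perm response permutations for significance (default 999).
#' @param seed integer seed.
#' @return object of class `importance_result`: data.frame per predictor
#'   (`predictor`, `inc_mse`, `p`) with attribute `var_explained`
#'   (out-of-bag pseudo R-squared).
#' @export
rf_importance <- function(x, y, n_trees = 1000, n_perm = 999, seed = 1) {
  x <- as.data.frame(x)
  if (nrow(x) < 10) stop("need >= 10 samples")
  if (any(!is.finite(as.matrix(x)))) stop("predictors must be finite")
  if (sd(y) == 0) stop("constant response")
  imp_of <- function(resp) {
    fit <- randomForest::randomForest(x, resp, ntree = n_trees,
                                      importance = TRUE)
    list(imp = randomForest::importance(fit, type = 1, scale = TRUE)[, 1],
         r2 = 1 - mean((resp - fit$predicted)^2) / var(resp) /
           ((length(resp) - 1) / length(resp)))
  }
  with_seed(seed, {
    obs <- imp_of(y)
    null_imp <- matrix(0, n_perm, ncol(x))
    for (b in seq_len(n_perm))
      null_imp[b, ] <- imp_of(sample(y))$imp
    p <- vapply(seq_len(ncol(x)), function(j)
      (1 + sum(null_imp[, j] >= obs$imp[j])) / (1 + n_perm), numeric(1))
    out <- data.frame(predictor = colnames(x), inc_mse = unname(obs$imp),
                      p = p, row.names = NULL)
    attr(out, "var_explained") <- obs$r2
    class(out) <- c("importance_result", "data.frame")
    out
  })
}

#' Recursive standardized path analysis
#'
#' Fits a declared acyclic path diagram by ordinary least squares on
#' z-scored variables: each endogenous variable is regressed on its
#' parents, the coefficients are standardized path weights, and effects on
#' the outcome are obtained by path tracing - the standardized total
#' effect (STE) of a source is the sum over all directed paths to the
#' outcome of the products of path coefficients (direct + indirect).
#'
#' @param data per-sample data.frame holding every variable in the diagram.
#' @param diagram data.frame of directed edges with columns `from`, `to`.
#' @param outcome the outcome variable; defaults to the unique sink.
#' @return object of class `path_model`: list with `coefficients`
#'   (per-edge standardized weights), `effects` (per-variable direct,
#'   indirect, total on the outcome), `r_squared` and `mse` per equation.
#' @export
fit_path_model <- function(data, diagram, outcome = NULL) {
  stopifnot(all(c("from", "to") %in% names(diagram)))
  vars <- unique(c(diagram$from, diagram$to))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variable(s) missing from data: ",
                         paste(miss, collapse = ", "))
  g <- igraph::graph_from_data_frame(diagram[, c("from", "to")])
  if (!igraph::is_dag(g)) stop("path diagram must be acyclic")
  if (is.null(outcome)) {
    sinks <- vars[vapply(vars, function(v)
      !v %in% diagram$from, logical(1))]
    if (length(sinks) != 1)
      stop("outcome is ambiguous; pass `outcome` explicitly")
    outcome <- sinks
  }
  z <- as.data.frame(lapply(data[vars], function(v) zscore(as.numeric(v))))
  coefs <- diagram
  coefs$coefficient <- NA_real_
  r2 <- mse <- numeric(0)
  for (v in unique(diagram$to)) {
    parents <- diagram$from[diagram$to == v]
    if (nrow(z) < length(parents) + 2)
      stop("too few samples for equation of ", v)
    fit <- lm(reformulate(sprintf("`%s`", parents), response = sprintf("`%s`", v)), data = z)
    b <- coef(fit)[-1]
    names(b) <- parents
    coefs$coefficient[coefs$to == v] <- unname(b[coefs$from[coefs$to == v]])
    r2[v] <- summary(fit)$r.squared
    mse[v] <- mean(fit$residuals^2)
  }
  ## path tracing: total effect on the outcome by dynamic programming over
  ## the DAG (effect(outcome) = 1; effect(v) = sum over children of
  ## coefficient * effect(child))
  total_to <- setNames(numeric(length(vars)), vars)
  total_to[outcome] <- 1
  order_rev <- rev(names(igraph::topo_sort(g)))
  for (v in order_rev) {
    if (v == outcome) next
    kids <- coefs[coefs$from == v, , drop = FALSE]
    total_to[v] <- sum(kids$coefficient * total_to[kids$to])
  }
  direct <- setNames(numeric(length(vars)), vars)
  de <- coefs[coefs$to == outcome, , drop = FALSE]
  direct[de$from] <- de$coefficient
  effects <- data.frame(variable = vars, direct = direct[vars],
                        indirect = total_to[vars] - direct[vars],
                        total = total_to[vars], row.names = NULL)
  effects <- effects[effects$variable != outcome, , drop = FALSE]
  structure(list(coefficients = coefs, effects = effects, outcome = outcome,
                 r_squared = r2, mse = mse, n = nrow(z)),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("recursive path model, outcome:", x$outcome,
      sprintf("(R2 = %.2f)\n", x$r_squared[x$outcome]))
  for (i in seq_len(nrow(x$coefficients)))
    cat(sprintf("  %s -> %s: %.3f\n", x$coefficients$from[i],
                x$coefficients$to[i], x$coefficients$coefficient[i]))
  cat("standardized total effects on", x$outcome, ":\n")
  for (i in seq_len(nrow(x$effects)))
    cat(sprintf("  %s: total %.3f (direct %.3f, indirect %.3f)\n",
                x$effects$variable[i], x$effects$total[i],
                x$effects$direct[i], x$effects$indirect[i]))
  invisible(x)
}

#' Assemble the per-sample driver table
#'
#' Joins per-sample alpha diversity of both kingdoms (prefixed `B_`/`F_`),
#' cohesion-based network complexity, per-sample assembly summaries (mean
#' betaNTI over pairs involving the sample; the sample group's MST), the
#' SMC index and the soil variables into one table keyed by sample id.
#'
#' @param results a `rhizo_results` list from [run_pipeline].
#' @return data.frame with one row per sample and no missing cells.
#' @export
assemble_driver_table <- function(results) {
  for (stage in c("meta", "smc", "alpha", "cohesion", "assembly"))
    if (is.null(results[[stage]]))
      stop("missing upstream stage: ", stage)
  meta <- results$meta
  ids <- meta$sample_id
  out <- data.frame(sample_id = ids,
                    stand_type = as.character(meta$stand_type),
                    SMC = unname(results$smc$smc[ids]))
  for (kd in c("bacteria", "fungi")) {
    pre <- if (kd == "bacteria") "B_" else "F_"
    a <- results$alpha[[kd]]
    for (v in c("shannon", "simpson", "chao1", "pielou"))
      out[[paste0(pre, v)]] <- a[ids, v]
  }
  coh <- results$cohesion
  out$cohesion_pos <- coh$cohesion_pos[match(ids, coh$sample_id)]
  out$cohesion_neg <- coh$cohesion_neg[match(ids, coh$sample_id)]
  for (kd in c("bacteria", "fungi")) {
    pre <- if (kd == "bacteria") "B_" else "F_"
    bnti <- results$assembly[[kd]]$bnti$bnti[ids, ids]
    diag(bnti) <- NA
    out[[paste0(pre, "mean_bnti")]] <- rowMeans(bnti, na.rm = TRUE)
    out[[paste0(pre, "mst")]] <-
      unname(results$assembly[[kd]]$mst[out$stand_type])
  }
  for (v in soil_variables()) out[[v]] <- meta[[v]]
  if (any(!is.finite(as.matrix(out[, -(1:2)]))))
    stop("driver table contains missing cells")
  out
}
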