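#' Full-factorial regression design matrix
#'
#' Builds the design matrix for a multiple linear regression with all main
#' effects and all interaction products of the included factors (2^m
#' columns including the intercept for m factors). The condition factor is
#' coded 0/1 (sham/tACS); continuous predictors are left on their raw
#' scale unless `standardize = TRUE`.
#'
#' @param predictors Data frame of per-subject predictors (columns among
#'   `condition`, `precision_spat`, `precision_freq`, `strength`,
#'   `strength_skin`, `strength_eye`).
#' @param factors Character vector of factor names to include; `character(0)`
#'   gives the intercept-only design.
#' @param standardize Z-score continuous factors before expansion.
#' @return Numeric design matrix (n x 2^m) with an `"(Intercept)"` column.
#' @export
build_design <- function(predictors, factors, standardize = FALSE) {
  stopifnot(is.data.frame(predictors))
  if (anyNA(predictors[, factors, drop = FALSE]))
    stop("missing predictor values")
  dat <- predictors
  if ("condition" %in% names(dat) && !is.numeric(dat$condition))
    dat$condition <- as.integer(dat$condition == "tacs")
  if (standardize)
    for (f in setdiff(factors, "condition"))
      dat[[f]] <- as.numeric(scale(dat[[f]]))
  if (length(factors) == 0) {
    X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    fml <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
    X <- stats::model.matrix(fml, dat)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  X
}

#' Ordinary least squares fit with classical inference
#'
#' Fits the regression by least squares and reports per-term coefficients
#' with t and p values, the coefficient of determination, the overall F
#' test, and the Gaussian AIC (see [aic()]).
#'
#' @param design Design matrix from [build_design()] (with intercept).
#' @param response Numeric response vector (e.g. ROI power increase).
#' @return Object of class `model_fit`: `coefficients` (data frame with
#'   `term`, `beta`, `t`, `p`), `r_squared`, `f`, `df1`, `df2`, `p_value`,
#'   `aic`, `n`, `k`, `rss`, `residuals`, `fitted`, `design`, `response`.
#' @export
fit_ols <- function(design, response) {
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  y <- as.numeric(response)
  n <- length(y)
  k <- ncol(X)
  if (n <= k) stop("need more observations than design columns")
  fit <- stats::lm.fit(X, y)
  if (fit$rank < k) stop("design matrix is rank deficient")
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  df2 <- n - k
  sigma2 <- rss / df2
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  df1 <- k - 1
  fstat <- if (df1 > 0) (r2 / df1) / ((1 - r2) / df2) else NA_real_
  p_overall <- if (df1 > 0) stats::pf(fstat, df1, df2, lower.tail = FALSE) else NA_real_
  out <- structure(list(
    coefficients = data.frame(term = colnames(X), beta = unname(beta),
                              t = unname(tval), p = unname(pval)),
    r_squared = r2, f = fstat, df1 = df1, df2 = df2, p_value = p_overall,
    n = n, k = k, rss = rss, residuals = res, fitted = fit$fitted.values,
    design = X, response = y), class = "model_fit")
  out$aic <- aic(out)
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> R2 = %.3f, F(%d, %d) = %.3f, p = %.3g, AIC = %.2f\n",
              x$r_squared, x$df1, x$df2, x$f, x$p_value, x$aic))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Gaussian AIC of a least-squares fit
#'
#' `AIC = n ln(RSS / n) + 2 (k + 1)`, counting the residual variance as an
#' estimated parameter alongside the k regression coefficients. Constant
#' additive terms shared by all models on the same data are dropped, so
#' only AIC differences are meaningful.
#'
#' @param fit A [fit_ols()] result.
#' @return AIC value.
#' @export
aic <- function(fit) {
  if (fit$rss <= 0) stop("degenerate perfect fit: RSS = 0")
  fit$n * log(fit$rss / fit$n) + 2 * (fit$k + 1)
}

#' All-subsets model comparison by AIC
#'
#' Fits one model per subset of the factor pool (including the empty
#' subset = intercept-only model), each subset carrying its full factorial
#' interaction structure, and ranks the candidates by AIC (ascending).
#'
#' @param predictors Predictor data frame (see [build_design()]).
#' @param pool Factor pool (m <= 6).
#' @param response Response vector.
#' @param standardize Passed to [build_design()].
#' @return Object of class `model_ranking`: `table` (data frame with
#'   `model`, `factors`, `k`, `r_squared`, `aic`, `delta_aic`, ordered by
#'   AIC), `fits` (list of `model_fit`s in table order), `failed`
#'   (character vector of subsets whose fit failed).
#' @export
all_subsets_selection <- function(predictors, pool, response,
                                  standardize = FALSE) {
  if (length(pool) > 6) stop("factor pool limited to 6 factors")
  subsets <- list(character(0))
  for (f in pool)
    subsets <- c(subsets, lapply(subsets, function(s) c(s, f)))
  fits <- list(); rows <- list(); failed <- character(0)
  for (s in subsets) {
    lab <- if (length(s)) paste(s, collapse = "+") else "(intercept)"
    fit <- tryCatch({
      X <- build_design(predictors, s, standardize = standardize)
      fit_ols(X, response)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, paste0(lab, ": ", conditionMessage(fit)))
      next
    }
    fits[[length(fits) + 1L]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      model = lab, n_factors = length(s), k = fit$k,
      r_squared = fit$r_squared, aic = fit$aic)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ord], failed = failed),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("<model_ranking> ", nrow(x$table), " candidate models\n", sep = "")
  print(utils::head(x$table, 10), digits = 3)
  invisible(x)
}

#' Leave-one-out cross-validation of a regression model
#'
#' Refits the model n times on n - 1 observations and predicts the held-out
#' observation each time. The cross-validated R2 is reported either as the
#' squared Pearson correlation between held-out predictions and
#' observations (default) or as `1 - PRESS / SS_tot`.
#'
#' @param design Design matrix (with intercept).
#' @param response Response vector.
#' @param definition `"corr2"` or `"press"`.
#' @return Object of class `loocv_result`: `predictions` (length n),
#'   `r_squared_cv`, `definition`, `press`.
#' @export
loocv <- function(design, response, definition = c("corr2", "press")) {
  definition <- match.arg(definition)
  X <- as.matrix(design)
  y <- as.numeric(response)
  n <- length(y)
  if (n <= ncol(X) + 1) stop("need n > columns + 1 for LOOCV refits")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])
    if (fit$rank < ncol(X)) stop("rank-deficient refit at observation ", i)
    preds[i] <- sum(X[i, ] * fit$coefficients)
  }
  press <- sum((y - preds)^2)
  r2cv <- switch(definition,
                 corr2 = stats::cor(preds, y)^2,
                 press = 1 - press / sum((y - mean(y))^2))
  structure(list(predictions = preds, observed = y, r_squared_cv = r2cv,
                 definition = definition, press = press, n = n),
            class = "loocv_result")
}

#' Within-subject sham-controlled response
#'
#' Per-subject difference of ROI power increases between the tACS and sham
#' sessions (power increase relative to baseline after tACS minus power
#' increase relative to baseline after sham).
#'
#' @param dpower_tacs,dpower_sham Numeric vectors of per-subject ROI power
#'   increases, subject-matched.
#' @return Numeric response vector.
#' @export
sham_controlled_response <- function(dpower_tacs, dpower_sham) {
  if (length(dpower_tacs) != length(dpower_sham))
    stop("both sessions must be present for every subject")
  if (anyNA(dpower_tacs) || anyNA(dpower_sham)) stop("missing session data")
  dpower_tacs - dpower_sham
}

#' Peripheral control model
#'
#' Fits the control model pool (skin strength, eye strength, frequency
#' precision) with the same all-subsets machinery, and compares its best
#' AIC with the best AIC of the brain-field model pool.
#'
#' @param predictors Predictor table including `strength_skin`,
#'   `strength_eye`, `precision_freq` (and the brain pool columns).
#' @param response Response vector.
#' @param brain_pool Factors of the brain-field model (default the
#'   3-factor targeting model).
#' @param peripheral_pool Factors of the control model.
#' @return List: `peripheral` (model_ranking), `brain` (model_ranking),
#'   `full_peripheral_fit` (the full 3-factor peripheral model),
#'   `best_aic_peripheral`, `best_aic_brain`, `brain_wins`.
#' @export
peripheral_model <- function(predictors, response,
                             brain_pool = c("precision_spat", "precision_freq",
                                            "strength"),
                             peripheral_pool = c("strength_skin", "strength_eye",
                                                 "precision_freq")) {
  per <- all_subsets_selection(predictors, peripheral_pool, response)
  brn <- all_subsets_selection(predictors, brain_pool, response)
  full_per <- fit_ols(build_design(predictors, peripheral_pool), response)
  list(peripheral = per, brain = brn, full_peripheral_fit = full_per,
       best_aic_peripheral = per$table$aic[1],
       best_aic_brain = brn$table$aic[1],
       brain_wins = brn$table$aic[1] < per$table$aic[1])
}

#' Export a fitted model and ranking as TSV
#'
#' @param fit A [fit_ols()] result.
#' @param ranking A [all_subsets_selection()] result.
#' @param path_terms,path_ranking Output paths (either may be `NULL`).
#' @export
write_model_tsv <- function(fit = NULL, ranking = NULL,
                            path_terms = NULL, path_ranking = NULL) {
  if (!is.null(fit) && !is.null(path_terms))
    utils::write.table(fit$coefficients, path_terms, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(ranking) && !is.null(path_ranking))
    utils::write.table(ranking$table, path_ranking, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
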