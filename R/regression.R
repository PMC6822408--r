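#' Counting model container
#'
#' A linear model GN = intercept + sum(coef * feature') over an ordered
#' subset of the normalized features (CD', Sk', Co'). Constructed by
#' [fit_count_model()] or taken from the published registry
#' [printed_models()].
#'
#' @param terms character subset of `c("cd", "sk", "co")`, in order.
#' @param coefficients numeric, one per term.
#' @param intercept numeric.
#' @param group optional list/character describing (subspecies, device,
#'   shape).
#' @param norm_stats optional `norm_stats` used to normalize new images.
#' @param fit_r2,fit_rmse optional in-sample fit statistics.
#' @return object of class `count_model`.
#' @export
count_model <- function(terms, coefficients, intercept, group = NULL,
                        norm_stats = NULL, fit_r2 = NULL, fit_rmse = NULL) {
  terms <- match.arg(terms, c("cd", "sk", "co"), several.ok = TRUE)
  if (length(coefficients) != length(terms))
    stop("need exactly one coefficient per term")
  structure(list(terms = terms, coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept), group = group,
                 norm_stats = norm_stats, fit_r2 = fit_r2,
                 fit_rmse = fit_rmse),
            class = "count_model")
}

#' @export
print.count_model <- function(x, ...) {
  lbl <- c(cd = "CD'", sk = "Sk'", co = "Co'")
  eq <- paste(sprintf("%.4g x %s", x$coefficients, lbl[x$terms]), collapse = " + ")
  cat("count_model: GN =", eq, sprintf("%+.4g", x$intercept), "\n")
  if (!is.null(x$group)) cat("  group:", paste(unlist(x$group), collapse = " / "), "\n")
  if (!is.null(x$fit_r2))
    cat(sprintf("  in-sample R2 = %.4f, RMSE = %.4f\n", x$fit_r2, x$fit_rmse))
  invisible(x)
}

#' Fit a linear counting model by ordinary least squares
#'
#' Regresses grain counts on the selected normalized features
#' (columns `cd_n`, `sk_n`, `co_n`) with an intercept, via `stats::lm()`.
#'
#' @param nf data frame of normalized features (from
#'   [normalize_features()]).
#' @param counts positive integer grain counts, one per row of `nf`.
#' @param terms ordered subset of `c("cd", "sk", "co")`; default all three.
#' @param group,norm_stats stored in the returned model (see
#'   [count_model()]).
#' @return a `count_model` with in-sample `fit_r2` and `fit_rmse`.
#' @export
fit_count_model <- function(nf, counts, terms = c("cd", "sk", "co"),
                            group = NULL, norm_stats = NULL) {
  terms <- match.arg(terms, c("cd", "sk", "co"), several.ok = TRUE)
  cols <- paste0(terms, "_n")
  if (!all(cols %in% names(nf))) stop("nf lacks normalized feature columns")
  if (length(counts) != nrow(nf)) stop("counts and nf lengths differ")
  if (any(counts <= 0)) stop("counts must be positive")
  if (nrow(nf) < length(terms) + 1) stop("need at least ", length(terms) + 1, " rows")
  df <- nf[, cols, drop = FALSE]
  df$.gn <- as.numeric(counts)
  fit <- lm(.gn ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) stop("rank-deficient design: collinear or constant features")
  pred <- fit$fitted.values
  ss_tot <- sum((counts - mean(counts))^2)
  r2 <- if (ss_tot > 0) 1 - sum((pred - counts)^2) / ss_tot else NA_real_
  count_model(terms = terms, coefficients = unname(cf[cols]),
              intercept = unname(cf[1]), group = group,
              norm_stats = norm_stats, fit_r2 = r2,
              fit_rmse = sqrt(mean((pred - counts)^2)))
}

# round half away from zero: 0.5 -> 1, -0.5 -> -1
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Predict grain number
#'
#' Evaluates the linear model on normalized features. The raw prediction is
#' returned unclamped; the integer count is rounded half-away-from-zero and
#' clamped to >= 0 for reporting.
#'
#' @param model a `count_model`.
#' @param nf data frame with columns `cd_n`/`sk_n`/`co_n` covering every
#'   model term (extra columns ignored), or a named numeric vector.
#' @return data frame with one row per input row: `gn_raw`, `gn_count`.
#' @examples
#' m <- printed_models()[["indica.scanner.B"]]
#' predict_count(m, data.frame(cd_n = 0, sk_n = 0, co_n = 0))
#' @export
predict_count <- function(model, nf) {
  stopifnot(inherits(model, "count_model"))
  if (is.numeric(nf) && !is.null(names(nf))) nf <- as.data.frame(as.list(nf))
  cols <- paste0(model$terms, "_n")
  missing <- setdiff(cols, names(nf))
  if (length(missing))
    stop("missing model term(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(nf[, cols, drop = FALSE])
  raw <- as.numeric(X %*% model$coefficients) + model$intercept
  data.frame(gn_raw = raw, gn_count = pmax(0, .round_half_away(raw)))
}

#' Evaluate predicted against true grain counts
#'
#' R2 = 1 - SS_res / SS_tot, RMSE = sqrt(mean((pred - truth)^2)), and mean
#' per-image counting accuracy = mean(1 - |pred - truth| / truth) x 100.
#'
#' @param preds numeric predictions (integer counts or raw values).
#' @param truths positive true counts of the same length.
#' @param accuracy compute the accuracy column (requires truths > 0).
#' @return object of class `eval_report`: list with `r2`, `rmse`,
#'   `accuracy_pct` and `n`. With zero variance in `truths` the R2 is
#'   undefined: reported as `NA` with a warning.
#' @examples
#' evaluate_model(c(100, 90), c(100, 100))
#' @export
evaluate_model <- function(preds, truths, accuracy = TRUE) {
  if (length(preds) != length(truths)) stop("preds and truths lengths differ")
  if (length(preds) < 1) stop("need at least one pair")
  ss_tot <- sum((truths - mean(truths))^2)
  ss_res <- sum((preds - truths)^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in truths: R2 undefined")
    NA_real_
  } else 1 - ss_res / ss_tot
  out <- list(r2 = r2,
              rmse = sqrt(mean((preds - truths)^2)),
              accuracy_pct = NA_real_,
              n = length(preds))
  if (accuracy) {
    if (any(truths <= 0)) stop("accuracy requires positive truths")
    out$accuracy_pct <- mean(1 - abs(preds - truths) / truths) * 100
  }
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (n=%d): R2=%.4f RMSE=%.4f accuracy=%.2f%%\n",
              x$n, x$r2, x$rmse, x$accuracy_pct))
  invisible(x)
}

#' Published multivariate counting models
#'
#' The eight optimal multivariate models (two subspecies x two devices x
#' two panicle shapes) with their published coefficients, e.g. for Indica,
#' Scanner + Shape B: GN = 364.93 CD' + 0.70 Sk' - 3.90 Co' + 2.801. These
#' models expect features normalized with the original training extremes,
#' so they serve as transcription references and worked examples rather
#' than drop-in predictors for new data.
#'
#' @return named list of 8 `count_model` objects, keyed
#'   `<subspecies>.<device>.<shape>` (e.g. `"indica.scanner.B"`).
#' @examples
#' printed_models()[["japonica.camera.B"]]
#' @export
printed_models <- function() {
  spec <- list(
    list("indica",   "scanner", "B", c(364.93, 0.70,   -3.90),   2.801,  0.990, 4.6732, 0.980, 6.3254),
    list("indica",   "scanner", "C", c(363.72, 10.50,  -13.48),  5.348,  0.990, 4.6345, 0.980, 6.3574),
    list("indica",   "camera",  "B", c(396.82, -21.70, -7.32),   11.823, 0.974, 7.6989, 0.965, 8.3016),
    list("indica",   "camera",  "C", c(395.60, -11.90, -16.90),  14.369, 0.975, 7.5595, 0.964, 8.3956),
    list("japonica", "scanner", "B", c(481.49, 178.22, -164.85), -18.485, 0.979, 6.0957, 0.975, 6.4714),
    list("japonica", "scanner", "C", c(482.28, 178.63, -164.00), -17.031, 0.980, 5.9838, 0.976, 6.4587),
    list("japonica", "camera",  "B", c(500.64, 188.62, -205.06), -5.477,  0.954, 9.1121, 0.953, 8.5389),
    list("japonica", "camera",  "C", c(501.43, 189.03, -204.22), -4.023,  0.954, 9.0961, 0.953, 8.5910))
  models <- lapply(spec, function(s)
    count_model(terms = c("cd", "sk", "co"), coefficients = s[[4]],
                intercept = s[[5]],
                group = list(subspecies = s[[1]], device = s[[2]], shape = s[[3]]),
                fit_r2 = s[[6]], fit_rmse = s[[7]]))
  names(models) <- vapply(spec, function(s)
    paste(s[[1]], s[[2]], s[[3]], sep = "."), "")
  models
}

#' Serialize a counting model
#' @param model a `count_model`.
#' @param path JSON file path.
#' @export
write_count_model <- function(model, path) {
  x <- unclass(model)
  if (!is.null(x$norm_stats)) x$norm_stats <- unclass(x$norm_stats)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_count_model
#' @export
read_count_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ns <- NULL
  if (!is.null(x$norm_stats) && length(x$norm_stats))
    ns <- structure(list(cd = as.numeric(x$norm_stats$cd),
                         sk = as.numeric(x$norm_stats$sk),
                         co = as.numeric(x$norm_stats$co),
                         group = x$norm_stats$group),
                    class = "norm_stats")
  count_model(terms = x$terms, coefficients = x$coefficients,
              intercept = x$intercept, group = x$group, norm_stats = ns,
              fit_r2 = x$fit_r2, fit_rmse = x$fit_rmse)
}
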