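#' Determination coefficient r2
#'
#' `1 - RSS/TSS`: the fraction of response variance explained by the
#' predictions.
#'
#' @param obs,pred Numeric vectors of equal length (>= 2).
#' @return r2 (dimensionless, <= 1).
#' @export
r_squared <- function(obs, pred) {
  .check_pair(obs, pred, min_n = 2)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) stop("observed values are constant: r2 undefined",
                     call. = FALSE)
  1 - sum((obs - pred)^2) / tss
}

#' Adjusted r2
#'
#' `((N - 1) r2 - p) / (N - 1 - p)`, penalizing model size.
#'
#' @param r2 Determination coefficient.
#' @param n Number of observations.
#' @param p Number of model parameters (descriptors or components).
#' @return Adjusted r2.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n - 1 - p <= 0) stop("no residual degrees of freedom", call. = FALSE)
  ((n - 1) * r2 - p) / (n - 1 - p)
}

#' Variance ratio (F statistic)
#'
#' Explained mean square over residual mean square:
#' `[sum(pred - mean(obs))^2 / p] / [sum(obs - pred)^2 / (N - p - 1)]`.
#' Returns `Inf` for a residual-free fit.
#'
#' @inheritParams r_squared
#' @param p Number of model parameters.
#' @return F value (or `Inf`).
#' @export
f_statistic <- function(obs, pred, p) {
  .check_pair(obs, pred, min_n = 2)
  n <- length(obs)
  if (n - p - 1 <= 0) stop("no residual degrees of freedom", call. = FALSE)
  rss <- sum((obs - pred)^2)
  ess <- sum((pred - mean(obs))^2)
  if (rss == 0) return(Inf)
  (ess / p) / (rss / (n - p - 1))
}

#' Standard error of estimate
#'
#' `sqrt(RSS / df)`. Both degrees-of-freedom conventions are exposed: the
#' default `n_minus_p_minus_1` matches the usual regression definition;
#' `n_minus_p` is the convention under which published values of this model
#' family reproduce.
#'
#' @inheritParams f_statistic
#' @param df_convention `"n_minus_p_minus_1"` (default) or `"n_minus_p"`.
#' @return Standard error (response units).
#' @export
std_error <- function(obs, pred, p,
                      df_convention = c("n_minus_p_minus_1", "n_minus_p")) {
  .check_pair(obs, pred, min_n = 2)
  df_convention <- match.arg(df_convention)
  n <- length(obs)
  df <- if (df_convention == "n_minus_p_minus_1") n - p - 1 else n - p
  if (df <= 0) stop("non-positive degrees of freedom", call. = FALSE)
  sqrt(sum((obs - pred)^2) / df)
}

#' Leave-one-out cross-validation
#'
#' Refits the model on every N-1 subset and predicts the held-out row.
#' PRESS = sum of squared LOO errors; SDEP = sqrt(PRESS/N);
#' q2 = 1 - PRESS / sum((Y - mean(Y))^2) with the mean taken over the full
#' training set.
#'
#' @param data Data frame of training rows.
#' @param response Name of the response column.
#' @param fit_fn Function taking a data frame of training rows and returning a
#'   fitted object supporting `predict(object, newdata)`.
#' @return A list of class `loo_result`: `press`, `sdep`, `q2`, and
#'   `predictions` (tibble with `row`, `observed`, `predicted`).
#' @export
loo_cv <- function(data, response, fit_fn) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n < 3) stop("leave-one-out needs at least 3 rows", call. = FALSE)
  y <- data[[response]]
  pred <- vapply(seq_len(n), function(i) {
    fit <- tryCatch(fit_fn(data[-i, , drop = FALSE]), error = function(e)
      stop("model refit failed on fold ", i, ": ", conditionMessage(e),
           call. = FALSE))
    as.numeric(predict(fit, data[i, , drop = FALSE]))
  }, numeric(1))
  press <- sum((y - pred)^2)
  structure(
    list(press = press, sdep = sqrt(press / n),
         q2 = 1 - press / sum((y - mean(y))^2),
         predictions = tibble::tibble(row = seq_len(n), observed = y,
                                      predicted = pred)),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result: PRESS = %.4g, SDEP = %.4g, q2 = %.4f>\n",
              x$press, x$sdep, x$q2))
  invisible(x)
}

# r2 of a least-squares regression through the origin of y on x:
# 1 - sum((y - k x)^2) / sum((y - mean(y))^2), k = sum(xy)/sum(x^2).
.r2_origin <- function(y, x) {
  k <- sum(x * y) / sum(x^2)
  1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
}

#' The rm2 metric family
#'
#' Roy's modified r2 metrics penalizing divergence between the correlation of
#' observed and predicted activity with and without the origin constraint:
#' `rm2 = r2 (1 - sqrt(r2 - r0^2))` and the primed analogue with the axes
#' swapped, plus their average and absolute difference. `r0^2` / `r0'^2` are
#' the determination coefficients of the least-squares regressions through
#' the origin (predicted-on-observed and observed-on-predicted). When `scale`
#' is on, both vectors are first min-max scaled by the observed range.
#' Negative radicands (anticorrelated predictions) are clamped to zero and
#' flagged.
#'
#' @inheritParams r_squared
#' @param scale Min-max scale by the observed range first (default `TRUE`).
#' @return A one-row tibble: `rm2`, `rm2_prime`, `rm2_avg`, `delta_rm2`,
#'   `clamped`.
#' @export
rm2_metrics <- function(obs, pred, scale = TRUE) {
  .check_pair(obs, pred, min_n = 3)
  if (scale) {
    rng <- range(obs)
    if (diff(rng) == 0) stop("observed range is zero: cannot scale",
                             call. = FALSE)
    obs <- (obs - rng[1]) / diff(rng)
    pred <- (pred - rng[1]) / diff(rng)
  }
  r2 <- stats::cor(obs, pred)^2
  r0 <- .r2_origin(pred, obs)
  r0p <- .r2_origin(obs, pred)
  clamped <- FALSE
  rad <- r2 - r0
  radp <- r2 - r0p
  if (rad < 0 || radp < 0) clamped <- TRUE
  rm2 <- r2 * (1 - sqrt(max(rad, 0)))
  rm2p <- r2 * (1 - sqrt(max(radp, 0)))
  tibble::tibble(
    rm2 = rm2, rm2_prime = rm2p,
    rm2_avg = (rm2 + rm2p) / 2,
    delta_rm2 = abs(rm2 - rm2p),
    clamped = clamped
  )
}

#' External predictive r2
#'
#' `1 - sum((obs_test - pred_test)^2) / sum((obs_test - train_mean)^2)`:
#' test-set predictivity relative to the training-set observed mean.
#'
#' @param obs_test,pred_test Test-set observed and predicted activity.
#' @param train_mean Mean observed activity of the training set.
#' @return r2_pred (<= 1).
#' @export
r2_pred <- function(obs_test, pred_test, train_mean) {
  .check_pair(obs_test, pred_test, min_n = 1)
  denom <- sum((obs_test - train_mean)^2)
  if (denom == 0) stop("zero denominator: test observations equal the training mean",
                       call. = FALSE)
  1 - sum((obs_test - pred_test)^2) / denom
}

#' Root mean square error of prediction
#'
#' @inheritParams r2_pred
#' @return RMSEP (response units).
#' @export
rmsep <- function(obs_test, pred_test) {
  .check_pair(obs_test, pred_test, min_n = 1)
  sqrt(mean((obs_test - pred_test)^2))
}

#' External validation over a k-subset partition
#'
#' Partitions the rows into subsets (e.g. 6 subsets of size 4), trains on the
#' complement of each subset and evaluates `r2_pred` and RMSEP on the held-out
#' rows. With one row per subset this reduces to leave-one-out: the summed
#' squared held-out errors equal PRESS.
#'
#' @inheritParams loo_cv
#' @param k Number of subsets (rows assigned at random; requires `seed`).
#' @param subset_size If given, mandates equal subset sizes and errors when
#'   `nrow(data)` is not a multiple of it.
#' @param folds Optional explicit integer fold assignment (overrides `k`).
#' @param seed Integer seed for the random partition.
#' @return A tibble with one row per fold: `fold`, `n_test`, `r2_pred`,
#'   `rmsep`; held-out predictions in the `predictions` attribute.
#' @export
kfold_external <- function(data, response, fit_fn, k = NULL,
                           subset_size = NULL, folds = NULL, seed = NULL) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (is.null(folds)) {
    if (!is.null(subset_size)) {
      if (n %% subset_size != 0) {
        stop("rows (", n, ") are not a multiple of the mandated subset size ",
             subset_size, call. = FALSE)
      }
      k <- n / subset_size
    }
    if (is.null(k)) stop("provide k, subset_size or folds", call. = FALSE)
    if (is.null(seed)) stop("random partition requires a seed", call. = FALSE)
    folds <- withr::with_seed(seed,
      sample(rep(seq_len(k), length.out = n)))
  }
  if (length(folds) != n || !setequal(unique(folds), seq_len(max(folds)))) {
    stop("folds must assign every row to one of 1..k", call. = FALSE)
  }
  y <- data[[response]]
  per_fold <- lapply(sort(unique(folds)), function(f) {
    test_idx <- which(folds == f)
    fit <- fit_fn(data[-test_idx, , drop = FALSE])
    pred <- as.numeric(predict(fit, data[test_idx, , drop = FALSE]))
    obs <- y[test_idx]
    train_mean <- mean(y[-test_idx])
    list(stats = tibble::tibble(
           fold = f, n_test = length(test_idx),
           r2_pred = r2_pred(obs, pred, train_mean),
           rmsep = rmsep(obs, pred)),
         preds = tibble::tibble(row = test_idx, fold = f, observed = obs,
                                predicted = pred))
  })
  out <- dplyr::bind_rows(lapply(per_fold, `[[`, "stats"))
  attr(out, "predictions") <- dplyr::bind_rows(lapply(per_fold, `[[`, "preds"))
  out
}

#' Assemble a full validation report
#'
#' Bundles the quality and validation statistics for one model: training-set
#' r2, adjusted r2, F, standard error, the rm2 family, and (when test rows or
#' a refit function are given) external r2_pred/RMSEP and LOO PRESS/SDEP/q2.
#'
#' @param obs,pred Training-set observed and predicted activity.
#' @param p Number of model parameters.
#' @param obs_test,pred_test Optional test-set vectors.
#' @param loo Optional [loo_cv()] result.
#' @param df_convention Passed to [std_error()].
#' @return A one-row tibble of class `validation_report`; absent statistics
#'   are `NA`. `n`, `p` and the df convention are recorded as attributes.
#' @export
validation_report <- function(obs, pred, p, obs_test = NULL, pred_test = NULL,
                              loo = NULL,
                              df_convention = "n_minus_p_minus_1") {
  rm <- rm2_metrics(obs, pred)
  r2_val <- r_squared(obs, pred)
  out <- tibble::tibble(
    r2 = r2_val,
    r2_adj = adjusted_r2(r2_val, length(obs), p),
    f_stat = f_statistic(obs, pred, p),
    std_error = std_error(obs, pred, p, df_convention),
    press = if (is.null(loo)) NA_real_ else loo$press,
    sdep = if (is.null(loo)) NA_real_ else loo$sdep,
    q2 = if (is.null(loo)) NA_real_ else loo$q2,
    rm2 = rm$rm2, rm2_prime = rm$rm2_prime, rm2_avg = rm$rm2_avg,
    delta_rm2 = rm$delta_rm2,
    r2_pred = if (is.null(obs_test)) NA_real_ else
      r2_pred(obs_test, pred_test, mean(obs)),
    rmsep = if (is.null(obs_test)) NA_real_ else rmsep(obs_test, pred_test)
  )
  attr(out, "n") <- length(obs)
  attr(out, "p") <- p
  attr(out, "df_convention") <- df_convention
  attr(out, "rm2_clamped") <- rm$clamped
  class(out) <- c("validation_report", class(out))
  out
}

#' Write a validation report as flat JSON
#'
#' @param report A [validation_report()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  rec <- as.list(as.data.frame(report))
  rec$n <- attr(report, "n")
  rec$p <- attr(report, "p")
  rec$df_convention <- attr(report, "df_convention")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.check_pair <- function(obs, pred, min_n) {
  if (length(obs) != length(pred)) {
    stop("observed and predicted vectors differ in length", call. = FALSE)
  }
  if (length(obs) < min_n) {
    stop("need at least ", min_n, " values", call. = FALSE)
  }
  if (anyNA(obs) || anyNA(pred)) stop("missing values", call. = FALSE)
  invisible(TRUE)
}
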