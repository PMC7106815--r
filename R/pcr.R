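#' Principal components of a descriptor matrix
#'
#' Singular-value decomposition of the (optionally standardized) descriptor
#' matrix X. Loadings columns are unit-norm eigendirections ordered by
#' decreasing explained variance; scores are `T = X_std %*% P`, so
#' `X_std = T %*% t(P)` at full rank. Sign convention: the largest-magnitude
#' loading in each column is made positive, which fixes the otherwise
#' arbitrary component signs.
#'
#' @param x Numeric matrix or data frame of descriptors (rows = compounds).
#' @param standardize Center and scale columns to unit variance before the
#'   decomposition (default `TRUE`; descriptor scales differ by orders of
#'   magnitude, e.g. Id ~ 800 vs IdwAverage ~ 7.7).
#' @return An object of class `qsar_pca`: list with `scores`, `loadings`,
#'   `shares` (explained-variance fractions), `center`, `scale`, `rank`.
#' @export
principal_components <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  if (ncol(x) < 1) stop("need at least 1 column", call. = FALSE)
  if (anyNA(x)) stop("descriptor matrix contains missing values",
                     call. = FALSE)
  cn <- colnames(x) %||% paste0("X", seq_len(ncol(x)))
  ctr <- colMeans(x)
  if (standardize) {
    scl <- apply(x, 2, stats::sd)
    if (any(scl == 0)) {
      stop("zero-variance column(s) with standardization on: ",
           paste(cn[scl == 0], collapse = ", "), call. = FALSE)
    }
  } else {
    scl <- rep(1, ncol(x))
  }
  xs <- scale(x, center = ctr, scale = scl)
  sv <- svd(xs)
  tol <- max(dim(xs)) * max(sv$d) * .Machine$double.eps
  rk <- sum(sv$d > tol)
  loadings <- sv$v
  # sign convention: largest-magnitude loading positive per component
  for (k in seq_len(ncol(loadings))) {
    lead <- which.max(abs(loadings[, k]))
    if (loadings[lead, k] < 0) loadings[, k] <- -loadings[, k]
  }
  scores <- xs %*% loadings
  eig <- sv$d^2
  dimnames(loadings) <- list(cn, paste0("PC", seq_len(ncol(loadings))))
  colnames(scores) <- colnames(loadings)
  structure(
    list(scores = scores, loadings = loadings,
         shares = eig / sum(eig), center = ctr,
         scale = scl, rank = rk, standardized = standardize),
    class = "qsar_pca"
  )
}

#' @export
print.qsar_pca <- function(x, ...) {
  cat(sprintf("<qsar_pca: %d x %d, rank %d>\n", nrow(x$scores),
              ncol(x$loadings), x$rank))
  cat("explained variance:",
      paste(sprintf("%.3f", x$shares[seq_len(min(6, length(x$shares)))]),
            collapse = " "), "\n")
  invisible(x)
}

#' Linear QSAR model (intercept + named coefficients)
#'
#' The descriptor-space form pIC50 = b0 + sum_j b_j X_j, used both for fitted
#' PCR models after back-transformation and for published coefficient records.
#'
#' @param intercept Numeric intercept b0.
#' @param coefficients Named numeric vector of descriptor coefficients.
#' @param name Optional model name.
#' @param metadata Optional list (source, p_prime, seed, reference stats).
#' @return An object of class `qsar_lm`.
#' @export
linear_model <- function(intercept, coefficients, name = NULL,
                         metadata = list()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients))
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients)) ||
      any(!nzchar(names(coefficients)))) {
    stop("coefficients must carry unique non-empty names", call. = FALSE)
  }
  structure(
    list(intercept = unname(intercept), coefficients = coefficients,
         name = name, metadata = metadata),
    class = "qsar_lm"
  )
}

#' @export
print.qsar_lm <- function(x, ...) {
  cat(sprintf("<qsar_lm%s>\n", if (is.null(x$name)) "" else paste0(" ", x$name)))
  eq <- paste(sprintf("%+.4f %s", x$coefficients, names(x$coefficients)),
              collapse = " ")
  cat("  y =", eq, sprintf("%+.4f", x$intercept), "\n")
  invisible(x)
}

#' Predict activity from a linear QSAR model
#'
#' @param object A [linear_model()].
#' @param newdata Data frame containing every descriptor column the model
#'   names (extra columns ignored).
#' @param ... Unused.
#' @return Numeric vector of predicted activities (pIC50 units).
#' @export
predict.qsar_lm <- function(object, newdata, ...) {
  needed <- names(object$coefficients)
  missing_cols <- setdiff(needed, colnames(newdata))
  if (length(missing_cols) > 0) {
    stop("missing descriptor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(newdata)[, needed, drop = FALSE])
  drop(object$intercept + x %*% object$coefficients)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy qsar_lm
tidy.qsar_lm <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' Fit a principal-components regression model
#'
#' Regresses the response on the leading `p_prime` principal-component scores
#' of the descriptor block (plus intercept) and back-transforms to an
#' equivalent descriptor-space [linear_model()]. With `p_prime = "auto"` the
#' retained-component count maximizing the adjusted r-squared is chosen, ties
#' broken toward fewer components. At `p_prime = rank(X)` the fit reproduces
#' ordinary least squares on the original descriptors.
#'
#' @param data Data frame with the response column and descriptor columns.
#' @param response Name of the response column (string).
#' @param descriptors Character vector of descriptor column names; default all
#'   numeric columns except the response.
#' @param p_prime Integer number of components, or `"auto"`.
#' @param standardize Passed to [principal_components()].
#' @return An object of class `pcr_model`: the PCA, the component-space
#'   coefficients, the equivalent `qsar_lm`, fit statistics.
#' @examples
#' d <- gen_qsar_dataset(synthetic_spec(seed = 1))
#' m <- fit_pcr(d, "activity", p_prime = "auto")
#' glance(m)
#' @export
fit_pcr <- function(data, response, descriptors = NULL, p_prime = "auto",
                    standardize = TRUE) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  if (is.null(descriptors)) {
    descriptors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                           response)
  }
  x <- as.matrix(data[, descriptors, drop = FALSE])
  y <- data[[response]]
  pca <- principal_components(x, standardize = standardize)
  max_p <- min(pca$rank, nrow(x) - 2)
  if (identical(p_prime, "auto")) {
    cand <- seq_len(max_p)
    r2a <- vapply(cand, function(k) {
      fit <- stats::lm.fit(cbind(1, pca$scores[, seq_len(k), drop = FALSE]), y)
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      adjusted_r2(r2, length(y), k)
    }, numeric(1))
    p_prime <- cand[which.max(r2a)]  # which.max takes the first maximum
  } else {
    p_prime <- as.integer(p_prime)
    if (p_prime < 1 || p_prime > pca$rank) {
      stop("p_prime must lie in 1..rank(X) = 1..", pca$rank, call. = FALSE)
    }
    if (nrow(x) < p_prime + 2) {
      stop("need at least p_prime + 2 rows", call. = FALSE)
    }
  }
  scores_p <- pca$scores[, seq_len(p_prime), drop = FALSE]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, scores_p), y)
  beta_scores <- fit$coefficients[-1]
  b0_scores <- fit$coefficients[1]
  # back-transform: y = b0 + T c = b0 + (X - mu)/s P c
  beta_x <- drop(pca$loadings[, seq_len(p_prime), drop = FALSE] %*%
                   beta_scores) / pca$scale
  intercept <- b0_scores - sum(beta_x * pca$center)
  lmod <- linear_model(intercept, stats::setNames(beta_x, descriptors),
                       metadata = list(source = "fitted", p_prime = p_prime))
  fitted <- drop(cbind(1, scores_p) %*% fit$coefficients)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(
    list(pca = pca, p_prime = p_prime, beta_scores = beta_scores,
         intercept_scores = b0_scores, linear_model = lmod,
         descriptors = descriptors, response = response,
         fitted = fitted, residuals = y - fitted, y = y,
         n = length(y), r2 = r2,
         r2_adj = adjusted_r2(r2, length(y), p_prime)),
    class = "pcr_model"
  )
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("<pcr_model: %d compounds, %d descriptors, p' = %d>\n",
              x$n, length(x$descriptors), x$p_prime))
  cat(sprintf("  r2 = %.4f, adjusted r2 = %.4f\n", x$r2, x$r2_adj))
  print(x$linear_model)
  invisible(x)
}

#' @export
predict.pcr_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict(object$linear_model, newdata)
}

#' @export
#' @method tidy pcr_model
tidy.pcr_model <- function(x, ...) tidy(x$linear_model)

#' @export
#' @method glance pcr_model
glance.pcr_model <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2, r2_adj = x$r2_adj, p_prime = x$p_prime,
    n = x$n, n_descriptors = length(x$descriptors)
  )
}

#' Genetic-algorithm control parameters
#'
#' Defaults target reproducible desk-scale searches; the published software's
#' GA settings are not public, so these are this package's own choices.
#'
#' @param pop_size Population size (fixed-size bitmask population).
#' @param generations Number of generations.
#' @param tournament_size Tournament selection size.
#' @param crossover_rate Uniform-crossover probability per mating.
#' @param mutation_rate Per-bit mutation probability.
#' @param elitism Number of best individuals copied unchanged each generation.
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 50, generations = 100, tournament_size = 3,
                       crossover_rate = 0.8, mutation_rate = 0.02,
                       elitism = 1) {
  structure(list(pop_size = pop_size, generations = generations,
                 tournament_size = tournament_size,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, elitism = elitism),
            class = "ga_control")
}

# Fast least-squares fitness for a descriptor mask. Full-rank PCR on a subset
# is identical to OLS on that subset, so fitness is evaluated by direct OLS.
.mask_fitness <- function(mask, x, y, fitness) {
  xs <- cbind(1, x[, mask, drop = FALSE])
  qrx <- qr(xs)
  res <- qr.resid(qrx, y)
  tss <- sum((y - mean(y))^2)
  p <- sum(mask)
  if (fitness == "adjusted_r2") {
    if (length(y) - 1 - p <= 0) return(-Inf)
    r2 <- 1 - sum(res^2) / tss
    ((length(y) - 1) * r2 - p) / (length(y) - 1 - p)
  } else {
    # exact LOO for least squares via the hat matrix
    q <- qr.Q(qrx)
    h <- rowSums(q^2)
    if (any(h >= 1 - 1e-10)) return(-Inf)
    press <- sum((res / (1 - h))^2)
    1 - press / tss
  }
}

#' Descriptor-subset selection by genetic algorithm
#'
#' Evolves a fixed-size population of descriptor bitmasks under tournament
#' selection, uniform crossover, per-bit mutation and elitism; fitness is the
#' adjusted r-squared or the leave-one-out q2 of the least-squares model on
#' the selected descriptors (equivalent to full-rank PCR on that subset).
#' All-zero masks are repaired by activating one random bit. Deterministic for
#' a given seed; the random state is local, never global.
#'
#' @param data Data frame with response and candidate descriptor columns.
#' @param response Name of the response column.
#' @param descriptors Candidate descriptor columns; default all numeric
#'   columns except the response (at least 2 required).
#' @param fitness `"adjusted_r2"` (default) or `"loo_q2"`.
#' @param ga_params A [ga_control()] list.
#' @param seed Integer random seed (required, for reproducibility).
#' @return A list of class `ga_result`: `subset` (selected descriptor names),
#'   `fitness` (best fitness), `model` (PCR refit on the subset at full rank),
#'   `history` (best fitness per generation).
#' @export
ga_select_descriptors <- function(data, response, descriptors = NULL,
                                  fitness = c("adjusted_r2", "loo_q2"),
                                  ga_params = ga_control(), seed) {
  fitness <- match.arg(fitness)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  data <- tibble::as_tibble(data)
  if (is.null(descriptors)) {
    descriptors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                           response)
  }
  if (length(descriptors) < 2) {
    stop("need at least 2 candidate descriptors", call. = FALSE)
  }
  x <- as.matrix(data[, descriptors, drop = FALSE])
  y <- data[[response]]
  p <- ncol(x)
  gp <- ga_params
  withr::with_seed(seed, {
    pop <- matrix(stats::runif(gp$pop_size * p) < 0.5, nrow = gp$pop_size)
    pop <- t(apply(pop, 1, .repair_mask, p = p))
    cache <- new.env(parent = emptyenv())
    eval_pop <- function(pop) {
      apply(pop, 1, function(mask) {
        key <- paste(which(mask), collapse = ",")
        if (!is.null(cache[[key]])) return(cache[[key]])
        f <- .mask_fitness(mask, x, y, fitness)
        cache[[key]] <- f
        f
      })
    }
    fit <- eval_pop(pop)
    history <- numeric(gp$generations)
    for (gen in seq_len(gp$generations)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(gp$elitism)], , drop = FALSE]
      newpop <- matrix(FALSE, gp$pop_size, p)
      newpop[seq_len(gp$elitism), ] <- elite
      k <- gp$elitism
      while (k < gp$pop_size) {
        pa <- .tournament(fit, gp$tournament_size)
        pb <- .tournament(fit, gp$tournament_size)
        child_a <- pop[pa, ]; child_b <- pop[pb, ]
        if (stats::runif(1) < gp$crossover_rate) {
          swap <- stats::runif(p) < 0.5
          tmp <- child_a[swap]; child_a[swap] <- child_b[swap]
          child_b[swap] <- tmp
        }
        for (child in list(child_a, child_b)) {
          if (k >= gp$pop_size) break
          flip <- stats::runif(p) < gp$mutation_rate
          child <- xor(child, flip)
          k <- k + 1
          newpop[k, ] <- .repair_mask(child, p)
        }
      }
      pop <- newpop
      fit <- eval_pop(pop)
      history[gen] <- max(fit)
    }
    best <- which.max(fit)
    subset <- descriptors[pop[best, ]]
    model <- fit_pcr(data[, c(response, subset)], response,
                     descriptors = subset, p_prime = "auto")
    structure(
      list(subset = subset, fitness = fit[best], model = model,
           history = history, fitness_type = fitness, seed = seed,
           ga_params = gp),
      class = "ga_result"
    )
  })
}

.repair_mask <- function(mask, p) {
  if (!any(mask)) mask[sample.int(p, 1)] <- TRUE
  mask
}

.tournament <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = TRUE)
  cand[which.max(fit[cand])]
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result: %d descriptors selected, %s = %.4f>\n",
              length(x$subset), x$fitness_type, x$fitness))
  cat("  subset:", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / deserialize linear QSAR models as JSON
#'
#' Flat records: `{name, intercept, coefficients: {descriptor: value},
#' metadata: {...}}`.
#'
#' @param model A [linear_model()] (or a `pcr_model`, whose equivalent linear
#'   form is written).
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly; `read_model_json()`
#'   returns a `qsar_lm`.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "pcr_model")) model <- model$linear_model
  stopifnot(inherits(model, "qsar_lm"))
  rec <- list(
    name = model$name %||% "unnamed",
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    metadata = model$metadata
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_model(rec$intercept, unlist(rec$coefficients),
               name = rec$name, metadata = as.list(rec$metadata))
}
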