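#' Specification for a synthetic descriptor/activity dataset
#'
#' Describes the statistical structure the PCR pipeline assumes: a linear
#' response on correlated descriptors plus Gaussian noise, split into training
#' and test compounds. Defaults emulate the published study conditions: 24
#' compounds (20 train / 4 test), a handful of inter-correlated descriptors,
#' and a small noise level relative to the pIC50 scale.
#'
#' @param n_compounds Number of compounds (must exceed `n_descriptors + 2`).
#' @param n_descriptors Number of descriptor columns.
#' @param rho Compound-symmetric inter-descriptor correlation in [0, 1).
#' @param beta True coefficient vector (zeros mark inactive descriptors);
#'   default: first three descriptors active with coefficients 1, -1, 0.5.
#' @param intercept True intercept.
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param train_fraction Fraction of compounds assigned to the training set.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 24, n_descriptors = 6, rho = 0.3,
                           beta = NULL, intercept = 0, sigma = 0.05,
                           train_fraction = 20 / 24, seed = 1) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (n_compounds <= n_descriptors + 2) {
    stop("n_compounds must exceed n_descriptors + 2", call. = FALSE)
  }
  if (is.null(beta)) {
    beta <- rep(0, n_descriptors)
    beta[seq_len(min(3, n_descriptors))] <-
      c(1, -1, 0.5)[seq_len(min(3, n_descriptors))]
  }
  stopifnot(length(beta) == n_descriptors)
  structure(
    list(n_compounds = n_compounds, n_descriptors = n_descriptors, rho = rho,
         beta = beta, intercept = intercept, sigma = sigma,
         train_fraction = train_fraction, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a correlated Gaussian descriptor matrix
#'
#' Rows are i.i.d. zero-mean Gaussian vectors with compound-symmetric
#' correlation `rho` (every descriptor pair shares the same correlation),
#' generated as `sqrt(rho) * z_common + sqrt(1 - rho) * z_own`. The random
#' state is local to the call.
#'
#' @param spec A [synthetic_spec()], or `NULL` to pass sizes directly.
#' @param n,p,rho,seed Used when `spec` is `NULL`.
#' @return A tibble (`n` x `p`) with columns `X1..Xp`.
#' @export
gen_descriptor_matrix <- function(spec = NULL, n = NULL, p = NULL, rho = NULL,
                                  seed = NULL) {
  if (!is.null(spec)) {
    n <- spec$n_compounds; p <- spec$n_descriptors
    rho <- spec$rho; seed <- spec$seed
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  withr::with_seed(seed, {
    common <- stats::rnorm(n)
    own <- matrix(stats::rnorm(n * p), n, p)
    x <- sqrt(rho) * common + sqrt(1 - rho) * own
    colnames(x) <- paste0("X", seq_len(p))
    tibble::as_tibble(x)
  })
}

#' Generate activity values from a planted linear model
#'
#' `Y = intercept + X beta + N(0, sigma^2)` — the ground truth every
#' parameter-recovery test is scored against.
#'
#' @param x Descriptor matrix or data frame.
#' @param beta Coefficient vector (length = ncol(x)).
#' @param intercept Intercept.
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return Numeric activity vector.
#' @export
gen_activity <- function(x, beta, intercept = 0, sigma = 0, seed = 1) {
  x <- as.matrix(x)
  stopifnot(length(beta) == ncol(x))
  withr::with_seed(seed, {
    drop(intercept + x %*% beta + stats::rnorm(nrow(x), sd = sigma))
  })
}

#' Reproducible train/test split tags
#'
#' @param n Number of rows.
#' @param train_fraction Fraction in (0, 1) assigned to training; counts are
#'   `round(n * train_fraction)`.
#' @param seed Integer seed.
#' @return Character vector of `"train"` / `"test"` tags.
#' @export
make_split <- function(n, train_fraction, seed) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  n_train <- round(n * train_fraction)
  if (n_train == 0 || n_train == n) {
    stop("degenerate split: one part would be empty", call. = FALSE)
  }
  withr::with_seed(seed, {
    tags <- rep("test", n)
    tags[sample.int(n, n_train)] <- "train"
    tags
  })
}

#' Generate a complete synthetic QSAR dataset
#'
#' Descriptors, activity and split in the same tabular layout the published
#' fixtures use, so synthetic and real data are interchangeable everywhere.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble: `compound_id`, `X1..Xp`, `activity`, `split`; the true
#'   coefficients are kept in the `truth` attribute.
#' @examples
#' d <- gen_qsar_dataset(synthetic_spec(seed = 7))
#' dplyr::count(d, split)
#' @export
gen_qsar_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  x <- gen_descriptor_matrix(spec)
  y <- gen_activity(x, spec$beta, spec$intercept, spec$sigma,
                    seed = spec$seed + 1L)
  split <- make_split(spec$n_compounds, spec$train_fraction,
                      seed = spec$seed + 2L)
  out <- dplyr::bind_cols(
    tibble::tibble(compound_id = sprintf("cmpd_%02d", seq_len(nrow(x)))),
    x,
    tibble::tibble(activity = y, split = split)
  )
  attr(out, "truth") <- list(beta = spec$beta, intercept = spec$intercept,
                             sigma = spec$sigma)
  out
}

#' Generate a random molecule-like graph
#'
#' A random spanning tree plus optional ring-closing edges, degree capped at
#' 4, elements drawn from {C, O} with hybridization tags. Connected by
#' construction and chemically plausible rather than valence-exact: the
#' descriptor machinery needs labelled graphs, not full chemistry.
#'
#' @param n_atoms Number of heavy atoms (>= 2).
#' @param extra_ring_prob Probability of attempting one ring-closing edge per
#'   atom (default 0.15).
#' @param seed Integer seed.
#' @return A [mol_graph()].
#' @export
gen_molecule_graph <- function(n_atoms, extra_ring_prob = 0.15, seed = 1) {
  if (n_atoms < 2) stop("need at least 2 atoms", call. = FALSE)
  withr::with_seed(seed, {
    deg <- integer(n_atoms)
    bonds <- matrix(0L, nrow = 0, ncol = 2)
    for (v in 2:n_atoms) {
      open <- which(deg[seq_len(v - 1)] < 4)
      u <- if (length(open) == 1) open else sample(open, 1)
      bonds <- rbind(bonds, c(u, v))
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
    }
    n_extra <- stats::rbinom(1, n_atoms, extra_ring_prob)
    for (k in seq_len(n_extra)) {
      open <- which(deg < 4)
      if (length(open) < 2) break
      cand <- if (length(open) == 2) open else sample(open, 2)
      key <- paste(pmin(bonds[, 1], bonds[, 2]),
                   pmax(bonds[, 1], bonds[, 2]))
      if (paste(min(cand), max(cand)) %in% key) next
      bonds <- rbind(bonds, cand)
      deg[cand] <- deg[cand] + 1L
    }
    element <- sample(c("C", "O"), n_atoms, replace = TRUE,
                      prob = c(0.8, 0.2))
    hybrid <- ifelse(stats::runif(n_atoms) < 0.3, "sp2", "sp3")
    mol_graph(
      atoms = tibble::tibble(element = element, hybrid = hybrid),
      bonds = tibble::tibble(i = as.integer(bonds[, 1]),
                             j = as.integer(bonds[, 2]),
                             order = 1L)
    )
  })
}
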