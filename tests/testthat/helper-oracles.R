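# Graph builders and independent brute-force oracles used across the suite.
# The oracles deliberately avoid the package's own code paths (plain BFS /
# direct formula transliterations) so agreement is evidence, not tautology.

make_path_graph <- function(n, element = "C", hybrid = "sp3") {
  mol_graph(
    atoms = tibble::tibble(element = rep(element, n),
                           hybrid = rep(hybrid, n)),
    bonds = if (n > 1) {
      tibble::tibble(i = seq_len(n - 1), j = 2:n, order = 1L)
    } else {
      tibble::tibble(i = integer(), j = integer(), order = integer())
    }
  )
}

make_star_graph <- function(n_leaves) {
  mol_graph(
    atoms = tibble::tibble(element = rep("C", n_leaves + 1),
                           hybrid = rep("sp3", n_leaves + 1)),
    bonds = tibble::tibble(i = rep(1L, n_leaves), j = seq_len(n_leaves) + 1L,
                           order = 1L)
  )
}

make_ring_graph <- function(n, hybrid = "aromatic", order = 4L) {
  mol_graph(
    atoms = tibble::tibble(element = rep("C", n), hybrid = rep(hybrid, n)),
    bonds = tibble::tibble(i = seq_len(n), j = c(2:n, 1L), order = order)
  )
}

make_benzene <- function() make_ring_graph(6)

# Plain queue-based BFS over an adjacency list; no igraph.
bfs_distances_oracle <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# Exhaustive DFS enumeration of simple paths with exactly `len` edges.
count_paths_oracle <- function(g, len) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  total <- 0L
  walk <- function(v, visited, depth) {
    if (depth == len) { total <<- total + 1L; return(invisible()) }
    for (w in adj[[v]]) {
      if (!w %in% visited) walk(w, c(visited, w), depth + 1)
    }
  }
  for (s in seq_len(n)) walk(s, s, 0)
  as.integer(total / 2)
}

# Direct transliterations of the validation-metric formulas.
r2_oracle <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}
r2a_oracle <- function(r2, n, p) ((n - 1) * r2 - p) / (n - 1 - p)
f_oracle <- function(obs, pred, p) {
  n <- length(obs)
  (sum((pred - mean(obs))^2) / p) / (sum((obs - pred)^2) / (n - p - 1))
}
se_oracle <- function(obs, pred, df) sqrt(sum((obs - pred)^2) / df)
r2pred_oracle <- function(obs, pred, train_mean) {
  1 - sum((obs - pred)^2) / sum((obs - train_mean)^2)
}
rmsep_oracle <- function(obs, pred) sqrt(sum((obs - pred)^2) / length(obs))
rm2_oracle <- function(obs, pred) {
  rng <- range(obs)
  o <- (obs - rng[1]) / diff(rng); pr <- (pred - rng[1]) / diff(rng)
  r2 <- cor(o, pr)^2
  k <- sum(o * pr) / sum(o^2)
  r0 <- 1 - sum((pr - k * o)^2) / sum((pr - mean(pr))^2)
  kp <- sum(o * pr) / sum(pr^2)
  r0p <- 1 - sum((o - kp * pr)^2) / sum((o - mean(o))^2)
  rm2 <- r2 * (1 - sqrt(max(r2 - r0, 0)))
  rm2p <- r2 * (1 - sqrt(max(r2 - r0p, 0)))
  c(rm2 = rm2, rm2_prime = rm2p, rm2_avg = (rm2 + rm2p) / 2,
    delta_rm2 = abs(rm2 - rm2p))
}

# OLS via the normal equations, the independent check for full-rank PCR.
ols_oracle <- function(x, y) {
  x1 <- cbind(1, as.matrix(x))
  solve(t(x1) %*% x1, t(x1) %*% y)
}

# Simple fit function for loo_cv / kfold tests: least squares on all
# numeric descriptor columns, predicting via the returned closure object.
ols_fit_fn <- function(response, descriptors) {
  function(data) {
    x <- as.matrix(data[, descriptors, drop = FALSE])
    beta <- ols_oracle(x, data[[response]])
    structure(list(beta = beta, descriptors = descriptors),
              class = "test_ols")
  }
}
predict.test_ols <- function(object, newdata, ...) {
  x <- cbind(1, as.matrix(newdata[, object$descriptors, drop = FALSE]))
  drop(x %*% object$beta)
}
registerS3method("predict", "test_ols", predict.test_ols)

mean_fit_fn <- function(response) {
  function(data) structure(list(m = mean(data[[response]])),
                           class = "test_meanfit")
}
predict.test_meanfit <- function(object, newdata, ...) {
  rep(object$m, nrow(newdata))
}
registerS3method("predict", "test_meanfit", predict.test_meanfit)

# One planted-model GA recovery replicate: TRUE when every active descriptor
# is selected. Reduced GA sizes keep the 50-replicate sweep at desk scale.
ga_recovery_replicate <- function(seed) {
  beta <- c(1, -1, 0.5, 0, 0, 0, 0, 0)
  x <- gen_descriptor_matrix(n = 40, p = 8, rho = 0.3, seed = seed)
  y <- gen_activity(x, beta, intercept = 0.5, sigma = 0.05, seed = seed + 1000)
  d <- dplyr::bind_cols(x, tibble::tibble(activity = y))
  res <- ga_select_descriptors(
    d, "activity", fitness = "adjusted_r2",
    ga_params = ga_control(pop_size = 24, generations = 30), seed = seed
  )
  all(c("X1", "X2", "X3") %in% res$subset)
}
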