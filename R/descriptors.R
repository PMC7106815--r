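#' Second-order kappa alpha shape index
#'
#' Kier's alpha-modified second-order shape index, a function of the heavy-atom
#' count A, the number of length-2 paths P, and the alpha hybridization/element
#' correction. Two variants are provided: `kier_standard` is Kier's formula
#' (A + a - 1)(A + a - 2)^2 / (P + a)^2; `literal_printed` replaces the second
#' factor with (A + a - 1)^2 as it is sometimes typeset, and is kept selectable
#' for auditing published values. The default is `kier_standard`.
#'
#' @param g A [mol_graph()] with at least 3 atoms.
#' @param variant `"kier_standard"` (default) or `"literal_printed"`.
#' @return The kappa-2-alpha value (dimensionless).
#' @examples
#' kappa2_alpha(read_structure("CCCCC"))  # n-pentane: 4
#' @export
kappa2_alpha <- function(g, variant = c("kier_standard", "literal_printed")) {
  variant <- match.arg(variant)
  a_count <- n_atoms(g)
  if (a_count < 3) stop("kappa2_alpha needs at least 3 atoms", call. = FALSE)
  alpha <- alpha_sum(g)
  p2 <- path_count(g, 2)
  if (p2 + alpha <= 0) {
    stop("degenerate denominator: P + alpha <= 0", call. = FALSE)
  }
  second <- if (variant == "kier_standard") a_count + alpha - 2 else
    a_count + alpha - 1
  (a_count + alpha - 1) * second^2 / (p2 + alpha)^2
}

# Groups the strict-upper-triangle entries of a distance matrix into equality
# classes. Deterministic: sort, then split where consecutive gaps exceed the
# tolerance (absolute for integer topological distances, relative otherwise).
.distance_classes <- function(dm, tolerance = NULL) {
  a <- nrow(dm)
  if (a < 2) stop("distance matrix has no pairwise entries", call. = FALSE)
  vals <- dm[upper.tri(dm)]
  mode <- attr(dm, "mode")
  if (is.null(tolerance)) {
    tolerance <- if (identical(mode, "reciprocal_square")) 1e-9 else 0
  }
  vals <- sort(vals)
  gaps <- diff(vals)
  thresh <- if (identical(mode, "reciprocal_square") || tolerance > 0) {
    tolerance * pmax(abs(vals[-length(vals)]), 1e-300)
  } else {
    rep(0, length(gaps))
  }
  breaks <- c(0, which(gaps > thresh), length(vals))
  diff(breaks)
}

#' Total information content on distance equality (Id)
#'
#' With K = A(A-1)/2 pairwise distances partitioned into G equality classes of
#' sizes f_g, Id = K log2 K - sum_g f_g log2 f_g (bits). Maximal (K log2 K)
#' when all distances are distinct; 0 when A = 2.
#'
#' @param dm A distance matrix from [topological_distance_matrix()] or
#'   [reciprocal_square_distance_matrix()].
#' @param tolerance Equality tolerance for class grouping. Defaults to exact
#'   equality for topological matrices and 1e-9 relative for
#'   reciprocal-square matrices.
#' @return Id in bits.
#' @examples
#' g <- read_structure("CCC")
#' total_info_distance(topological_distance_matrix(g))  # 2.7549
#' @export
total_info_distance <- function(dm, tolerance = NULL) {
  f <- .distance_classes(dm, tolerance)
  k <- sum(f)
  k * log2(k) - sum(f * log2(f))
}

#' Mean information content on distance equality (IdwAverage)
#'
#' The Shannon entropy (bits) of the distance-equality class distribution:
#' -sum_g p_g log2 p_g with p_g = 2 f_g / (A(A-1)). Equals Id / K, so it is
#' bounded by log2 K.
#'
#' @inheritParams total_info_distance
#' @return IdwAverage in bits.
#' @export
mean_info_distance <- function(dm, tolerance = NULL) {
  f <- .distance_classes(dm, tolerance)
  p <- f / sum(f)
  -sum(p * log2(p))
}

#' Moment of inertia about the Y axis
#'
#' Translates the conformer to its center of mass and returns
#' sum_i m_i (x_i^2 + z_i^2) in amu * Angstrom^2. For 2D records the planar
#' coordinates are used as-is and the value is flagged 2D-derived via the
#' `derived_2d` attribute.
#'
#' @param coords Numeric matrix (n x 3) of Cartesian coordinates, or a
#'   [mol_graph()] carrying coordinates.
#' @param masses Numeric vector of atomic masses; taken from the graph when
#'   `coords` is a `mol_graph`.
#' @return Moment of inertia (amu A^2), with attribute `derived_2d` when all
#'   z coordinates are zero.
#' @export
moment_of_inertia_y <- function(coords, masses = NULL) {
  if (inherits(coords, "mol_graph")) {
    g <- coords
    if (is.null(g$coords)) {
      stop("molecular graph carries no coordinates", call. = FALSE)
    }
    masses <- g$masses
    coords <- g$coords
  }
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  if (is.null(masses)) stop("atomic masses required", call. = FALSE)
  if (anyNA(coords) || anyNA(masses)) {
    stop("missing coordinates or masses", call. = FALSE)
  }
  com <- colSums(coords * masses) / sum(masses)
  centred <- sweep(coords, 2, com)
  val <- sum(masses * (centred[, 1]^2 + centred[, 3]^2))
  attr(val, "derived_2d") <- all(coords[, 3] == 0)
  val
}

#' Compute the topological/geometric descriptor vector for one molecule
#'
#' @param g A [mol_graph()].
#' @param distance_mode `"topological"` (default) or `"reciprocal_square"`,
#'   the distance matrix the information descriptors are computed from.
#' @param kappa_variant Passed to [kappa2_alpha()].
#' @return A one-row tibble with columns `k2alpha`, `Id`, `IdwAverage`,
#'   `MomInertiaY` (NA when the structure has no coordinates).
#' @export
compute_descriptors <- function(g,
                                distance_mode = c("topological",
                                                  "reciprocal_square"),
                                kappa_variant = "kier_standard") {
  distance_mode <- match.arg(distance_mode)
  dm <- if (distance_mode == "topological") {
    topological_distance_matrix(g)
  } else {
    reciprocal_square_distance_matrix(g)
  }
  tibble::tibble(
    k2alpha = kappa2_alpha(g, kappa_variant),
    Id = total_info_distance(dm),
    IdwAverage = mean_info_distance(dm),
    MomInertiaY = if (is.null(g$coords)) NA_real_ else
      as.numeric(moment_of_inertia_y(g))
  )
}

#' Assemble a descriptor table from structures and supplied columns
#'
#' Computes `k2alpha`, `Id`, `IdwAverage` and `MomInertiaY` from the structures
#' and joins externally supplied descriptor columns (typically the
#' quantum-chemical `Most+vePotential` and `DeltaEpsilonC`, which this package
#' never computes). Per-cell provenance (`computed` / `supplied` / `missing`)
#' is recorded in the `provenance` attribute.
#'
#' @param structures A tibble with columns `compound_id` and `structure` (list
#'   of [mol_graph()]), as returned by [read_structures()], or a named list of
#'   `mol_graph` objects.
#' @param supplied Optional data frame keyed by `compound_id` with extra
#'   descriptor columns.
#' @param distance_mode,kappa_variant Passed to [compute_descriptors()].
#' @return A tibble, one row per compound: `compound_id` then descriptor
#'   columns.
#' @export
build_descriptor_table <- function(structures, supplied = NULL,
                                   distance_mode = "topological",
                                   kappa_variant = "kier_standard") {
  if (is.list(structures) && !is.data.frame(structures) &&
      all(vapply(structures, inherits, logical(1), "mol_graph"))) {
    structures <- tibble::tibble(
      compound_id = names(structures) %||%
        as.character(seq_along(structures)),
      structure = unname(structures)
    )
  }
  stopifnot(all(c("compound_id", "structure") %in% names(structures)))
  if (anyDuplicated(structures$compound_id)) {
    stop("duplicate compound IDs: ",
         paste(unique(structures$compound_id[
           duplicated(structures$compound_id)]), collapse = ", "),
         call. = FALSE)
  }
  computed <- purrr::map_dfr(structures$structure, compute_descriptors,
                             distance_mode = distance_mode,
                             kappa_variant = kappa_variant)
  out <- dplyr::bind_cols(
    tibble::tibble(compound_id = structures$compound_id), computed)
  prov <- out
  prov[, -1] <- lapply(out[, -1], function(x)
    ifelse(is.na(x), "missing", "computed"))
  if (!is.null(supplied)) {
    supplied <- tibble::as_tibble(supplied)
    if (!"compound_id" %in% names(supplied)) {
      stop("supplied table needs a compound_id column", call. = FALSE)
    }
    unmatched <- setdiff(supplied$compound_id, out$compound_id)
    if (length(unmatched) > 0) {
      stop("supplied IDs not present among structures: ",
           paste(unmatched, collapse = ", "), call. = FALSE)
    }
    out <- dplyr::left_join(out, supplied, by = "compound_id")
    for (col in setdiff(names(supplied), "compound_id")) {
      prov[[col]] <- ifelse(out$compound_id %in% supplied$compound_id &
                              !is.na(out[[col]]), "supplied", "missing")
    }
  }
  attr(out, "provenance") <- prov
  out
}

#' Read / write descriptor tables as CSV
#'
#' Header-first CSV with `compound_id` followed by descriptor columns, using
#' the published column names verbatim (including `Most+vePotential`).
#'
#' @param path CSV file path.
#' @return `read_descriptor_table()` returns a tibble;
#'   `write_descriptor_table()` returns `path` invisibly.
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_descriptor_table
#' @param x A descriptor table (data frame).
#' @export
write_descriptor_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
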