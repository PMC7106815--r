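#' Heavy-atom molecular graphs
#'
#' A `mol_graph` is the minimal structural object the topological descriptors
#' are built on: a connected, hydrogen-suppressed graph whose vertices carry an
#' element symbol and a hybridization tag (`sp3`, `sp2`, `sp`, `aromatic`) and
#' whose edges carry a bond order. Optional per-atom 3D coordinates (Angstrom)
#' and atomic masses (amu) support geometric descriptors.
#'
#' @param atoms A data frame with columns `element` (symbol, e.g. `"C"`) and
#'   `hybrid` (one of `"sp3"`, `"sp2"`, `"sp"`, `"aromatic"`).
#' @param bonds A data frame with integer columns `i`, `j` (1-based atom
#'   indices, `i != j`) and `order` (1, 2, 3, or 4 for aromatic). May have zero
#'   rows for a single-atom molecule.
#' @param coords Optional numeric matrix (atoms x 3) of Cartesian coordinates.
#' @param masses Optional numeric vector of atomic masses; defaults to a
#'   standard-atomic-weight lookup by element.
#' @param id Optional compound identifier.
#'
#' @return An object of class `mol_graph`.
#' @examples
#' propane <- mol_graph(
#'   atoms = data.frame(element = rep("C", 3), hybrid = rep("sp3", 3)),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1)
#' )
#' n_atoms(propane)
#' @export
mol_graph <- function(atoms, bonds, coords = NULL, masses = NULL, id = NULL) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("element", "hybrid") %in% names(atoms)))
  if (nrow(bonds) == 0) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  }
  stopifnot(all(c("i", "j", "order") %in% names(bonds)))
  a <- nrow(atoms)
  if (a < 1) stop("a molecular graph needs at least one atom", call. = FALSE)
  bad <- atoms$hybrid[!atoms$hybrid %in% c("sp3", "sp2", "sp", "aromatic")]
  if (length(bad) > 0) {
    stop("unknown hybridization tag(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(bonds) > 0) {
    if (any(bonds$i == bonds$j)) stop("self-loop bond found", call. = FALSE)
    if (any(bonds$i < 1 | bonds$i > a | bonds$j < 1 | bonds$j > a)) {
      stop("bond index out of range", call. = FALSE)
    }
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond found", call. = FALSE)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == a, ncol(coords) == 3)
  }
  if (is.null(masses)) {
    masses <- unname(.atomic_masses[atoms$element])
  }
  g <- structure(
    list(atoms = atoms, bonds = bonds, coords = coords,
         masses = masses, id = id),
    class = "mol_graph"
  )
  if (!.is_connected(g)) {
    stop("molecular graph is disconnected (multi-fragment input unsupported)",
         call. = FALSE)
  }
  g
}

# Standard atomic weights (amu) for the elements the package handles.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph%s: %d heavy atoms, %d bonds%s>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              n_atoms(x), nrow(x$bonds),
              if (is.null(x$coords)) "" else ", 3D coordinates"))
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param g A [mol_graph()].
#' @return Integer atom count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

.as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = g$bonds[, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(g)))
  )
}

.is_connected <- function(g) {
  if (n_atoms(g) == 1) return(TRUE)
  if (nrow(g$bonds) < n_atoms(g) - 1) return(FALSE)
  igraph::is_connected(.as_igraph(g))
}

#' Parse a chemical structure into a heavy-atom molecular graph
#'
#' Reads a single molecule from a SMILES string or an SDF/MOL V2000 record
#' (file path or character text). Hydrogens are dropped; hybridization is
#' inferred from the record's own bond orders and aromatic flags (order 4 in
#' MOL, lowercase atoms in SMILES) — no aromaticity perception is performed.
#' 3D/2D coordinates are attached when the source provides them; SMILES input
#' carries no coordinates.
#'
#' @param source A SMILES string, a path to an SDF/MOL file, or the text of a
#'   MOL block.
#' @param format `"auto"` (default), `"smiles"`, or `"sdf"`. Auto treats
#'   existing file paths and multi-line text as SDF/MOL, anything else as
#'   SMILES.
#' @param id Optional compound identifier; defaults to the MOL title when
#'   present.
#' @return A [mol_graph()].
#' @examples
#' g <- read_structure("CCC")
#' n_atoms(g)
#' @export
read_structure <- function(source, format = c("auto", "smiles", "sdf"),
                           id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    is_file <- length(source) == 1 && !grepl("\n", source) &&
      nchar(source) < 1000 && file.exists(source)
    format <- if (is_file || grepl("\n", source)) "sdf" else "smiles"
  }
  if (format == "smiles") {
    .read_smiles(source, id = id)
  } else {
    .read_molblock(source, id = id)
  }
}

#' Read all molecules from an SDF file
#'
#' @param path Path to an SDF file (one or more V2000 records).
#' @return A tibble with columns `compound_id` and `structure` (a list column
#'   of [mol_graph()] objects), keyed by the SDF title line.
#' @export
read_structures <- function(path) {
  sdfset <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfset)
  graphs <- lapply(seq_along(sdfset), function(k) {
    .sdf_to_mol_graph(sdfset[[k]], id = ids[k])
  })
  tibble::tibble(compound_id = ids, structure = graphs)
}

.read_smiles <- function(smiles, id = NULL) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES input needs the ChemmineOB package", call. = FALSE)
  }
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("could not parse SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  g <- .sdf_to_mol_graph(sdfset[[1]], id = id, has_coords = FALSE)
  # Open Babel kekulizes on MOL export; recover aromatic tags from the
  # input's own lowercase atom tokens (the SMILES aromatic flags).
  arom <- .smiles_aromatic_flags(smiles)
  if (!is.null(arom)) {
    heavy <- arom$element != "H"
    if (sum(heavy) == n_atoms(g) &&
        all(toupper(arom$element[heavy]) == toupper(g$atoms$element))) {
      g$atoms$hybrid[arom$aromatic[heavy]] <- "aromatic"
    }
  }
  g
}

# Lexes atom tokens out of a SMILES string in order of appearance.
# Returns NULL when the string contains constructs the lexer does not cover.
.smiles_aromatic_flags <- function(smiles) {
  two_letter <- c("Cl", "Br")
  chars <- strsplit(smiles, "")[[1]]
  element <- character(0); aromatic <- logical(0)
  k <- 1
  while (k <= length(chars)) {
    ch <- chars[k]
    if (ch == "[") {
      close <- k + which(chars[(k + 1):length(chars)] == "]")[1]
      if (is.na(close)) return(NULL)
      body <- paste(chars[(k + 1):(close - 1)], collapse = "")
      m <- regmatches(body, regexec("^[0-9]*([A-Za-z][a-z]?)", body))[[1]]
      if (length(m) < 2) return(NULL)
      sym <- m[2]
      aromatic <- c(aromatic, sym %in% c("c", "n", "o", "s", "p", "se", "as"))
      element <- c(element, paste0(toupper(substr(sym, 1, 1)),
                                   substring(sym, 2)))
      k <- close + 1
    } else if (k < length(chars) &&
               paste0(ch, chars[k + 1]) %in% two_letter) {
      element <- c(element, paste0(ch, chars[k + 1]))
      aromatic <- c(aromatic, FALSE)
      k <- k + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I", "H")) {
      element <- c(element, ch); aromatic <- c(aromatic, FALSE); k <- k + 1
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      element <- c(element, toupper(ch)); aromatic <- c(aromatic, TRUE)
      k <- k + 1
    } else if (ch %in% c("(", ")", "=", "#", "-", "+", "/", "\\", ".", "@",
                         ":", "%") || grepl("[0-9]", ch)) {
      k <- k + 1
    } else {
      return(NULL)
    }
  }
  list(element = element, aromatic = aromatic)
}

.read_molblock <- function(source, id = NULL) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    src_name <- source
  } else {
    lines <- strsplit(source, "\n")[[1]]
    src_name <- "<mol text>"
  }
  if (!any(grepl("\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  sdfset <- tryCatch(
    ChemmineR::read.SDFset(tmp),
    error = function(e) stop("could not parse structure record from ",
                             src_name, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(sdfset) != 1) {
    stop("expected a single molecule in ", src_name, ", found ",
         length(sdfset), call. = FALSE)
  }
  if (is.null(id)) {
    title <- ChemmineR::sdfid(sdfset)[1]
    if (!is.na(title) && nzchar(title)) id <- title
  }
  .sdf_to_mol_graph(sdfset[[1]], id = id)
}

# Converts a ChemmineR SDF object to a hydrogen-suppressed mol_graph.
.sdf_to_mol_graph <- function(sdf, id = NULL, has_coords = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  n_all <- nrow(ab)
  if (is.null(bb) || (is.matrix(bb) && nrow(bb) == 0)) {
    bonds_all <- matrix(integer(0), ncol = 3)
  } else {
    bb <- as.matrix(bb)
    bonds_all <- bb[, 1:3, drop = FALSE]
  }
  heavy <- which(elements != "H")
  if (length(heavy) == 0) stop("no heavy atoms in record", call. = FALSE)
  remap <- integer(n_all); remap[heavy] <- seq_along(heavy)
  keep <- bonds_all[, 1] %in% heavy & bonds_all[, 2] %in% heavy
  bonds <- bonds_all[keep, , drop = FALSE]
  hybrid <- .infer_hybridization(length(heavy),
                                 cbind(remap[bonds[, 1]], remap[bonds[, 2]]),
                                 bonds[, 3])
  coords <- NULL
  if (has_coords && ncol(ab) >= 3) {
    coords <- unname(ab[heavy, 1:3, drop = FALSE])
    if (all(coords == 0)) coords <- NULL
  }
  mol_graph(
    atoms = tibble::tibble(element = elements[heavy], hybrid = hybrid),
    bonds = tibble::tibble(i = as.integer(remap[bonds[, 1]]),
                           j = as.integer(remap[bonds[, 2]]),
                           order = as.integer(bonds[, 3])),
    coords = coords,
    id = id
  )
}

# Hybridization from bond orders only: aromatic bond (order 4) -> aromatic;
# triple or two+ double bonds -> sp; one double bond -> sp2; else sp3.
.infer_hybridization <- function(n, ij, order) {
  hybrid <- rep("sp3", n)
  if (length(order) == 0) return(hybrid)
  for (a in seq_len(n)) {
    inc <- order[ij[, 1] == a | ij[, 2] == a]
    if (any(inc == 4)) hybrid[a] <- "aromatic"
    else if (any(inc == 3) || sum(inc == 2) >= 2) hybrid[a] <- "sp"
    else if (any(inc == 2)) hybrid[a] <- "sp2"
  }
  hybrid
}

#' Topological distance matrix
#'
#' Shortest-path bond counts between all pairs of heavy atoms.
#'
#' @param g A [mol_graph()]; must be connected.
#' @return A symmetric integer matrix with zero diagonal and attribute
#'   `mode = "topological"`.
#' @examples
#' g <- read_structure("CCC")
#' topological_distance_matrix(g)
#' @export
topological_distance_matrix <- function(g) {
  a <- n_atoms(g)
  if (a == 1) {
    d <- matrix(0, 1, 1)
  } else {
    d <- igraph::distances(.as_igraph(g))
    d <- d[order(as.integer(rownames(d))), order(as.integer(colnames(d)))]
    dimnames(d) <- NULL
  }
  structure(d, mode = "topological")
}

#' Reciprocal-square distance matrix
#'
#' The weighted distance matrix with off-diagonal entries 1/d^2, where d is
#' the topological (bond-count) distance; the diagonal stays zero. This is the
#' distance weighting behind the `Idw`-style information descriptors.
#'
#' @param g A [mol_graph()] with at least two atoms.
#' @return A symmetric matrix with entries in (0, 1] off the diagonal and
#'   attribute `mode = "reciprocal_square"`.
#' @export
reciprocal_square_distance_matrix <- function(g) {
  if (n_atoms(g) < 2) {
    stop("reciprocal-square distances need at least two atoms", call. = FALSE)
  }
  d <- topological_distance_matrix(g)
  w <- ifelse(d > 0, 1 / d^2, 0)
  structure(w, mode = "reciprocal_square")
}

#' Count simple paths of a given bond length
#'
#' Counts distinct undirected simple paths with exactly `length` bonds. The
#' length-2 count is the `P` in the second-order kappa shape index.
#'
#' @param g A [mol_graph()].
#' @param length Path length in bonds (>= 1).
#' @return Integer path count.
#' @examples
#' path_count(read_structure("CCCCC"), 2)
#' @export
path_count <- function(g, length) {
  if (length < 1) stop("path length must be >= 1", call. = FALSE)
  if (length == 1) return(nrow(g$bonds))
  if (nrow(g$bonds) == 0) return(0L)
  if (length == 2) {
    # closed form: one length-2 path per unordered neighbour pair at a vertex
    deg <- tabulate(c(g$bonds$i, g$bonds$j), nbins = n_atoms(g))
    return(as.integer(sum(deg * (deg - 1) / 2)))
  }
  ig <- .as_igraph(g)
  total <- 0L
  for (v in seq_len(n_atoms(g))) {
    paths <- igraph::all_simple_paths(ig, from = v, cutoff = length)
    total <- total + sum(lengths(paths) == length + 1)
  }
  as.integer(total / 2)  # each undirected path found from both endpoints
}

#' Kier alpha contributions
#'
#' Per-atom alpha values from Kier's covalent-radius ratios,
#' alpha_i = r_i / r(C sp3) - 1, tabulated by element and hybridization.
#'
#' @format A tibble with columns `element`, `hybrid`, `alpha`.
#' @return The alpha lookup table as a tibble.
#' @export
kier_alpha_table <- function() {
  tibble::tribble(
    ~element, ~hybrid,    ~alpha,
    "C",      "sp3",       0.00,
    "C",      "sp2",      -0.13,
    "C",      "aromatic", -0.13,
    "C",      "sp",       -0.22,
    "N",      "sp3",      -0.04,
    "N",      "sp2",      -0.20,
    "N",      "aromatic", -0.20,
    "N",      "sp",       -0.29,
    "O",      "sp3",      -0.04,
    "O",      "sp2",      -0.20,
    "O",      "aromatic", -0.20,
    "F",      "sp3",      -0.07,
    "P",      "sp3",       0.43,
    "P",      "sp2",       0.30,
    "S",      "sp3",       0.35,
    "S",      "sp2",       0.22,
    "S",      "aromatic",  0.22,
    "Cl",     "sp3",       0.29,
    "Br",     "sp3",       0.48,
    "I",      "sp3",       0.73
  )
}

#' Total alpha correction for a molecular graph
#'
#' Sums the Kier alpha contribution of every heavy atom. All-sp3-carbon
#' skeletons give 0 by construction.
#'
#' @param g A [mol_graph()].
#' @return The alpha sum (dimensionless).
#' @export
alpha_sum <- function(g) {
  tab <- kier_alpha_table()
  key <- paste(tab$element, tab$hybrid)
  lookup <- stats::setNames(tab$alpha, key)
  # halogens and sp3-only elements fall back to their single tabulated row
  atom_key <- paste(g$atoms$element, g$atoms$hybrid)
  vals <- lookup[atom_key]
  if (anyNA(vals)) {
    miss <- which(is.na(vals))[1]
    stop(sprintf("no Kier alpha value for atom %d (%s, %s)",
                 miss, g$atoms$element[miss], g$atoms$hybrid[miss]),
         call. = FALSE)
  }
  sum(vals)
}
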