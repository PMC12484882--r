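#' Molecular conformation container
#'
#' A conformation couples a list of atomic numbers with a matrix of 3D
#' coordinates (in Angstrom). It can optionally carry a reference
#' equilibrium geometry and the perturbation that produced the current
#' (high-energy) coordinates from it, so that relaxation models can be
#' supervised against the equilibrium state.
#'
#' @param elements integer vector of atomic numbers, one per atom.
#' @param positions numeric matrix `n x 3` of coordinates (Angstrom).
#' @param equilibrium_positions optional `n x 3` matrix of the equilibrium
#'   geometry the conformation was derived from.
#' @param perturbation optional `n x 3` matrix; when given it must satisfy
#'   `positions == equilibrium_positions + perturbation`.
#' @param mol_id identifier string.
#' @return an object of class `conformation`.
#' @export
conformation <- function(elements, positions,
                         equilibrium_positions = NULL,
                         perturbation = NULL,
                         mol_id = "mol") {
  elements <- as.integer(elements)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (length(elements) != nrow(positions))
    stop("number of elements (", length(elements),
         ") does not match number of position rows (", nrow(positions), ")")
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  if (any(elements < 1L)) stop("atomic numbers must be positive")
  if (!is.null(equilibrium_positions)) {
    equilibrium_positions <- as.matrix(equilibrium_positions)
    storage.mode(equilibrium_positions) <- "double"
    if (!identical(dim(equilibrium_positions), dim(positions)))
      stop("equilibrium_positions must match positions in shape")
    if (!all(is.finite(equilibrium_positions)))
      stop("all equilibrium coordinates must be finite")
  }
  if (!is.null(perturbation)) {
    if (is.null(equilibrium_positions))
      stop("perturbation requires equilibrium_positions")
    perturbation <- as.matrix(perturbation)
    storage.mode(perturbation) <- "double"
    if (!identical(dim(perturbation), dim(positions)))
      stop("perturbation must match positions in shape")
    if (max(abs(positions - equilibrium_positions - perturbation)) > 1e-9)
      stop("positions must equal equilibrium_positions + perturbation")
  }
  structure(list(elements = elements,
                 positions = positions,
                 equilibrium_positions = equilibrium_positions,
                 perturbation = perturbation,
                 mol_id = as.character(mol_id)),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", x$mol_id, ": ", length(x$elements), " atoms",
      if (!is.null(x$equilibrium_positions)) " (+equilibrium)" else "",
      "\n", sep = "")
  invisible(x)
}

n_atoms <- function(conf) length(conf$elements)

#' Apply a Gaussian perturbation to an equilibrium geometry
#'
#' Displaces each coordinate by i.i.d. zero-mean Gaussian noise with
#' standard deviation `sigma`, emulating a thermally excited high-energy
#' conformation. The unperturbed geometry is retained as
#' `equilibrium_positions` so relaxation can be supervised against it.
#'
#' @param conf a [conformation()]. If it has no `equilibrium_positions`,
#'   its current positions are treated as the equilibrium.
#' @param sigma noise standard deviation per coordinate (Angstrom, >= 0).
#' @param seed optional integer seed; fixing it makes the output
#'   reproducible.
#' @return a `conformation` with perturbed `positions`, the equilibrium
#'   geometry, and the realized `perturbation`.
#' @export
perturb_conformation <- function(conf, sigma = 0.3, seed = NULL) {
  stopifnot(inherits(conf, "conformation"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number")
  eq <- conf$equilibrium_positions %||% conf$positions
  n <- nrow(eq)
  noise <- if (sigma == 0) {
    matrix(0, n, 3L)
  } else if (is.null(seed)) {
    matrix(stats::rnorm(3L * n, sd = sigma), n, 3L)
  } else {
    with_seed(seed, matrix(stats::rnorm(3L * n, sd = sigma), n, 3L))
  }
  conformation(conf$elements, eq + noise,
               equilibrium_positions = eq,
               perturbation = noise,
               mol_id = conf$mol_id)
}

#' Rigidly transform a conformation
#'
#' @param conf a [conformation()].
#' @param rotation 3 x 3 orthogonal matrix (may include a reflection).
#' @param translation length-3 numeric vector.
#' @return the transformed `conformation`; any equilibrium geometry is
#'   transformed alongside the positions.
#' @export
transform_conformation <- function(conf, rotation = diag(3),
                                   translation = c(0, 0, 0)) {
  stopifnot(inherits(conf, "conformation"))
  rotation <- as.matrix(rotation)
  tr <- function(p) sweep(p %*% t(rotation), 2L, -translation)
  eq <- conf$equilibrium_positions
  conformation(conf$elements, tr(conf$positions),
               equilibrium_positions = if (!is.null(eq)) tr(eq),
               perturbation = if (!is.null(conf$perturbation))
                 conf$perturbation %*% t(rotation),
               mol_id = conf$mol_id)
}

#' Mirror a conformation through the yz plane
#'
#' Produces the enantiomeric geometry by negating the x coordinate of every
#' atom (composing with rotations reaches any mirror plane).
#'
#' @param conf a [conformation()].
#' @return the reflected `conformation`.
#' @export
reflect_conformation <- function(conf) {
  transform_conformation(conf, rotation = diag(c(-1, 1, 1)))
}
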