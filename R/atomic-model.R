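#' Construct an atomic model
#'
#' An `atomic_model` is an ordered table of atoms, each carrying a position
#' (angstrom), an atomic number Z and a Gaussian width `bwidth` (angstrom) —
#' the "B-factor" in this package's sense: the scale of the Gaussian that
#' models the atom's density spread, not the crystallographic
#' \eqn{8\pi^2\langle u^2\rangle} unless explicitly converted. Optional bonds
#' (pairs of atom indices) feed the built-in relaxer and synthetic
#' topologies.
#'
#' @param atoms data frame with columns `serial`, `element`, `atomic_number`,
#'   `chain_id`, `residue_index`, `residue_name`, `atom_name`, `x`, `y`, `z`,
#'   `bwidth`. Missing `serial` is filled with the row number; missing
#'   `atomic_number` is inferred from `element`.
#' @param bonds optional integer matrix (m x 2) of atom indices.
#' @return Object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, bonds = NULL) {
  req <- c("element", "chain_id", "residue_index", "residue_name",
           "atom_name", "x", "y", "z", "bwidth")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop_cf("atoms lack column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$atomic_number)) {
    atoms$atomic_number <- element_to_z(atoms$element)
    if (anyNA(atoms$atomic_number))
      stop_cf("unknown element(s): ",
              paste(unique(atoms$element[is.na(atoms$atomic_number)]),
                    collapse = ", "))
  }
  if (nrow(atoms) > 0) {
    if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop_cf("atom positions must be finite")
    if (any(!is.finite(atoms$bwidth)) || any(atoms$bwidth <= 0))
      stop_cf("bwidth must be positive and finite")
    if (any(atoms$atomic_number < 0))
      stop_cf("atomic_number must be >= 0")
    key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
    if (anyDuplicated(key))
      stop_cf("duplicate (chain_id, residue_index, atom_name): ",
              paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) > 0) {
      if (any(bonds < 1) || any(bonds > nrow(atoms)) ||
          any(bonds[, 1] == bonds[, 2]))
        stop_cf("bonds must reference two distinct existing atoms")
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("atomic_model: %d atoms, %d chain(s), %d residue(s)%s\n",
              nrow(a), length(unique(a$chain_id)),
              length(unique(paste(a$chain_id, a$residue_index))),
              if (is.null(x$bonds)) "" else
                sprintf(", %d bonds", nrow(x$bonds))))
  if (nrow(a) > 0)
    cat(sprintf("  bwidth range [%.3g, %.3g] A\n",
                min(a$bwidth), max(a$bwidth)))
  invisible(x)
}

#' Model accessors
#'
#' `n_atoms()` counts atoms; `atom_positions()` returns the n x 3 coordinate
#' matrix (angstrom); `set_atom_positions()` replaces it, preserving
#' everything else.
#'
#' @param model an `atomic_model`.
#' @param xyz n x 3 numeric matrix of new positions.
#' @return A count, a matrix, or the updated model respectively.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' @rdname n_atoms
#' @export
atom_positions <- function(model)
  as.matrix(model$atoms[, c("x", "y", "z"), drop = FALSE])

#' @rdname n_atoms
#' @export
set_atom_positions <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Residue grouping key
#'
#' Residues are identified by the pair (chain_id, residue_index) for the
#' residue-average B restraint and the per-residue scores.
#' @param model an `atomic_model`.
#' @return character vector, one key per atom.
#' @keywords internal
residue_key <- function(model)
  paste(model$atoms$chain_id, model$atoms$residue_index, sep = "|")

#' B-factor convention conversions
#'
#' `bcryst_to_sigma()` converts crystallographic temperature factors
#' \eqn{B = 8\pi^2\sigma^2} to the Gaussian width \eqn{\sigma};
#' `sigma_to_bcryst()` is the exact inverse.
#'
#' @param b,sigma numeric vectors.
#' @return numeric vector.
#' @export
bcryst_to_sigma <- function(b) sqrt(b / (8 * pi^2))

#' @rdname bcryst_to_sigma
#' @export
sigma_to_bcryst <- function(sigma) 8 * pi^2 * sigma^2
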