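## Atomic-model file I/O. PDB and mmCIF parsing/writing of coordinates goes
## through bio3d; the B column is interpreted per the chosen convention:
## "sigma" stores the Gaussian width verbatim (this package's native
## meaning), "crystallographic" stores 8*pi^2*sigma^2.

.bfactor_in <- function(b, convention, b_floor) {
  bw <- if (convention == "sigma") b else bcryst_to_sigma(pmax(b, 0))
  bad <- !is.finite(bw) | bw <= 0
  if (any(bad)) {
    cf_log(sum(bad), " non-positive B value(s) replaced by the floor ",
           b_floor, " A")
    bw[bad] <- b_floor
  }
  bw
}

## convert a bio3d pdb object to an atomic_model
.from_bio3d <- function(pdb, convention, b_floor) {
  a <- pdb$atom
  if (!is.null(a$alt)) {
    alt <- a$alt
    alt[is.na(alt)] <- ""
    first_alt <- alt %in% c("", "A", "1")
    dup <- duplicated(paste(a$chain, a$resno, a$elety)) & !first_alt
    if (any(!first_alt)) {
      keep <- first_alt | !duplicated(paste(a$chain, a$resno, a$elety))
      if (any(!keep))
        warning(sum(!keep), " alternate-conformer atom(s) beyond the ",
                "first dropped", call. = FALSE)
      a <- a[keep, , drop = FALSE]
    }
  }
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(trimws(elem) == "")) {
    ## infer the element from the leading letters of the atom name
    elem <- sub("^([0-9]*)([A-Za-z]).*$", "\\2", trimws(a$elety))
  }
  elem <- trimws(elem)
  z <- element_to_z(elem)
  if (anyNA(z)) {
    guess <- substr(toupper(trimws(a$elety[is.na(z)])), 1, 1)
    z2 <- element_to_z(guess)
    if (anyNA(z2))
      stop_cf("cannot infer the element for atom name(s): ",
              paste(unique(a$elety[is.na(z)][is.na(z2)]), collapse = ", "))
    elem[is.na(z)] <- guess
    z[is.na(z)] <- z2
  }
  occ <- a$o
  if (!is.null(occ) && any(is.finite(occ) & occ != 1))
    cf_log(sum(occ != 1, na.rm = TRUE), " atom(s) with occupancy != 1 ",
           "(occupancy is ignored)")
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atomic_model(data.frame(
    serial = a$eleno,
    element = elem,
    atomic_number = z,
    chain_id = chain,
    residue_index = a$resno,
    residue_name = a$resid,
    atom_name = trimws(a$elety),
    x = a$x, y = a$y, z = a$z,
    bwidth = .bfactor_in(a$b, convention, b_floor)))
}

#' Read an atomic model from PDB or mmCIF
#'
#' Populates each atom's Gaussian width from the B-factor column: verbatim
#' under `bfactor_convention = "sigma"` (the package's native meaning), or
#' via \eqn{\sigma = \sqrt{B / 8\pi^2}} under `"crystallographic"`.
#' Zero/negative column values are replaced by `b_floor` and logged.
#' Alternate conformers beyond the first are dropped with a warning;
#' occupancy is ignored (logged when not 1). Unknown elements are inferred
#' from the atom name, or raise an error when ambiguous.
#'
#' @param path a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param bfactor_convention `"sigma"` (default) or `"crystallographic"`.
#' @param b_floor replacement width for non-positive B values, angstrom.
#' @return An [atomic_model()].
#' @export
read_model <- function(path, bfactor_convention = c("sigma",
                                                    "crystallographic"),
                       b_floor = 0.25) {
  bfactor_convention <- match.arg(bfactor_convention)
  if (!file.exists(path)) stop_cf("no such file: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, verbose = FALSE)
  .from_bio3d(pdb, bfactor_convention, b_floor)
}

#' Write an atomic model to PDB or mmCIF
#'
#' The B column carries the Gaussian width per the chosen convention (see
#' [read_model()]); a write/read round trip preserves widths within the
#' column precision. The format follows the file extension. Coordinates
#' exceeding the PDB fixed-width fields (|x| >= 10^4) raise an error
#' suggesting mmCIF.
#'
#' @param model an [atomic_model()].
#' @param path output path (`.pdb` or `.cif`).
#' @param bfactor_convention `"sigma"` (default) or `"crystallographic"`.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path, bfactor_convention = c("sigma",
                                                    "crystallographic")) {
  bfactor_convention <- match.arg(bfactor_convention)
  a <- model$atoms
  bcol <- if (bfactor_convention == "sigma") a$bwidth
          else sigma_to_bcryst(a$bwidth)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  if (is_cif) {
    .write_cif(model, bcol, path)
    return(invisible(path))
  }
  if (nrow(a) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  xyz <- atom_positions(model)
  if (any(abs(xyz) >= 1e4) || any(abs(bcol) >= 1e3))
    stop_cf("coordinates or B values exceed the PDB fixed-width fields; ",
            "write mmCIF instead (.cif extension)")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(xyz)),
                   type = rep("ATOM", nrow(a)),
                   resno = a$residue_index, resid = a$residue_name,
                   eleno = a$serial, elety = a$atom_name,
                   chain = a$chain_id, o = rep(1, nrow(a)), b = bcol,
                   elesy = a$element)
  invisible(path)
}

## mmCIF atom_site writer with the canonical deposited-file column set
.write_cif <- function(model, bcol, path) {
  a <- model$atoms
  hdr <- c("data_cryofit", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- if (nrow(a) == 0) character(0) else
    sprintf(paste("ATOM %d %s %s . %s %s 1 %d ? %.4f %.4f %.4f 1.00",
                  "%.4f ? %d %s %s %s 1"),
            a$serial, a$element, a$atom_name, a$residue_name, a$chain_id,
            a$residue_index, a$x, a$y, a$z, bcol,
            a$residue_index, a$residue_name, a$chain_id, a$atom_name)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
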