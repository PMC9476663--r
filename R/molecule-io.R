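#' Construct a Molecule
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3), Angstrom.
#' @param name molecule label.
#' @param provenance source path or generator spec.
#' @return a \linkS4class{Molecule}.
#' @examples
#' m <- Molecule("C", matrix(0, 1, 3), name = "bare carbon")
#' nAtoms(m)
#' @export
Molecule <- function(elements, coords, name = "", provenance = "") {
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  storage.mode(coords) <- "double"
  new("Molecule", elements = as.character(elements), coords = coords,
      name = as.character(name)[1L], provenance = as.character(provenance)[1L])
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line (kept as the
#' molecule name), then one \code{element x y z} row per atom, coordinates
#' in Angstrom.
#'
#' @param path path to an XYZ file.
#' @return a \linkS4class{Molecule} with atoms in file order.
#' @seealso [writeXYZ()], [readPDB()]
#' @export
readXYZ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop("XYZ parse error in '", path, "': fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("XYZ parse error in '", path, "' line 1: malformed atom count '",
         lines[1L], "'")
  if (length(lines) < n + 2L)
    stop("XYZ parse error in '", path, "': declared ", n,
         " atoms but file has ", length(lines) - 2L, " atom rows")
  el <- character(n)
  xyz <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    ln <- k + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 4L)
      stop("XYZ parse error in '", path, "' line ", ln,
           ": expected 'element x y z'")
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v))
      stop("XYZ parse error in '", path, "' line ", ln,
           ": non-numeric coordinate")
    el[k] <- tok[1L]
    xyz[k, ] <- v
  }
  if (!all(el %in% names(corderoRadii())))
    stop("XYZ parse error in '", path, "': unknown element(s) ",
         paste(setdiff(el, names(corderoRadii())), collapse = ", "))
  Molecule(el, xyz, name = trimws(lines[2L]), provenance = path)
}

#' Write a molecule to an XYZ file
#'
#' Coordinates are written with 6 decimals; write-then-read reproduces the
#' element sequence exactly and the coordinates to the written precision.
#'
#' @param molecule a \linkS4class{Molecule}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeXYZ <- function(molecule, path) {
  stopifnot(is(molecule, "Molecule"))
  rows <- sprintf("%-3s %14.6f %14.6f %14.6f",
                  molecule@elements,
                  molecule@coords[, 1L], molecule@coords[, 2L],
                  molecule@coords[, 3L])
  writeLines(c(as.character(nAtoms(molecule)), moleculeName(molecule), rows),
             path)
  invisible(path)
}

#' Read a molecule from a PDB file (minimal subset)
#'
#' Parses ATOM/HETATM records for element symbols and Cartesian coordinates
#' only (via \pkg{bio3d}); chains, residues and connectivity records are
#' ignored beyond provenance. Alternate locations other than blank or
#' \code{'A'} are dropped. Bonds are always re-perceived from geometry, so
#' CONECT records are not needed.
#'
#' @param path path to a PDB file.
#' @return a \linkS4class{Molecule} in record order.
#' @export
readPDB <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in '", path, "': ",
                         conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("PDB parse error in '", path, "': no atoms")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  el <- trimws(at$elesy)
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back to the leading letters of the atom name, e.g. " CA " -> C
    guess <- sub("^[0-9']*([A-Za-z]).*$", "\\1", trimws(at$elety[miss]))
    el[miss] <- guess
  }
  el <- paste0(toupper(substr(el, 1L, 1L)),
               tolower(substr(el, 2L, 2L)))
  el <- trimws(el)
  if (any(el == ""))
    stop("PDB parse error in '", path, "': missing element information")
  Molecule(el, cbind(at$x, at$y, at$z), name = basename(path),
           provenance = path)
}

#' Empirical formula of an atom set
#' @param elements character vector of element symbols.
#' @return Hill-ordered formula string (C, H, then alphabetical).
#' @examples elementFormula(c("C", "H", "H", "H", "H"))  # "CH4"
#' @export
elementFormula <- function(elements) {
  tab <- table(elements)
  nm <- names(tab)
  ord <- c(intersect(c("C", "H"), nm), sort(setdiff(nm, c("C", "H"))))
  paste0(vapply(ord, function(e)
    if (tab[[e]] == 1L) e else paste0(e, tab[[e]]), ""), collapse = "")
}
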