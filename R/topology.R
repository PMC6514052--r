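#' Build a topology table
#'
#' A topology is an ordered table of atoms: one row per atom with its serial
#' number, atom name, residue name, author residue number, chain identifier,
#' element, mass (amu) and optional partial charge (e). Atom order is
#' significant and is preserved by all operations; residue numbers are the
#' author numbers from the source file (never renumbered), so residues can be
#' addressed the way the structural literature does (e.g. W755, E723).
#'
#' @param serial positive integer atom serial numbers, unique.
#' @param name atom name strings (e.g. `"CA"`, `"NE1"`).
#' @param resname 3-letter residue codes.
#' @param resid author residue numbers (integer).
#' @param chain single-character chain identifiers.
#' @param element element symbols; when `NULL`, guessed from the atom name.
#' @param mass atomic masses in amu; when `NULL`, looked up from the element.
#' @param charge partial charges in e, or `NA` when absent.
#' @return A `data.frame` of class `"topology"` with the columns above.
#' @examples
#' top <- topology(
#'   serial = 1:2, name = c("CA", "CA"), resname = c("ALA", "GLY"),
#'   resid = 1:2, chain = "A"
#' )
#' n_atoms(top)
#' @export
topology <- function(serial, name, resname, resid, chain,
                     element = NULL, mass = NULL, charge = NA_real_) {
  n <- length(serial)
  if (is.null(element)) element <- guess_element(name)
  if (is.null(mass)) mass <- .mass_for_element(element)
  top <- data.frame(
    serial = as.integer(serial),
    name = as.character(name),
    resname = as.character(resname),
    resid = as.integer(resid),
    chain = rep_len(as.character(chain), n),
    element = as.character(element),
    mass = as.numeric(mass),
    charge = rep_len(as.numeric(charge), n),
    stringsAsFactors = FALSE
  )
  class(top) <- c("topology", "data.frame")
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  if (anyDuplicated(top$serial)) {
    stop("topology invariant violated: duplicate atom serial numbers",
         call. = FALSE)
  }
  if (any(!is.finite(top$mass)) || any(top$mass <= 0)) {
    stop("topology invariant violated: all masses must be > 0", call. = FALSE)
  }
  if (any(!nzchar(top$element))) {
    stop("topology invariant violated: empty element symbol", call. = FALSE)
  }
  invisible(top)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues, chains: %s\n",
              nrow(x), nrow(unique(x[, c("chain", "resid")])),
              paste(unique(x$chain), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x a `topology` or `trajectory` object.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) nrow(x$topology) else nrow(x)
}

# Guess an element symbol from a PDB atom name: strip digits/primes, handle
# the 4-character hydrogen convention (leading digit), take leading letters.
guess_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9'\"]", "", trimws(nm))
    if (!nzchar(nm)) return("C")
    two <- toupper(substr(nm, 1, 2))
    if (two %in% c("CL", "NA", "MG", "ZN", "FE", "MN", "SE", "BR")) return(two)
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

# (chain, resid) -> list of atom index vectors, in first-appearance order.
residue_index <- function(top) {
  key <- paste(top$chain, top$resid, sep = "\r")
  split(seq_len(nrow(top)), factor(key, levels = unique(key)))
}
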