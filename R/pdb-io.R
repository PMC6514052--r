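#' Read a (multi-model) PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single-frame trajectory. Coordinates are converted from
#' Angstrom to nm at this boundary; author residue numbering, chain ids and
#' atom names are preserved verbatim. `HETATM` records (including waters) are
#' kept — whether they enter an analysis is decided by selections, not by the
#' reader. A `CRYST1` record with 90-degree angles is read as an orthorhombic
#' periodic box; non-rectangular cells are ignored with a warning.
#'
#' Only the first alternate location of an atom is kept. Insertion codes are
#' not interpreted (pass-through in the resid column is not attempted).
#'
#' @param path PDB file path.
#' @param dt_ps time spacing assigned to successive models, ps (PDB files
#'   carry no time axis). Default 1.
#' @return a [trajectory()].
#' @seealso [write_pdb()]
#' @export
read_pdb <- function(path, dt_ps = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)

  box <- NULL
  cryst <- which(startsWith(rec, "CRYST1"))
  if (length(cryst)) {
    cl <- lines[cryst[1]]
    abc <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                        substr(cl, 25, 33)))
    ang <- as.numeric(c(substr(cl, 34, 40), substr(cl, 41, 47),
                        substr(cl, 48, 54)))
    if (all(is.finite(abc)) && all(abs(ang - 90) < 1e-6) && all(abc > 0)) {
      box <- abc * 0.1  # Angstrom -> nm
    } else if (all(is.finite(abc))) {
      warning("non-orthorhombic CRYST1 cell ignored")
    }
  }

  # Assign each atom line to a model block.
  if (any(is_model)) {
    model_id <- cumsum(is_model) - cumsum(c(0, utils::head(is_endmdl, -1)))
    atom_lines <- which(is_atom & model_id > 0)
    groups <- split(atom_lines, cumsum(is_model)[atom_lines])
  } else {
    groups <- list(which(is_atom))
  }

  parse_block <- function(idx) {
    ll <- lines[idx]
    x <- suppressWarnings(as.numeric(substr(ll, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ll, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ll, 47, 54)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
    if (length(bad)) {
      stop(sprintf("malformed ATOM/HETATM record at line %d of %s",
                   idx[bad[1]], path), call. = FALSE)
    }
    list(lines = ll, xyz = cbind(x, y, z) * 0.1)  # Angstrom -> nm
  }

  first <- parse_block(groups[[1]])
  ll <- first$lines
  altloc <- substr(ll, 17, 17)
  keep <- altloc %in% c(" ", "", "A", "1")
  serial <- suppressWarnings(as.integer(substr(ll, 7, 11)))
  bad <- which(keep & !is.finite(serial))
  if (length(bad)) {
    stop(sprintf("malformed ATOM/HETATM record at line %d of %s",
                 groups[[1]][bad[1]], path), call. = FALSE)
  }
  name <- trimws(substr(ll, 13, 16))
  resname <- trimws(substr(ll, 18, 20))
  chain <- substr(ll, 22, 22)
  resid <- suppressWarnings(as.integer(substr(ll, 23, 26)))
  element <- trimws(substr(ll, 77, 78))
  element <- ifelse(nzchar(element), element, guess_element(name))

  top <- topology(serial[keep], name[keep], resname[keep], resid[keep],
                  chain[keep], element = element[keep])
  na <- nrow(top)
  nf <- length(groups)
  coords <- array(NA_real_, dim = c(na, 3, nf))
  coords[, , 1] <- first$xyz[keep, , drop = FALSE]
  if (nf > 1) {
    for (k in 2:nf) {
      blk <- parse_block(groups[[k]])
      alt_k <- substr(blk$lines, 17, 17)
      keep_k <- alt_k %in% c(" ", "", "A", "1")
      if (sum(keep_k) != na) {
        stop(sprintf(
          "inconsistent atom count across MODELs in %s: model 1 has %d, model %d has %d",
          path, na, k, sum(keep_k)), call. = FALSE)
      }
      coords[, , k] <- blk$xyz[keep_k, , drop = FALSE]
    }
  }
  trajectory(top, coords, times = (seq_len(nf) - 1) * dt_ps,
             box = if (is.null(box)) NULL else
               matrix(box, nrow = nf, ncol = 3, byrow = TRUE))
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame; coordinates converted nm to
#' Angstrom and printed with 3 decimals (ties resolved round-half-even by
#' the C formatting of the binary value). Atom names, residue names, author
#' residue numbers and chain ids are written verbatim; an orthorhombic box,
#' when present, is emitted as a `CRYST1` record.
#'
#' @param traj a [trajectory()]; must have at least one frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  if (!inherits(traj, "trajectory") || n_frames(traj) < 1) {
    stop("write_pdb requires a non-empty trajectory", call. = FALSE)
  }
  top <- traj$topology
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path, call. = FALSE)
  })
  on.exit(close(con))
  if (!is.null(traj$box)) {
    b <- traj$box[1, ] * 10
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      b[1], b[2], b[3], 90, 90, 90), con)
  }
  # PDB atom-name column convention: names shorter than 4 chars start in
  # column 14 unless the element symbol is two characters wide.
  fmt_name <- ifelse(
    nchar(top$name) >= 4 | nchar(top$element) >= 2,
    formatC(top$name, width = -4),
    paste0(" ", formatC(top$name, width = -3)))
  record <- ifelse(top$resname %in% c(.protein_resnames), "ATOM  ", "HETATM")
  nf <- n_frames(traj)
  for (k in seq_len(nf)) {
    xyz <- frame_coords(traj, k) * 10  # nm -> Angstrom
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, top$serial %% 100000L, fmt_name, top$resname, top$chain,
      top$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      formatC(top$element, width = 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
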