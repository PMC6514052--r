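#' Hydrogen-bond geometric specification
#'
#' Standard-practice geometric criteria: donor-acceptor distance at most
#' `d_cutoff` and, when a hydrogen atom is given, donor-hydrogen-acceptor
#' angle at least `angle_cutoff`.
#'
#' @param donor,acceptor single-atom masks.
#' @param hydrogen single-atom mask or `NULL` (distance-only criterion).
#' @param d_cutoff donor-acceptor cutoff, nm. Default 0.35.
#' @param angle_cutoff minimum D-H-A angle, degrees. Default 120.
#' @return list of class `"hbond_spec"`.
#' @export
hbond_spec <- function(donor, acceptor, hydrogen = NULL,
                       d_cutoff = 0.35, angle_cutoff = 120) {
  if (length(donor) != 1 || length(acceptor) != 1 ||
      (!is.null(hydrogen) && length(hydrogen) != 1)) {
    stop("hbond_spec masks must be single atoms", call. = FALSE)
  }
  if (d_cutoff <= 0 || angle_cutoff <= 0) {
    stop("hbond_spec cutoffs must be positive", call. = FALSE)
  }
  structure(list(donor = as.integer(donor), acceptor = as.integer(acceptor),
                 hydrogen = if (is.null(hydrogen)) NULL else
                   as.integer(hydrogen),
                 d_cutoff = d_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_spec")
}

#' Is a hydrogen bond present in one frame?
#'
#' True iff the donor-acceptor distance is `<= d_cutoff` AND (no hydrogen
#' given, or the donor-hydrogen-acceptor angle is `>= angle_cutoff`). Both
#' boundaries are inclusive.
#'
#' @param traj a [trajectory()].
#' @param spec an [hbond_spec()].
#' @param frame frame index (default 1).
#' @return logical.
#' @export
hbond_present <- function(traj, spec, frame = 1) {
  hbond_series(traj, spec)[frame]
}

#' Per-frame hydrogen-bond indicator
#' @inheritParams hbond_present
#' @return logical vector, one entry per frame.
#' @export
hbond_series <- function(traj, spec) {
  stopifnot(inherits(spec, "hbond_spec"))
  na <- n_atoms(traj)
  atoms <- c(spec$donor, spec$acceptor, spec$hydrogen)
  if (any(atoms < 1 | atoms > na)) {
    stop("hbond_spec atoms do not resolve in this topology", call. = FALSE)
  }
  nf <- n_frames(traj)
  vapply(seq_len(nf), function(k) {
    d <- traj$coords[spec$donor, , k]
    a <- traj$coords[spec$acceptor, , k]
    if (sqrt(sum((d - a)^2)) > spec$d_cutoff) return(FALSE)
    if (is.null(spec$hydrogen)) return(TRUE)
    h <- traj$coords[spec$hydrogen, , k]
    vector_angle(d - h, a - h) >= spec$angle_cutoff
  }, logical(1))
}

vector_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Hydrogen-bond occupancy across a trajectory
#'
#' Fraction of frames in which [hbond_present()] is true — the quantity
#' usually reported as "formed in X% of the snapshots". Invariant under
#' frame reordering.
#'
#' @inheritParams hbond_present
#' @return fraction in `[0, 1]`.
#' @export
hbond_occupancy <- function(traj, spec) {
  if (n_frames(traj) < 1) stop("occupancy needs >= 1 frame", call. = FALSE)
  mean(hbond_series(traj, spec))
}

# Side-chain charged-atom rule per residue type: the atoms whose (midpoint)
# position represents the charged moiety.
.charged_atom_rule <- list(
  LYS = list(atoms = "NZ"),
  ARG = list(atoms = "CZ"),
  GLU = list(atoms = c("OE1", "OE2")),   # carboxylate midpoint
  ASP = list(atoms = c("OD1", "OD2")),
  HIS = list(atoms = c("ND1", "NE2"))
)

#' Charge-center definition
#'
#' A set of member residues whose charged side-chain moieties define one
#' electrostatic center, e.g. the negatively charged helix-12 N-terminal
#' patch (Glu residues) versus the positively charged helix-3 C-terminal
#' patch (Lys/Arg). The representative point of each member is taken from a
#' fixed atom table (Lys `NZ`; Arg `CZ`; Glu `OE1`/`OE2` midpoint; Asp
#' `OD1`/`OD2` midpoint; His `ND1`/`NE2` midpoint), or the alpha carbon when
#' `rule = "ca"`.
#'
#' Two presets for the progesterone-receptor LBD surface centers ship with
#' the package (see [pr_lbd_charge_centers()]); note that published residue
#' lists for the positive center differ between sources, so both variants
#' are provided.
#'
#' @param members data frame with columns `chain`, `resid` (one row per
#'   member residue); non-empty.
#' @param rule `"sidechain"` (charged-atom table) or `"ca"`.
#' @param charge net charge of the center, e.
#' @return list of class `"charge_center"`.
#' @export
charge_center <- function(members, rule = c("sidechain", "ca"), charge = 0) {
  rule <- match.arg(rule)
  if (!nrow(members)) stop("charge_center needs >= 1 member", call. = FALSE)
  structure(list(members = members[, c("chain", "resid")], rule = rule,
                 charge = charge),
            class = "charge_center")
}

#' Position of a charge center in one frame
#'
#' Unweighted centroid of the rule-selected representative points of the
#' member residues.
#'
#' @param traj a [trajectory()].
#' @param center a [charge_center()].
#' @param frame frame index.
#' @return length-3 position, nm.
#' @export
charge_center_position <- function(traj, center, frame = 1) {
  pts <- charge_center_points(traj, center, frame)
  colMeans(pts)
}

charge_center_points <- function(traj, center, frame) {
  top <- traj$topology
  missing <- character(0)
  pts <- matrix(NA_real_, nrow(center$members), 3)
  for (i in seq_len(nrow(center$members))) {
    ch <- center$members$chain[i]
    rs <- center$members$resid[i]
    in_res <- which(top$chain == ch & top$resid == rs)
    if (!length(in_res)) {
      missing <- c(missing, sprintf("%s%d (residue absent)", ch, rs))
      next
    }
    if (center$rule == "ca") {
      want <- in_res[top$name[in_res] == "CA"]
    } else {
      rule <- .charged_atom_rule[[top$resname[in_res[1]]]]
      if (is.null(rule)) {
        missing <- c(missing, sprintf("%s%d (%s has no charged-atom rule)",
                                      ch, rs, top$resname[in_res[1]]))
        next
      }
      want <- in_res[match(rule$atoms, top$name[in_res])]
    }
    if (any(is.na(want)) || !length(want)) {
      missing <- c(missing, sprintf("%s%d (atoms not found)", ch, rs))
      next
    }
    pts[i, ] <- colMeans(traj$coords[want, , frame, drop = FALSE][, , 1,
                                                                  drop = FALSE])
  }
  if (length(missing)) {
    stop("charge_center_position: unresolvable members: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pts
}

#' Charge-center distance series
#'
#' Per-frame distance between the centroids of two charge centers, nm.
#'
#' @param traj a [trajectory()].
#' @param center_a,center_b [charge_center()] objects.
#' @return an [md_series()] in nm.
#' @export
charge_center_distance_series <- function(traj, center_a, center_b) {
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    pa <- charge_center_position(traj, center_a, k)
    pb <- charge_center_position(traj, center_b, k)
    sqrt(sum((pa - pb)^2))
  }, numeric(1))
  md_series(traj$times, vals, label = "charge-center distance", units = "nm")
}

#' Progesterone-receptor LBD surface charge-center presets
#'
#' The negatively charged helix-12 N-terminal center (H12NT) and the
#' positively charged helix-3 C-terminal center (H3CT) on chain A.
#' `variant = "discussion"` (default) uses H12NT = E904/E907/E911 and
#' H3CT = K733/R740; `variant = "methods"` uses the alternative published
#' list H3CT = K731/K734/K740 with the same acidic residues plus E723.
#' The two variants exist because published residue lists disagree; compare
#' both when the choice matters.
#'
#' @param variant `"discussion"` or `"methods"`.
#' @param chain chain identifier. Default `"A"`.
#' @return list with `h12nt` and `h3ct` [charge_center()]s.
#' @export
pr_lbd_charge_centers <- function(variant = c("discussion", "methods"),
                                  chain = "A") {
  variant <- match.arg(variant)
  if (variant == "discussion") {
    neg <- data.frame(chain = chain, resid = c(904L, 907L, 911L))
    pos <- data.frame(chain = chain, resid = c(733L, 740L))
  } else {
    neg <- data.frame(chain = chain, resid = c(723L, 907L, 911L))
    pos <- data.frame(chain = chain, resid = c(731L, 734L, 740L))
  }
  list(h12nt = charge_center(neg, charge = -nrow(neg)),
       h3ct = charge_center(pos, charge = +nrow(pos)))
}

#' Dielectric-screened Coulomb energy
#'
#' Interaction energy of two point charges at separation `d` in a uniform
#' dielectric: `E = kC q1 q2 / (eps d)` in kJ/mol, with
#' `kC = 138.935458 kJ mol^-1 nm e^-2`. The `"as_printed"` form divides by
#' `d^2` instead of `d`; it is dimensionally a force law, not an energy, and
#' is provided only for comparison with literature that prints it — results
#' carry a `formula` attribute flagging the non-standard form.
#'
#' @param q1,q2 charges, e.
#' @param d separation, nm (> 0); vectorised.
#' @param epsilon relative dielectric constant (> 0). Default 80, the usual
#'   choice for fully solvent-exposed charge pairs.
#' @param form `"coulomb_1_over_d"` (default) or `"as_printed_1_over_d2"`.
#' @return energy (or energies), kJ/mol, with attribute `formula`.
#' @examples
#' coulomb_energy(1, -1, d = 0.3)  # about -5.79 kJ/mol
#' @export
coulomb_energy <- function(q1, q2, d, epsilon = 80,
                           form = c("coulomb_1_over_d",
                                    "as_printed_1_over_d2")) {
  form <- match.arg(form)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (any(d <= 0)) stop("separation d must be > 0", call. = FALSE)
  denom <- if (form == "coulomb_1_over_d") d else d^2
  e <- .const$kc_kJmol_nm * q1 * q2 / (epsilon * denom)
  attr(e, "formula") <- if (form == "coulomb_1_over_d") {
    sprintf("kC*q1*q2/(eps*d), eps = %g", epsilon)
  } else {
    sprintf("kC*q1*q2/(eps*d^2), eps = %g [non-standard: force-law form]",
            epsilon)
  }
  e
}

# Charged side-chain atom names used for salt-bridge N-O distances.
.basic_n_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                       HIS = c("ND1", "NE2"))
.acidic_o_atoms <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

#' Salt-bridge distance series between two residues
#'
#' Per frame, the minimum distance between the basic side-chain nitrogen
#' atoms of one residue and the acidic side-chain oxygen atoms of the other
#' (which residue carries which group is detected from the residue types).
#' A contact flag marks frames with the minimum N-O distance `<=`
#' `contact_cutoff`.
#'
#' @param traj a [trajectory()].
#' @param chain_a,resid_a,chain_b,resid_b the two residues.
#' @param contact_cutoff contact threshold, nm. Default 0.4.
#' @return an [md_series()] (nm) with an extra logical column `contact`.
#' @export
salt_bridge_series <- function(traj, chain_a, resid_a, chain_b, resid_b,
                               contact_cutoff = 0.4) {
  top <- traj$topology
  grab <- function(ch, rs) which(top$chain == ch & top$resid == rs)
  ra <- grab(chain_a, resid_a); rb <- grab(chain_b, resid_b)
  if (!length(ra) || !length(rb)) {
    stop("salt_bridge_series: residue not found", call. = FALSE)
  }
  group_atoms <- function(res_idx) {
    rn <- top$resname[res_idx[1]]
    if (!is.null(.basic_n_atoms[[rn]])) {
      list(kind = "basic",
           idx = res_idx[top$name[res_idx] %in% .basic_n_atoms[[rn]]])
    } else if (!is.null(.acidic_o_atoms[[rn]])) {
      list(kind = "acidic",
           idx = res_idx[top$name[res_idx] %in% .acidic_o_atoms[[rn]]])
    } else {
      stop(sprintf("residue %s has no charged side-chain group", rn),
           call. = FALSE)
    }
  }
  ga <- group_atoms(ra); gb <- group_atoms(rb)
  if (ga$kind == gb$kind) {
    stop("salt_bridge_series needs one basic and one acidic residue",
         call. = FALSE)
  }
  if (!length(ga$idx) || !length(gb$idx)) {
    stop("charged side-chain atoms missing from topology", call. = FALSE)
  }
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    A <- frame_coords(traj, k, ga$idx)
    B <- frame_coords(traj, k, gb$idx)
    min(apply(A, 1, function(p) min(point_distances(B, p))))
  }, numeric(1))
  out <- md_series(traj$times, vals, label = "min N-O distance", units = "nm")
  out$contact <- vals <= contact_cutoff
  out
}
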