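# Residue-lipid contact detection with HBPLUS-style geometric criteria.
# Three contact classes are recognized: hydrogen bonds (protein donor to
# lipid acceptor; lipid hydrogens are never placed, so lipid-donated
# bonds are not scored), van der Waals contacts (heavy-atom radii sum
# plus a tolerance) and salt bridges (oppositely charged heavy atoms
# within a cutoff). Every contact is classified as head- or tail-group
# according to the lipid's atom partition.

#' Geometric criteria for contact detection
#'
#' @param da_max Maximum donor-acceptor distance for a hydrogen bond
#'   (A, default 3.9; the bond requires D-A strictly below this).
#' @param ha_max Maximum hydrogen-acceptor distance (A, default 2.5,
#'   inclusive).
#' @param min_angle Minimum value (degrees, exclusive) of the three
#'   angles D-H-A, D-A-AA and H-A-AA (default 90).
#' @param aromatic_axis_max Maximum D-A-AX and H-A-AX angle (degrees) for
#'   amino-aromatic hydrogen bonds (default 20); only consulted when an
#'   acceptor carries an aromatic ring axis.
#' @param vdw_tolerance Distance allowance above the radii sum for van
#'   der Waals contacts (A, default 0.5).
#' @param salt_bridge_max Maximum charged-pair heavy-atom distance for a
#'   salt bridge (A, default 4.0).
#' @param radii Named per-element van der Waals radii (A). Elements
#'   without an entry fall back to 1.7 A.
#' @return Object of class `geometry_params`.
#' @export
geometry_params <- function(da_max = 3.9, ha_max = 2.5, min_angle = 90,
                            aromatic_axis_max = 20, vdw_tolerance = 0.5,
                            salt_bridge_max = 4.0,
                            radii = c(C = 1.7, N = 1.55, O = 1.52,
                                      S = 1.8, P = 1.8)) {
  stopifnot(da_max > 0, ha_max > 0, vdw_tolerance >= 0, salt_bridge_max > 0,
            min_angle > 0, min_angle < 180,
            aromatic_axis_max > 0, aromatic_axis_max < 180,
            all(radii > 0))
  structure(list(da_max = da_max, ha_max = ha_max, min_angle = min_angle,
                 aromatic_axis_max = aromatic_axis_max,
                 vdw_tolerance = vdw_tolerance,
                 salt_bridge_max = salt_bridge_max, radii = radii),
            class = "geometry_params")
}

element_radius <- function(element, params) {
  r <- params$radii[element]
  miss <- is.na(r)
  if (any(miss)) {
    message("no van der Waals radius for element(s) ",
            paste(unique(element[miss]), collapse = ", "),
            "; using 1.7 A")
    r[miss] <- 1.7
  }
  unname(r)
}

#' Evaluate the hydrogen-bond geometric criteria for one candidate
#'
#' A hydrogen bond requires (i) donor-acceptor distance < `da_max`,
#' (ii) hydrogen-acceptor distance <= `ha_max`, and (iii) the three
#' angles D-H-A, D-A-AA and H-A-AA all > `min_angle`, for every acceptor
#' antecedent AA. For amino-aromatic bonds (acceptor ring with axis
#' `ax`), D-A-AX and H-A-AX must additionally be < `aromatic_axis_max`.
#'
#' @param d,h,a Coordinates (length-3) of donor, hydrogen, acceptor.
#' @param aa List of (or single) length-3 coordinates of the acceptor
#'   antecedent atom(s).
#' @param params A [geometry_params()].
#' @param ax Optional aromatic ring axis unit vector at the acceptor.
#' @return Logical scalar.
#' @export
hbond_criteria <- function(d, h, a, aa, params = geometry_params(), ax = NULL) {
  if (!is.list(aa)) aa <- list(aa)
  if (vec_norm(a - d) >= params$da_max) return(FALSE)
  if (vec_norm(a - h) > params$ha_max) return(FALSE)
  if (angle_deg(d, h, a) <= params$min_angle) return(FALSE)
  for (x in aa) {
    if (angle_deg(d, a, x) <= params$min_angle) return(FALSE)
    if (angle_deg(h, a, x) <= params$min_angle) return(FALSE)
  }
  if (!is.null(ax)) {
    axp <- a + vec_unit(ax)
    if (angle_deg(d, a, axp) >= params$aromatic_axis_max) return(FALSE)
    if (angle_deg(h, a, axp) >= params$aromatic_axis_max) return(FALSE)
  }
  TRUE
}

empty_contacts <- function() {
  data.frame(chain_id = character(), resno = integer(), resid = character(),
             residue_atom = character(), lipid_instance = character(),
             het_id = character(), lipid_atom = character(),
             contact_type = character(), lipid_group = character(),
             distance = numeric(), stringsAsFactors = FALSE)
}

contact_rows <- function(chain, lipid, res_idx, lip_idx, type, dist) {
  at <- chain$atoms
  data.frame(chain_id = chain$chain_id,
             resno = at$resno[res_idx], resid = at$resid[res_idx],
             residue_atom = at$elety[res_idx],
             lipid_instance = lipid$instance_id, het_id = lipid$het_id,
             lipid_atom = lipid$atoms$elety[lip_idx],
             contact_type = type, lipid_group = NA_character_,
             distance = dist, stringsAsFactors = FALSE)
}

# Acceptor atoms on a lipid: oxygens (lipid hydrogens are not modelled,
# so lipids never donate). Antecedents come from the instance bond graph.
lipid_acceptors <- function(lipid) {
  ox <- which(lipid$atoms$element == "O")
  if (!length(ox)) return(NULL)
  bonds <- lipid$bonds
  ante <- lapply(ox, function(i) {
    nm <- lipid$atoms$elety[i]
    nb <- c(bonds$a2[bonds$a1 == nm], bonds$a1[bonds$a2 == nm])
    match(nb, lipid$atoms$elety)
  })
  list(idx = ox, antecedents = ante)
}

#' Detect protein-to-lipid hydrogen bonds
#'
#' Applies the geometric criteria of [hbond_criteria()] between every
#' placed polar hydrogen of the chain and every lipid oxygen acceptor.
#' Acceptors with no bonded antecedent atom are skipped with a message.
#'
#' @param chain A `protein_chain`; hydrogens are placed on the fly when
#'   absent (see [place_polar_hydrogens()]).
#' @param lipids List of `lipid_instance` objects.
#' @param params A [geometry_params()].
#' @return Contact records (one row per donor-acceptor pair; `distance`
#'   is the donor-acceptor distance).
#' @export
detect_hbonds <- function(chain, lipids, params = geometry_params()) {
  if (is.null(chain$hydrogens)) {
    acc_xyz <- do.call(rbind, lapply(lipids, function(l)
      as.matrix(l$atoms[l$atoms$element == "O", c("x", "y", "z")])))
    chain <- place_polar_hydrogens(chain, acceptors = acc_xyz)
  }
  hyd <- chain$hydrogens
  if (nrow(hyd) == 0L) return(empty_contacts())
  at <- chain$atoms
  donor_idx <- match(paste(hyd$resno, hyd$donor),
                     paste(at$resno, at$elety))
  d_xyz <- as.matrix(at[donor_idx, c("x", "y", "z")])
  h_xyz <- as.matrix(hyd[, c("x", "y", "z")])

  out <- list()
  for (lipid in lipids) {
    acc <- lipid_acceptors(lipid)
    if (is.null(acc)) next
    a_xyz <- as.matrix(lipid$atoms[acc$idx, c("x", "y", "z")])
    cand <- neighbor_pairs(d_xyz, a_xyz, params$da_max)
    cand <- cand[cand$distance < params$da_max, , drop = FALSE]
    if (!nrow(cand)) next
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      ante <- acc$antecedents[[j]]
      ante <- ante[!is.na(ante)]
      if (!length(ante)) {
        message("acceptor ", lipid$atoms$elety[acc$idx[j]], " of ",
                lipid$instance_id, " has no antecedent; skipped")
        next
      }
      aa <- lapply(ante, function(k) as.numeric(lipid$atoms[k, c("x", "y", "z")]))
      keep[r] <- hbond_criteria(d_xyz[i, ], h_xyz[i, ], a_xyz[j, ], aa, params)
    }
    if (any(keep)) {
      cand <- cand[keep, , drop = FALSE]
      out[[length(out) + 1L]] <- contact_rows(
        chain, lipid, donor_idx[cand$i], acc$idx[cand$j], "hbond",
        cand$distance)
    }
  }
  if (!length(out)) return(empty_contacts())
  res <- do.call(rbind, out)
  # One record per donor-acceptor atom pair (several hydrogens on one
  # donor can satisfy the criteria).
  res[!duplicated(res[, c("resno", "residue_atom", "lipid_instance",
                          "lipid_atom")]), , drop = FALSE]
}

#' Detect van der Waals contacts
#'
#' A heavy-atom pair is in contact when its distance is at most the sum
#' of the element radii plus `vdw_tolerance`. Pairs already identified as
#' hydrogen-bonded (passed via `exclude`) are not reported again.
#'
#' @param chain A `protein_chain`.
#' @param lipids List of `lipid_instance` objects.
#' @param params A [geometry_params()].
#' @param exclude Optional contact data.frame whose (residue atom, lipid
#'   atom) pairs are suppressed.
#' @return Contact records.
#' @export
detect_vdw <- function(chain, lipids, params = geometry_params(),
                       exclude = NULL) {
  at <- chain$atoms
  p_xyz <- as.matrix(at[, c("x", "y", "z")])
  p_rad <- element_radius(at$element, params)
  max_cut <- 2 * max(c(params$radii, 1.7)) + params$vdw_tolerance
  out <- list()
  for (lipid in lipids) {
    l_xyz <- as.matrix(lipid$atoms[, c("x", "y", "z")])
    l_rad <- element_radius(lipid$atoms$element, params)
    cand <- neighbor_pairs(p_xyz, l_xyz, max_cut)
    if (!nrow(cand)) next
    thr <- p_rad[cand$i] + l_rad[cand$j] + params$vdw_tolerance
    cand <- cand[cand$distance <= thr, , drop = FALSE]
    if (!nrow(cand)) next
    out[[length(out) + 1L]] <- contact_rows(chain, lipid, cand$i, cand$j,
                                            "vdw", cand$distance)
  }
  if (!length(out)) return(empty_contacts())
  res <- do.call(rbind, out)
  if (!is.null(exclude) && nrow(exclude)) {
    key <- function(x) paste(x$resno, x$residue_atom, x$lipid_instance,
                             x$lipid_atom)
    res <- res[!(key(res) %in% key(exclude)), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

# Formal charge assignments for salt bridges.
PROTEIN_POSITIVE <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                         HIS = c("ND1", "NE2"))
PROTEIN_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

lipid_charged_atoms <- function(lipid) {
  atoms <- lipid$atoms; bonds <- lipid$bonds
  neighbors <- function(nm) c(bonds$a2[bonds$a1 == nm], bonds$a1[bonds$a2 == nm])
  elem_of <- stats::setNames(atoms$element, atoms$elety)
  neg <- which(atoms$element == "O" &
                 vapply(atoms$elety, function(nm)
                   any(elem_of[neighbors(nm)] == "P"), logical(1)))
  pos <- which(atoms$element == "N" &
                 vapply(atoms$elety, function(nm)
                   length(neighbors(nm)) >= 4L, logical(1)))
  list(neg = neg, pos = pos)
}

#' Detect salt bridges between charged residue and lipid atoms
#'
#' Positive protein centers: ARG NE/NH1/NH2, LYS NZ, HIS ND1/NE2.
#' Negative: ASP OD1/OD2, GLU OE1/OE2. On the lipid, phosphate oxygens
#' (O bonded to P) are negative and quaternary amines (N with four heavy
#' neighbors) positive. Oppositely charged heavy-atom pairs within
#' `salt_bridge_max` are reported.
#'
#' @inheritParams detect_vdw
#' @return Contact records.
#' @export
detect_salt_bridges <- function(chain, lipids, params = geometry_params()) {
  at <- chain$atoms
  sel <- function(tab) {
    which(mapply(function(rid, aty) aty %in% (tab[[rid]] %||% character()),
                 at$resid, at$elety))
  }
  p_pos <- sel(PROTEIN_POSITIVE)
  p_neg <- sel(PROTEIN_NEGATIVE)
  out <- list()
  for (lipid in lipids) {
    ch_l <- lipid_charged_atoms(lipid)
    for (pair in list(list(p = p_pos, l = ch_l$neg),
                      list(p = p_neg, l = ch_l$pos))) {
      if (!length(pair$p) || !length(pair$l)) next
      cand <- neighbor_pairs(as.matrix(at[pair$p, c("x", "y", "z"), drop = FALSE]),
                             as.matrix(lipid$atoms[pair$l, c("x", "y", "z"), drop = FALSE]),
                             params$salt_bridge_max)
      if (!nrow(cand)) next
      out[[length(out) + 1L]] <- contact_rows(
        chain, lipid, pair$p[cand$i], pair$l[cand$j], "salt", cand$distance)
    }
  }
  if (!length(out)) return(empty_contacts())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the head/tail group of each contact from the lipid partitions
#'
#' @param records Contact records.
#' @param lipids List of `lipid_instance` objects (with partitions).
#' @return The records with `lipid_group` filled in (`"head"`/`"tail"`).
#' @export
classify_contacts <- function(records, lipids) {
  if (!nrow(records)) return(records)
  parts <- stats::setNames(lapply(lipids, function(l) l$partition),
                           vapply(lipids, function(l) l$instance_id, character(1)))
  records$lipid_group <- mapply(function(inst, atom) {
    p <- parts[[inst]]
    if (is.null(p)) stop("no partition for lipid instance ", inst)
    if (atom %in% p$tail_atoms) "tail"
    else if (atom %in% p$head_atoms) "head"
    else stop("lipid atom ", atom, " of ", inst, " is in neither group")
  }, records$lipid_instance, records$lipid_atom, USE.NAMES = FALSE)
  records
}

#' Detect and classify all residue-lipid contacts of a chain
#'
#' Runs hydrogen-bond, salt-bridge and van der Waals detection, removes
#' duplicate atom pairs with precedence hbond > salt > vdw, and labels
#' each contact head or tail.
#'
#' @inheritParams detect_vdw
#' @return Classified contact records.
#' @export
detect_contacts <- function(chain, lipids, params = geometry_params()) {
  if (is.null(chain$hydrogens)) {
    acc_xyz <- do.call(rbind, lapply(lipids, function(l)
      as.matrix(l$atoms[l$atoms$element == "O", c("x", "y", "z")])))
    chain <- place_polar_hydrogens(chain, acceptors = acc_xyz)
  }
  hb <- detect_hbonds(chain, lipids, params)
  sb <- detect_salt_bridges(chain, lipids, params)
  vw <- detect_vdw(chain, lipids, params, exclude = hb)
  all <- rbind(hb, sb, vw)
  if (nrow(all)) {
    key <- paste(all$resno, all$residue_atom, all$lipid_instance, all$lipid_atom)
    all <- all[!duplicated(key), , drop = FALSE]
    rownames(all) <- NULL
  }
  classify_contacts(all, lipids)
}

#' Per-residue head/tail binding flags
#'
#' A residue is head-bound when at least one of its contacts targets a
#' head-group atom, tail-bound when at least one targets a tail-group
#' atom; both flags can be set (classification is per contact, not per
#' residue).
#'
#' @param records Classified contact records.
#' @param chain The `protein_chain` the records belong to.
#' @return data.frame with columns `resno`, `resid`, `head_bound`,
#'   `tail_bound`, one row per chain residue.
#' @export
contact_summary <- function(records, chain) {
  res <- chain$residues
  hb <- res$resno %in% records$resno[records$lipid_group == "head"]
  tb <- res$resno %in% records$resno[records$lipid_group == "tail"]
  data.frame(resno = res$resno, resid = res$resid,
             head_bound = hb, tail_bound = tb, stringsAsFactors = FALSE)
}

#' Number of lipid-contacting residues in a contact table
#' @param records Contact records.
#' @return Integer count of distinct residues with any contact.
#' @export
n_contact_residues <- function(records) length(unique(records$resno))
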