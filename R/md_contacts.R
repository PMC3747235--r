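# Fractional lipid-binding counts from multi-frame trajectories. The
# binding count of residue k is the fraction of snapshots in which it
# contacts any lipid molecule,
#
#     N_k^b = sum_t I_k(t) / n_frames,
#
# a real number in [0, 1] that generalizes the binary crystal-structure
# flag; the per-type binding counts feeding the propensity score are the
# sums of these occupancies over residues of each type.
#
# Per-snapshot "contact" defaults to a heavy-atom distance criterion (any
# residue heavy atom within `cutoff` of any lipid heavy atom of the given
# group); the full crystal-style geometric criteria are available via
# criteria = "hbplus", at the cost of per-frame hydrogen placement.

#' Read a multi-model PDB trajectory
#'
#' The frames must share one topology (identical atom ordering). The
#' first model provides the topology: protein chains and registry lipid
#' instances are extracted as in [screen_structure()] but without the
#' crystal screening filters (trajectory frames carry no resolution).
#'
#' @param file Multi-model PDB file.
#' @param registry A [lipid_registry()].
#' @param structure_id Identifier; defaults to the file name.
#' @return Object of class `lipid_trajectory`: list with `chain` (first
#'   protein chain), `chains` (all of them), `lipids`, `xyz` (n_frames x
#'   3*n_atoms matrix, bio3d layout), `atom` (the topology atom table)
#'   and `n_frames`.
#' @export
read_trajectory <- function(file, registry, structure_id = NULL) {
  stopifnot(inherits(registry, "lipid_registry"))
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(file),
                        ignore.case = TRUE)
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  el <- atom$elesy
  bad <- is.na(el) | !nzchar(trimws(el))
  el[bad] <- guess_element(atom$elety[bad])
  atom$element <- toupper(trimws(el))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atom)) {
    stop("frame atom count does not match the topology")
  }

  reg_ids <- names(registry$entries)
  is_lipid <- atom$resid %in% reg_ids
  is_protein <- atom$resid %in% c(STANDARD_AA, "MSE") & !is_lipid

  chains <- list()
  for (cid in unique(atom$chain[is_protein])) {
    sel <- which(is_protein & atom$chain == cid)
    ca <- atom[sel, , drop = FALSE]
    ca$resid[ca$resid == "MSE"] <- "MET"
    ch <- new_protein_chain(structure_id, cid,
                            ca[, c("elety", "resid", "resno", "element",
                                   "x", "y", "z")])
    ch$atom_idx <- sel[order(ca$resno)]
    chains[[chain_key(ch)]] <- ch
  }
  if (!length(chains)) stop("no protein chain in trajectory topology")

  lipids <- list()
  lsel <- which(is_lipid)
  if (length(lsel)) {
    la <- atom[lsel, , drop = FALSE]
    key <- paste(la$resid, la$chain, la$resno, sep = "_")
    for (ik in unique(key)) {
      rows <- lsel[key == ik]
      li <- atom[rows, , drop = FALSE]
      het <- li$resid[1]
      entry <- registry_entry(registry, het)
      defn <- entry$definition
      if (is.null(defn)) {
        defn <- lipid_definition(het,
                                 atoms = data.frame(name = li$elety,
                                                    element = li$element,
                                                    stringsAsFactors = FALSE),
                                 bonds = bonds_from_distance(
                                   data.frame(name = li$elety,
                                              element = li$element,
                                              x = li$x, y = li$y, z = li$z)))
      }
      part <- partition_lipid(defn, tail_start = entry$tail_start)
      inst <- new_lipid_instance(het, ik,
                                 data.frame(elety = li$elety,
                                            element = li$element,
                                            x = li$x, y = li$y, z = li$z,
                                            stringsAsFactors = FALSE),
                                 part, defn$bonds)
      inst$atom_idx <- rows[order(li$elety)]
      lipids[[ik]] <- inst
    }
  }
  structure(list(chain = chains[[1]], chains = chains, lipids = lipids,
                 xyz = xyz, atom = atom, n_frames = nrow(xyz)),
            class = "lipid_trajectory")
}

#' @export
print.lipid_trajectory <- function(x, ...) {
  cat("<lipid_trajectory> ", x$n_frames, " frames, ",
      nrow(x$chain$residues), " residues, ", length(x$lipids),
      " lipid molecule(s)\n", sep = "")
  invisible(x)
}

frame_coords <- function(traj, idx, frame) {
  v <- traj$xyz[frame, ]
  cbind(v[3 * (idx - 1) + 1], v[3 * (idx - 1) + 2], v[3 * (idx - 1) + 3])
}

#' Per-frame binary contact indicators for one frame
#'
#' @param traj A `lipid_trajectory`.
#' @param frame Frame number (1-based).
#' @param cutoff Heavy-atom distance criterion in Angstrom (default 4.5).
#' @param criteria `"distance"` (default) or `"hbplus"` for the full
#'   crystal-style hydrogen-bond/vdW/salt criteria.
#' @param params [geometry_params()], used when `criteria = "hbplus"`.
#' @return data.frame `resno`, `resid`, `head`, `tail` (logical
#'   indicators for the chain's residues).
#' @export
frame_contacts <- function(traj, frame, cutoff = 4.5,
                           criteria = c("distance", "hbplus"),
                           params = geometry_params()) {
  criteria <- match.arg(criteria)
  ch <- traj$chain
  res <- ch$residues
  head_hit <- logical(nrow(res)); tail_hit <- logical(nrow(res))
  p_xyz <- frame_coords(traj, ch$atom_idx, frame)

  if (criteria == "distance") {
    for (lipid in traj$lipids) {
      l_xyz <- frame_coords(traj, lipid$atom_idx, frame)
      grp <- ifelse(lipid$atoms$elety %in% lipid$partition$tail_atoms,
                    "tail", "head")
      cand <- neighbor_pairs(p_xyz, l_xyz, cutoff)
      if (!nrow(cand)) next
      rn <- ch$atoms$resno[cand$i]
      hit_head <- unique(rn[grp[cand$j] == "head"])
      hit_tail <- unique(rn[grp[cand$j] == "tail"])
      head_hit <- head_hit | res$resno %in% hit_head
      tail_hit <- tail_hit | res$resno %in% hit_tail
    }
  } else {
    fch <- ch
    fch$atoms[, c("x", "y", "z")] <- p_xyz
    fch$hydrogens <- NULL
    flip <- lapply(traj$lipids, function(l) {
      l$atoms[, c("x", "y", "z")] <- frame_coords(traj, l$atom_idx, frame)
      l
    })
    rec <- detect_contacts(fch, flip, params)
    head_hit <- res$resno %in% rec$resno[rec$lipid_group == "head"]
    tail_hit <- res$resno %in% rec$resno[rec$lipid_group == "tail"]
  }
  data.frame(resno = res$resno, resid = res$resid,
             head = head_hit, tail = tail_hit, stringsAsFactors = FALSE)
}

#' Occupancy fractions from per-frame indicators
#'
#' @param indicators Logical or 0/1 matrix, frames in rows, residues in
#'   columns.
#' @return Numeric vector of per-residue occupancies (column means),
#'   exactly `(number of contact frames) / n_frames`.
#' @export
#' @examples
#' m <- matrix(c(rep(1, 300), rep(0, 700)), ncol = 1)
#' occupancy(m)   # 0.3
occupancy <- function(indicators) {
  m <- as.matrix(indicators)
  stopifnot(nrow(m) >= 1L)
  colMeans(m)
}

#' Residue occupancies over a whole trajectory
#'
#' Runs [frame_contacts()] on every frame and averages the indicators.
#'
#' @inheritParams frame_contacts
#' @param mask Optional integer vector of residue numbers to exclude from
#'   the table (e.g. a large extra-membranous domain).
#' @return data.frame `resno`, `resid`, `head_occupancy`,
#'   `tail_occupancy` with attribute `n_frames`.
#' @export
trajectory_occupancy <- function(traj, cutoff = 4.5,
                                 criteria = c("distance", "hbplus"),
                                 params = geometry_params(), mask = NULL) {
  criteria <- match.arg(criteria)
  res <- traj$chain$residues
  head_m <- matrix(0, traj$n_frames, nrow(res))
  tail_m <- matrix(0, traj$n_frames, nrow(res))
  for (t in seq_len(traj$n_frames)) {
    ind <- frame_contacts(traj, t, cutoff = cutoff, criteria = criteria,
                          params = params)
    head_m[t, ] <- ind$head
    tail_m[t, ] <- ind$tail
  }
  out <- data.frame(resno = res$resno, resid = res$resid,
                    head_occupancy = occupancy(head_m),
                    tail_occupancy = occupancy(tail_m),
                    stringsAsFactors = FALSE)
  if (!is.null(mask)) out <- out[!(out$resno %in% mask), , drop = FALSE]
  attr(out, "n_frames") <- traj$n_frames
  out
}

#' Fractional contact counts of a trajectory, ready for the propensity score
#'
#' Sums the per-residue occupancies into per-type binding counts; with
#' all occupancies 0 or 1 this reduces exactly to the crystal-structure
#' computation.
#'
#' @param traj A `lipid_trajectory`.
#' @param occ Occupancy table from [trajectory_occupancy()]; computed
#'   when omitted.
#' @param contact_class `"head"` or `"tail"`.
#' @param ... Passed on to [trajectory_occupancy()].
#' @return A [chain_contact_counts()] table with fractional `n_bound`.
#' @export
md_contact_counts <- function(traj, occ = NULL,
                              contact_class = c("head", "tail"), ...) {
  contact_class <- match.arg(contact_class)
  if (is.null(occ)) occ <- trajectory_occupancy(traj, ...)
  ch <- traj$chain
  ch$residues <- ch$residues[ch$residues$resno %in% occ$resno, , drop = FALSE]
  chain_contact_counts(ch, occ, contact_class)
}
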