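# Reading PDB-format structures, screening filters, and extraction of
# protein chains and registry lipids. Parsing is delegated to bio3d; this
# module adds the dataset-construction rules: resolution cutoff, minimum
# chain length, standard-residue composition (MSE read as MET), altloc
# selection, and cluster-representative picking.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Parse the crystallographic resolution from a PDB file
#'
#' Reads the `REMARK   2 RESOLUTION.` record. Entries without a numeric
#' resolution (NMR and other methods) yield `NA`.
#'
#' @param file Path to a PDB-format file.
#' @return Resolution in Angstrom, or `NA_real_`.
#' @export
parse_resolution <- function(file) {
  lines <- readLines(file, warn = FALSE)
  rem <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (!length(rem)) return(NA_real_)
  m <- regmatches(rem[1], regexpr("[0-9]+\\.[0-9]+", rem[1]))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

guess_element <- function(elety) {
  # First alphabetic character of the atom name, with two-letter symbols
  # for the elements that occur in proteins/phospholipids.
  e <- toupper(gsub("[^A-Za-z].*$|^[0-9]+", "", elety))
  e <- substr(gsub("^[0-9]*", "", e), 1, 2)
  one <- substr(e, 1, 1)
  ifelse(e %in% c("SE", "CL", "BR", "NA", "MG", "ZN", "FE"), e, one)
}

# Highest-occupancy altloc conformer; ties resolved toward altloc 'A'
# (then alphabetically).
select_altloc <- function(atom) {
  if (!"alt" %in% names(atom)) return(atom)
  alt <- atom$alt
  if (all(is.na(alt))) return(atom)
  occ <- if ("o" %in% names(atom)) ifelse(is.na(atom$o), 1, atom$o) else rep(1, nrow(atom))
  key <- paste(atom$chain, atom$resno, atom$resid, atom$elety, sep = "|")
  alt_rank <- ifelse(is.na(alt), "", alt)
  ord <- order(key, -occ, alt_rank)
  keep <- ord[!duplicated(key[ord])]
  atom[sort(keep), , drop = FALSE]
}

new_protein_chain <- function(structure_id, chain_id, atoms, resolution = NA_real_,
                              tm_label = "unknown", cluster_id = NA_character_) {
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  res <- unique(atoms[, c("resno", "resid")])
  rownames(res) <- NULL
  structure(list(structure_id = structure_id, chain_id = chain_id,
                 atoms = atoms, residues = res, resolution = resolution,
                 tm_label = tm_label, cluster_id = cluster_id),
            class = "protein_chain")
}

#' @export
print.protein_chain <- function(x, ...) {
  cat("<protein_chain> ", chain_key(x), ": ", nrow(x$residues),
      " residues, resolution ",
      ifelse(is.na(x$resolution), "NA", format(x$resolution)), " A, ",
      x$tm_label, "\n", sep = "")
  invisible(x)
}

#' Unique key for a chain (structure id + chain id)
#' @param chain A `protein_chain`.
#' @return Character scalar `"<structure_id>_<chain_id>"`.
#' @export
chain_key <- function(chain) paste(chain$structure_id, chain$chain_id, sep = "_")

new_lipid_instance <- function(het_id, instance_id, atoms, partition, bonds) {
  atoms <- atoms[order(atoms$elety), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(het_id = het_id, instance_id = instance_id, atoms = atoms,
                 partition = partition, bonds = bonds),
            class = "lipid_instance")
}

#' @export
print.lipid_instance <- function(x, ...) {
  cat("<lipid_instance> ", x$instance_id, " (", x$het_id, "): ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Read chain annotations (cluster ids and TM labels) from a sidecar TSV
#'
#' Sequence clustering and membrane-topology annotation are inputs, not
#' computations, of this package; the sidecar file carries them. Columns:
#' `structure_id`, `chain_id`, `cluster_id`, `tm_label`.
#'
#' @param file Path to the TSV.
#' @return data.frame with the four columns.
#' @export
read_chain_annotations <- function(file) {
  tab <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("structure_id", "chain_id", "cluster_id", "tm_label")
  if (!all(need %in% names(tab))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  tab[, need]
}

#' Read a PDB structure and apply the dataset screening filters
#'
#' Retains X-ray structures solved at `max_resolution` or better (entries
#' without a resolution record, e.g. NMR, are rejected), drops protein
#' chains shorter than `min_length` residues or containing non-standard
#' residues (selenomethionine is read as MET), and extracts every lipid
#' molecule whose HET ID is in the registry. Chains with no lipid contacts
#' are *not* dropped here; that filter needs the contact engine and is
#' applied downstream.
#'
#' @param file PDB-format file.
#' @param registry A [lipid_registry()].
#' @param max_resolution Resolution cutoff in Angstrom (default 4.0).
#' @param min_length Minimum chain length in residues (default 30).
#' @param annotations Optional annotation data.frame from
#'   [read_chain_annotations()].
#' @param structure_id Identifier for the structure; defaults to the file
#'   name without extension.
#' @return List with elements `chains` (list of `protein_chain`) and
#'   `lipids` (list of `lipid_instance`). Both empty when the structure
#'   itself is rejected.
#' @export
screen_structure <- function(file, registry, max_resolution = 4.0,
                             min_length = 30L, annotations = NULL,
                             structure_id = NULL) {
  stopifnot(inherits(registry, "lipid_registry"))
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(file),
                        ignore.case = TRUE)
  }
  resolution <- parse_resolution(file)
  if (is.na(resolution) || resolution > max_resolution) {
    return(list(chains = list(), lipids = list()))
  }
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)
  atom <- select_altloc(pdb$atom)
  el <- atom$elesy
  bad <- is.na(el) | !nzchar(trimws(el))
  el[bad] <- guess_element(atom$elety[bad])
  atom$element <- toupper(trimws(el))
  atom <- atom[atom$element != "H", , drop = FALSE]

  reg_ids <- names(registry$entries)
  is_lipid <- atom$resid %in% reg_ids
  is_protein <- atom$resid %in% c(STANDARD_AA, "MSE") & !is_lipid

  chains <- list()
  prot <- atom[is_protein, , drop = FALSE]
  for (cid in unique(prot$chain)) {
    ca <- prot[prot$chain == cid, , drop = FALSE]
    # Any non-standard residue (other than MSE) in this chain's polymer?
    # Polymer records: ATOM-typed residues plus HETATM selenomethionine;
    # registry lipids and waters on the same chain are not polymer.
    polym <- atom$chain == cid & !is_lipid & atom$resid != "HOH" &
      (atom$type == "ATOM" | atom$resid == "MSE")
    nonstd <- setdiff(unique(atom$resid[polym]), c(STANDARD_AA, "MSE"))
    if (length(nonstd)) next
    # Selenomethionine is treated as MET.
    mse <- ca$resid == "MSE"
    ca$resid[mse] <- "MET"
    ca$elety[mse & ca$elety == "SE"] <- "SD"
    ca$element[mse & ca$element == "SE"] <- "S"
    ch <- new_protein_chain(structure_id, cid,
                            ca[, c("elety", "resid", "resno", "element",
                                   "x", "y", "z")],
                            resolution = resolution)
    if (nrow(ch$residues) < min_length) next
    chains[[chain_key(ch)]] <- ch
  }

  if (!is.null(annotations) && length(chains)) {
    for (k in seq_along(chains)) {
      hit <- annotations$structure_id == chains[[k]]$structure_id &
        annotations$chain_id == chains[[k]]$chain_id
      if (any(hit)) {
        chains[[k]]$cluster_id <- annotations$cluster_id[which(hit)[1]]
        chains[[k]]$tm_label <- annotations$tm_label[which(hit)[1]]
      }
    }
  }

  lipids <- list()
  lip <- atom[is_lipid, , drop = FALSE]
  if (nrow(lip)) {
    key <- paste(lip$resid, lip$chain, lip$resno, sep = "_")
    for (ik in unique(key)) {
      la <- lip[key == ik, , drop = FALSE]
      het <- la$resid[1]
      entry <- registry_entry(registry, het)
      la_atoms <- data.frame(name = la$elety, element = la$element,
                             x = la$x, y = la$y, z = la$z,
                             stringsAsFactors = FALSE)
      defn <- entry$definition
      if (is.null(defn)) {
        defn <- lipid_definition(het,
                                 atoms = la_atoms[, c("name", "element")],
                                 bonds = bonds_from_distance(la_atoms))
      }
      part <- partition_lipid(defn, tail_start = entry$tail_start)
      inst <- new_lipid_instance(het, ik,
                                 data.frame(elety = la$elety,
                                            element = la$element,
                                            x = la$x, y = la$y, z = la$z,
                                            stringsAsFactors = FALSE),
                                 part, defn$bonds)
      lipids[[ik]] <- inst
    }
  }
  list(chains = chains, lipids = lipids)
}

#' Re-apply the chain screening filters to a chain list
#'
#' Screening is idempotent: chains that already pass are returned
#' unchanged.
#'
#' @param chains List of `protein_chain` objects.
#' @param max_resolution,min_length As in [screen_structure()].
#' @return Filtered list.
#' @export
screen_chains <- function(chains, max_resolution = 4.0, min_length = 30L) {
  keep <- vapply(chains, function(ch) {
    !is.na(ch$resolution) && ch$resolution <= max_resolution &&
      nrow(ch$residues) >= min_length &&
      all(ch$residues$resid %in% STANDARD_AA)
  }, logical(1))
  chains[keep]
}

#' Select one representative chain per sequence cluster
#'
#' Within each cluster the chain with the most lipid-contacting residues
#' is chosen. Clusters in which every member has fewer than
#' `min_contact_residues` lipid-contacting residues are discarded
#' entirely. Ties are broken lexicographically on (structure_id,
#' chain_id) for determinism.
#'
#' @param chains List of `protein_chain` objects; each must have a
#'   `cluster_id`.
#' @param contact_counts Named numeric vector of lipid-contacting residue
#'   counts, names being [chain_key()]s.
#' @param min_contact_residues Cluster-retention threshold (default 5):
#'   a cluster survives iff at least one member has at least this many
#'   contacting residues.
#' @return List of representative chains (one per surviving cluster).
#' @export
select_representatives <- function(chains, contact_counts,
                                   min_contact_residues = 5L) {
  keys <- vapply(chains, chain_key, character(1))
  missing_cl <- vapply(chains, function(ch) is.na(ch$cluster_id), logical(1))
  if (any(missing_cl)) {
    stop("chains without cluster_id: ",
         paste(keys[missing_cl], collapse = ", "))
  }
  if (!all(keys %in% names(contact_counts))) {
    stop("contact_counts missing entries for: ",
         paste(setdiff(keys, names(contact_counts)), collapse = ", "))
  }
  cnt <- contact_counts[keys]
  cl <- vapply(chains, function(ch) ch$cluster_id, character(1))
  reps <- list()
  for (cluster in sort(unique(cl))) {
    idx <- which(cl == cluster)
    if (max(cnt[idx]) < min_contact_residues) next  # "less than five" -> drop
    best <- idx[cnt[idx] == max(cnt[idx])]
    if (length(best) > 1L) {
      ids <- vapply(chains[best], function(ch)
        paste(ch$structure_id, ch$chain_id), character(1))
      best <- best[order(ids)][1]
    }
    reps[[length(reps) + 1L]] <- chains[[best]]
  }
  reps
}
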