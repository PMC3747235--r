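#' Phospholipid HET-ID registry
#'
#' The registry holds the set of PDB chemical-component identifiers (HET
#' IDs) that are treated as phospholipids, together with optional
#' per-lipid metadata: an explicit tail-start override for mimetic lipids
#' that lack an acyl carbonyl (ether-linked or phosphonate analogues,
#' where the first tail carbon cannot be located mechanically) and,
#' optionally, a full molecular definition (atoms and bonds).
#'
#' The default registry ships with 98 curated phosphoglyceride HET IDs and
#' no overrides. Registry files are tab-separated with columns `HET_ID`,
#' `TAIL_START_ATOMS` (comma-separated atom names, may be empty) and
#' `NOTES`.
#'
#' @param file Path to a registry TSV. `NULL` (default) loads the bundled
#'   registry.
#' @return An object of class `lipid_registry`: a list with one entry per
#'   HET ID, each a list with elements `het_id`, `tail_start` (character
#'   vector, possibly empty) and `definition` (a [lipid_definition()] or
#'   `NULL`).
#' @seealso [registry_add()], [partition_lipid()]
#' @export
#' @examples
#' reg <- lipid_registry()
#' length(reg$entries)     # 98 bundled phospholipid HET IDs
#' "CDL" %in% names(reg$entries)
lipid_registry <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "lipid_registry.tsv", package = "lipropen")
  }
  tab <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("HET_ID", "TAIL_START_ATOMS") %in% names(tab))) {
    stop("registry file must have columns HET_ID and TAIL_START_ATOMS")
  }
  ids <- toupper(trimws(tab$HET_ID))
  if (anyDuplicated(ids)) stop("duplicate HET IDs in registry file")
  if (any(nchar(ids) < 1L | nchar(ids) > 3L)) {
    stop("HET IDs must be 1-3 characters")
  }
  entries <- lapply(seq_along(ids), function(k) {
    ts <- trimws(strsplit(tab$TAIL_START_ATOMS[k], ",", fixed = TRUE)[[1]])
    ts <- ts[nzchar(ts)]
    list(het_id = ids[k], tail_start = ts, definition = NULL)
  })
  names(entries) <- ids
  structure(list(entries = entries), class = "lipid_registry")
}

#' @export
print.lipid_registry <- function(x, ...) {
  n_def <- sum(vapply(x$entries, function(e) !is.null(e$definition), logical(1)))
  cat("<lipid_registry> ", length(x$entries), " HET IDs (",
      n_def, " with bond graphs)\n", sep = "")
  invisible(x)
}

#' Add or replace a registry entry
#'
#' @param registry A [lipid_registry()].
#' @param het_id 1-3 character HET ID (upper-cased).
#' @param definition Optional [lipid_definition()] carrying the atom list
#'   and bond graph.
#' @param tail_start Optional character vector of tail-start atom names
#'   (override for lipids without an ester carbonyl).
#' @return The updated registry.
#' @export
registry_add <- function(registry, het_id, definition = NULL, tail_start = character()) {
  stopifnot(inherits(registry, "lipid_registry"))
  het_id <- toupper(het_id)
  if (nchar(het_id) < 1L || nchar(het_id) > 3L) stop("HET ID must be 1-3 characters")
  if (!is.null(definition) && !identical(definition$het_id, het_id)) {
    stop("definition het_id does not match")
  }
  registry$entries[[het_id]] <- list(het_id = het_id, tail_start = tail_start,
                                     definition = definition)
  registry
}

registry_entry <- function(registry, het_id) {
  e <- registry$entries[[toupper(het_id)]]
  if (is.null(e)) {
    stop("HET ID '", het_id, "' is not in the lipid registry", call. = FALSE)
  }
  e
}

#' Molecular definition of one lipid component
#'
#' Atom names, elements and the covalent bond graph of a lipid chemical
#' component, as needed for the head/tail partition. Bonds can come from
#' a chemical-component dictionary ([read_ccd_bonds()]) or be inferred
#' from coordinates ([bonds_from_distance()]).
#'
#' @param het_id HET ID (1-3 characters).
#' @param atoms data.frame with columns `name`, `element`.
#' @param bonds data.frame with columns `a1`, `a2` (atom names).
#' @return Object of class `lipid_definition`.
#' @export
lipid_definition <- function(het_id, atoms, bonds) {
  het_id <- toupper(het_id)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "element") %in% names(atoms)),
            all(c("a1", "a2") %in% names(bonds)))
  if (anyDuplicated(atoms$name)) stop("duplicate atom names in lipid definition")
  unknown <- setdiff(c(bonds$a1, bonds$a2), atoms$name)
  if (length(unknown)) {
    stop("bond endpoints name atoms not in the atom list: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(het_id = het_id, atoms = atoms, bonds = bonds),
            class = "lipid_definition")
}

#' Infer a bond graph from interatomic distances
#'
#' Deposited lipids frequently lack CONECT records; heavy-atom pairs
#' closer than `dmax` are taken as covalently bonded.
#'
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`.
#' @param dmax Bond distance cutoff in Angstrom (default 1.9).
#' @return data.frame with columns `a1`, `a2`.
#' @export
bonds_from_distance <- function(atoms, dmax = 1.9) {
  heavy <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  if (nrow(xyz) < 2L) return(data.frame(a1 = character(), a2 = character()))
  d <- pair_distances(xyz, xyz)
  hit <- which(d <= dmax & upper.tri(d), arr.ind = TRUE)
  data.frame(a1 = heavy$name[hit[, 1]], a2 = heavy$name[hit[, 2]],
             stringsAsFactors = FALSE)
}

#' Read bonds for one component from a chemical-component dictionary
#'
#' Minimal reader for the `_chem_comp_atom` / `_chem_comp_bond` loops of
#' an mmCIF chemical-component file, returning a [lipid_definition()].
#'
#' @param file Path to a chemical-component mmCIF file.
#' @param het_id Component ID to extract.
#' @return A [lipid_definition()].
#' @export
read_ccd_bonds <- function(file, het_id) {
  het_id <- toupper(het_id)
  lines <- readLines(file, warn = FALSE)
  parse_loop <- function(prefix) {
    starts <- grep("^loop_", lines)
    for (s in starts) {
      k <- s + 1L
      cols <- character()
      while (k <= length(lines) && startsWith(trimws(lines[k]), prefix)) {
        cols <- c(cols, sub(paste0("^", prefix, "\\."), "", trimws(lines[k])))
        k <- k + 1L
      }
      if (!length(cols)) next
      rows <- list()
      while (k <= length(lines)) {
        ln <- trimws(lines[k])
        if (!nzchar(ln) || startsWith(ln, "loop_") || startsWith(ln, "_") ||
            startsWith(ln, "#")) break
        fields <- scan(text = ln, what = character(), quiet = TRUE)
        if (length(fields) == length(cols)) rows[[length(rows) + 1L]] <- fields
        k <- k + 1L
      }
      if (length(rows)) {
        m <- do.call(rbind, rows)
        colnames(m) <- cols
        return(as.data.frame(m, stringsAsFactors = FALSE))
      }
    }
    NULL
  }
  at <- parse_loop("_chem_comp_atom")
  bd <- parse_loop("_chem_comp_bond")
  if (is.null(at) || is.null(bd)) {
    stop("no _chem_comp_atom/_chem_comp_bond loops found in ", file)
  }
  at <- at[toupper(at$comp_id) == het_id, , drop = FALSE]
  bd <- bd[toupper(bd$comp_id) == het_id, , drop = FALSE]
  if (!nrow(at)) stop("component ", het_id, " not found in ", file)
  strip <- function(x) gsub('"', "", x, fixed = TRUE)
  lipid_definition(
    het_id,
    atoms = data.frame(name = strip(at$atom_id),
                       element = toupper(at$type_symbol),
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = strip(bd$atom_id_1), a2 = strip(bd$atom_id_2),
                       stringsAsFactors = FALSE)
  )
}

# Adjacency list over heavy atoms of a definition.
lipid_adjacency <- function(defn) {
  heavy <- defn$atoms$name[toupper(defn$atoms$element) != "H"]
  adj <- stats::setNames(vector("list", length(heavy)), heavy)
  for (k in seq_len(nrow(defn$bonds))) {
    a <- defn$bonds$a1[k]; b <- defn$bonds$a2[k]
    if (a %in% heavy && b %in% heavy) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, unique)
}

graph_components <- function(adj) {
  seen <- character()
  comps <- list()
  for (start in names(adj)) {
    if (start %in% seen) next
    comp <- character(); queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# Ester carbonyl carbons: C bonded to exactly one terminal O (the carbonyl
# oxygen), exactly one bridging O (the ester oxygen, which has a further
# carbon neighbor), and at least one C (the first acyl carbon). A free
# carboxylate (two terminal oxygens, as in a serine head group) does not
# match.
find_carbonyl_carbons <- function(defn, adj) {
  el <- stats::setNames(toupper(defn$atoms$element), defn$atoms$name)
  is_c <- function(a) el[[a]] == "C"
  is_o <- function(a) el[[a]] == "O"
  out <- character()
  for (a in names(adj)) {
    if (!is_c(a)) next
    nb <- adj[[a]]
    o_nb <- nb[vapply(nb, is_o, logical(1))]
    c_nb <- nb[vapply(nb, is_c, logical(1))]
    if (length(o_nb) != 2L || length(c_nb) < 1L) next
    term <- vapply(o_nb, function(o) length(adj[[o]]) == 1L, logical(1))
    bridge <- vapply(o_nb, function(o) {
      others <- setdiff(adj[[o]], a)
      any(vapply(others, is_c, logical(1)))
    }, logical(1))
    if (sum(term) == 1L && sum(bridge & !term) == 1L) out <- c(out, a)
  }
  out
}

#' Partition a lipid's heavy atoms into head and tail groups
#'
#' The hydrophobic tail group consists of the aliphatic acyl-chain atoms,
#' starting at the carbon bonded to the ester carbonyl carbon (acyl C2)
#' and running to the terminal methyl; the carbonyl carbon itself, both
#' ester oxygens, glycerol, phosphate and the polar substituent remain in
#' the hydrophilic head group. Tail atoms are found by traversing
#' carbon-carbon bonds from each tail-start atom, never crossing a
#' carbonyl carbon or a heteroatom. For mimetic lipids without a carbonyl
#' (e.g. ether-linked), the tail-start carbons must be supplied via
#' `tail_start` (normally the registry override), since "the corresponding
#' carbon" cannot be located mechanically.
#'
#' @param defn A [lipid_definition()] with a connected heavy-atom bond
#'   graph.
#' @param tail_start Optional character vector of tail-start atom names;
#'   when empty, tail starts are derived from the ester groups.
#' @return Object of class `lipid_partition` with elements `het_id`,
#'   `head_atoms`, `tail_atoms` (disjoint; union = all heavy atoms).
#'   Hydrogens, when present in the definition, follow their parent heavy
#'   atom and are not listed.
#' @export
#' @examples
#' defn <- lipid_definition("ZZL",
#'   atoms = data.frame(name = c("P1", "O1", "O2", "C1", "C2"),
#'                      element = c("P", "O", "O", "C", "C")),
#'   bonds = data.frame(a1 = c("P1", "P1", "O2", "C1"),
#'                      a2 = c("O1", "O2", "C1", "C2")))
#' partition_lipid(defn, tail_start = "C1")
partition_lipid <- function(defn, tail_start = character()) {
  stopifnot(inherits(defn, "lipid_definition"))
  adj <- lipid_adjacency(defn)
  if (length(adj) == 0L) stop("lipid has no heavy atoms")
  comps <- graph_components(adj)
  if (length(comps) > 1L) {
    stop("malformed lipid '", defn$het_id,
         "': bond graph is disconnected (", length(comps), " components)")
  }
  el <- stats::setNames(toupper(defn$atoms$element), defn$atoms$name)

  carbonyls <- character()
  if (length(tail_start) == 0L) {
    carbonyls <- find_carbonyl_carbons(defn, adj)
    if (length(carbonyls) == 0L) {
      stop("lipid '", defn$het_id, "' has no ester carbonyl and no ",
           "tail-start override; register TAIL_START_ATOMS for mimetic lipids")
    }
    tail_start <- unique(unlist(lapply(carbonyls, function(cc) {
      nb <- adj[[cc]]
      nb[el[nb] == "C"]
    })))
  } else {
    missing <- setdiff(tail_start, names(adj))
    if (length(missing)) {
      stop("tail-start atoms not in lipid '", defn$het_id, "': ",
           paste(missing, collapse = ", "))
    }
    if (any(el[tail_start] != "C")) stop("tail-start atoms must be carbons")
  }

  # Traverse carbon-carbon bonds only, blocking carbonyl carbons.
  blocked <- carbonyls
  tail <- character()
  queue <- setdiff(tail_start, blocked)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% tail) next
    tail <- c(tail, v)
    nxt <- adj[[v]]
    nxt <- nxt[el[nxt] == "C" & !(nxt %in% blocked) & !(nxt %in% tail)]
    queue <- c(queue, nxt)
  }
  head <- setdiff(names(adj), tail)
  p_atoms <- names(adj)[el[names(adj)] == "P"]
  if (any(p_atoms %in% tail)) {
    stop("internal error: phosphorus assigned to the tail group")
  }
  structure(list(het_id = defn$het_id,
                 head_atoms = sort(head), tail_atoms = sort(tail)),
            class = "lipid_partition")
}

#' @export
print.lipid_partition <- function(x, ...) {
  cat("<lipid_partition> ", x$het_id, ": ", length(x$head_atoms),
      " head / ", length(x$tail_atoms), " tail atoms\n", sep = "")
  invisible(x)
}
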