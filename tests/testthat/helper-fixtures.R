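# Shared fixtures, built in code.

# A two-chain phosphatidylcholine-like lipid graph: glycerol + phosphate
# + choline head, two fatty-acid esters with n1/n2 carbons (carbonyl
# carbon counted as acyl C1, so the tail holds n - 1 carbons per chain).
pc_lipid <- function(n1 = 16, n2 = 18, het = "PCX") {
  atoms <- data.frame(name = character(), element = character())
  bonds <- data.frame(a1 = character(), a2 = character())
  add_atom <- function(name, element) {
    atoms <<- rbind(atoms, data.frame(name = name, element = element))
  }
  add_bond <- function(a, b) {
    bonds <<- rbind(bonds, data.frame(a1 = a, a2 = b))
  }
  # glycerol
  for (nm in c("C1G", "C2G", "C3G")) add_atom(nm, "C")
  add_bond("C1G", "C2G"); add_bond("C2G", "C3G")
  # phosphate bridge to choline
  add_atom("O3G", "O"); add_bond("C3G", "O3G")
  add_atom("P", "P"); add_bond("O3G", "P")
  add_atom("O1P", "O"); add_bond("P", "O1P")
  add_atom("O2P", "O"); add_bond("P", "O2P")
  add_atom("O4P", "O"); add_bond("P", "O4P")
  add_atom("C1C", "C"); add_bond("O4P", "C1C")
  add_atom("C2C", "C"); add_bond("C1C", "C2C")
  add_atom("NC", "N"); add_bond("C2C", "NC")
  for (nm in c("CM1", "CM2", "CM3")) { add_atom(nm, "C"); add_bond("NC", nm) }
  # two fatty-acid esters
  ester <- function(gly_c, tag, n_carbons) {
    oe <- paste0("OE", tag); cc <- paste0("CC", tag); oc <- paste0("OC", tag)
    add_atom(oe, "O"); add_bond(gly_c, oe)
    add_atom(cc, "C"); add_bond(oe, cc)       # carbonyl carbon
    add_atom(oc, "O"); add_bond(cc, oc)       # carbonyl oxygen (terminal)
    prev <- cc
    for (k in seq_len(n_carbons - 1)) {       # acyl C2 .. terminal methyl
      t <- sprintf("T%s_%d", tag, k)
      add_atom(t, "C"); add_bond(prev, t)
      prev <- t
    }
  }
  ester("C1G", "1", n1)
  ester("C2G", "2", n2)
  lipid_definition(het, atoms, bonds)
}

# Independent partition oracle: walk from each terminal methyl over C-C
# bonds, stopping at the carbonyl carbons (named CC<tag> in pc_lipid).
pc_tail_oracle <- function(defn) {
  el <- setNames(defn$atoms$element, defn$atoms$name)
  adj <- list()
  for (k in seq_len(nrow(defn$bonds))) {
    a <- defn$bonds$a1[k]; b <- defn$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  carbonyls <- grep("^CC", defn$atoms$name, value = TRUE)
  terminal_methyls <- names(adj)[vapply(names(adj), function(a) {
    el[[a]] == "C" && length(adj[[a]]) == 1L && grepl("^T", a)
  }, logical(1))]
  tail <- character()
  for (tm in terminal_methyls) {
    queue <- tm
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% tail || v %in% carbonyls || el[[v]] != "C") next
      tail <- c(tail, v)
      queue <- c(queue, setdiff(adj[[v]], tail))
    }
  }
  sort(tail)
}

# Minimal hand-built protein chain from a list of residues, each
# list(resid, resno, atoms = data.frame(elety, element, x, y, z)).
mini_chain <- function(residues, structure_id = "test") {
  atoms <- do.call(rbind, lapply(residues, function(r) {
    data.frame(elety = r$atoms$elety, resid = r$resid, resno = r$resno,
               element = r$atoms$element,
               x = r$atoms$x, y = r$atoms$y, z = r$atoms$z,
               stringsAsFactors = FALSE)
  }))
  lipropen:::new_protein_chain(structure_id, "A", atoms, resolution = 2.0)
}

# One ZZL lipid instance with its C1 (tail) or O1 (head) atom at `pos`,
# remaining atoms trailing along `dir`.
mini_zzl <- function(pos, dir = c(1, 0, 0), mode = "tail", id = "ZZL_L_1") {
  co <- lipropen:::zzl_coords(pos, dir / sqrt(sum(dir^2)), mode)
  lipropen:::zzl_instance(id, co)
}

# Brute-force all-pairs neighbor oracle.
brute_pairs <- function(a, b, cutoff) {
  out <- data.frame(i = integer(), j = integer(), distance = numeric())
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d <= cutoff) out <- rbind(out, data.frame(i = i, j = j, distance = d))
  }
  out
}

angle_at <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}
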