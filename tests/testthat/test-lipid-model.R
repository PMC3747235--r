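test_that("default registry holds 98 unique uppercase HET IDs and is extensible", {
  reg <- lipid_registry()
  ids <- names(reg$entries)
  expect_length(ids, 98)
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(ids == toupper(ids)))
  expect_true(all(nchar(ids) >= 1 & nchar(ids) <= 3))
  expect_true(all(c("CDL", "POV", "LPC", "XPX") %in% ids))

  reg2 <- registry_add(reg, "zzl", definition = zzl_definition(),
                       tail_start = "C1")
  expect_length(reg2$entries, 99)
  expect_identical(reg2$entries$ZZL$tail_start, "C1")
})

test_that("partition of a two-chain phosphoglyceride matches the walk-from-methyl oracle", {
  defn <- pc_lipid(16, 18)
  part <- partition_lipid(defn)

  # 16:0 chain contributes 15 tail carbons, 18:1 chain 17
  expect_length(part$tail_atoms, 15 + 17)
  expect_identical(part$tail_atoms, pc_tail_oracle(defn))

  # phosphate is head; acyl C2 (first carbon after the carbonyl) is tail;
  # the carbonyl carbon and both ester oxygens are head
  expect_true("P" %in% part$head_atoms)
  expect_true(all(c("T1_1", "T2_1") %in% part$tail_atoms))
  expect_true(all(c("CC1", "OC1", "OE1", "CC2", "OC2", "OE2") %in% part$head_atoms))

  # exhaustive and exclusive over heavy atoms
  heavy <- defn$atoms$name[defn$atoms$element != "H"]
  expect_setequal(c(part$head_atoms, part$tail_atoms), heavy)
  expect_length(intersect(part$head_atoms, part$tail_atoms), 0)
})

test_that("partition is invariant under atom and bond order permutation", {
  defn <- pc_lipid(12, 14)
  base <- partition_lipid(defn)
  set.seed(11)
  for (k in 1:5) {
    shuffled <- lipid_definition(
      defn$het_id,
      atoms = defn$atoms[sample(nrow(defn$atoms)), ],
      bonds = defn$bonds[sample(nrow(defn$bonds)), ]
    )
    p <- partition_lipid(shuffled)
    expect_identical(p$head_atoms, base$head_atoms)
    expect_identical(p$tail_atoms, base$tail_atoms)
  }
})

test_that("tail set splits into one connected run per acyl chain, each with one terminal methyl", {
  for (spec in list(c(10, 12), c(16, 18), c(8, 8))) {
    defn <- pc_lipid(spec[1], spec[2])
    part <- partition_lipid(defn)
    tail <- part$tail_atoms
    adj <- lipropen:::lipid_adjacency(defn)
    tadj <- lapply(adj[tail], function(nb) intersect(nb, tail))
    comps <- lipropen:::graph_components(tadj)
    expect_length(comps, 2)
    expect_setequal(vapply(comps, length, integer(1)), spec - 1L)
    for (comp in comps) {
      # a linear run has exactly two degree-1 atoms: the acyl C2 end
      # (its bond to the head-side carbonyl is severed) and the terminal
      # methyl
      n_end <- sum(vapply(comp, function(a) length(tadj[[a]]) == 1L,
                          logical(1)))
      expect_equal(n_end, 2)
    }
  }
})

test_that("mimetic lipids use the tail-start override", {
  part <- partition_lipid(zzl_definition(), tail_start = "C1")
  expect_setequal(part$tail_atoms, paste0("C", 1:8))
  expect_setequal(part$head_atoms, c("P1", "O1", "O2"))
})

test_that("partition errors are informative", {
  reg <- lipid_registry()
  expect_error(lipropen:::registry_entry(reg, "QQQ"), "not in the lipid registry")

  # no carbonyl and no override
  expect_error(partition_lipid(zzl_definition()), "tail-start")

  # disconnected bond graph
  atoms <- data.frame(name = c("C1", "C2", "C3", "C4"),
                      element = rep("C", 4))
  bonds <- data.frame(a1 = c("C1", "C3"), a2 = c("C2", "C4"))
  defn <- lipid_definition("BAD", atoms, bonds)
  expect_error(partition_lipid(defn, tail_start = "C1"), "disconnected")

  # bond endpoint not in atom list
  expect_error(lipid_definition("BAD", atoms,
                                data.frame(a1 = "C1", a2 = "C9")),
               "not in the atom list")
})

test_that("bonds can be read from a chemical-component dictionary file", {
  defn <- zzl_definition()
  lines <- c(
    "data_ZZL", "#", "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    sprintf("ZZL %s %s", defn$atoms$name, defn$atoms$element),
    "#", "loop_",
    "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2",
    sprintf("ZZL %s %s", defn$bonds$a1, defn$bonds$a2),
    "#"
  )
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(lines, f)
  got <- read_ccd_bonds(f, "ZZL")
  expect_identical(sort(got$atoms$name), sort(defn$atoms$name))
  p1 <- partition_lipid(got, tail_start = "C1")
  p2 <- partition_lipid(defn, tail_start = "C1")
  expect_identical(p1$tail_atoms, p2$tail_atoms)
})

test_that("distance-based bond inference recovers a linear chain", {
  atoms <- data.frame(name = paste0("C", 1:5), element = "C",
                      x = (0:4) * 1.5, y = 0, z = 0)
  bonds <- bonds_from_distance(atoms)
  expect_equal(nrow(bonds), 4)
  # 1.5 A neighbors bonded, 3.0 A second neighbors not
  expect_true(all(abs(as.numeric(sub("C", "", bonds$a1)) -
                        as.numeric(sub("C", "", bonds$a2))) == 1))
})
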