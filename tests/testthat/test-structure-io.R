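reg <- synthetic_registry()

write_fixture <- function(..., resolution = 2.0, file = tempfile(fileext = ".pdb")) {
  cx <- make_complex(...)
  write_complex(cx, file, resolution = resolution)
  list(cx = cx, file = file)
}

test_that("resolution screening keeps <= 4.0 A and rejects unresolved entries", {
  f37 <- write_fixture(n_residues = 40, tail_residues = 10, seed = 1,
                       resolution = 3.7)
  sc <- screen_structure(f37$file, reg)
  expect_length(sc$chains, 1)
  expect_equal(sc$chains[[1]]$resolution, 3.7)
  expect_length(sc$lipids, 1)

  f45 <- write_fixture(n_residues = 40, tail_residues = 10, seed = 1,
                       resolution = 4.5)
  expect_length(screen_structure(f45$file, reg)$chains, 0)

  # no REMARK 2 record at all (NMR-style entry)
  lines <- readLines(f37$file)
  f_nores <- tempfile(fileext = ".pdb")
  writeLines(lines[!grepl("^REMARK   2", lines)], f_nores)
  expect_true(is.na(parse_resolution(f_nores)))
  expect_length(screen_structure(f_nores, reg)$chains, 0)
})

test_that("short chains and non-standard residues are dropped; MSE is read as MET", {
  f29 <- write_fixture(n_residues = 29, seed = 2)
  expect_length(screen_structure(f29$file, reg)$chains, 0)

  f30 <- write_fixture(n_residues = 30, seed = 2)
  expect_length(screen_structure(f30$file, reg)$chains, 1)

  # rewrite one residue as a nonstandard type -> chain dropped
  base <- write_fixture(n_residues = 35, seed = 3)
  lines <- readLines(base$file)
  target <- sprintf("%3s A  12", base$cx$sequence[12])
  bad <- gsub(target, sprintf("%3s A  12", "XYZ"), lines, fixed = TRUE)
  f_bad <- tempfile(fileext = ".pdb")
  writeLines(bad, f_bad)
  expect_length(screen_structure(f_bad, reg)$chains, 0)

  # ... but selenomethionine is kept, renamed MET
  mse <- gsub(target, "MSE A  12", lines, fixed = TRUE)
  f_mse <- tempfile(fileext = ".pdb")
  writeLines(mse, f_mse)
  sc <- screen_structure(f_mse, reg)
  expect_length(sc$chains, 1)
  expect_equal(sc$chains[[1]]$residues$resid[12], "MET")
  expect_false("MSE" %in% sc$chains[[1]]$residues$resid)
})

test_that("lipid extraction attaches the registry partition", {
  fx <- write_fixture(n_residues = 35, tail_residues = c(8, 20),
                      head_residues = 14, seed = 4)
  sc <- screen_structure(fx$file, reg)
  expect_length(sc$lipids, 3)
  for (l in sc$lipids) {
    expect_s3_class(l$partition, "lipid_partition")
    expect_setequal(l$partition$tail_atoms, paste0("C", 1:8))
  }
})

test_that("chain screening is idempotent", {
  fx <- write_fixture(n_residues = 40, seed = 5)
  sc <- screen_structure(fx$file, reg)
  once <- screen_chains(sc$chains)
  expect_identical(screen_chains(once), once)
  expect_length(once, length(sc$chains))
})

test_that("representative selection picks the max-contact chain per cluster", {
  mk <- function(sid, cid, cluster) {
    ch <- make_complex(n_residues = 31, seed = 1, structure_id = sid)$chain
    ch$chain_id <- cid
    ch$cluster_id <- cluster
    ch
  }
  chains <- list(mk("s1", "A", "c1"), mk("s1", "B", "c1"),
                 mk("s2", "A", "c2"), mk("s2", "B", "c2"),
                 mk("s3", "A", "c3"))
  counts <- c(s1_A = 7, s1_B = 12, s2_A = 4, s2_B = 3, s3_A = 5)

  reps <- select_representatives(chains, counts)
  keys <- vapply(reps, chain_key, character(1))
  # c1 -> B (max); c2 discarded (all members below five); c3 kept at the
  # boundary (five is not "less than five")
  expect_setequal(keys, c("s1_B", "s3_A"))

  # the representative's count is at least every clustermate's
  expect_true(counts["s1_B"] >= counts["s1_A"])

  # deterministic lexicographic tie-break
  counts_tie <- c(s1_A = 12, s1_B = 12, s2_A = 4, s2_B = 3, s3_A = 5)
  reps_tie <- select_representatives(chains, counts_tie)
  expect_true("s1_A" %in% vapply(reps_tie, chain_key, character(1)))

  # missing cluster ids are a configuration error
  nocl <- chains
  nocl[[1]]$cluster_id <- NA_character_
  expect_error(select_representatives(nocl, counts), "cluster_id")
})

test_that("chain annotations merge from the sidecar TSV", {
  fx <- write_fixture(n_residues = 32, seed = 6)
  f_ann <- tempfile(fileext = ".tsv")
  sid <- sub("\\.pdb$", "", basename(fx$file))  # screen derives the id from the file name
  writeLines(c("structure_id\tchain_id\tcluster_id\ttm_label",
               paste(sid, "A", "c9", "TM", sep = "\t")),
             f_ann)
  ann <- read_chain_annotations(f_ann)
  sc <- screen_structure(fx$file, reg, annotations = ann)
  expect_equal(sc$chains[[1]]$cluster_id, "c9")
  expect_equal(sc$chains[[1]]$tm_label, "TM")
})
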