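test_that("occupancy is the exact fraction of contact frames", {
  m <- matrix(c(rep(1, 300), rep(0, 700)), ncol = 1)
  expect_identical(occupancy(m), 0.3)
  expect_identical(occupancy(matrix(1, 50, 1)), 1)
  expect_identical(occupancy(matrix(rep(c(1, 0), 500), ncol = 1)), 0.5)
})

test_that("occupancies are invariant to frame order and self-concatenation", {
  tr <- make_trajectory(data.frame(resno = c(8, 17), occupancy = c(0.25, 0.6),
                                   class = c("tail", "head")),
                        n_residues = 24, n_frames = 40, seed = 21)
  base <- trajectory_occupancy(tr)

  set.seed(22)
  shuf <- tr
  shuf$xyz <- tr$xyz[sample(tr$n_frames), , drop = FALSE]
  expect_equal(trajectory_occupancy(shuf), base)

  doubled <- tr
  doubled$xyz <- rbind(tr$xyz, tr$xyz)
  doubled$n_frames <- 2L * tr$n_frames
  d_occ <- trajectory_occupancy(doubled)
  expect_equal(d_occ$head_occupancy, base$head_occupancy)
  expect_equal(d_occ$tail_occupancy, base$tail_occupancy)
})

test_that("frame indicators match a brute-force distance scan", {
  tr <- make_trajectory(data.frame(resno = c(5, 12), occupancy = c(0.5, 0.3),
                                   class = c("tail", "tail")),
                        n_residues = 18, n_frames = 10, seed = 23)
  cutoff <- 4.5
  for (f in c(1, 4, 10)) {
    got <- frame_contacts(tr, f, cutoff = cutoff)
    ch <- tr$chain
    for (ri in seq_len(nrow(ch$residues))) {
      rn <- ch$residues$resno[ri]
      idx <- ch$atom_idx[ch$atoms$resno == rn]
      px <- lipropen:::frame_coords(tr, idx, f)
      want_head <- FALSE; want_tail <- FALSE
      for (l in tr$lipids) {
        lx <- lipropen:::frame_coords(tr, l$atom_idx, f)
        grp <- ifelse(l$atoms$elety %in% l$partition$tail_atoms, "tail", "head")
        for (i in seq_len(nrow(px))) for (j in seq_len(nrow(lx))) {
          if (sqrt(sum((px[i, ] - lx[j, ])^2)) <= cutoff) {
            if (grp[j] == "tail") want_tail <- TRUE else want_head <- TRUE
          }
        }
      }
      expect_identical(got$head[ri], want_head)
      expect_identical(got$tail[ri], want_tail)
    }
  }
})

test_that("fractional counts reduce to the crystal computation for 0/1 occupancies", {
  cx <- make_complex(n_residues = 30, tail_residues = c(5, 9, 22), seed = 24)
  rec <- detect_contacts(cx$chain, cx$lipids)
  summ <- contact_summary(rec, cx$chain)

  occ <- data.frame(resno = summ$resno, resid = summ$resid,
                    head_occupancy = as.numeric(summ$head_bound),
                    tail_occupancy = as.numeric(summ$tail_bound))
  from_flags <- chain_contact_counts(cx$chain, summ, "tail")
  from_occ <- chain_contact_counts(cx$chain, occ, "tail")
  expect_equal(from_flags$n_bound, from_occ$n_bound)
  expect_equal(chain_propensity(from_flags), chain_propensity(from_occ))
})

test_that("prescribed occupancies are realized exactly through the pipeline", {
  targets <- data.frame(resno = c(6, 11, 19), occupancy = c(0.3, 0.85, 0),
                        class = c("tail", "head", "tail"))
  tr <- make_trajectory(targets, n_residues = 24, n_frames = 20, seed = 25)
  occ <- trajectory_occupancy(tr)
  expect_identical(occ$tail_occupancy[occ$resno == 6], 0.3)
  expect_identical(occ$head_occupancy[occ$resno == 11], 0.85)
  expect_identical(occ$tail_occupancy[occ$resno == 19], 0)
  # no stray contacts anywhere else
  others <- !(occ$resno %in% targets$resno)
  expect_true(all(occ$head_occupancy[others] == 0))
  expect_true(all(occ$tail_occupancy[others] == 0))
})

test_that("Bernoulli-generated indicator series recover their contact probability", {
  set.seed(26)
  n_frames <- 400
  q <- c(0.1, 0.5, 0.9)
  m <- sapply(q, function(qi) rbinom(n_frames, 1, qi))
  got <- occupancy(m)
  for (k in seq_along(q)) {
    tol <- 3 * sqrt(q[k] * (1 - q[k]) / n_frames)
    expect_lt(abs(got[k] - q[k]), tol)
  }
})

test_that("the residue mask excludes an extra-membranous segment from the counts", {
  tr <- make_trajectory(data.frame(resno = c(7, 15), occupancy = c(0.5, 0.5),
                                   class = c("tail", "tail")),
                        n_residues = 20, n_frames = 8, seed = 27)
  occ <- trajectory_occupancy(tr, mask = 1:10)
  expect_false(any(occ$resno <= 10))
  cnt <- md_contact_counts(tr, occ = occ, contact_class = "tail")
  expect_equal(attr(cnt, "N"), 10)
})

test_that("the crystal-style criteria mode finds the designed contacts too", {
  tr <- make_trajectory(data.frame(resno = 9, occupancy = 1, class = "tail"),
                        n_residues = 16, n_frames = 2, seed = 28)
  ind <- frame_contacts(tr, 1, criteria = "hbplus")
  # contact atom placed at 3.5 A from the residue anchor: inside the
  # C..C van der Waals criterion (3.9 A)
  expect_true(ind$tail[ind$resno == 9])
  expect_equal(sum(ind$tail), 1)
  expect_equal(sum(ind$head), 0)
})

test_that("a written multi-model trajectory reads back with identical occupancies", {
  f <- withr::local_tempfile(fileext = ".pdb")
  tr <- make_trajectory(data.frame(resno = 10, occupancy = 0.4, class = "head"),
                        n_residues = 15, n_frames = 10, seed = 29, file = f)
  tr2 <- read_trajectory(f, synthetic_registry())
  expect_equal(tr2$n_frames, 10)
  expect_equal(trajectory_occupancy(tr2), trajectory_occupancy(tr))
})
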