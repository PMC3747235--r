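# Constructed-geometry and oracle tests of the contact engine.

test_that("each hydrogen-bond criterion is individually necessary", {
  p <- geometry_params()
  # base geometry: comfortably satisfies every criterion
  base <- list(d = c(0, 0, 0), h = c(1, 0, 0), a = c(2.9, 0, 0),
               aa = c(3.6, 1.3, 0))
  # variants, each designed to violate exactly one criterion
  cases <- list(
    da    = list(d = c(0, 0, 0), h = c(1.45, 0, 0), a = c(3.95, 0, 0),
                 aa = c(4.65, 1.3, 0)),
    ha    = list(d = c(0, 0, 0), h = c(0.3, 0, 0), a = c(2.9, 0, 0),
                 aa = c(3.6, 1.3, 0)),
    dha   = list(d = c(0, 0, 0), h = c(1.5, 1.6, 0), a = c(3, 0, 0),
                 aa = c(4.0, 0.3, 0)),
    daaa  = list(d = c(0, 0, 0), h = c(1.2, 0.8, 0), a = c(3, 0, 0),
                 aa = c(2.7, -1.3, 0)),
    haaa  = list(d = c(0, 0, 0), h = c(1.2, 0.8, 0), a = c(3, 0, 0),
                 aa = c(3.3, 1.3, 0))
  )
  crit <- function(g) {
    c(da = sqrt(sum((g$a - g$d)^2)) < p$da_max,
      ha = sqrt(sum((g$a - g$h)^2)) <= p$ha_max,
      dha = angle_at(g$d, g$h, g$a) > p$min_angle,
      daaa = angle_at(g$d, g$a, g$aa) > p$min_angle,
      haaa = angle_at(g$h, g$a, g$aa) > p$min_angle)
  }
  expect_true(all(crit(base)))
  expect_true(hbond_criteria(base$d, base$h, base$a, base$aa, p))
  for (nm in names(cases)) {
    g <- cases[[nm]]
    v <- crit(g)
    expect_identical(names(which(!v)), nm)  # exactly one criterion broken
    expect_false(hbond_criteria(g$d, g$h, g$a, g$aa, p))
  }
})

test_that("detected hydrogen bonds respect the donor-acceptor cutoffs end to end", {
  # LYS NZ donating to a ZZL head-group oxygen placed on the ammonium
  # N-H cone (tetrahedral angle off the CE-NZ axis), so one rotamer
  # hydrogen points straight at it
  lys <- list(resid = "LYS", resno = 1L, atoms = data.frame(
    elety = c("N", "CA", "CE", "NZ"),
    element = c("N", "C", "C", "N"),
    x = c(-2.9, -1.5, -1.5, 0), y = c(0, 1.2, 0, 0), z = 0))
  ch <- mini_chain(list(lys))
  u <- c(cos(70.53 * pi / 180), sin(70.53 * pi / 180), 0)
  # O1 at distance d from NZ along u; its antecedent P1 farther out
  lip_at <- function(d) mini_zzl(d * u, u, "head")
  hb_ok <- detect_hbonds(ch, list(lip_at(2.9)))
  expect_equal(nrow(hb_ok), 1)
  expect_equal(hb_ok$residue_atom, "NZ")
  expect_equal(hb_ok$lipid_atom, "O1")
  expect_equal(hb_ok$contact_type, "hbond")

  hb_far <- detect_hbonds(ch, list(lip_at(4.1)))
  expect_equal(nrow(hb_far), 0)
})

test_that("van der Waals contacts use radii sums plus tolerance", {
  gly <- function() list(resid = "GLY", resno = 1L, atoms = data.frame(
    elety = c("N", "CA"), element = c("N", "C"),
    x = c(-1.4, 0), y = 0, z = 0))
  ch <- mini_chain(list(gly()))
  # C..C threshold = 1.7 + 1.7 + 0.5 = 3.9
  lip_near <- mini_zzl(c(3.5, 0, 0), c(1, 0, 0), "tail")
  vw <- detect_vdw(ch, list(lip_near))
  expect_true(any(vw$residue_atom == "CA" & vw$lipid_atom == "C1"))

  lip_far <- mini_zzl(c(4.0, 0, 0), c(1, 0, 0), "tail")
  vw2 <- detect_vdw(ch, list(lip_far))
  expect_false(any(vw2$residue_atom == "CA" & vw2$lipid_atom == "C1"))
})

test_that("salt bridges require opposite charges within the cutoff", {
  mk_ch <- function(resid, tip_elety, tip_element) {
    mini_chain(list(list(resid = resid, resno = 1L, atoms = data.frame(
      elety = c("N", "CA", tip_elety),
      element = c("N", "C", tip_element),
      x = c(-2.9, -1.5, 0), y = c(0, 1.2, 0), z = 0))))
  }
  # phosphate oxygen O1 (bonded to P1) at 3.5 A from LYS NZ -> salt
  lip <- mini_zzl(c(3.5, 0, 0), c(1, 0, 0), "head")
  sb <- detect_salt_bridges(mk_ch("LYS", "NZ", "N"), list(lip))
  expect_equal(nrow(sb), 1)
  expect_equal(sb$contact_type, "salt")
  expect_equal(sb$lipid_atom, "O1")

  # beyond 4.0 A -> none
  lip_far <- mini_zzl(c(4.5, 0, 0), c(1, 0, 0), "head")
  expect_equal(nrow(detect_salt_bridges(mk_ch("LYS", "NZ", "N"), list(lip_far))), 0)

  # an uncharged side chain never forms a salt bridge, however close
  lip_close <- mini_zzl(c(3.0, 0, 0), c(1, 0, 0), "head")
  ch_leu <- mk_ch("LEU", "CD1", "C")
  expect_equal(nrow(detect_salt_bridges(ch_leu, list(lip_close))), 0)
  vw <- detect_vdw(ch_leu, list(lip_close))
  expect_true(any(vw$residue_atom == "CD1" & vw$lipid_atom == "O1"))
})

test_that("grid neighbor search equals the brute-force all-pairs oracle", {
  set.seed(20)
  for (rep in 1:4) {
    a <- matrix(runif(3 * 120, 0, 25), ncol = 3)
    b <- matrix(runif(3 * 80, 0, 25), ncol = 3)
    for (cutoff in c(1.5, 4.0, 9.0)) {
      got <- neighbor_pairs(a, b, cutoff)
      want <- brute_pairs(a, b, cutoff)
      expect_equal(got$i, want$i)
      expect_equal(got$j, want$j)
      expect_equal(got$distance, want$distance, tolerance = 1e-12)
    }
  }
})

test_that("the full vdW detector matches a brute-force scan on a random complex", {
  cx <- make_complex(n_residues = 45, tail_residues = c(6, 14, 30),
                     head_residues = c(22, 38), seed = 8)
  p <- geometry_params()
  got <- detect_vdw(cx$chain, cx$lipids)
  # independent oracle: loop every residue-atom / lipid-atom pair
  radius <- function(e) c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)[[e]]
  want <- 0L
  at <- cx$chain$atoms
  for (l in cx$lipids) for (i in seq_len(nrow(at))) for (j in seq_len(nrow(l$atoms))) {
    d <- sqrt(sum((as.numeric(at[i, c("x", "y", "z")]) -
                     as.numeric(l$atoms[j, c("x", "y", "z")]))^2))
    if (d <= radius(at$element[i]) + radius(l$atoms$element[j]) + p$vdw_tolerance)
      want <- want + 1L
  }
  expect_equal(nrow(got), want)
})

test_that("contact detection is invariant under rigid-body motion", {
  cx <- make_complex(n_residues = 30, tail_residues = c(5, 12),
                     head_residues = 20, seed = 9)
  base <- detect_contacts(cx$chain, cx$lipids)

  R <- lipropen:::rotation_matrix(c(1, 2, 3), 67)
  shift <- c(11, -4, 7)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + shift[1]; df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  ch2 <- cx$chain; ch2$atoms <- move(ch2$atoms); ch2$hydrogens <- NULL
  lip2 <- lapply(cx$lipids, function(l) { l$atoms <- move(l$atoms); l })
  moved <- detect_contacts(ch2, lip2)

  ord <- function(x) x[order(x$resno, x$residue_atom, x$lipid_instance,
                             x$lipid_atom), ]
  b <- ord(base); m <- ord(moved)
  expect_equal(b$resno, m$resno)
  expect_equal(b$contact_type, m$contact_type)
  expect_equal(b$lipid_group, m$lipid_group)
  expect_equal(b$distance, m$distance, tolerance = 1e-6)
})

test_that("per-contact head/tail classification sets residue flags independently", {
  # one residue touching a head atom of one lipid and a tail atom of another
  res <- list(resid = "GLY", resno = 1L, atoms = data.frame(
    elety = c("N", "CA"), element = c("N", "C"),
    x = c(0, 0), y = c(1.4, 0), z = 0))
  ch <- mini_chain(list(res))
  head_lip <- mini_zzl(c(3.0, 0, 0), c(1, 0, 0), "head", id = "ZZL_L_1")
  tail_lip <- mini_zzl(c(-3.4, 0, 0), c(-1, 0, 0), "tail", id = "ZZL_L_2")

  both <- contact_summary(detect_contacts(ch, list(head_lip, tail_lip)), ch)
  expect_true(both$head_bound[1] && both$tail_bound[1])

  only_head <- contact_summary(detect_contacts(ch, list(head_lip)), ch)
  expect_true(only_head$head_bound[1])
  expect_false(only_head$tail_bound[1])

  none <- contact_summary(lipropen:::empty_contacts(), ch)
  expect_false(none$head_bound[1] || none$tail_bound[1])
})

test_that("an ARG guanidinium receives five donor hydrogens", {
  # planar-ish guanidinium built by hand
  arg <- list(resid = "ARG", resno = 1L, atoms = data.frame(
    elety = c("N", "CA", "CD", "NE", "CZ", "NH1", "NH2"),
    element = c("N", "C", "C", "N", "C", "N", "N"),
    x = c(-6, -5, -2.2, -1.2, 0, 0.6, 0.6),
    y = c(0, 1, 1.0, 0.2, 0.5, 1.7, -0.6),
    z = 0))
  ch <- place_polar_hydrogens(mini_chain(list(arg)))
  side <- ch$hydrogens[ch$hydrogens$donor %in% c("NE", "NH1", "NH2"), ]
  expect_equal(nrow(side), 5)
  # all at the 1.0 A bond length from their donors
  for (k in seq_len(nrow(side))) {
    dxyz <- ch$atoms[ch$atoms$elety == side$donor[k], c("x", "y", "z")]
    expect_equal(sqrt(sum((as.numeric(dxyz) -
                             as.numeric(side[k, c("x", "y", "z")]))^2)),
                 1.0, tolerance = 1e-9)
  }
})

test_that("backbone amide hydrogens bisect the neighbor directions; GLY gets only NH", {
  cx <- make_complex(n_residues = 12, sequence = rep("GLY", 12), seed = 1)
  ch <- place_polar_hydrogens(cx$chain)
  h <- ch$hydrogens
  expect_setequal(unique(h$name), "H")
  expect_equal(nrow(h), 11)  # no H on the chain-initial amide
  # sp2 geometry: H-N-CA and H-N-C(prev) angles equal
  res <- ch$residues
  for (k in c(3, 7)) {
    n <- as.numeric(ch$atoms[ch$atoms$resno == k & ch$atoms$elety == "N", c("x", "y", "z")])
    ca <- as.numeric(ch$atoms[ch$atoms$resno == k & ch$atoms$elety == "CA", c("x", "y", "z")])
    cp <- as.numeric(ch$atoms[ch$atoms$resno == k - 1 & ch$atoms$elety == "C", c("x", "y", "z")])
    hh <- as.numeric(h[h$resno == k, c("x", "y", "z")])
    expect_equal(angle_at(hh, n, ca), angle_at(hh, n, cp), tolerance = 1e-6)
  }
})
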