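# Idealized polar-hydrogen placement on protein chains. Only donors that
# matter for protein-to-lipid hydrogen bonds get hydrogens: backbone
# amides and the side-chain N/O donors. Bond length 1.0 A; sp2 donors at
# planar geometry, sp3 donors (hydroxyls, lysine ammonium) on a
# tetrahedral cone about the parent bond with the rotamer chosen to
# optimize proximity to nearby acceptors.

H_BOND_LENGTH <- 1.0
TETRAHEDRAL_CONE <- 180 - 109.47  # cone half-angle about the parent axis

# Side-chain donor geometry table. type: sp2_1 (one H, two heavy
# neighbors), sp2_2 (two H in the plane of C and ref), sp3_rot (n H on a
# rotatable cone about parent->donor).
SIDECHAIN_DONORS <- list(
  ARG = list(
    list(donor = "NE",  type = "sp2_1", nb = c("CD", "CZ"), h = "HE"),
    list(donor = "NH1", type = "sp2_2", c = "CZ", ref = "NE", h = c("HH11", "HH12")),
    list(donor = "NH2", type = "sp2_2", c = "CZ", ref = "NE", h = c("HH21", "HH22"))
  ),
  LYS = list(list(donor = "NZ", type = "sp3_rot", parent = "CE", n_h = 3L,
                  h = c("HZ1", "HZ2", "HZ3"))),
  HIS = list(
    list(donor = "ND1", type = "sp2_1", nb = c("CG", "CE1"), h = "HD1"),
    list(donor = "NE2", type = "sp2_1", nb = c("CD2", "CE1"), h = "HE2")
  ),
  TRP = list(list(donor = "NE1", type = "sp2_1", nb = c("CD1", "CE2"), h = "HE1")),
  ASN = list(list(donor = "ND2", type = "sp2_2", c = "CG", ref = "OD1",
                  h = c("HD21", "HD22"))),
  GLN = list(list(donor = "NE2", type = "sp2_2", c = "CD", ref = "OE1",
                  h = c("HE21", "HE22"))),
  SER = list(list(donor = "OG",  type = "sp3_rot", parent = "CB", n_h = 1L, h = "HG")),
  THR = list(list(donor = "OG1", type = "sp3_rot", parent = "CB", n_h = 1L, h = "HG1")),
  TYR = list(list(donor = "OH",  type = "sp3_rot", parent = "CZ", n_h = 1L, h = "HH"))
)

sp2_one_h <- function(d, n1, n2) {
  d + H_BOND_LENGTH * vec_unit(-(vec_unit(n1 - d) + vec_unit(n2 - d)))
}

sp2_two_h <- function(d, cc, ref) {
  u <- vec_unit(d - cc)
  nrm <- vec_unit(vec_cross(d - cc, ref - cc))
  p <- vec_cross(nrm, u)
  s <- sin(pi / 3); co <- cos(pi / 3)
  list(d + H_BOND_LENGTH * (co * u + s * p),
       d + H_BOND_LENGTH * (co * u - s * p))
}

# n_h hydrogens on the cone about parent->donor, azimuth phi (degrees).
sp3_cone_h <- function(d, parent, n_h, phi) {
  u <- vec_unit(d - parent)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- vec_unit(vec_cross(u, ref))
  q <- vec_cross(u, p)
  th <- TETRAHEDRAL_CONE * pi / 180
  lapply(seq_len(n_h), function(k) {
    a <- (phi + (k - 1) * 360 / n_h) * pi / 180
    d + H_BOND_LENGTH * (cos(th) * u + sin(th) * (cos(a) * p + sin(a) * q))
  })
}

best_cone_phi <- function(d, parent, n_h, acceptors, step = 10) {
  if (is.null(acceptors) || nrow(acceptors) == 0L) return(0)
  dd <- pair_distances(matrix(d, nrow = 1), acceptors)
  if (min(dd) > 5) return(0)
  phis <- seq(0, 360 - step, by = step)
  score <- vapply(phis, function(phi) {
    hs <- sp3_cone_h(d, parent, n_h, phi)
    min(vapply(hs, function(h)
      min(pair_distances(matrix(h, nrow = 1), acceptors)), numeric(1)))
  }, numeric(1))
  phis[which.min(score)]
}

#' Place idealized polar hydrogens on a protein chain
#'
#' Adds hydrogens (bond length 1.0 A) to backbone amide nitrogens and to
#' the standard side-chain donors (ARG, LYS, HIS, TRP, ASN, GLN, SER,
#' THR, TYR). sp2 donors get planar geometry; rotatable sp3 donors
#' (hydroxyls, the lysine ammonium) are sampled about their parent bond
#' and oriented toward the nearest acceptor among `acceptors`, when one is
#' within 5 A. Prolines and chain-initial amides (no preceding carbonyl)
#' receive no backbone hydrogen. Residues with missing backbone atoms are
#' skipped with a warning; side-chain donors with missing atoms are
#' skipped silently (pseudo-atom models).
#'
#' @param chain A `protein_chain`.
#' @param acceptors Optional matrix (n x 3) of acceptor coordinates used
#'   to orient rotatable donors.
#' @return The chain with an added `hydrogens` data.frame (columns
#'   `resno`, `resid`, `donor`, `name`, `x`, `y`, `z`).
#' @export
place_polar_hydrogens <- function(chain, acceptors = NULL) {
  stopifnot(inherits(chain, "protein_chain"))
  at <- chain$atoms
  coords <- function(resno, elety) {
    r <- at[at$resno == resno & at$elety == elety, c("x", "y", "z")]
    if (nrow(r) != 1L) return(NULL)
    as.numeric(r[1, ])
  }
  rows <- list()
  add <- function(resno, resid, donor, name, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resno = resno, resid = resid, donor = donor, name = name,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  res <- chain$residues
  for (k in seq_len(nrow(res))) {
    rn <- res$resno[k]; rid <- res$resid[k]
    n <- coords(rn, "N"); ca <- coords(rn, "CA")
    if (is.null(n) || is.null(ca)) {
      warning("residue ", rid, rn, " lacks backbone atoms; skipped")
      next
    }
    # Backbone amide H (not PRO, needs the preceding carbonyl carbon).
    if (rid != "PRO" && k > 1L) {
      cprev <- coords(res$resno[k - 1L], "C")
      if (!is.null(cprev)) add(rn, rid, "N", "H", sp2_one_h(n, ca, cprev))
    }
    for (spec in SIDECHAIN_DONORS[[rid]]) {
      d <- coords(rn, spec$donor)
      if (is.null(d)) next
      if (spec$type == "sp2_1") {
        n1 <- coords(rn, spec$nb[1]); n2 <- coords(rn, spec$nb[2])
        if (is.null(n1) || is.null(n2)) next
        add(rn, rid, spec$donor, spec$h, sp2_one_h(d, n1, n2))
      } else if (spec$type == "sp2_2") {
        cc <- coords(rn, spec$c); ref <- coords(rn, spec$ref)
        if (is.null(cc) || is.null(ref)) next
        hs <- sp2_two_h(d, cc, ref)
        add(rn, rid, spec$donor, spec$h[1], hs[[1]])
        add(rn, rid, spec$donor, spec$h[2], hs[[2]])
      } else {
        parent <- coords(rn, spec$parent)
        if (is.null(parent)) next
        phi <- best_cone_phi(d, parent, spec$n_h, acceptors)
        hs <- sp3_cone_h(d, parent, spec$n_h, phi)
        for (j in seq_along(hs)) add(rn, rid, spec$donor, spec$h[j], hs[[j]])
      }
    }
  }
  chain$hydrogens <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resno = integer(), resid = character(), donor = character(),
               name = character(), x = numeric(), y = numeric(), z = numeric())
  chain
}
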