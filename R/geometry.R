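# Small 3D vector helpers shared by the contact and synthesis code.
# Coordinates are plain numeric length-3 vectors or n x 3 matrices (Angstrom).

vec_norm <- function(v) sqrt(sum(v * v))

vec_unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle (degrees) at vertex b of the path a-b-c.
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

# All pairwise distances between rows of a (n x 3) and b (m x 3).
pair_distances <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Neighbor pairs within a distance cutoff (cell-list search)
#'
#' Finds all pairs (i, j) with `|a[i, ] - b[j, ]| <= cutoff` using a
#' spatial grid with cells of edge `cutoff`, so only the 27 neighboring
#' cells of each occupied cell are scanned. Equivalent to a brute-force
#' all-pairs scan (a property the test suite asserts) but subquadratic for
#' spread-out coordinate sets.
#'
#' @param a,b Numeric matrices with 3 columns (x, y, z in Angstrom).
#' @param cutoff Positive distance cutoff in Angstrom.
#' @return A data.frame with columns `i`, `j` (row indices into `a` and
#'   `b`) and `distance`.
#' @export
neighbor_pairs <- function(a, b, cutoff) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  empty <- data.frame(i = integer(), j = integer(), distance = numeric())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)

  orig <- pmin(apply(a, 2, min), apply(b, 2, min))
  cell_of <- function(m) {
    cm <- floor(sweep(m, 2, orig) / cutoff)
    paste(cm[, 1], cm[, 2], cm[, 3], sep = ",")
  }
  ca_int <- floor(sweep(a, 2, orig) / cutoff)
  key_a <- paste(ca_int[, 1], ca_int[, 2], ca_int[, 3], sep = ",")
  b_by_cell <- split(seq_len(nrow(b)), cell_of(b))

  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0L

  for (cell in unique(key_a)) {
    ai <- which(key_a == cell)
    base <- as.integer(strsplit(cell, ",", fixed = TRUE)[[1]])
    neigh <- sweep(offsets, 2, base, "+")
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3], sep = ",")
    bj <- unlist(b_by_cell[keys], use.names = FALSE)
    if (is.null(bj) || length(bj) == 0L) next
    d <- pair_distances(a[ai, , drop = FALSE], b[bj, , drop = FALSE])
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    k <- k + 1L
    out_i[[k]] <- ai[hit[, 1]]
    out_j[[k]] <- bj[hit[, 2]]
    out_d[[k]] <- d[hit]
  }
  if (k == 0L) return(empty)
  res <- data.frame(i = unlist(out_i), j = unlist(out_j),
                    distance = unlist(out_d))
  res[order(res$i, res$j), , drop = FALSE]
}

# Rigid-body helpers used by tests and the synthetic generator.
rotation_matrix <- function(axis, angle_deg) {
  u <- vec_unit(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}
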