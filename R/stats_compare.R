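# Comparison of residue-level vectors (propensities, lipophilicity
# scales) via Pearson's product-moment correlation with a jackknife
# standard error. Undefined entries (NA) propagate as missing: all
# statistics are taken over the intersection of defined amino acid
# types, and correlations use raw (unrounded, unranked) values.

common_defined <- function(x, y, exclude = NULL) {
  nm <- intersect(names(x), names(y))
  nm <- setdiff(nm, exclude)
  nm <- nm[!is.na(x[nm]) & !is.na(y[nm])]
  list(x = as.numeric(x[nm]), y = as.numeric(y[nm]), types = nm)
}

pearson_formula <- function(x, y) {
  # Explicit product-moment form; kept independent of stats::cor so the
  # two routes can be cross-checked.
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  if (den == 0) stop("zero variance: correlation undefined")
  num / den
}

#' Pearson correlation between two residue-level vectors
#'
#' @param x,y Named numeric vectors (names are amino acid types); `NA`
#'   entries are dropped pairwise.
#' @param exclude Character vector of types to leave out.
#' @return The correlation coefficient.
#' @export
#' @examples
#' scales <- lipophilicity_scales()
#' popc <- setNames(scales$popc, scales$aa)
#' octa <- setNames(scales$octanol, scales$aa)
#' pearson_r(popc, octa)   # 0.92: the two transfer scales agree closely
pearson_r <- function(x, y, exclude = NULL) {
  cd <- common_defined(x, y, exclude)
  if (length(cd$x) < 3L) stop("need at least 3 common defined types")
  pearson_formula(cd$x, cd$y)
}

#' Jackknife standard error of a correlation coefficient
#'
#' Leave-one-type-out replicates `C_(-i)` are combined as
#' `sigma^2 = ((N + 1) / N) * sum_i (C_(-i) - <C>)^2` with `N` the number
#' of common defined types. The default scale factor `(N + 1) / N` is the
#' one this analysis tradition prints; `conventional = TRUE` switches to
#' the textbook jackknife factor `(N - 1) / N`. Replicates where a
#' leave-one-out vector becomes degenerate (zero variance) are skipped
#' with a message and `N` reduced accordingly.
#'
#' @inheritParams pearson_r
#' @param conventional Use the `(N - 1) / N` factor instead.
#' @return The jackknife standard error (square root of `sigma^2`).
#' @export
jackknife_se <- function(x, y, exclude = NULL, conventional = FALSE) {
  cd <- common_defined(x, y, exclude)
  n <- length(cd$x)
  if (n < 4L) stop("need at least 4 common defined types for the jackknife")
  reps <- numeric(0)
  for (i in seq_len(n)) {
    ci <- tryCatch(pearson_formula(cd$x[-i], cd$y[-i]), error = function(e) NA_real_)
    if (is.na(ci)) {
      message("leave-one-out replicate ", cd$types[i],
              " degenerate; skipped")
      next
    }
    reps <- c(reps, ci)
  }
  m <- length(reps)
  fac <- if (conventional) (m - 1) / m else (m + 1) / m
  sqrt(fac * sum((reps - mean(reps))^2))
}

#' Correlation with jackknife error and optional type exclusions
#'
#' @inheritParams jackknife_se
#' @return Object of class `correlation_result`: list with `r`,
#'   `jackknife_se`, `n_points`, `excluded_types`.
#' @export
#' @examples
#' ref <- reference_propensities()
#' ch <- setNames(ref$crystal_head, ref$aa)
#' mh <- setNames(ref$md_head, ref$aa)
#' correlate(ch, mh)                                   # r = 0.81 (0.06)
#' correlate(ch, mh, exclude = c("TRP", "ARG", "LYS")) # r rises to 0.88
correlate <- function(x, y, exclude = NULL, conventional = FALSE) {
  cd <- common_defined(x, y, exclude)
  structure(list(r = pearson_r(x, y, exclude),
                 jackknife_se = jackknife_se(x, y, exclude, conventional),
                 n_points = length(cd$x),
                 excluded_types = exclude %||% character()),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 2, ...) {
  cat(sprintf("r = %.*f (jackknife SE %.*f), n = %d",
              digits, x$r, digits, x$jackknife_se, x$n_points))
  if (length(x$excluded_types)) {
    cat(" excluding", paste(x$excluded_types, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Pairwise correlation matrix over a set of residue vectors
#'
#' @param vectors Named list of named numeric vectors.
#' @param conventional Passed to [jackknife_se()].
#' @return List with matrices `r` (unit diagonal, symmetric) and `se`,
#'   and `formatted`, a character matrix of `"r (se)"` cells.
#' @export
correlation_matrix <- function(vectors, conventional = FALSE) {
  k <- length(vectors)
  nm <- names(vectors)
  r <- matrix(1, k, k, dimnames = list(nm, nm))
  se <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    r[i, j] <- r[j, i] <- pearson_r(vectors[[i]], vectors[[j]])
    se[i, j] <- se[j, i] <- jackknife_se(vectors[[i]], vectors[[j]],
                                         conventional = conventional)
  }
  fmt <- matrix(sprintf("%.2f (%.2f)", r, se), k, k, dimnames = list(nm, nm))
  list(r = r, se = se, formatted = fmt)
}

#' Scatterplot of two propensity/lipophilicity vectors
#'
#' Produces a labelled scatterplot (one point per amino acid) comparing
#' two residue-level vectors, the standard way these propensity analyses
#' are visualized. Requires ggplot2.
#'
#' @param x,y Named numeric vectors.
#' @param xlab,ylab Axis labels.
#' @param exclude Types to drop before plotting.
#' @return A ggplot object.
#' @export
plot_propensity_scatter <- function(x, y, xlab = "x", ylab = "y",
                                    exclude = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  cd <- common_defined(x, y, exclude)
  df <- data.frame(aa = cd$types, px = cd$x, py = cd$y)
  ggplot2::ggplot(df, ggplot2::aes(x = px, y = py)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = aa), vjust = -0.6, size = 3) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_bw()
}
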