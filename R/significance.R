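# Pooled over/under-representation statistics. Counts from a dataset of
# chains are summed per amino acid type; the expected binding count is
# E_i = N_i * N^b / N over the pooled totals, and each type is tested
# with the one-cell goodness-of-fit statistic chi2_i = (O_i - E_i)^2 /
# E_i, reported with the sign of (O_i - E_i) so that positive values mean
# over-representation. P-values come from the upper tail of the 1-d.f.
# chi-square distribution of the unsigned statistic.

#' Pool per-chain contact counts into a dataset-level summary
#'
#' Chains with fewer than `min_binding_residues` binding residues for the
#' contact class are excluded before pooling (proteins with very few
#' contacts carry little signal and would otherwise dominate the expected
#' counts with noise).
#'
#' @param counts_list List of [chain_contact_counts()] tables, all of the
#'   same contact class.
#' @param min_binding_residues Minimum per-chain binding-residue total for
#'   inclusion (default 6; a chain with exactly 6 is included).
#' @return A `count_summary` data.frame with columns `aa`, `observed`,
#'   `expected`, `n_total` and attributes `N`, `N_b`, `n_chains_pooled`,
#'   `contact_class`. `sum(expected) == sum(observed)` exactly.
#' @export
pool_counts <- function(counts_list, min_binding_residues = 6) {
  if (!length(counts_list)) stop("empty count list")
  classes <- unique(vapply(counts_list, attr, character(1), "contact_class"))
  if (length(classes) != 1L) stop("mixed contact classes in pool")
  keep <- vapply(counts_list, function(x)
    attr(x, "N_b") >= min_binding_residues, logical(1))
  if (!any(keep)) {
    stop("no chain has at least ", min_binding_residues,
         " binding residues for the ", classes, " class; empty pool")
  }
  kept <- counts_list[keep]
  aa <- amino_acids()
  O <- rowSums(vapply(kept, function(x) x$n_bound[match(aa, x$aa)],
                      numeric(length(aa))))
  Ni <- rowSums(vapply(kept, function(x) as.numeric(x$n_total[match(aa, x$aa)]),
                       numeric(length(aa))))
  N <- sum(Ni); N_b <- sum(O)
  E <- Ni * N_b / N
  structure(data.frame(aa = aa, observed = unname(O), expected = unname(E),
                       n_total = unname(Ni), stringsAsFactors = FALSE),
            N = N, N_b = N_b, n_chains_pooled = sum(keep),
            contact_class = classes,
            class = c("count_summary", "data.frame"))
}

#' Signed chi-square statistic with 1-d.f. p-values
#'
#' For each amino acid type, `chi2 = (O - E)^2 / E`, reported with the
#' sign of `O - E`; the p-value is the upper tail of the chi-square
#' distribution with one degree of freedom at the unsigned statistic.
#' Types with `E = 0` are skipped (statistic `NA`) with a message.
#'
#' @param observed A `count_summary` from [pool_counts()] (or any
#'   data.frame with `observed`/`expected` columns, e.g. a subset of
#'   [reference_contact_counts()]), or a numeric vector of observed
#'   counts.
#' @param expected Numeric vector of expected counts (ignored for
#'   data.frame input).
#' @return data.frame with columns `aa` (when available), `observed`,
#'   `expected`, `signed_chi2`, `p_value`, and `p_bonferroni` (a
#'   convenience column: Bonferroni-adjusted over the tested types; the
#'   primary `p_value` column is unadjusted).
#' @export
#' @examples
#' signed_chi_square(22, 9.12)   # strongly over-represented: +18.19
#' signed_chi_square(11, 23.18)  # under-represented: -6.40
signed_chi_square <- function(observed, expected = NULL) {
  aa <- NULL
  if (is.data.frame(observed)) {
    if (!all(c("observed", "expected") %in% names(observed))) {
      stop("data.frame input needs 'observed' and 'expected' columns")
    }
    aa <- observed$aa
    expected <- observed$expected
    observed <- observed$observed
  }
  stopifnot(is.numeric(observed), is.numeric(expected),
            length(observed) == length(expected))
  chi2 <- rep(NA_real_, length(observed))
  ok <- expected > 0
  if (any(!ok)) message(sum(!ok), " type(s) with zero expected count skipped")
  chi2[ok] <- (observed[ok] - expected[ok])^2 / expected[ok]
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p[!is.na(chi2) & chi2 == 0] <- 1
  signed <- sign(observed - expected) * chi2
  out <- data.frame(observed = observed, expected = expected,
                    signed_chi2 = signed, p_value = p,
                    p_bonferroni = pmin(1, p * sum(ok)),
                    stringsAsFactors = FALSE)
  if (!is.null(aa)) out <- cbind(aa = aa, out)
  out
}

#' Dataset-level enrichment table for both contact classes
#'
#' Pools a chain set and reports the signed chi-square statistics for
#' head and tail contacts side by side (the layout of a
#' contact-statistics report table).
#'
#' @param head_counts,tail_counts Lists of [chain_contact_counts()].
#' @param min_binding_residues Pooling threshold, applied per class
#'   independently.
#' @return data.frame with one row per amino acid and per class.
#' @export
enrichment_table <- function(head_counts, tail_counts, min_binding_residues = 6) {
  h <- signed_chi_square(pool_counts(head_counts, min_binding_residues))
  t <- signed_chi_square(pool_counts(tail_counts, min_binding_residues))
  h$contact_class <- "head"; t$contact_class <- "tail"
  rbind(h, t)
}
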