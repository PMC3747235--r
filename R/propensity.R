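# Amino acid lipid-contact propensity scores. For a chain, the propensity
# of residue type i is
#
#     P_i = (N_i^b / N_i) / (N^b / N)
#
# the fraction of type-i residues in lipid contact, normalized by the
# chain's overall contacting fraction. P_i = 1 is a neutral preference.
# Binding counts N_i^b are integers for crystal structures and fractional
# occupancy sums for trajectories.

#' Per-chain contact counts for one contact class
#'
#' Builds the count table feeding the propensity score: residue totals
#' `n_total` and binding counts `n_bound` per amino acid type, for head
#' or tail contacts.
#'
#' @param chain A `protein_chain`.
#' @param summary Per-residue flags from [contact_summary()], or a
#'   per-residue occupancy table from [trajectory_occupancy()] (fractional
#'   counts).
#' @param contact_class `"head"` or `"tail"`.
#' @return Object of class `chain_contact_counts`: a data.frame with one
#'   row per amino acid type and columns `aa`, `n_total`, `n_bound`, with
#'   attributes `N`, `N_b`, `contact_class` and `chain` (the chain key).
#' @export
chain_contact_counts <- function(chain, summary, contact_class = c("head", "tail")) {
  contact_class <- match.arg(contact_class)
  col_flag <- paste0(contact_class, "_bound")
  col_occ <- paste0(contact_class, "_occupancy")
  b <- if (col_flag %in% names(summary)) as.numeric(summary[[col_flag]])
       else if (col_occ %in% names(summary)) summary[[col_occ]]
       else stop("summary has neither ", col_flag, " nor ", col_occ)
  stopifnot(nrow(summary) == nrow(chain$residues),
            all(b >= 0), all(b <= 1))
  aa <- amino_acids()
  type <- factor(summary$resid, levels = aa)
  tab <- data.frame(
    aa = aa,
    n_total = as.integer(table(type)),
    n_bound = as.numeric(tapply(b, type, sum, default = 0)),
    stringsAsFactors = FALSE
  )
  new_chain_counts(tab, contact_class, chain_key(chain))
}

new_chain_counts <- function(tab, contact_class, chain = NA_character_) {
  stopifnot(all(tab$n_bound <= tab$n_total + 1e-9), all(tab$n_bound >= 0))
  structure(tab,
            N = sum(tab$n_total), N_b = sum(tab$n_bound),
            contact_class = contact_class, chain = chain,
            class = c("chain_contact_counts", "data.frame"))
}

#' Propensity scores of one chain
#'
#' Computes `P_i = (N_i^b / N_i) / (N^b / N)` per amino acid type.
#' Types absent from the chain (`N_i = 0`) are undefined (`NA`) and
#' excluded from averages; present but never-binding types score 0. A
#' chain with no binding residues at all contributes nothing (all `NA`).
#'
#' @param counts A [chain_contact_counts()] table.
#' @return Named numeric vector over the 20 amino acid types.
#' @export
#' @examples
#' counts <- make_count_tables(n_chains = 1, chain_length = 100,
#'                             p_bind = 0.1, seed = 1)[[1]]
#' chain_propensity(counts)
chain_propensity <- function(counts) {
  stopifnot(inherits(counts, "chain_contact_counts"))
  N <- attr(counts, "N"); N_b <- attr(counts, "N_b")
  if (N <= 0) stop("chain has no residues")
  p <- rep(NA_real_, nrow(counts))
  names(p) <- counts$aa
  if (N_b <= 0) return(p)  # whole-chain propensities undefined
  present <- counts$n_total > 0
  p[present] <- (counts$n_bound[present] / counts$n_total[present]) /
    (N_b / N)
  p
}

#' Average per-chain propensities over a protein set
#'
#' The mean for each amino acid type is taken over the chains where the
#' propensity is defined; the standard error of the mean is `s / sqrt(n)`
#' with `s` the sample standard deviation (n-1 denominator) and `n` the
#' number of such chains. With a single defined chain the SEM is `NA`.
#'
#' @param propensities List of per-chain propensity vectors (from
#'   [chain_propensity()]), or a list of [chain_contact_counts()] which
#'   are converted first.
#' @return A `propensity_table` data.frame: `aa`, `mean`, `sem`,
#'   `n_chains`.
#' @export
average_propensities <- function(propensities) {
  if (!length(propensities)) stop("no chains supplied")
  propensities <- lapply(propensities, function(p) {
    if (inherits(p, "chain_contact_counts")) chain_propensity(p) else p
  })
  aa <- amino_acids()
  m <- do.call(rbind, lapply(propensities, function(p) p[aa]))
  n <- colSums(!is.na(m))
  mean_p <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
  sem <- vapply(seq_along(aa), function(k) {
    v <- m[, k]; v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  structure(data.frame(aa = aa, mean = unname(mean_p), sem = sem,
                       n_chains = unname(n), stringsAsFactors = FALSE),
            class = c("propensity_table", "data.frame"))
}

#' Full crystal-structure propensity workflow for a chain set
#'
#' Convenience wrapper: detects contacts per chain, builds head and tail
#' count tables, and averages the propensities across chains.
#'
#' @param chains List of `protein_chain` objects.
#' @param lipids List of `lipid_instance` objects (shared pool; each
#'   chain is scanned against all of them).
#' @param params A [geometry_params()].
#' @return A data.frame in the layout `aa`, `head_mean`, `head_sem`,
#'   `tail_mean`, `tail_sem`, `n_chains_head`, `n_chains_tail`.
#' @export
lipid_propensities <- function(chains, lipids, params = geometry_params()) {
  heads <- list(); tails <- list()
  for (ch in chains) {
    rec <- detect_contacts(ch, lipids, params)
    summ <- contact_summary(rec, ch)
    heads[[chain_key(ch)]] <- chain_contact_counts(ch, summ, "head")
    tails[[chain_key(ch)]] <- chain_contact_counts(ch, summ, "tail")
  }
  h <- average_propensities(heads)
  t <- average_propensities(tails)
  data.frame(aa = h$aa, head_mean = h$mean, head_sem = h$sem,
             tail_mean = t$mean, tail_sem = t$sem,
             n_chains_head = h$n_chains, n_chains_tail = t$n_chains,
             stringsAsFactors = FALSE)
}
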