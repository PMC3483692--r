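# Pairwise no-replicate differential expression: the Audic-Claverie exact
# test for tag counts, Benjamini-Hochberg FDR, and the four-part call
# filter (TPM >= 20, P <= 0.001, |log2 ratio| >= 1, FDR < 0.05).

#' Audic-Claverie two-library count test
#'
#' For a tag/gene observed x times among N1 clean tags in one library and y
#' times among N2 in another, the posterior probability of the second count
#' given the first under Poisson sampling is
#' \deqn{P(Y = k \mid x) = \left(\frac{N_2}{N_1}\right)^k
#'   \frac{(x+k)!}{x!\,k!\,(1+N_2/N_1)^{x+k+1}}}
#' which is a negative binomial with size x+1 and success probability
#' N1/(N1+N2); tail masses are evaluated through `pnbinom`, i.e. stable
#' incomplete-beta routines rather than naive summation. The two-sided p
#' doubles the smaller of the two complementary tails,
#' `min(1, 2 * min(P(Y <= y), P(Y > y)))`; splitting the observed point
#' into the lower tail this way makes the test exactly symmetric under
#' swapping the libraries, `p(x, y, N1, N2) = p(y, x, N2, N1)`, so calls
#' never depend on the order in which two stages are compared.
#'
#' @param x,y non-negative integer counts (vectorized).
#' @param N1,N2 library clean-tag totals (> 0).
#' @return two-sided p-values in [0, 1].
#' @export
count_test_p <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)))
    stop("counts must be non-negative integers")
  stopifnot(all(N1 > 0), all(N2 > 0))
  prob <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = prob)                      # P(Y <= y)
  upper <- pnbinom(y, size = x + 1, prob = prob, lower.tail = FALSE)  # P(Y > y)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_i = min_{p_j >= p_i} m * p_j / rank_j`,
#' capped at 1; invariant under permutation of the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Call differential expression between two stages
#'
#' A gene is differentially expressed iff all four filters pass:
#' \itemize{
#'   \item reliability: TPM >= `tpm_min` in at least one of the two stages;
#'   \item significance: Audic-Claverie p <= `p_max` on the (rounded)
#'     distributed counts with the clean-tag totals as library sizes;
#'   \item effect size: |log2(TPM_B / TPM_A)| >= `lfc_min`, where a zero TPM
#'     is floored at the TPM equivalent of a single tag
#'     (1e6 / clean_tag_total) so ratios stay finite — a detection-limit
#'     floor;
#'   \item FDR: Benjamini-Hochberg q < `fdr_max`, the family being all genes
#'     passing the TPM filter within this comparison.
#' }
#'
#' @param matrix an `ExpressionMatrix`.
#' @param comparison length-2 character vector `c(stageA, stageB)`; the
#'   ratio is B over A.
#' @param tpm_min,p_max,lfc_min,fdr_max filter thresholds.
#' @param use_distributed if `FALSE`, test raw unambiguous counts instead
#'   of distributed counts.
#' @return `data.table` (one row per gene) with columns `gene`,
#'   `stage_a`, `stage_b`, `count_a`, `count_b`, `tpm_a`, `tpm_b`,
#'   `log2_ratio`, `p_value`, `fdr_q`, the four `passes_*` flags, `is_de`
#'   and `direction` ("up"/"down").
#' @export
call_de <- function(matrix, comparison, tpm_min = 20, p_max = 0.001,
                    lfc_min = 1, fdr_max = 0.05, use_distributed = TRUE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), length(comparison) == 2L)
  miss <- setdiff(comparison, matrix$stages)
  if (length(miss)) stop("unknown stage label(s): ", paste(miss, collapse = ", "))
  a <- comparison[1]; b <- comparison[2]
  cm <- if (use_distributed) matrix$distributed else matrix$counts
  xa <- round_half_up(cm[, a]); xb <- round_half_up(cm[, b])
  na <- matrix$clean_totals[a]; nb <- matrix$clean_totals[b]
  tpma <- matrix$tpm[, a]; tpmb <- matrix$tpm[, b]
  floor_a <- 1e6 / na; floor_b <- 1e6 / nb
  lfc <- log2(pmax(tpmb, floor_b) / pmax(tpma, floor_a))
  p <- count_test_p(xa, xb, na, nb)
  pass_tpm <- tpma >= tpm_min | tpmb >= tpm_min
  q <- rep(NA_real_, length(p))
  q[pass_tpm] <- bh_fdr(p[pass_tpm])
  res <- data.table::data.table(
    gene = rownames(cm),
    stage_a = a, stage_b = b,
    count_a = xa, count_b = xb,
    tpm_a = tpma, tpm_b = tpmb,
    log2_ratio = lfc, p_value = p, fdr_q = q,
    passes_tpm_filter = pass_tpm,
    passes_p = p <= p_max,
    passes_fc = abs(lfc) >= lfc_min,
    passes_fdr = !is.na(q) & q < fdr_max)
  res$is_de <- res$passes_tpm_filter & res$passes_p & res$passes_fc & res$passes_fdr
  res$direction <- ifelse(res$log2_ratio > 0, "up", "down")
  res[]
}

#' Run [call_de()] over a set of pairwise comparisons
#'
#' @param matrix an `ExpressionMatrix`.
#' @param comparisons list of length-2 character vectors, or a character
#'   vector like `"0h:6h"`.
#' @param ... passed to [call_de()].
#' @return named list of per-comparison `data.table`s; names `"A:B"`.
#' @export
call_de_all <- function(matrix, comparisons, ...) {
  if (is.character(comparisons)) comparisons <- strsplit(comparisons, ":", fixed = TRUE)
  out <- lapply(comparisons, function(cp) call_de(matrix, cp, ...))
  names(out) <- vapply(comparisons, paste, "", collapse = ":")
  out
}
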