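# qRT-PCR relative quantification (2^-ddCt) and RNA-Seq vs qPCR
# concordance (Pearson r / R^2, overall and per stage).

#' Relative expression from a Ct table (2^-ddCt)
#'
#' Standard delta-delta-Ct relative quantification with amplification
#' efficiency fixed at 2: replicate-averaged dCt = Ct(target) -
#' Ct(reference) per (gene, stage); ddCt = dCt(stage) - dCt(baseline);
#' ratio = 2^(-ddCt). The baseline stage has ratio 1 by construction.
#'
#' @param ct data.frame/data.table with columns `gene`, `stage`, `target_ct`,
#'   `reference_ct` (one row per replicate; replicates averaged on the Ct
#'   scale).
#' @param baseline baseline stage label, present for every gene.
#' @return `data.table` with `gene`, `stage`, `delta_ct`, `ratio`,
#'   `log2_ratio`.
#' @export
relative_expression <- function(ct, baseline) {
  ct <- data.table::as.data.table(ct)
  stopifnot(all(c("gene", "stage", "target_ct", "reference_ct") %in% names(ct)),
            all(is.finite(ct$target_ct)), all(is.finite(ct$reference_ct)),
            all(ct$target_ct > 0), all(ct$reference_ct > 0))
  target_ct <- reference_ct <- gene <- stage <- NULL
  d <- ct[, list(delta_ct = mean(target_ct) - mean(reference_ct)),
          by = list(gene, stage)]
  base <- d[stage == baseline]
  miss <- setdiff(unique(d$gene), base$gene)
  if (length(miss))
    stop("baseline stage '", baseline, "' missing for gene(s): ",
         paste(head(miss, 5), collapse = ", "))
  d <- merge(d, base[, list(gene, base_delta_ct = delta_ct)], by = "gene")
  d$log2_ratio <- -(d$delta_ct - d$base_delta_ct)
  d$ratio <- 2^d$log2_ratio
  d[, list(gene, stage, delta_ct, ratio, log2_ratio)]
}

#' RNA-Seq vs qRT-PCR concordance
#'
#' Inner-joins the two platforms on (gene, stage) and reports the Pearson
#' correlation of their log2 ratios, overall or per stage. Groups with
#' fewer than `min_pairs` pairs are skipped with a warning.
#'
#' @param rnaseq data.frame with `gene`, `stage`, `log2_ratio` (sequencing
#'   side, e.g. log2 TPM ratio vs the baseline stage).
#' @param qpcr data.frame with `gene`, `stage`, `log2_ratio`
#'   ([relative_expression()] output works directly).
#' @param grouping `"overall"` or `"per_stage"`.
#' @param min_pairs minimum paired observations per group (default 3).
#' @return `data.table` with `group`, `n`, `r`, `r_squared`.
#' @export
platform_correlation <- function(rnaseq, qpcr, grouping = c("overall", "per_stage"),
                                 min_pairs = 3L) {
  grouping <- match.arg(grouping)
  a <- data.table::as.data.table(rnaseq)
  b <- data.table::as.data.table(qpcr)
  d <- merge(a[, c("gene", "stage", "log2_ratio")],
             b[, c("gene", "stage", "log2_ratio")],
             by = c("gene", "stage"), suffixes = c("_seq", "_qpcr"))
  one <- function(dd, label) {
    if (nrow(dd) < min_pairs) {
      warning("group '", label, "' has ", nrow(dd), " pairs (< ", min_pairs, "); skipped")
      return(NULL)
    }
    r <- cor(dd$log2_ratio_seq, dd$log2_ratio_qpcr)
    data.table::data.table(group = label, n = nrow(dd), r = r, r_squared = r^2)
  }
  if (grouping == "overall") return(one(d, "overall"))
  data.table::rbindlist(
    Filter(Negate(is.null), lapply(split(d, d$stage), function(dd)
      one(dd, dd$stage[1]))))
}

#' Sequencing-side log2 ratios versus a baseline stage
#'
#' Companion to [relative_expression()]: log2(TPM(stage) / TPM(baseline))
#' with the single-tag TPM floor applied to zeros, shaped for
#' [platform_correlation()].
#'
#' @param em an `ExpressionMatrix`.
#' @param genes genes to report.
#' @param baseline baseline stage label.
#' @return `data.table` with `gene`, `stage`, `log2_ratio`.
#' @export
rnaseq_ratios <- function(em, genes, baseline) {
  stopifnot(inherits(em, "ExpressionMatrix"), baseline %in% em$stages)
  floors <- 1e6 / em$clean_totals
  tpm <- em$tpm[genes, , drop = FALSE]
  fl <- sweep(tpm, 2, floors, FUN = pmax)
  lr <- log2(fl / fl[, baseline])
  data.table::data.table(
    gene = rep(genes, times = length(em$stages)),
    stage = rep(em$stages, each = length(genes)),
    log2_ratio = as.vector(lr))
}
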