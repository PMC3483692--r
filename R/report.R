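# Accounting summary (per-library tag bookkeeping table) and the
# end-to-end pipeline driver.

#' Per-library tag-accounting summary table
#'
#' Reproduces the layout of a tag-accounting overview: one row per library
#' with clean-tag total, unambiguous tags (n, % of clean), unambiguous
#' tag-matched genes (n, % of taggable genes), unknown tags (n, % of
#' clean), plus a final "Total" row (column sums) and an "Average" row
#' (column means rounded half-up to the nearest integer; percentages in
#' both recomputed from the row's own absolute numbers).
#'
#' @param accounting data.frame with columns `label`, `clean`,
#'   `unambiguous`, `unambiguous_genes`, `unknown` (as produced by
#'   [accounting_from_mappings()], or entered directly from a printed
#'   table). Missing count columns are allowed and yield NA columns.
#' @param gene_denominator denominator for the gene percentage column
#'   (printed accounting tables typically use the full reference gene
#'   count); NA to skip the percentage.
#' @return `data.table` with absolute and percentage (character, 2-decimal)
#'   columns and the Total/Average rows appended.
#' @export
summary_table <- function(accounting, gene_denominator = NA_integer_) {
  acc <- data.table::as.data.table(accounting)
  if (!nrow(acc)) {
    return(data.table::data.table(
      label = character(), clean = numeric(), unambiguous = numeric(),
      unambiguous_pct = character(), unambiguous_genes = numeric(),
      unambiguous_genes_pct = character(), unknown = numeric(),
      unknown_pct = character()))
  }
  stopifnot("label" %in% names(acc), "clean" %in% names(acc))
  for (col in c("unambiguous", "unambiguous_genes", "unknown"))
    if (!col %in% names(acc)) acc[[col]] <- NA_real_
  num <- c("clean", "unambiguous", "unambiguous_genes", "unknown")
  tot <- c(label = "Total", as.list(acc[, lapply(.SD, function(x)
    if (all(is.na(x))) NA_real_ else sum(x)), .SDcols = num]))
  avg <- c(label = "Average", as.list(acc[, lapply(.SD, function(x)
    if (all(is.na(x))) NA_real_ else round_half_up(mean(x))), .SDcols = num]))
  out <- data.table::rbindlist(list(acc[, c("label", num), with = FALSE],
                                    tot, avg), use.names = TRUE)
  pct <- function(n, d) ifelse(is.na(n) | is.na(d) | d <= 0, NA_character_,
                               format_pct(n, d))
  out$unambiguous_pct <- pct(out$unambiguous, out$clean)
  out$unambiguous_genes_pct <- pct(out$unambiguous_genes,
                                   rep(gene_denominator, nrow(out)))
  out$unknown_pct <- pct(out$unknown, out$clean)
  data.table::setcolorder(out, c("label", "clean", "unambiguous",
                                 "unambiguous_pct", "unambiguous_genes",
                                 "unambiguous_genes_pct", "unknown", "unknown_pct"))
  out[]
}

#' Build the accounting rows from mapping results
#'
#' @param mappings list of `MappingResult`.
#' @return data.table suitable for [summary_table()].
#' @export
accounting_from_mappings <- function(mappings) {
  data.table::rbindlist(lapply(mappings, function(m) data.table::data.table(
    label = m$label, clean = m$clean_tag_total,
    unambiguous = m$unambiguous_tag_total,
    unambiguous_genes = m$unambiguous_gene_count,
    unknown = m$unknown_tag_total)))
}

#' Pipeline configuration
#'
#' @param fasta reference transcriptome FASTA path.
#' @param tag_files named character vector stage label -> raw tag TSV path.
#' @param stages ordered stage labels (default: names of `tag_files`).
#' @param windows process windows passed to [stage_design()].
#' @param ct_file optional qRT-PCR Ct TSV (gene, stage, target_ct,
#'   reference_ct).
#' @param adaptor_prefixes adaptor prefixes for [filter_raw_tags()].
#' @param tpm_min,p_max,lfc_min,fdr_max DE filter thresholds.
#' @param multiread_cap multi-read gene-set cap.
#' @param cluster_k number of expression types, or "auto".
#' @param seed RNG seed for clustering restarts.
#' @return validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(fasta, tag_files, stages = names(tag_files),
                            windows = NULL, ct_file = NULL,
                            adaptor_prefixes = character(),
                            tpm_min = 20, p_max = 0.001, lfc_min = 1,
                            fdr_max = 0.05, multiread_cap = 20L,
                            cluster_k = 5L, seed = 1L) {
  stopifnot(length(stages) >= 2L, all(stages %in% names(tag_files)),
            tpm_min > 0, p_max > 0, lfc_min > 0, fdr_max > 0)
  structure(list(fasta = fasta, tag_files = tag_files, stages = stages,
                 windows = windows, ct_file = ct_file,
                 adaptor_prefixes = adaptor_prefixes,
                 tpm_min = tpm_min, p_max = p_max, lfc_min = lfc_min,
                 fdr_max = fdr_max, multiread_cap = as.integer(multiread_cap),
                 cluster_k = cluster_k, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the whole tag-DGE pipeline
#'
#' reference DB -> cleaning -> mapping -> expression matrix -> pairwise DE
#' over the design comparisons -> up/down histogram, process Venn,
#' profile clustering of DE genes -> optional qRT-PCR concordance.
#' Failures abort with the stage named. When `outdir` is given, all module
#' TSV outputs plus a manifest (input checksums, seed, package version)
#' are written there.
#'
#' @param config a `PipelineConfig`.
#' @param outdir optional output directory.
#' @return list with `db`, `libraries` (clean), `mappings`, `matrix`,
#'   `de`, `design`, `histogram`, `venn`, `clusters`, `summary`,
#'   `crossval` (NULL without Ct input).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  for (st in config$stages)
    if (!file.exists(config$tag_files[[st]]))
      stop("pipeline stage 'input' failed: tag file missing for stage '", st, "'")
  db <- step("refdb", index_db(build_db(config$fasta)))
  libs <- step("preprocess", lapply(config$stages, function(st)
    filter_raw_tags(read_tag_tsv(config$tag_files[[st]], label = st),
                    adaptor_prefixes = config$adaptor_prefixes)))
  names(libs) <- config$stages
  mappings <- step("tagmap", lapply(libs, map_library, db = db))
  em <- step("quantify", build_expression_matrix(mappings, cap = config$multiread_cap))
  design <- step("design", stage_design(config$stages, config$windows))
  de <- step("detest", call_de_all(em, design$comparisons,
                                   tpm_min = config$tpm_min, p_max = config$p_max,
                                   lfc_min = config$lfc_min, fdr_max = config$fdr_max))
  hist <- step("trajectory", updown_histogram(de, design))
  venn <- step("trajectory", process_venn(de, design))
  de_genes <- sort(unique(unlist(lapply(de, function(d) d$gene[d$is_de]))))
  clusters <- if (length(de_genes) >= 12L && length(config$stages) >= 3L)
    step("trajectory", cluster_profiles(em, genes = de_genes, k = config$cluster_k,
                                        seed = config$seed)) else NULL
  summary <- step("report", summary_table(accounting_from_mappings(mappings),
                                          gene_denominator = db$gene_count))
  cv <- NULL
  if (!is.null(config$ct_file)) {
    cv <- step("crossval", {
      ct <- data.table::fread(config$ct_file, sep = "\t")
      baseline <- config$stages[1]
      q <- relative_expression(ct, baseline)
      genes <- intersect(unique(q$gene), rownames(em$tpm))
      rs <- rnaseq_ratios(em, genes, baseline)
      list(qpcr = q,
           overall = platform_correlation(rs, q, "overall"),
           per_stage = platform_correlation(rs, q, "per_stage"))
    })
  }
  res <- list(db = db, libraries = libs, mappings = mappings, matrix = em,
              de = de, design = design, histogram = hist, venn = venn,
              clusters = clusters, summary = summary, crossval = cv)
  if (!is.null(outdir)) write_pipeline_outputs(res, config, outdir)
  res
}

write_pipeline_outputs <- function(res, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  write_db(res$db, out("refdb.tsv"))
  write_expression_tsv(res$matrix, out("expression.tsv"))
  for (cp in names(res$de))
    data.table::fwrite(res$de[[cp]], out(paste0("de_", gsub(":", "_vs_", cp), ".tsv")),
                       sep = "\t")
  data.table::fwrite(res$histogram, out("updown.tsv"), sep = "\t")
  venn_dt <- data.table::data.table(region = names(res$venn$regions),
                                    n_genes = as.integer(res$venn$regions))
  data.table::fwrite(venn_dt, out("venn.tsv"), sep = "\t")
  if (!is.null(res$clusters)) {
    data.table::fwrite(res$clusters$assignment, out("clusters.tsv"), sep = "\t")
    centers <- data.table::as.data.table(res$clusters$centers)
    centers <- cbind(data.table::data.table(type = seq_len(nrow(res$clusters$centers))), centers)
    data.table::fwrite(centers, out("cluster_centers.tsv"), sep = "\t")
  }
  data.table::fwrite(res$summary, out("summary.tsv"), sep = "\t")
  if (!is.null(res$crossval)) {
    data.table::fwrite(res$crossval$qpcr, out("qpcr_ratios.tsv"), sep = "\t")
    data.table::fwrite(data.table::rbindlist(list(res$crossval$overall,
                                                  res$crossval$per_stage)),
                       out("platform_correlation.tsv"), sep = "\t")
  }
  inputs <- c(config$fasta, unlist(config$tag_files), config$ct_file)
  manifest <- data.table::data.table(
    field = c("package_version", "seed", paste0("md5_", basename(inputs))),
    value = c(as.character(utils::packageVersion("tagdge")),
              as.character(config$seed),
              unname(tools::md5sum(inputs))))
  data.table::fwrite(manifest, out("manifest.tsv"), sep = "\t")
  invisible(outdir)
}
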