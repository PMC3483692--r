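# Gene-level quantification: unambiguous counts, proportional multi-read
# distribution (capped at 20 candidate genes), TPM, and saturation curves.

#' Per-gene unambiguous tag counts for one library
#'
#' @param mapping a `MappingResult`.
#' @return named numeric vector gene -> summed counts of unambiguous tags.
#' @export
gene_counts <- function(mapping) {
  status <- NULL
  a <- mapping$assignments[status == "unambiguous"]
  if (!nrow(a)) return(setNames(numeric(), character()))
  v <- tapply(a$count, a$genes, sum)
  setNames(as.numeric(v), names(v))
}

#' Distribute ambiguous tag counts across candidate genes
#'
#' Each ambiguous tag matching between 2 and `cap` genes has its count split
#' across those genes in proportion to their unambiguous counts (the
#' unique-read evidence). Tags matching more than `cap` genes are discarded
#' and accounted. If every candidate gene has unambiguous count 0 the count
#' is split equally. One proportional pass, no iteration.
#'
#' @param mapping a `MappingResult`.
#' @param counts named vector of unambiguous counts ([gene_counts()]).
#' @param cap maximum number of candidate genes (default 20).
#' @return list with `distributed` (named vector: gene -> unambiguous +
#'   allocated ambiguous mass, fractional) and `discarded` (tag mass dropped
#'   because the gene set exceeded `cap`).
#' @export
distribute_multireads <- function(mapping, counts = gene_counts(mapping), cap = 20L) {
  status <- n_genes <- NULL
  amb <- mapping$assignments[status == "ambiguous"]
  out <- counts
  discarded <- 0
  if (nrow(amb)) {
    over <- amb$n_genes > cap
    discarded <- sum(amb$count[over])
    amb <- amb[!over]
    for (i in seq_len(nrow(amb))) {
      genes <- strsplit(amb$genes[i], ",", fixed = TRUE)[[1]]
      w <- counts[genes]
      w[is.na(w)] <- 0
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(genes), length(genes))
      add <- amb$count[i] * w
      miss <- setdiff(genes, names(out))
      if (length(miss)) out[miss] <- 0
      out[genes] <- out[genes] + add
    }
  }
  list(distributed = out, discarded = discarded)
}

#' Build a gene-by-stage expression matrix
#'
#' Combines per-library mapping results into raw unambiguous counts,
#' distributed counts (after multi-read allocation) and TPM. TPM is defined
#' per million *clean* tags of the library (not per million mapped tags):
#' `TPM(g,s) = distributed_count(g,s) / clean_tag_total(s) * 1e6`.
#'
#' @param mappings list of `MappingResult`, one per stage, in stage order.
#' @param cap multi-read gene-set cap passed to [distribute_multireads()].
#' @return object of class `ExpressionMatrix`: list with matrices `counts`
#'   (raw unambiguous), `distributed`, `tpm` (genes x stages), vector
#'   `clean_totals`, vector `discarded`, and `stages`.
#' @export
build_expression_matrix <- function(mappings, cap = 20L) {
  stages <- vapply(mappings, `[[`, "", "label")
  if (anyDuplicated(stages)) stop("duplicate stage labels")
  per_stage <- lapply(mappings, function(m) {
    cc <- gene_counts(m)
    d <- distribute_multireads(m, cc, cap = cap)
    list(counts = cc, distributed = d$distributed, discarded = d$discarded)
  })
  genes <- sort(unique(unlist(lapply(per_stage, function(p) names(p$distributed)))))
  grab <- function(field) {
    m <- vapply(per_stage, function(p) {
      v <- p[[field]][genes]
      v[is.na(v)] <- 0
      v
    }, numeric(length(genes)))
    m <- matrix(m, nrow = length(genes), dimnames = list(genes, stages))
    m
  }
  em <- list(
    counts = grab("counts"),
    distributed = grab("distributed"),
    tpm = NULL,
    clean_totals = setNames(vapply(mappings, `[[`, 0, "clean_tag_total"), stages),
    discarded = setNames(vapply(per_stage, `[[`, 0, "discarded"), stages),
    stages = stages)
  class(em) <- "ExpressionMatrix"
  tpm(em)
}

#' Construct an expression matrix directly from gene-level counts
#'
#' For count-level work (simulation studies, external count tables) where
#' no tag mapping is involved: distributed counts equal the raw counts and
#' TPM is computed against the supplied clean-tag totals.
#'
#' @param counts numeric gene x stage matrix with dimnames.
#' @param clean_totals per-stage clean-tag totals (named or in column
#'   order).
#' @return an `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, clean_totals) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)),
            length(clean_totals) == ncol(counts))
  if (is.null(names(clean_totals))) names(clean_totals) <- colnames(counts)
  em <- list(counts = counts, distributed = counts, tpm = NULL,
             clean_totals = clean_totals[colnames(counts)],
             discarded = setNames(rep(0, ncol(counts)), colnames(counts)),
             stages = colnames(counts))
  class(em) <- "ExpressionMatrix"
  tpm(em)
}

#' Fill the TPM slot of an expression matrix
#'
#' @param matrix an `ExpressionMatrix` with `distributed` and `clean_totals`.
#' @return the matrix with `tpm` computed; errors if any stage has zero
#'   clean tags.
#' @export
tpm <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (any(matrix$clean_totals <= 0))
    stop("zero clean-tag total for stage(s): ",
         paste(names(matrix$clean_totals)[matrix$clean_totals <= 0], collapse = ", "))
  matrix$tpm <- sweep(matrix$distributed, 2, matrix$clean_totals, "/") * 1e6
  matrix
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d stages (%s)\n",
              nrow(x$distributed), length(x$stages),
              paste(x$stages, collapse = ", ")))
  invisible(x)
}

#' Write an expression matrix as TSV
#'
#' One row per gene; per-stage raw count, distributed count and TPM columns.
#' @param em an `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression_tsv <- function(em, path) {
  d <- data.table::data.table(gene = rownames(em$distributed))
  for (s in em$stages) {
    d[[paste0("count_", s)]] <- em$counts[, s]
    d[[paste0("distributed_", s)]] <- em$distributed[, s]
    d[[paste0("tpm_", s)]] <- em$tpm[, s]
  }
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Sequencing saturation curve
#'
#' Subsamples the clean library without replacement at each fraction of the
#' grid (averaged over `reps` draws) and counts genes detected by at least
#' one unambiguous tag, answering whether deeper sequencing would still
#' discover new genes.
#'
#' @param lib a clean `TagLibrary`.
#' @param db a `ReferenceTagDB`.
#' @param grid fractions in (0, 1].
#' @param reps subsample replicates per fraction.
#' @param seed RNG seed.
#' @return `data.table` with columns `fraction`, `tags_sampled`,
#'   `genes_detected` (mean over reps).
#' @export
saturation_curve <- function(lib, db, grid = seq(0.1, 1, by = 0.1),
                             reps = 5L, seed = 1L) {
  stopifnot(all(grid > 0 & grid <= 1), reps >= 1L)
  mapping <- map_library(lib, db)
  a <- mapping$assignments
  unamb <- a$status == "unambiguous"
  # expand to one entry per tag occurrence, carrying its gene (or NA)
  gene_per_occurrence <- rep(ifelse(unamb, a$genes, NA_character_), times = a$count)
  n_total <- length(gene_per_occurrence)
  full <- length(unique(gene_per_occurrence[!is.na(gene_per_occurrence)]))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  res <- lapply(sort(grid), function(f) {
    n <- max(1L, round(f * n_total))
    detected <- if (n >= n_total) rep(full, reps) else
      vapply(seq_len(reps), function(r) {
        s <- gene_per_occurrence[sample.int(n_total, n)]
        length(unique(s[!is.na(s)]))
      }, 1L)
    data.table::data.table(fraction = f, tags_sampled = n,
                           genes_detected = mean(detected))
  })
  out <- data.table::rbindlist(res)
  out$genes_detected <- cummax(out$genes_detected)  # monotone by construction
  out[]
}
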