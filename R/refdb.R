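# Virtual reference tag database: every NlaIII-anchored 21-bp tag
# (CATG + 17 nt) a transcript can yield, on both strands.

#' Extract all virtual 21-bp tags from one transcript sequence
#'
#' The tag-library protocol digests cDNA with NlaIII (recognition site CATG)
#' and releases, via MmeI, a 21-bp fragment consisting of the 4-bp CATG site
#' plus the 17 nt downstream. This function enumerates every such window that
#' is fully contained in the sense sequence and in its reverse complement
#' (unigene orientation is generally unknown for EST assemblies, so both
#' strands are indexed). Windows containing characters outside \{A,C,G,T\}
#' are skipped, since they could never be observed as a clean tag.
#'
#' The 3'-most sense-strand site is flagged canonical: it is the site the wet
#' protocol actually captures (NlaIII cuts everywhere, but only the 3'-most
#' CATG remains attached to the bead-bound polyA end). The canonical flag is
#' used by the simulator only; mapping uses all windows.
#'
#' @param gene_id identifier of the transcript.
#' @param sequence nucleotide string (any case; non-ACGT allowed but windows
#'   containing them are skipped).
#' @return `data.table` with columns `tag`, `gene_id`, `strand`
#'   ("sense"/"antisense"), `offset` (0-based CATG start on the named
#'   strand) and `canonical` (logical). Zero rows if no full-length site.
#'   Rows ordered sense 5'->3' then antisense 5'->3'.
#' @export
extract_reference_tags <- function(gene_id, sequence) {
  stopifnot(length(gene_id) == 1L, length(sequence) == 1L)
  seq_up <- toupper(sequence)
  one_strand <- function(s, strand) {
    hits <- gregexpr(ANCHOR, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    starts <- as.integer(hits)
    starts <- starts[starts + TAG_LEN - 1L <= nchar(s)]
    if (!length(starts)) return(NULL)
    tags <- substring(s, starts, starts + TAG_LEN - 1L)
    keep <- !grepl("[^ACGT]", tags)
    if (!any(keep)) return(NULL)
    data.table::data.table(
      tag = tags[keep], gene_id = gene_id, strand = strand,
      offset = starts[keep] - 1L, canonical = FALSE)
  }
  sense <- one_strand(seq_up, "sense")
  anti  <- one_strand(revcomp(seq_up), "antisense")
  if (!is.null(sense)) sense$canonical[nrow(sense)] <- TRUE  # 3'-most sense site
  out <- data.table::rbindlist(list(sense, anti))
  if (!nrow(out)) {
    out <- data.table::data.table(
      tag = character(), gene_id = character(), strand = character(),
      offset = integer(), canonical = logical())
  }
  out[]
}

#' Build the reference tag database from a transcriptome FASTA
#'
#' Aggregates [extract_reference_tags()] over every record. A gene is
#' "taggable" iff it yields at least one full-length CATG+17 window on either
#' strand; untaggable genes are invisible to the assay.
#'
#' @param fasta_path path to a multi-FASTA with unique record ids.
#' @return an object of class `ReferenceTagDB`: a list with `tags` (the
#'   pooled tag table), `gene_ids`, `gene_count`, `taggable_gene_count` and
#'   `fraction_taggable`.
#' @export
build_db <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no records in FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chr <- as.character(seqs)
  tab <- data.table::rbindlist(
    lapply(seq_along(ids), function(i) extract_reference_tags(ids[i], chr[i])))
  taggable <- unique(tab$gene_id)
  db <- list(
    tags = tab,
    gene_ids = ids,
    gene_count = length(ids),
    taggable_gene_count = length(taggable),
    fraction_taggable = length(taggable) / length(ids))
  class(db) <- "ReferenceTagDB"
  db
}

#' @export
print.ReferenceTagDB <- function(x, ...) {
  cat(sprintf("ReferenceTagDB: %d genes, %d taggable (%.2f%%), %d tag records (%d distinct tags)\n",
              x$gene_count, x$taggable_gene_count, 100 * x$fraction_taggable,
              nrow(x$tags), data.table::uniqueN(x$tags$tag)))
  invisible(x)
}

#' Canonical tag per gene
#'
#' @param db a `ReferenceTagDB`.
#' @return named character vector, gene id -> canonical (3'-most sense) tag;
#'   genes without a sense-strand site are absent.
#' @export
canonical_tags <- function(db) {
  canonical <- NULL
  ct <- db$tags[canonical == TRUE]
  setNames(ct$tag, ct$gene_id)
}

#' Write / read a reference tag database as TSV
#'
#' Columns: tag, gene_id, strand, offset, canonical; one-line header.
#'
#' @param db a `ReferenceTagDB`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_db <- function(db, path) {
  out <- data.table::copy(db$tags)
  out$canonical <- as.integer(out$canonical)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_db
#' @param gene_ids full gene-id universe (reconstructs taggable fraction);
#'   defaults to the genes present in the file.
#' @export
read_db <- function(path, gene_ids = NULL) {
  tab <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("tag", "gene_id", "strand"), integer = c("offset", "canonical")))
  tab$canonical <- as.logical(tab$canonical)
  if (is.null(gene_ids)) gene_ids <- unique(tab$gene_id)
  db <- list(
    tags = tab, gene_ids = gene_ids, gene_count = length(gene_ids),
    taggable_gene_count = data.table::uniqueN(tab$gene_id),
    fraction_taggable = data.table::uniqueN(tab$gene_id) / length(gene_ids))
  class(db) <- "ReferenceTagDB"
  db
}
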