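# Tag-to-reference mapping with at most one nucleotide mismatch and
# unambiguous / ambiguous / unknown classification.

# distinct (tag, gene) pairs of the DB, keyed by tag for hash joins
db_tag_index <- function(db) {
  idx <- attr(db, ".tag_index")
  if (!is.null(idx)) return(idx)
  tag <- gene_id <- NULL
  idx <- unique(db$tags[, list(tag, gene_id)])
  data.table::setkey(idx, tag)
  idx
}

#' Attach a precomputed tag index to a ReferenceTagDB
#'
#' Avoids re-deriving the keyed (tag, gene) table on every mapping call.
#' @param db a `ReferenceTagDB`.
#' @return the same DB with a cached index attribute.
#' @export
index_db <- function(db) {
  attr(db, ".tag_index") <- db_tag_index(db)
  db
}

# all 3*21 = 63 Hamming-distance-1 neighbours of each query tag
hamming1_neighbors <- function(tags) {
  n <- length(tags)
  if (!n) return(data.table::data.table(query = character(), variant = character()))
  bases <- c("A", "C", "G", "T")
  m <- matrix(unlist(strsplit(tags, ""), use.names = FALSE), nrow = TAG_LEN)
  out_q <- vector("list", TAG_LEN)
  out_v <- vector("list", TAG_LEN)
  for (pos in seq_len(TAG_LEN)) {
    orig <- m[pos, ]
    subs <- lapply(bases, function(b) {
      keep <- orig != b
      if (!any(keep)) return(NULL)
      mm <- m[, keep, drop = FALSE]
      mm[pos, ] <- b
      list(q = tags[keep], v = apply(mm, 2, paste, collapse = ""))
    })
    subs <- subs[!vapply(subs, is.null, TRUE)]
    out_q[[pos]] <- unlist(lapply(subs, `[[`, "q"), use.names = FALSE)
    out_v[[pos]] <- unlist(lapply(subs, `[[`, "v"), use.names = FALSE)
  }
  data.table::data.table(query = unlist(out_q), variant = unlist(out_v))
}

#' Map one clean tag against the reference tag database
#'
#' Exact hits take precedence: if the tag matches any reference tag
#' verbatim, the matched gene set is the union of exact hits (distance 0)
#' and distance-1 neighbours are never consulted. Otherwise all 63
#' single-substitution variants are looked up (distance 1). Status is
#' "unambiguous" for a single matched gene, "ambiguous" for several, and
#' "unknown" for none.
#'
#' @param tag 21-bp clean tag (A/C/G/T only).
#' @param db a `ReferenceTagDB`.
#' @return list with `status`, `genes` (character vector) and `distance`
#'   (0, 1, or NA for unknown).
#' @export
map_tag <- function(tag, db) {
  stopifnot(nchar(tag) == TAG_LEN, !grepl("[^ACGT]", tag))
  idx <- db_tag_index(db)
  hit <- idx[tag, on = "tag", nomatch = NULL]
  if (nrow(hit)) {
    g <- unique(hit$gene_id)
    return(list(status = if (length(g) == 1L) "unambiguous" else "ambiguous",
                genes = g, distance = 0L))
  }
  nb <- hamming1_neighbors(tag)
  hit <- idx[nb$variant, on = "tag", nomatch = NULL]
  if (nrow(hit)) {
    g <- unique(hit$gene_id)
    return(list(status = if (length(g) == 1L) "unambiguous" else "ambiguous",
                genes = g, distance = 1L))
  }
  list(status = "unknown", genes = character(), distance = NA_integer_)
}

#' Map a whole clean library against the reference tag database
#'
#' Vectorized version of [map_tag()] over all distinct tags of the library,
#' aggregating totals weighted by tag counts. Every clean tag receives
#' exactly one status, so the three totals partition `clean_tag_total`.
#'
#' @param lib a clean `TagLibrary` (output of [filter_raw_tags()]).
#' @param db a `ReferenceTagDB`.
#' @return object of class `MappingResult`: list with `label`,
#'   `assignments` (data.table: tag, count, status, distance, n_genes,
#'   genes as comma-joined string), per-status tag totals and distinct-tag
#'   counts, `unambiguous_gene_count`, and `clean_tag_total`.
#' @export
map_library <- function(lib, db) {
  stopifnot(inherits(lib, "TagLibrary"))
  idx <- db_tag_index(db)
  tags <- names(lib$tags)
  counts <- as.numeric(lib$tags)
  n <- length(tags)
  genes_of <- function(queries) {
    # query -> sorted unique gene vector (list), via one keyed join
    if (!length(queries)) return(list())
    hit <- idx[data.table::data.table(tag = queries), on = "tag",
               nomatch = NULL, allow.cartesian = TRUE]
    split(hit$gene_id, hit$tag)
  }
  status <- rep("unknown", n)
  distance <- rep(NA_integer_, n)
  gene_sets <- vector("list", n)

  exact <- genes_of(tags)
  hit0 <- tags %in% names(exact)
  gene_sets[hit0] <- lapply(exact[tags[hit0]], unique)
  distance[hit0] <- 0L

  if (any(!hit0)) {
    nb <- hamming1_neighbors(tags[!hit0])
    hit <- idx[nb, on = c(tag = "variant"), nomatch = NULL,
               allow.cartesian = TRUE]
    if (nrow(hit)) {
      by_query <- split(hit$gene_id, hit$query)
      i1 <- which(!hit0)[match(names(by_query), tags[!hit0])]
      gene_sets[i1] <- lapply(by_query, unique)
      distance[i1] <- 1L
    }
  }
  ng <- vapply(gene_sets, length, 1L)
  status[ng == 1L] <- "unambiguous"
  status[ng >= 2L] <- "ambiguous"

  assignments <- data.table::data.table(
    tag = tags, count = counts, status = status, distance = distance,
    n_genes = ng,
    genes = vapply(gene_sets, function(g)
      paste(sort(g), collapse = ","), character(1)))
  tot <- function(s) sum(counts[status == s])
  res <- list(
    label = lib$label,
    assignments = assignments,
    clean_tag_total = sum(counts),
    unambiguous_tag_total = tot("unambiguous"),
    ambiguous_tag_total = tot("ambiguous"),
    unknown_tag_total = tot("unknown"),
    distinct_unambiguous = sum(status == "unambiguous"),
    distinct_ambiguous = sum(status == "ambiguous"),
    distinct_unknown = sum(status == "unknown"),
    unambiguous_gene_count = length(unique(unlist(gene_sets[status == "unambiguous"]))))
  class(res) <- "MappingResult"
  res
}

#' @export
print.MappingResult <- function(x, ...) {
  cat(sprintf(
    "MappingResult '%s': clean %.0f | unambiguous %.0f (%s%%) | ambiguous %.0f | unknown %.0f (%s%%) | genes %d\n",
    x$label, x$clean_tag_total, x$unambiguous_tag_total,
    if (x$clean_tag_total > 0) format_pct(x$unambiguous_tag_total, x$clean_tag_total) else "NA",
    x$ambiguous_tag_total, x$unknown_tag_total,
    if (x$clean_tag_total > 0) format_pct(x$unknown_tag_total, x$clean_tag_total) else "NA",
    x$unambiguous_gene_count))
  invisible(x)
}
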