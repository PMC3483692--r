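# Raw-tag cleaning: adaptor, ambiguous-base ('N') and singleton filters.

#' Construct a tag library
#'
#' A tag library is one sequencing library reduced to a tag -> count
#' multiset plus accounting counters filled in by [filter_raw_tags()].
#'
#' @param label stage label (e.g. "0h", "NEC").
#' @param tags named integer vector: 21-bp tag sequence -> positive count.
#' @return object of class `TagLibrary`.
#' @export
tag_library <- function(label, tags) {
  counts <- as.integer(tags)
  stopifnot(length(label) == 1L, all(counts > 0), !is.null(names(tags)))
  if (anyDuplicated(names(tags))) {
    counts <- tapply(counts, names(tags), sum)
    tags <- setNames(as.integer(counts), names(counts))
  } else names(counts) <- names(tags)
  if (is.null(dim(counts))) tags <- counts
  structure(list(label = label, tags = tags,
                 counters = list(raw_tag_total = sum(as.numeric(tags)))),
            class = "TagLibrary")
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary '%s': %d distinct tags, %.0f total\n",
              x$label, length(x$tags), sum(as.numeric(x$tags))))
  if (!is.null(x$counters$clean_tag_total))
    cat(sprintf("  clean: %.0f (removed: adaptor %.0f, N %.0f, singleton %.0f, malformed %.0f)\n",
                x$counters$clean_tag_total, x$counters$removed_adaptor,
                x$counters$removed_N, x$counters$removed_singleton,
                x$counters$removed_malformed))
  invisible(x)
}

#' Clean a raw tag library
#'
#' Removal rules, applied in this fixed order so the counters are
#' unambiguous:
#' \enumerate{
#'   \item tags whose length differs from 21 (malformed);
#'   \item tags beginning with any adaptor prefix;
#'   \item tags containing a character outside \{A,C,G,T\} (the 'N' filter);
#'   \item tags with a library copy number of exactly 1 (probable
#'     sequencing error), evaluated on the multiset that survives the
#'     earlier rules.
#' }
#'
#' @param raw a `TagLibrary` of raw tags.
#' @param adaptor_prefixes character vector of adaptor prefixes to strip
#'   (prefix match); empty by default.
#' @return a clean `TagLibrary` with all counters populated:
#'   `raw_tag_total`, `clean_tag_total`, `removed_adaptor`, `removed_N`,
#'   `removed_singleton`, `removed_malformed`.
#' @export
filter_raw_tags <- function(raw, adaptor_prefixes = character()) {
  stopifnot(inherits(raw, "TagLibrary"))
  tags <- raw$tags
  n_raw <- sum(as.numeric(tags))

  bad_len <- nchar(names(tags)) != TAG_LEN
  removed_malformed <- sum(as.numeric(tags[bad_len]))
  tags <- tags[!bad_len]

  if (length(adaptor_prefixes) && length(tags)) {
    pat <- paste0("^(", paste(adaptor_prefixes, collapse = "|"), ")")
    is_adaptor <- grepl(pat, names(tags))
  } else is_adaptor <- rep(FALSE, length(tags))
  removed_adaptor <- sum(as.numeric(tags[is_adaptor]))
  tags <- tags[!is_adaptor]

  has_n <- grepl("[^ACGT]", names(tags))
  removed_N <- sum(as.numeric(tags[has_n]))
  tags <- tags[!has_n]

  singleton <- tags == 1L
  removed_singleton <- sum(as.numeric(tags[singleton]))
  tags <- tags[!singleton]

  out <- structure(list(label = raw$label, tags = tags, counters = list(
    raw_tag_total = n_raw,
    clean_tag_total = sum(as.numeric(tags)),
    removed_adaptor = removed_adaptor,
    removed_N = removed_N,
    removed_singleton = removed_singleton,
    removed_malformed = removed_malformed)), class = "TagLibrary")
  stopifnot(out$counters$raw_tag_total ==
              out$counters$clean_tag_total + removed_adaptor + removed_N +
              removed_singleton + removed_malformed)
  out
}

#' Read / write a tag library as two-column TSV (tag, count)
#'
#' @param path TSV path with header `tag<TAB>count`.
#' @param label stage label to attach.
#' @return a `TagLibrary` / the path, invisibly.
#' @export
read_tag_tsv <- function(path, label = sub("\\.[^.]*$", "", basename(path))) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = list(character = 1L, integer = 2L))
  tag_library(label, setNames(d[[2L]], d[[1L]]))
}

#' @rdname read_tag_tsv
#' @param lib a `TagLibrary`.
#' @export
write_tag_tsv <- function(lib, path) {
  data.table::fwrite(
    data.table::data.table(tag = names(lib$tags), count = as.integer(lib$tags)),
    path, sep = "\t")
  invisible(path)
}
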