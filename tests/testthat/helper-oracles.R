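# Independent brute-force oracles used across test files. Each is written
# as the most literal possible statement of the rule it checks, with no
# shared code paths with the package implementation.

oracle_random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

# position-by-position scan of one strand for CATG + 17 clean windows
oracle_scan_strand <- function(s) {
  hits <- list()
  for (i in seq_len(max(0, nchar(s) - 20))) {
    w <- substr(s, i, i + 20)
    if (substr(w, 1, 4) == "CATG" && !grepl("[^ACGT]", w))
      hits[[length(hits) + 1]] <- list(tag = w, offset = i - 1L)
  }
  hits
}

# every tag a gene can yield, both strands
oracle_extract_tags <- function(s) {
  s <- toupper(s)
  sense <- oracle_scan_strand(s)
  anti <- oracle_scan_strand(oracle_revcomp(s))
  list(sense = sense, antisense = anti)
}

# Hamming distance between two equal-length strings
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# classify one tag against a (tag, gene) table by full scan
oracle_map_tag <- function(tag, db_tags, db_genes) {
  d <- vapply(db_tags, oracle_hamming, 1L, a = tag)
  exact <- unique(db_genes[d == 0])
  if (length(exact))
    return(list(status = if (length(exact) == 1) "unambiguous" else "ambiguous",
                genes = sort(exact), distance = 0L))
  near <- unique(db_genes[d == 1])
  if (length(near))
    return(list(status = if (length(near) == 1) "unambiguous" else "ambiguous",
                genes = sort(near), distance = 1L))
  list(status = "unknown", genes = character(), distance = NA_integer_)
}

# literal application of the three cleaning rules, in order
oracle_clean <- function(tags, adaptor_prefixes = character()) {
  tags <- tags[nchar(names(tags)) == 21]
  if (length(adaptor_prefixes)) {
    for (p in adaptor_prefixes) tags <- tags[!startsWith(names(tags), p)]
  }
  tags <- tags[!grepl("[^ACGT]", names(tags))]
  tags[tags != 1]
}

# Audic-Claverie one-point posterior mass by direct log-space summation
oracle_ac_pointmass <- function(k, x, N1, N2) {
  exp(k * log(N2 / N1) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
        (x + k + 1) * log(1 + N2 / N1))
}

oracle_ac_p <- function(x, y, N1, N2) {
  # sum both tails directly so each retains full relative precision
  K <- ceiling(max(1000, 20 * (x + 10) * N2 / N1, 5 * y))
  mass <- oracle_ac_pointmass(0:K, x, N1, N2)
  lower <- sum(mass[1:(y + 1)])
  upper <- sum(mass[(y + 2):(K + 1)])    # strict upper tail P(Y > y)
  min(1, 2 * min(lower, upper))
}

# BH step-up from its definition: sort ascending, q(i) = min_{j >= i} m p(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))), 0)
  out <- numeric(m)
  out[o] <- q
  out
}

# within-cluster sum of squared Euclidean distances to cluster means
oracle_wss <- function(z, cl) {
  sum(vapply(unique(cl), function(j) {
    zz <- z[cl == j, , drop = FALSE]
    c0 <- colMeans(zz)
    sum(sweep(zz, 2, c0)^2)
  }, 0))
}

# exhaustive best 2-partition of n rows under the wss objective
oracle_best_bipartition <- function(z) {
  n <- nrow(z)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    cl <- as.integer(intToBits(mask))[1:n] + 1L
    if (length(unique(cl)) < 2) next
    w <- oracle_wss(z, cl)
    if (w < best) best <- w
  }
  best
}

# build a tiny reference DB in code from explicit sequences
make_db <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fa)
  tagdge::build_db(fa)
}

# gene x stage count matrix wrapped as an ExpressionMatrix
make_matrix <- function(counts, totals) {
  tagdge::expression_matrix(counts, totals)
}
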