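# hand-built MappingResult, bypassing sequence-level machinery
fake_mapping <- function(label, tags) {
  a <- data.table::rbindlist(lapply(tags, function(t)
    data.table::data.table(tag = t$tag, count = t$count, status = t$status,
                           distance = 0L, n_genes = length(t$genes),
                           genes = paste(sort(t$genes), collapse = ","))))
  structure(list(label = label, assignments = a,
                 clean_tag_total = sum(a$count),
                 unambiguous_tag_total = sum(a$count[a$status == "unambiguous"]),
                 ambiguous_tag_total = sum(a$count[a$status == "ambiguous"]),
                 unknown_tag_total = sum(a$count[a$status == "unknown"]),
                 unambiguous_gene_count = length(unique(unlist(
                   lapply(tags, function(t) if (t$status == "unambiguous") t$genes))))),
            class = "MappingResult")
}

tg <- function(tag, count, status, genes = character()) {
  list(tag = tag, count = count, status = status, genes = genes)
}

test_that("gene counts sum unambiguous tag counts per gene", {
  m <- fake_mapping("L", list(
    tg("t1", 30, "unambiguous", "g"),
    tg("t2", 12, "unambiguous", "g"),
    tg("t3", 7, "ambiguous", c("g", "h")),
    tg("t4", 4, "unknown")))
  cc <- gene_counts(m)
  expect_equal(cc[["g"]], 42)
  expect_false("h" %in% names(cc))  # only ambiguous evidence -> raw count 0
})

test_that("multi-read distribution splits proportionally, equally on zero evidence, and caps", {
  m <- fake_mapping("L", list(
    tg("u1", 30, "unambiguous", "a"),
    tg("u2", 10, "unambiguous", "b"),
    tg("m1", 10, "ambiguous", c("a", "b")),
    tg("m2", 10, "ambiguous", c("c", "d")),
    tg("m3", 50, "ambiguous", paste0("z", 1:25))))
  d <- distribute_multireads(m)
  expect_equal(d$distributed[["a"]], 37.5)
  expect_equal(d$distributed[["b"]], 12.5)
  expect_equal(d$distributed[["c"]], 5)
  expect_equal(d$distributed[["d"]], 5)
  expect_equal(d$discarded, 50)
  expect_false(any(grepl("^z", names(d$distributed))))
})

test_that("multi-read distribution matches an enumeration oracle and conserves mass", {
  set.seed(47)
  genes <- paste0("g", 1:30)
  for (rep in 1:20) {
    unamb <- lapply(sample(genes, 10), function(g)
      tg(paste0("u", g, rep), sample(1:50, 1), "unambiguous", g))
    amb <- lapply(1:50, function(i)
      tg(paste0("m", i), sample(1:30, 1), "ambiguous",
         sample(genes, sample(2:25, 1))))
    m <- fake_mapping("L", c(unamb, amb))
    cc <- gene_counts(m)
    d <- distribute_multireads(m, cc)

    want <- cc
    discarded <- 0
    for (t in amb) {
      if (length(t$genes) > 20) { discarded <- discarded + t$count; next }
      w <- want[t$genes]
      w[is.na(w)] <- 0
      w0 <- cc[t$genes]; w0[is.na(w0)] <- 0   # proportions on unambiguous evidence
      p <- if (sum(w0) > 0) w0 / sum(w0) else rep(1 / length(t$genes), length(t$genes))
      for (j in seq_along(t$genes)) {
        g <- t$genes[j]
        want[g] <- (if (g %in% names(want)) want[g] else 0) + t$count * p[j]
      }
    }
    want <- want[!is.na(want)]
    expect_equal(sort(names(d$distributed)), sort(names(want)))
    expect_equal(d$distributed[sort(names(want))], want[sort(names(want))],
                 tolerance = 1e-12)
    expect_equal(d$discarded, discarded)
    expect_equal(sum(d$distributed) + d$discarded,
                 m$unambiguous_tag_total + m$ambiguous_tag_total)
  }
})

test_that("TPM follows its definition, including the reliability-threshold boundary", {
  counts <- matrix(c(0, 70, 3500000), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "S"))
  em <- expression_matrix(counts, c(S = 3500000))
  expect_equal(em$tpm["a", "S"], 0)
  expect_equal(em$tpm["b", "S"], 20)       # the reliability threshold boundary
  expect_equal(em$tpm["c", "S"], 1e6)
  expect_error(expression_matrix(counts, c(S = 0)), "zero clean-tag")
})

test_that("TPM totals are bounded by one million and mass is conserved end to end", {
  cfg <- simulation_config(n_genes = 80, library_depth = 20000,
                           stages = c("A", "B"), seed = 53)
  ds <- simulate_dataset(cfg)
  db <- index_db(build_db(ds$transcriptome$fasta_path))
  mappings <- lapply(ds$libraries, function(l) map_library(filter_raw_tags(l), db))
  em <- build_expression_matrix(mappings)
  for (s in em$stages) {
    expect_lte(sum(em$tpm[, s]), 1e6 + 1e-6)
    m <- mappings[[s]]
    expect_equal(sum(em$distributed[, s]) + em$discarded[[s]],
                 m$unambiguous_tag_total + m$ambiguous_tag_total)
  }
})

test_that("saturation curve is monotone and exact at fraction 1", {
  cfg <- simulation_config(n_genes = 40, library_depth = 5000,
                           stages = c("A", "B"), seed = 59)
  ds <- simulate_dataset(cfg)
  db <- index_db(build_db(ds$transcriptome$fasta_path))
  clean <- filter_raw_tags(ds$libraries[["A"]])
  m <- map_library(clean, db)
  full_genes <- length(unique(m$assignments$genes[m$assignments$status == "unambiguous"]))
  sat <- saturation_curve(clean, db, grid = seq(0.2, 1, by = 0.2), reps = 3, seed = 1)
  expect_equal(sat$genes_detected[sat$fraction == 1], full_genes)
  expect_true(all(diff(sat$genes_detected) >= 0))
})

test_that("mean saturation at half depth matches the hypergeometric expectation", {
  # 10 genes with known per-gene tag counts totalling 100
  gene_counts_true <- c(30, 20, 15, 10, 8, 6, 5, 3, 2, 1) + 1  # all >= 2, total 110
  genes <- sprintf("g%02d", 1:10)
  set.seed(61)
  seqs <- setNames(vapply(1:10, function(i)
    paste0("CATG", oracle_random_seq(17)), ""), genes)
  db <- make_db(seqs)
  canon <- canonical_tags(db)
  lib <- filter_raw_tags(tag_library("L", setNames(gene_counts_true, canon[genes])))
  N <- sum(gene_counts_true)
  n <- round(0.5 * N)
  expected <- sum(1 - choose(N - gene_counts_true, n) / choose(N, n))
  sat <- saturation_curve(lib, db, grid = 0.5, reps = 800, seed = 2)
  expect_equal(sat$genes_detected, expected, tolerance = 0.03)
})
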