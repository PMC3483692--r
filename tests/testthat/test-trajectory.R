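fake_de <- function(genes, de_flags, comparison, direction = "up") {
  data.table::data.table(
    gene = genes,
    stage_a = sub(":.*", "", comparison), stage_b = sub(".*:", "", comparison),
    is_de = de_flags,
    direction = if (length(direction) == 1) rep(direction, length(genes)) else direction,
    log2_ratio = ifelse(de_flags, 2, 0))
}

test_that("the default nine-stage design defines three disjoint covering windows", {
  d <- stage_design()
  expect_equal(length(d$comparisons), 8L)
  expect_equal(d$windows$dedifferentiation, c("0h:6h", "6h:24h", "24h:48h", "48h:NEC"))
  expect_equal(d$windows$transition, "NEC:EC")
  expect_equal(d$windows$development, c("EC:GE", "GE:TE", "TE:CE"))
  expect_false(anyDuplicated(unlist(d$windows)) > 0)
  expect_error(stage_design(c("a", "b", "c"),
                            windows = list(w1 = "a:c")), "consecutive")
  expect_error(stage_design(c("a", "b", "c"),
                            windows = list(w1 = "a:b", w2 = c("a:b", "b:c"))),
               "more than one process")
})

test_that("up/down histogram counts DE genes by direction and errors on gaps", {
  d <- stage_design(c("a", "b", "c"), windows = list(p1 = "a:b", p2 = "b:c"))
  genes <- paste0("g", 1:10)
  de <- list(
    "a:b" = fake_de(genes, c(rep(TRUE, 3), rep(FALSE, 7)), "a:b",
                    c("up", "up", "down", rep("up", 7))),
    "b:c" = fake_de(genes, rep(FALSE, 10), "b:c"))
  h <- updown_histogram(de, d)
  expect_equal(h$n_up, c(2L, 0L))
  expect_equal(h$n_down, c(1L, 0L))
  expect_equal(h$n_up + h$n_down,
               vapply(de, function(x) sum(x$is_de), 0L)[h$comparison],
               ignore_attr = TRUE)
  expect_error(updown_histogram(de["a:b"], d), "missing DE results")
})

test_that("Venn regions match brute-force set algebra on planted membership", {
  set.seed(89)
  d <- stage_design()
  genes <- paste0("g", 1:500)
  for (rep in 1:10) {
    # plant random DE flags for every comparison
    de <- setNames(lapply(d$comparisons, function(cp)
      fake_de(genes, runif(500) < 0.15, cp)), d$comparisons)
    v <- process_venn(de, d)
    member <- vapply(names(d$windows), function(p) {
      Reduce(`|`, lapply(d$windows[[p]], function(cp) de[[cp]]$is_de))
    }, logical(500))
    dd <- member[, "dedifferentiation"]; tt <- member[, "transition"]
    dv <- member[, "development"]
    want <- c(
      "dedifferentiation" = sum(dd & !tt & !dv),
      "transition" = sum(!dd & tt & !dv),
      "development" = sum(!dd & !tt & dv),
      "dedifferentiation+transition" = sum(dd & tt & !dv),
      "dedifferentiation+development" = sum(dd & !tt & dv),
      "transition+development" = sum(!dd & tt & dv),
      "dedifferentiation+transition+development" = sum(dd & tt & dv))
    expect_equal(v$regions[names(want)], want)
    expect_equal(sum(v$regions), sum(rowSums(member) > 0))
    expect_equal(unname(v$process_totals), unname(colSums(member)))
  }
})

test_that("single-process and all-process genes land in the right regions", {
  d <- stage_design()
  genes <- c("only_transition", "everywhere")
  de <- setNames(lapply(d$comparisons, function(cp) {
    flags <- c(cp == "NEC:EC",
               cp %in% c("0h:6h", "NEC:EC", "EC:GE"))
    fake_de(genes, flags, cp)
  }), d$comparisons)
  v <- process_venn(de, d)
  expect_equal(unname(v$regions["transition"]), 1L)
  expect_equal(unname(v$regions["dedifferentiation+transition+development"]), 1L)
  expect_equal(v$fraction_all, 0.5)
})

test_that("Pearson distance honours its bounds and conventions", {
  u <- c(1, 2, 3, 4)
  expect_equal(pearson_distance(u, u * 3 + 2), 0)
  expect_equal(pearson_distance(u, -u), 2)
  expect_equal(pearson_distance(u, rep(1, 4)), 1)  # zero-variance convention
})

test_that("identical profiles always co-cluster; k-means descends monotonically", {
  set.seed(97)
  base <- rbind(matrix(rep(c(0, 1, 2, 3, 4, 5), 6), 6, byrow = TRUE),
                matrix(rep(c(5, 4, 3, 2, 1, 0), 6), 6, byrow = TRUE))
  x <- base + matrix(rnorm(72, 0, 0.05), 12)
  x[1, ] <- x[2, ]                       # two identical profiles
  rownames(x) <- paste0("g", 1:12)
  ca <- cluster_profiles(x, k = 2, seed = 1, subclusters = FALSE)
  cl <- ca$assignment$type
  expect_equal(cl[1], cl[2])
  expect_equal(cl[1:6], rep(cl[1], 6))
  expect_equal(cl[7:12], rep(cl[7], 6))
  expect_true(all(diff(ca$objective_trace) <= 1e-9))

  ca2 <- cluster_profiles(x, k = 2, seed = 1, subclusters = FALSE)
  expect_identical(ca$assignment, ca2$assignment)
})

test_that("k-means with restarts attains the exhaustive-search optimum on small instances", {
  set.seed(101)
  for (rep in 1:5) {
    tpl1 <- rnorm(5); tpl2 <- rnorm(5)
    x <- rbind(t(replicate(6, tpl1 + rnorm(5, 0, 0.2))),
               t(replicate(6, tpl2 + rnorm(5, 0, 0.2))))
    rownames(x) <- paste0("g", 1:12)
    ca <- cluster_profiles(x, k = 2, seed = rep, nstart = 20, subclusters = FALSE)
    z <- (x - rowMeans(x)) / apply(x, 1, sd)
    expect_equal(ca$objective, oracle_best_bipartition(z), tolerance = 1e-8)
  }
})

test_that("figure of merit finds the knee at the true number of templates", {
  set.seed(103)
  stages <- 8
  tpls <- list(seq(0, 4, length.out = stages),
               seq(4, 0, length.out = stages),
               c(seq(0, 4, length.out = stages / 2), seq(4, 0, length.out = stages / 2)))
  x <- do.call(rbind, lapply(tpls, function(t)
    t(replicate(20, t + rnorm(stages, 0, 0.35)))))
  rownames(x) <- paste0("g", 1:60)
  fom <- figure_of_merit(x, k_range = 1:6, seed = 7)
  expect_equal(attr(fom, "knee"), 3L)
  # the drop into k = 3 is much larger than the drop beyond it
  f <- fom$fom
  expect_gt((f[2] - f[3]) / f[2], 2 * (f[3] - f[4]) / f[3])

  fom2 <- figure_of_merit(x, k_range = 1:6, seed = 7)
  expect_identical(fom$fom, fom2$fom)
  expect_error(figure_of_merit(x, k_range = 1:60), "smaller")
})

test_that("automatic k selection and sub-clustering produce a full assignment", {
  set.seed(107)
  stages <- 9
  tpls <- list(seq(0, 3, length.out = stages), seq(3, 0, length.out = stages))
  x <- do.call(rbind, lapply(tpls, function(t)
    t(replicate(15, t + rnorm(stages, 0, 0.3)))))
  rownames(x) <- paste0("g", 1:30)
  ca <- cluster_profiles(x, k = "auto", seed = 11)
  expect_equal(ca$k, 2L)
  expect_true(all(!is.na(ca$assignment$type)))
  expect_true(all(ca$assignment$subcluster >= 1))
  # every clustered gene has exactly one (type, subcluster)
  expect_equal(nrow(ca$assignment), 30L)
  expect_equal(anyDuplicated(ca$assignment$gene), 0L)
})
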