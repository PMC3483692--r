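# Stage-structured downstream analysis: per-comparison up/down counts,
# three-process Venn partition, and expression-profile clustering by
# Pearson-distance k-means with figure-of-merit model selection.

#' Staged study design with process windows
#'
#' Defaults describe a somatic-embryogenesis time course: hypocotyl
#' explants (0h) through dedifferentiation (6h, 24h, 48h) to
#' non-embryogenic (NEC) and embryogenic (EC) calli and then globular,
#' torpedo and cotyledon embryos (GE, TE, CE). Consecutive stages form the
#' pairwise comparisons, grouped into three biological processes:
#' dedifferentiation (0h->6h ... 48h->NEC), the NEC->EC transition, and
#' embryo development (EC->GE, GE->TE, TE->CE).
#'
#' @param stages ordered character vector of stage labels.
#' @param windows named list process -> character vector of `"A:B"`
#'   comparisons; every comparison must join consecutive stages and belong
#'   to exactly one process. `NULL` builds the default three windows from
#'   the stage order (requires >= 3 stages).
#' @return object of class `StageDesign` with `stages`, `comparisons`
#'   (all `"A:B"` in order) and `windows`.
#' @export
stage_design <- function(stages = c("0h", "6h", "24h", "48h", "NEC", "EC", "GE", "TE", "CE"),
                         windows = NULL) {
  stopifnot(length(stages) >= 2L, !anyDuplicated(stages))
  consecutive <- paste(stages[-length(stages)], stages[-1], sep = ":")
  if (is.null(windows)) {
    if (length(stages) == 9L) {
      windows <- list(
        dedifferentiation = consecutive[1:4],
        transition = consecutive[5],
        development = consecutive[6:8])
    } else {
      windows <- list(all = consecutive)
    }
  }
  cmp <- unlist(windows, use.names = FALSE)
  if (anyDuplicated(cmp)) stop("a comparison belongs to more than one process")
  if (!all(cmp %in% consecutive))
    stop("process windows must use consecutive-stage comparisons")
  structure(list(stages = stages, comparisons = cmp, windows = windows),
            class = "StageDesign")
}

#' Up/down-regulated gene counts per comparison
#'
#' @param de_results named list of [call_de()] tables covering every design
#'   comparison.
#' @param design a `StageDesign`.
#' @return `data.table` with `comparison`, `n_up`, `n_down`.
#' @export
updown_histogram <- function(de_results, design) {
  miss <- setdiff(design$comparisons, names(de_results))
  if (length(miss)) stop("missing DE results for: ", paste(miss, collapse = ", "))
  data.table::rbindlist(lapply(design$comparisons, function(cp) {
    d <- de_results[[cp]]
    data.table::data.table(
      comparison = cp,
      n_up = sum(d$is_de & d$direction == "up"),
      n_down = sum(d$is_de & d$direction == "down"))
  }))
}

#' Three-process Venn partition of DE genes
#'
#' A gene belongs to a process iff it is DE in at least one comparison of
#' that process's window. Returns all 7 Venn regions (the region counts sum
#' to the number of genes DE in >= 1 process), per-process totals, and the
#' fraction of DE genes present in all processes.
#'
#' @inheritParams updown_histogram
#' @return list with `regions` (named counts, names like "dedifferentiation",
#'   "dedifferentiation+transition", ...), `process_totals`, `n_any`,
#'   `fraction_all`, and `membership` (data.table gene x process logicals).
#' @export
process_venn <- function(de_results, design) {
  procs <- names(design$windows)
  miss <- setdiff(design$comparisons, names(de_results))
  if (length(miss)) stop("missing DE results for: ", paste(miss, collapse = ", "))
  genes <- unique(unlist(lapply(de_results, function(d) d$gene)))
  member <- vapply(procs, function(p) {
    de_in <- lapply(design$windows[[p]], function(cp) {
      d <- de_results[[cp]]
      d$gene[d$is_de]
    })
    genes %in% unique(unlist(de_in))
  }, logical(length(genes)))
  member <- matrix(member, nrow = length(genes), dimnames = list(genes, procs))
  any_de <- rowSums(member) > 0
  key <- apply(member[any_de, , drop = FALSE], 1, function(r)
    paste(procs[r], collapse = "+"))
  all_regions <- unlist(lapply(seq_along(procs), function(k)
    apply(utils::combn(procs, k), 2, paste, collapse = "+")))
  regions <- setNames(integer(length(all_regions)), all_regions)
  tb <- table(key)
  regions[names(tb)] <- as.integer(tb)
  list(
    regions = regions,
    process_totals = colSums(member),
    n_any = sum(any_de),
    fraction_all = if (sum(any_de)) unname(regions[paste(procs, collapse = "+")] / sum(any_de)) else NA_real_,
    membership = data.table::data.table(gene = genes, as.data.frame(member)))
}

# ---- Pearson-distance k-means ------------------------------------------

# Row-standardize so squared Euclidean distance equals 2*(m-1)*(1 - Pearson r):
# z = (x - mean) / sd. Zero-variance rows get z = 0, the vector equidistant
# from all others, implementing the r = 0 (d = 1) convention for flat genes.
standardize_profiles <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

# Lloyd's algorithm on standardized rows. Objective = total within-cluster
# sum of squared distances to centroids, recorded after every assignment
# step (attribute "objective_trace", monotone non-increasing).
kmeans_pearson_once <- function(z, k) {
  n <- nrow(z)
  centers <- z[sample.int(n, k), , drop = FALSE]
  assign_step <- function(centers) {
    d2 <- outer(rowSums(z^2), rowSums(centers^2), "+") - 2 * z %*% t(centers)
    list(cl = max.col(-d2, ties.method = "first"),
         ss = sum(d2[cbind(seq_len(n), max.col(-d2, ties.method = "first"))]))
  }
  cl <- rep(0L, n)
  trace <- numeric()
  for (iter in 1:100) {
    st <- assign_step(centers)
    trace <- c(trace, max(0, st$ss))
    if (identical(st$cl, cl)) break
    cl <- st$cl
    for (j in seq_len(k)) {
      if (any(cl == j)) centers[j, ] <- colMeans(z[cl == j, , drop = FALSE])
      else centers[j, ] <- z[which.max(rowSums((z - centers[cl, , drop = FALSE])^2)), ]
    }
  }
  structure(list(cluster = cl, centers = centers, objective = trace[length(trace)],
                 objective_trace = trace), class = "pearson_kmeans")
}

# best of nstart restarts under the within-cluster objective
kmeans_pearson <- function(z, k, nstart = 10L) {
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- kmeans_pearson_once(z, k)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

#' Figure of merit for choosing the number of expression clusters
#'
#' Leave-one-stage-out predictive deviation: for each left-out stage,
#' genes are clustered on the remaining stages and the FOM contribution is
#' the root-mean-square deviation of the left-out stage's (standardized)
#' values from their cluster means, scaled by the small-cluster adjustment
#' sqrt(n / (n - k)). Contributions are summed over stages. FOM decreases
#' in k on average; the "knee" is the smallest k whose next increment
#' improves FOM by less than 10%.
#'
#' @param matrix an `ExpressionMatrix`, or a plain numeric gene x stage
#'   matrix of log-scale values.
#' @param genes gene subset (default all).
#' @param k_range integers >= 1 to evaluate.
#' @param seed RNG seed (restarts are random).
#' @param nstart k-means restarts per fit.
#' @return `data.table` with `k` and `fom`, plus attribute `knee`.
#' @export
figure_of_merit <- function(matrix, genes = NULL, k_range = 1:8, seed = 1L,
                            nstart = 5L) {
  x <- profile_matrix(matrix, genes)
  if (ncol(x) < 4L) stop("figure of merit needs at least 4 stages")
  if (max(k_range) >= nrow(x)) stop("k must be smaller than the number of genes")
  n <- nrow(x)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fom_k <- vapply(k_range, function(k) {
    contribs <- vapply(seq_len(ncol(x)), function(s) {
      z_train <- standardize_profiles(x[, -s, drop = FALSE])
      cl <- if (k == 1L) rep(1L, n) else kmeans_pearson(z_train, k, nstart)$cluster
      z_all <- standardize_profiles(x)
      left <- z_all[, s]
      pred <- tapply(left, cl, mean)[as.character(cl)]
      sqrt(mean((left - pred)^2)) * sqrt(n / max(1, n - k))
    }, 0)
    sum(contribs)
  }, 0)
  out <- data.table::data.table(k = k_range, fom = fom_k)
  attr(out, "knee") <- fom_knee(k_range, fom_k)
  out
}

# smallest k whose improvement from k to k+1 is < rel_tol of FOM(k)
fom_knee <- function(k_range, fom, rel_tol = 0.10) {
  ord <- order(k_range)
  k_range <- k_range[ord]; fom <- fom[ord]
  for (i in seq_len(length(k_range) - 1L)) {
    if ((fom[i] - fom[i + 1L]) / fom[i] < rel_tol) return(k_range[i])
  }
  k_range[length(k_range)]
}

profile_matrix <- function(matrix, genes = NULL) {
  x <- if (inherits(matrix, "ExpressionMatrix")) log2(matrix$tpm + 1) else matrix
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(x))
    if (length(miss)) stop("genes absent from matrix: ", paste(head(miss, 5), collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  x
}

#' Cluster expression profiles into types and sub-clusters
#'
#' Profiles are log2(TPM + 1), per-gene standardized; the dissimilarity is
#' the Pearson correlation distance 1 - r (realized as squared Euclidean
#' distance on standardized profiles, which k-means minimizes exactly).
#' Top-level k-means yields the expression "types"; within each type,
#' k-means with k = 2..4 chosen by the same figure-of-merit knee rule
#' yields sub-clusters (a type too small to split keeps one sub-cluster).
#'
#' @param matrix an `ExpressionMatrix` or plain gene x stage log-scale matrix.
#' @param genes gene subset to cluster (default all genes).
#' @param k number of types, or `"auto"` to select by figure-of-merit knee
#'   over 2..8.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @param subclusters whether to split each type into sub-clusters.
#' @return object of class `ClusterAssignment`: list with `assignment`
#'   (data.table gene, type, subcluster), `centers` (type centroids on the
#'   standardized scale), `objective`, `objective_trace`, `k`, and `fom`
#'   (when k = "auto").
#' @export
cluster_profiles <- function(matrix, genes = NULL, k = 5L, seed = 1L,
                             nstart = 10L, subclusters = TRUE) {
  x <- profile_matrix(matrix, genes)
  fom_tab <- NULL
  if (identical(k, "auto")) {
    kmax <- min(8L, nrow(x) - 1L)
    fom_tab <- figure_of_merit(x, k_range = 1:kmax, seed = seed)
    k <- max(2L, attr(fom_tab, "knee"))
  }
  k <- as.integer(k)
  if (nrow(x) < k) stop("fewer genes than clusters")
  if (ncol(x) < 3L) stop("need profiles over at least 3 stages")
  z <- standardize_profiles(x)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fit <- kmeans_pearson(z, k, nstart)
  sub <- rep(1L, nrow(z))
  if (subclusters) {
    for (ty in seq_len(k)) {
      idx <- which(fit$cluster == ty)
      if (length(idx) < 8L || ncol(x) < 4L) next
      ksub_max <- min(4L, length(idx) - 1L)
      fom_sub <- figure_of_merit(x[idx, , drop = FALSE],
                                 k_range = 1:ksub_max, seed = seed, nstart = 5L)
      ksub <- attr(fom_sub, "knee")
      if (ksub > 1L) sub[idx] <- kmeans_pearson(z[idx, , drop = FALSE], ksub, nstart)$cluster
    }
  }
  structure(list(
    assignment = data.table::data.table(gene = rownames(x),
                                        type = fit$cluster, subcluster = sub),
    centers = fit$centers,
    objective = fit$objective,
    objective_trace = fit$objective_trace,
    k = k, fom = fom_tab), class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d genes in %d types (objective %.3f)\n",
              nrow(x$assignment), x$k, x$objective))
  print(table(type = x$assignment$type, subcluster = x$assignment$subcluster))
  invisible(x)
}

#' Pearson correlation distance between two profiles
#'
#' `1 - r`; defined as 1 (r = 0 convention) if either profile has zero
#' variance. Range [0, 2].
#' @param u,v numeric vectors of equal length.
#' @export
pearson_distance <- function(u, v) {
  if (sd(u) == 0 || sd(v) == 0) return(1)
  1 - cor(u, v)
}
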