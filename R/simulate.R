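# Synthetic-data generator: a toy transcriptome plus staged tag libraries
# with known ground truth, emulating the statistical structure the
# analysis assumes (stage-dependent abundances spanning several orders of
# magnitude, five archetype trajectories, sequencing error, and adaptor /
# ambiguous-base / singleton / off-reference contamination).

#' Simulation configuration
#'
#' Defaults describe the study conditions at desk scale: 2,000 genes,
#' nine ordered stages, 2e5 clean-target tags per library (the real
#' libraries held ~3.5 M; depth is scaled down, the statistical structure
#' is not), per-base error 1e-3 (typical short-read substitution rate),
#' 94% of genes carrying a usable CATG site, and a 30% off-reference tag
#' stream standing in for transcripts absent from the reference.
#'
#' @param n_genes number of genes.
#' @param gene_length_range min/max transcript length (nt).
#' @param stages ordered stage labels.
#' @param library_depth target number of reference-derived tags per library.
#' @param base_error_rate per-base substitution probability.
#' @param adaptor_fraction,n_fraction,singleton_fraction,offref_fraction
#'   contamination rates, as fractions of `library_depth` added on top.
#' @param taggable_fraction fraction of genes guaranteed a CATG+17 site.
#' @param archetype_mix named proportions over trajectory archetypes
#'   I..V and "flat"; must sum to 1.
#' @param de_log2fc trajectory amplitude (log2) for non-flat archetypes.
#' @param adaptor_seq adaptor sequence used for adaptor contamination.
#' @param seed integer seed; the full dataset is a pure function of the
#'   configuration including the seed.
#' @return object of class `SimulationConfig` (a validated list).
#' @export
simulation_config <- function(
    n_genes = 2000L,
    gene_length_range = c(300L, 1500L),
    stages = c("0h", "6h", "24h", "48h", "NEC", "EC", "GE", "TE", "CE"),
    library_depth = 200000L,
    base_error_rate = 0.001,
    adaptor_fraction = 0.005,
    n_fraction = 0.005,
    singleton_fraction = 0.01,
    offref_fraction = 0.30,
    taggable_fraction = 0.94,
    archetype_mix = c(I = 0.05, II = 0.05, III = 0.05, IV = 0.05, V = 0.05, flat = 0.75),
    de_log2fc = 2,
    adaptor_seq = "TCGGACTGTAGAACTCTGAAC",
    seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              stages = stages, library_depth = as.integer(library_depth),
              base_error_rate = base_error_rate,
              adaptor_fraction = adaptor_fraction, n_fraction = n_fraction,
              singleton_fraction = singleton_fraction,
              offref_fraction = offref_fraction,
              taggable_fraction = taggable_fraction,
              archetype_mix = archetype_mix, de_log2fc = de_log2fc,
              adaptor_seq = adaptor_seq, seed = as.integer(seed))
  probs <- c(cfg$base_error_rate, cfg$adaptor_fraction, cfg$n_fraction,
             cfg$singleton_fraction, cfg$offref_fraction, cfg$taggable_fraction)
  stopifnot(cfg$n_genes >= 1L, cfg$library_depth >= 1L,
            all(probs >= 0 & probs <= 1),
            abs(sum(cfg$archetype_mix) - 1) < 1e-9,
            length(cfg$stages) >= 2L,
            diff(cfg$gene_length_range) >= 0, cfg$gene_length_range[1] >= TAG_LEN + 4L)
  class(cfg) <- "SimulationConfig"
  cfg
}

# Archetype trajectories on the log2 scale over nine stages, amplitude 1
# (scaled by de_log2fc). Shapes follow the five canonical expression types
# of staged embryogenesis series: I monotone up; II monotone down; III up
# during dedifferentiation then down; IV down early then up; V oscillating
# (peaks at 48h and EC); flat. For other stage counts the templates are
# linearly interpolated.
archetype_templates <- function(stages) {
  base <- list(
    I    = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4) / 4,
    II   = -c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4) / 4,
    III  = c(0, 0.6, 1, 1.2, 1.2, 0.4, -0.2, -0.6, -1) / 1.2,
    IV   = -c(0, 0.6, 1, 1.2, 1.2, 0.4, -0.2, -0.6, -1) / 1.2,
    V    = c(0, 0.4, 0.8, 1.2, -0.4, 1.2, 0.2, -0.2, -0.4) / 1.2,
    flat = rep(0, 9))
  m <- length(stages)
  lapply(base, function(tpl) {
    if (m == 9L) tpl else stats::approx(seq(0, 1, length.out = 9), tpl,
                                        xout = seq(0, 1, length.out = m))$y
  })
}

#' Simulate a toy transcriptome
#'
#' Random A/C/G/T sequences; a configurable fraction of genes gets a
#' guaranteed CATG + 17 nt site (inserted at a random admissible position),
#' the remainder have every CATG destroyed so they are untaggable. Writes a
#' FASTA and returns the per-gene canonical tag.
#'
#' @param config a `SimulationConfig`.
#' @param fasta_path output FASTA path.
#' @return list with `fasta_path`, `gene_ids`, `taggable` (logical), and
#'   `canonical` (named vector gene -> 3'-most sense tag, taggable genes).
#' @export
simulate_transcriptome <- function(config, fasta_path = tempfile(fileext = ".fa")) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$n_genes == 0L) stop("n_genes must be positive")
  set.seed(config$seed)
  n <- config$n_genes
  lens <- sample(config$gene_length_range[1]:config$gene_length_range[2], n, replace = TRUE)
  taggable <- runif(n) < config$taggable_fraction
  ids <- sprintf("gene%05d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i) {
    s <- random_dna(lens[i])
    if (taggable[i]) {
      pos <- sample.int(lens[i] - TAG_LEN + 1L, 1L)
      substr(s, pos, pos + 3L) <- ANCHOR
    } else {
      # destroy every CATG (either strand) so the gene stays untaggable
      while (grepl(ANCHOR, s, fixed = TRUE) || grepl(revcomp(ANCHOR), s, fixed = TRUE)) {
        s <- sub(ANCHOR, "CATC", s, fixed = TRUE)
        s <- sub(revcomp(ANCHOR), "CATC", s, fixed = TRUE)
      }
    }
    s
  }, "")
  writeLines(paste0(">", ids, "\n", seqs), fasta_path)
  canon <- vapply(seq_len(n), function(i) {
    if (!taggable[i]) return(NA_character_)
    tags <- extract_reference_tags(ids[i], seqs[i])
    ct <- tags$tag[tags$canonical]
    if (length(ct)) ct else NA_character_
  }, "")
  taggable <- !is.na(canon)   # guaranteed site may be antisense-only after edits
  list(fasta_path = fasta_path, gene_ids = ids, taggable = taggable,
       canonical = setNames(canon[taggable], ids[taggable]))
}

#' Ground-truth stage abundances and DE flags
#'
#' Assigns each gene an archetype, builds per-stage relative abundances as
#' baseline (log-normal across genes, spanning several orders of magnitude)
#' times the archetype trajectory (amplitude `de_log2fc`, small per-gene
#' shape jitter), normalized to sum to 1 within each stage. True DE flags
#' for any pair of stages are recomputable from the abundance table as
#' |log2 ratio| >= 1.
#'
#' @param config a `SimulationConfig`.
#' @param gene_ids gene identifiers.
#' @param expressed logical: which genes carry expression (untaggable genes
#'   can be excluded so that everything sequenced is mappable).
#' @return object of class `SyntheticTruth`: list with `archetype` (named),
#'   `abundance` (gene x stage, columns sum to 1) and `stages`.
#' @export
simulate_truth <- function(config, gene_ids, expressed = rep(TRUE, length(gene_ids))) {
  set.seed(config$seed + 1L)
  n <- length(gene_ids)
  mix <- config$archetype_mix
  arch <- sample(names(mix), n, replace = TRUE, prob = mix)
  tpl <- archetype_templates(config$stages)
  base <- rlnorm(n, meanlog = log(100), sdlog = 1.8)   # ~5 orders of magnitude
  jitter <- matrix(rnorm(n * length(config$stages), 0, 0.1),
                   nrow = n)
  logab <- matrix(0, n, length(config$stages),
                  dimnames = list(gene_ids, config$stages))
  for (i in seq_len(n)) {
    logab[i, ] <- log2(base[i]) + config$de_log2fc * tpl[[arch[i]]] + jitter[i, ]
  }
  ab <- 2^logab
  ab[!expressed, ] <- 0
  ab <- sweep(ab, 2, colSums(ab), "/")
  structure(list(archetype = setNames(arch, gene_ids), abundance = ab,
                 stages = config$stages), class = "SyntheticTruth")
}

#' True DE status for a pairwise comparison
#'
#' @param truth a `SyntheticTruth`.
#' @param comparison `c(stageA, stageB)`.
#' @param lfc_min log2-ratio threshold (default 1).
#' @return named logical vector over expressed genes (both abundances > 0).
#' @export
true_de <- function(truth, comparison, lfc_min = 1) {
  a <- truth$abundance[, comparison[1]]
  b <- truth$abundance[, comparison[2]]
  ok <- a > 0 & b > 0
  setNames(abs(log2(b[ok] / a[ok])) >= lfc_min, rownames(truth$abundance)[ok])
}

# corrupt each base of each tag occurrence independently at rate err
corrupt_tags <- function(tags, err) {
  if (err <= 0 || !length(tags)) return(tags)
  n_mut <- rbinom(length(tags), TAG_LEN, err)
  hit <- which(n_mut > 0)
  if (!length(hit)) return(tags)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(tags[i], "")[[1]]
    pos <- sample.int(TAG_LEN, n_mut[i])
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1L), "")
    tags[i] <- paste(ch, collapse = "")
  }
  tags
}

random_tags <- function(n) {
  if (!n) return(character())
  vapply(seq_len(n), function(i)
    paste0(ANCHOR, random_dna(TAG_LEN - 4L)), "")
}

#' Simulate raw tag libraries for every stage
#'
#' For each stage: `library_depth` tags are drawn multinomially from the
#' canonical tags of expressed genes, weighted by the stage's true
#' abundances (only the canonical 3'-most sense tag is ever sequenced,
#' mirroring the wet protocol); each base is corrupted independently at
#' `base_error_rate`; adaptor-, N-, singleton- and off-reference tags are
#' injected at the configured fractions (off-reference tags are drawn from
#' a stage-shared pool of CATG-anchored 21-mers absent from the reference,
#' with a skewed abundance so most survive the singleton filter).
#'
#' @param transcriptome result of [simulate_transcriptome()].
#' @param truth a `SyntheticTruth`.
#' @param config a `SimulationConfig`.
#' @param outdir if non-NULL, write one `<stage>.tsv` per stage plus
#'   `truth.tsv` and `config.txt` there.
#' @return named list of raw `TagLibrary` objects, one per stage, with the
#'   output directory as attribute "outdir" when written.
#' @export
simulate_libraries <- function(transcriptome, truth, config, outdir = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"), inherits(config, "SimulationConfig"))
  miss <- setdiff(config$stages, colnames(truth$abundance))
  if (length(miss)) stop("stage label(s) missing from truth: ", paste(miss, collapse = ", "))
  canon <- transcriptome$canonical
  ab <- truth$abundance[names(canon), , drop = FALSE]
  if (any(colSums(ab) == 0)) stop("no expressed taggable genes")
  set.seed(config$seed + 2L)
  depth <- config$library_depth
  # shared off-reference transcript pool with skewed (Zipf-like) abundances
  n_off <- max(50L, round(depth * config$offref_fraction / 50))
  off_pool <- random_tags(n_off)
  off_pool <- setdiff(off_pool, canon)
  off_w <- (seq_along(off_pool))^-1.2
  libs <- lapply(config$stages, function(st) {
    w <- ab[, st] / sum(ab[, st])
    # off-reference tags displace reference tags, so offref_fraction is the
    # expected share of the emitted stream, not an addition on top of it
    n_off_draw <- rbinom(1, depth, config$offref_fraction)
    counts <- as.vector(rmultinom(1, depth - n_off_draw, w))
    occ <- rep(unname(canon), counts)
    occ <- corrupt_tags(occ, config$base_error_rate)
    off_counts <- as.vector(rmultinom(1, n_off_draw, off_w))
    occ <- c(occ, corrupt_tags(rep(off_pool, off_counts), config$base_error_rate))
    n_adapt <- rbinom(1, depth, config$adaptor_fraction)
    if (n_adapt > 0) occ <- c(occ, rep(config$adaptor_seq, n_adapt))
    n_n <- rbinom(1, depth, config$n_fraction)
    if (n_n > 0) {
      nt <- random_tags(n_n)
      substr(nt, 10, 10) <- "N"
      occ <- c(occ, nt)
    }
    n_single <- rbinom(1, depth, config$singleton_fraction)
    if (n_single > 0) occ <- c(occ, random_tags(n_single))
    tb <- table(occ)
    tag_library(st, setNames(as.integer(tb), names(tb)))
  })
  names(libs) <- config$stages
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (st in config$stages)
      write_tag_tsv(libs[[st]], file.path(outdir, paste0(st, ".tsv")))
    tr <- data.table::data.table(gene = rownames(truth$abundance),
                                 archetype = truth$archetype[rownames(truth$abundance)])
    for (st in config$stages) tr[[st]] <- truth$abundance[, st]
    data.table::fwrite(tr, file.path(outdir, "truth.tsv"), sep = "\t")
    writeLines(paste0(names(unlist(config)), "=", unlist(config)),
               file.path(outdir, "config.txt"))
    attr(libs, "outdir") <- outdir
  }
  libs
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: transcriptome + truth + per-stage raw libraries.
#'
#' @param config a `SimulationConfig`.
#' @param outdir optional output directory for TSV/FASTA artifacts.
#' @return list with `config`, `transcriptome`, `truth`, `libraries`.
#' @export
simulate_dataset <- function(config = simulation_config(), outdir = NULL) {
  fasta <- if (is.null(outdir)) tempfile(fileext = ".fa") else {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    file.path(outdir, "transcriptome.fa")
  }
  tx <- simulate_transcriptome(config, fasta)
  truth <- simulate_truth(config, tx$gene_ids, expressed = tx$taggable)
  libs <- simulate_libraries(tx, truth, config, outdir = outdir)
  list(config = config, transcriptome = tx, truth = truth, libraries = libs)
}
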