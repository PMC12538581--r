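# Synthetic annotated genomes with planted promoter clusters: every pipeline
# stage is testable without external downloads or an external predictor.

#' Configuration for the synthetic-genome generator
#'
#' Describes a toy phage-like genome: non-overlapping genes separated by
#' intergenic gaps, with sigma70 consensus-like motifs planted into chosen
#' intergenic regions and a matching prediction table. All randomness flows
#' from `seed`; identical configs give byte-identical output.
#'
#' @param genome_length Genome size in bp (default 20000).
#' @param n_genes Number of genes (default 12).
#' @param gene_len_range Min/max gene length in bp (default 600-1200).
#' @param intergenic_len_range Min/max intergenic gap in bp (default
#'   150-300, enough room for several planted 29 bp promoter footprints).
#' @param planted_iprs List of planted promoter clusters, each a list with
#'   `region` (1-based index into the intergenic regions, ordered by
#'   position; region 1 is the span before the first gene), `strand`,
#'   `n` (number of promoters) and `score_mean`/`score_sd` (normal draw,
#'   clamped to `[0, 1]` -- the clamp reproduces the pile-up of maximal
#'   scores that real predictors show).
#' @param seed Integer seed fixing all randomness.
#' @param gc_content GC fraction of the background sequence (default 0.35,
#'   a typical staphylococcal phage composition).
#' @param strand_pattern `"alternate"` (default), `"plus"`, or `"random"`
#'   gene orientation.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(genome_length = 20000L, n_genes = 12L,
                       gene_len_range = c(600L, 1200L),
                       intergenic_len_range = c(150L, 300L),
                       planted_iprs = list(), seed = 1L,
                       gc_content = 0.35,
                       strand_pattern = c("alternate", "plus", "random")) {
  strand_pattern <- match.arg(strand_pattern)
  stopifnot(genome_length > 0, n_genes >= 0,
            length(gene_len_range) == 2L, gene_len_range[1] <= gene_len_range[2],
            length(intergenic_len_range) == 2L,
            intergenic_len_range[1] <= intergenic_len_range[2],
            intergenic_len_range[1] >= 0,
            gc_content >= 0, gc_content <= 1)
  need <- n_genes * gene_len_range[2] + (n_genes + 1L) * intergenic_len_range[2]
  if (need > genome_length)
    stop("infeasible simulation config: ", n_genes, " genes of up to ",
         gene_len_range[2], " bp with gaps up to ", intergenic_len_range[2],
         " bp need ", need, " bp > genome_length ", genome_length)
  for (pl in planted_iprs) {
    stopifnot(is.list(pl), !is.null(pl$region), !is.null(pl$n))
    if (pl$region < 1 || pl$region > n_genes + 1L)
      stop("planted region index ", pl$region, " out of range")
    if (pl$n * 29L > intergenic_len_range[1])
      stop("infeasible simulation config: ", pl$n,
           " planted 29 bp promoters cannot fit in a ",
           intergenic_len_range[1], " bp minimum intergenic gap")
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 intergenic_len_range = as.integer(intergenic_len_range),
                 planted_iprs = planted_iprs, seed = as.integer(seed),
                 gc_content = gc_content, strand_pattern = strand_pattern),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Demonstration simulation config
#'
#' The walkthrough fixture used by the documentation and the command-line
#' `simulate` subcommand: a 20 kb genome of 12 plus-strand genes with three
#' planted promoter clusters of decreasing density and score (5 promoters at
#' mean 0.95, 4 at 0.8, 3 at 0.6) placed in intergenic regions 2, 7 and 12,
#' so one cluster drives a gene in each temporal third of the genome.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
demo_sim_config <- function(seed = 1L) {
  sim_config(
    seed = seed, strand_pattern = "plus",
    planted_iprs = list(
      list(region = 2, strand = "+", n = 5, score_mean = 0.95, score_sd = 0.1),
      list(region = 7, strand = "+", n = 4, score_mean = 0.8, score_sd = 0.1),
      list(region = 12, strand = "+", n = 3, score_mean = 0.6, score_sd = 0.1)))
}

#' Simulate an annotated genome with planted promoters
#'
#' Lays out `n_genes` non-overlapping genes with random lengths and gaps,
#' fills the sequence with background composition `gc_content`, writes
#' sigma70-consensus-like motifs (`TTGACA` + 17 bp spacer + `TATAAT`, 29 bp
#' footprint) into the intergenic regions named by `planted_iprs`, and emits
#' a matching prediction table with scores drawn per cluster. Temporal
#' classes are assigned by genome thirds (early / middle / late), mimicking
#' the block structure of phage transcription programs.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `ipr_simulation`: a list with `genome`
#'   ([annotated_genome()]), `predictions` (forward-frame prediction table),
#'   `classes` (`data.frame` gene_id / temporal_class) and `config`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    L <- cfg$genome_length
    n <- cfg$n_genes
    glen <- if (n) sample(seq(cfg$gene_len_range[1], cfg$gene_len_range[2]),
                          n, replace = TRUE) else integer(0)
    gaps <- sample(seq(cfg$intergenic_len_range[1],
                       cfg$intergenic_len_range[2]),
                   n + 1L, replace = TRUE)
    starts <- integer(n)
    cur <- gaps[1]
    for (i in seq_len(n)) {
      starts[i] <- cur
      cur <- cur + glen[i] + gaps[i + 1L]
    }
    strand <- switch(cfg$strand_pattern,
                     alternate = rep_len(c("+", "-"), n),
                     plus = rep_len("+", n),
                     random = sample(c("+", "-"), n, replace = TRUE))
    gc <- cfg$gc_content
    seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

    # intergenic cores, ordered: leading gap, between-gene gaps, trailing span
    cores <- cbind(start = c(0L, if (n) starts + glen),
                   end = c(if (n) starts else integer(0), L))

    preds <- list()
    for (pl in cfg$planted_iprs) {
      cs <- cores[pl$region, "start"]; ce <- cores[pl$region, "end"]
      width <- ce - cs
      npl <- pl$n
      if (npl < 1L) next
      offs <- if (npl == 1L) (width - 29L) %/% 2L
        else as.integer(floor(seq(0, width - 29L, length.out = npl)))
      st <- pl$strand %||% "+"
      sc <- pmin(1, pmax(0, stats::rnorm(npl, pl$score_mean %||% 0.9,
                                         pl$score_sd %||% 0.1)))
      for (k in seq_len(npl)) {
        spacer <- paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE),
                        collapse = "")
        motif <- paste0("TTGACA", spacer, "TATAAT")
        s0 <- cs + offs[k]
        fwd_motif <- if (st == "+") motif else revcomp(motif)
        seqv[(s0 + 1L):(s0 + 29L)] <- strsplit(fwd_motif, "")[[1]]
        preds[[length(preds) + 1L]] <- data.frame(
          strand = st, start = s0, end = s0 + 29L, motif_seq = motif,
          score = sc[k], source = "synthetic", stringsAsFactors = FALSE)
      }
    }
    predictions <- if (length(preds)) {
      pr <- do.call(rbind, preds)
      pr <- pr[order(pr$start, pr$end, pr$strand), , drop = FALSE]
      rownames(pr) <- NULL
      pr
    } else empty_predictions()

    genes <- if (n) gene_features(
      gene_id = sprintf("gene_%02d", seq_len(n)),
      start = starts, end = starts + glen, strand = strand,
      product = sprintf("simulated protein %02d", seq_len(n)))
    else gene_features(character(0), integer(0), integer(0))
    genome <- annotated_genome("synthetic_phage",
                               paste(seqv, collapse = ""), genes)
    # temporal classes by thirds of the gene-occupied span: a block
    # structure with guaranteed early/middle/late representation
    mids <- (starts + starts + glen) / 2
    span0 <- if (n) starts[1] else 0
    span1 <- if (n) starts[n] + glen[n] else L
    third <- pmin(3L, pmax(1L, 1L + as.integer(
      3 * (mids - span0) / max(1, span1 - span0))))
    classes <- data.frame(
      gene_id = genes$gene_id,
      temporal_class = c("early", "middle", "late")[third],
      stringsAsFactors = FALSE)
    structure(list(genome = genome, predictions = predictions,
                   classes = classes, config = cfg),
              class = "ipr_simulation")
  })
}

#' @export
print.ipr_simulation <- function(x, ...) {
  cat(sprintf("<ipr_simulation> seed %d: %d bp, %d genes, %d planted promoter(s)\n",
              x$config$seed, genome_length(x$genome), nrow(x$genome$genes),
              nrow(x$predictions)))
  invisible(x)
}

#' Write a simulation to fixture files
#'
#' Emits `genome.gb` (GenBank), `predictions.tsv` (the external-predictor
#' table dialect) and `classes.tsv` into a directory, so the file-based
#' pipeline entry points can be exercised on synthetic data.
#'
#' @param sim An [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ipr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.gb"),
             predictions = file.path(dir, "predictions.tsv"),
             classes = file.path(dir, "classes.tsv"))
  write_genbank(sim$genome, paths["genome"])
  write_predictions_table(sim$predictions, paths["predictions"],
                          genome_length(sim$genome))
  utils::write.table(sim$classes, paths["classes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
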