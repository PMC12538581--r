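# Shared fixtures and independent oracles. The oracles deliberately use the
# dumbest correct method (per-base masks, exhaustive enumeration, direct
# summation) so they stay independent of the implementation they check.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_genome <- function(starts, ends, strands = "+", L = 1000L, ids = NULL,
                       products = "", parts = NULL, sequence = NULL,
                       topology = "linear", seq_id = "toy") {
  n <- length(starts)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
  if (is.null(sequence)) sequence <- strrep("ACGT", ceiling(L / 4))
  sequence <- substr(sequence, 1, L)
  annotated_genome(seq_id, sequence,
                   gene_features(ids, starts, ends, strands, products,
                                 parts = parts),
                   topology)
}

# per-base coverage-mask oracle for intergenic cores (positive-width only;
# a bitmap cannot represent the zero-width cores kept at abutting genes)
oracle_intergenic_cores <- function(genome) {
  L <- genome_length(genome)
  g <- genome$genes[!genome$genes$interior, , drop = FALSE]
  covered <- logical(L)
  for (i in seq_len(nrow(g)))
    covered[(g$start[i] + 1L):g$end[i]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[!r$values], end = ends[!r$values])
}

# exhaustive two-box PWM rescan: every (-35 position, spacer) pair scored by
# direct probability lookup, one strand at a time
oracle_pwm_hits <- function(seqchar, model, threshold) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seqchar, "")[[1]]
  L <- length(chars)
  w35 <- ncol(model$minus35); w10 <- ncol(model$minus10)
  score_box <- function(pos, m) {
    lo <- 0
    for (j in seq_len(ncol(m))) {
      b <- match(chars[pos + j - 1L], bases)
      if (is.na(b)) return(-Inf)
      lo <- lo + log(m[b, j] / model$background[b])
    }
    lo
  }
  hits <- list()
  for (i in seq_len(L)) {
    for (g in seq(model$spacer_range[1], model$spacer_range[2])) {
      flen <- w35 + g + w10
      if (i + flen - 1L > L) next
      total <- score_box(i, model$minus35) + score_box(i + w35 + g, model$minus10)
      sc <- 1 / (1 + exp(-(total - model$score_midpoint) / model$score_scale))
      if (is.finite(total) && sc >= threshold)
        hits[[length(hits) + 1L]] <- data.frame(start = i - 1L,
                                                end = i - 1L + flen,
                                                score = sc)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0),
                                       score = numeric(0)))
  do.call(rbind, hits)
}

# exhaustive insertion-site oracle: first same-strand gene at/after the hull
# in reading direction, by direct enumeration
oracle_select_gene <- function(ipr_strand, span_start, span_end, genes) {
  g <- genes[!genes$interior & genes$strand == ipr_strand, , drop = FALSE]
  if (ipr_strand == "+") {
    g <- g[g$start >= span_start, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    g[which.min(g$start), ]
  } else {
    g <- g[g$end <= span_end, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    g[which.max(g$end), ]
  }
}

# random non-overlapping gene layout on [0, L): returns a gene data.frame
random_gene_layout <- function(L, n_genes, min_len = 50L, max_len = 2000L) {
  starts <- integer(0); ends <- integer(0)
  cur <- sample.int(300L, 1L) - 1L
  for (i in seq_len(n_genes)) {
    len <- sample(seq(min_len, max_len), 1L)
    gap <- sample(0:400, 1L)
    if (cur + gap + len > L) break
    starts <- c(starts, cur + gap)
    ends <- c(ends, cur + gap + len)
    cur <- cur + gap + len
  }
  n <- length(starts)
  gene_features(sprintf("g%03d", seq_len(n)), starts, ends,
                sample(c("+", "-"), n, replace = TRUE))
}

# tiny GenBank record text used by the reader tests
toy_genbank_text <- function() {
  seq <- tolower(rand_dna(1000, seed = 42))
  chunks <- character(0)
  for (off in seq(1, 1000, by = 60)) {
    line <- substr(seq, off, min(off + 59, 1000))
    tens <- substring(line, seq(1, nchar(line), 10),
                      pmin(seq(10, nchar(line) + 9, 10), nchar(line)))
    chunks <- c(chunks, sprintf("%9d %s", off, paste(tens, collapse = " ")))
  }
  c("LOCUS       toyphage          1000 bp    DNA     linear   PHG 01-JAN-2000",
    "DEFINITION  toy phage.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     CDS             1..300",
    '                     /locus_tag="gA"',
    '                     /product="terminase"',
    "     CDS             complement(401..700)",
    '                     /locus_tag="gB"',
    '                     /product="hypothetical protein"',
    "     CDS             801..1000",
    '                     /locus_tag="gC"',
    "ORIGIN", chunks, "//")
}
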