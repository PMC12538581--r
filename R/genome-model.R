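# Genome model: annotated genomes, split-gene merging, intergenic extraction.
# All internal coordinates are 0-based half-open; GenBank I/O converts at the
# boundary (1-based inclusive), BED stays 0-based half-open.

#' Construct an annotated genome
#'
#' The central container of the package: a DNA sequence plus an ordered table
#' of gene features. Everything downstream (intergenic regions, promoter
#' predictions, IPRs, insertion sites, donor constructs) is expressed in this
#' coordinate frame.
#'
#' @param seq_id Sequence identifier (single string).
#' @param sequence DNA sequence as a single string over `A,C,G,T,N` (case
#'   insensitive), or a [Biostrings::DNAString].
#' @param genes A `data.frame` of gene features, typically built with
#'   [gene_features()]. Required columns: `gene_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`). Optional: `product` (free text, default `""`), `interior`
#'   (logical, default `FALSE`), `parts` (list column of two-column matrices
#'   of 0-based half-open spans for multi-part annotations).
#' @param topology `"linear"` (default) or `"circular"`.
#'
#' @return An object of class `annotated_genome`: a list with elements
#'   `seq_id`, `sequence` (uppercase character), `topology` and `genes`
#'   (sorted by `start`).
#' @export
annotated_genome <- function(seq_id, sequence, genes,
                             topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(seq_id), length(seq_id) == 1L)
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence is empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L)
    stop("sequence contains non-ACGTN characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  genes <- normalize_gene_table(genes, nchar(sequence))
  structure(list(seq_id = seq_id, sequence = sequence,
                 topology = topology, genes = genes),
            class = "annotated_genome")
}

#' Build a gene feature table
#'
#' @param gene_id Character vector of unique gene labels.
#' @param start,end 0-based half-open gene body coordinates.
#' @param strand `"+"` or `"-"`, recycled.
#' @param product Free-text product annotation, recycled.
#' @param parts Optional list of two-column matrices (`start`, `end`) giving
#'   the ordered spans of multi-part ("join") annotations; `NULL` entries mean
#'   a single contiguous span.
#' @return A `data.frame` suitable for [annotated_genome()].
#' @export
gene_features <- function(gene_id, start, end, strand = "+",
                          product = "", parts = NULL) {
  n <- length(gene_id)
  df <- data.frame(gene_id = as.character(gene_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   product = rep_len(as.character(product), n),
                   interior = rep_len(FALSE, n),
                   stringsAsFactors = FALSE)
  if (is.null(parts)) parts <- vector("list", n)
  stopifnot(length(parts) == n)
  df$parts <- lapply(seq_len(n), function(i) {
    p <- parts[[i]]
    if (is.null(p)) p <- cbind(start = df$start[i], end = df$end[i])
    p <- as.matrix(p)
    colnames(p) <- c("start", "end")
    storage.mode(p) <- "integer"
    p
  })
  df
}

normalize_gene_table <- function(genes, genome_length) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  genes$gene_id <- as.character(genes$gene_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  if (is.null(genes$product)) genes$product <- ""
  if (is.null(genes$interior)) genes$interior <- FALSE
  if (is.null(genes$parts))
    genes$parts <- lapply(seq_len(nrow(genes)), function(i)
      cbind(start = genes$start[i], end = genes$end[i]))
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene_ids: ",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
    if (!all(genes$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-'")
    if (any(genes$start < 0L | genes$start >= genes$end |
            genes$end > genome_length))
      stop("gene coordinates out of bounds (need 0 <= start < end <= ",
           genome_length, ")")
    for (i in seq_len(nrow(genes))) {
      p <- as.matrix(genes$parts[[i]])
      if (ncol(p) != 2L) stop("parts must be two-column (start, end)")
      colnames(p) <- c("start", "end")
      storage.mode(p) <- "integer"
      genes$parts[[i]] <- p
      if (min(p[, 1]) != genes$start[i] || max(p[, 2]) != genes$end[i])
        stop("gene '", genes$gene_id[i],
             "': start/end must equal the hull of its parts")
    }
    o <- order(genes$start, genes$end)
    genes <- genes[o, , drop = FALSE]
    rownames(genes) <- NULL
  }
  genes
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp (%s), %d genes (%d interior)\n",
              x$seq_id, format(genome_length(x), big.mark = ","), x$topology,
              nrow(x$genes), sum(x$genes$interior)))
  if (nrow(x$genes)) {
    show <- utils::head(x$genes[, c("gene_id", "start", "end", "strand", "product")], 8)
    print(show, row.names = FALSE)
    if (nrow(x$genes) > 8) cat("  ... and", nrow(x$genes) - 8, "more genes\n")
  }
  invisible(x)
}

#' Genome length in base pairs
#' @param genome An [annotated_genome()].
#' @return Integer length of the sequence.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Extract a subsequence in forward orientation
#' @param genome An [annotated_genome()].
#' @param start,end 0-based half-open span.
#' @return Character string of the span.
#' @export
genome_subseq <- function(genome, start, end) {
  L <- genome_length(genome)
  stopifnot(start >= 0, end >= start, end <= L)
  substr(genome$sequence, start + 1L, end)
}

#' Reading-frame sequences of all genes
#'
#' Returns each (non-interior by default) gene's sequence in its reading
#' orientation: reverse-complemented for minus-strand genes. Used by the
#' donor-design verification to assert that an in-silico edit conserves every
#' coding sequence.
#'
#' @param genome An [annotated_genome()].
#' @param include_interior Include genes flagged interior (nested inside a
#'   merged split-gene locus)?
#' @return Named character vector of gene sequences.
#' @export
gene_sequences <- function(genome, include_interior = TRUE) {
  g <- genome$genes
  if (!include_interior) g <- g[!g$interior, , drop = FALSE]
  out <- vapply(seq_len(nrow(g)), function(i) {
    s <- genome_subseq(genome, g$start[i], g$end[i])
    if (g$strand[i] == "-") s <- revcomp(s)
    s
  }, character(1))
  names(out) <- g$gene_id
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Reverse-complement a genome and its annotations
#'
#' Mirrors the sequence and every gene feature into the opposite strand's
#' coordinate frame. A span `[s, e)` on a genome of length `L` maps to
#' `[L - e, L - s)` with flipped strand. Useful for strand-involution checks:
#' the pipeline run on a genome and on its reverse complement must produce
#' mirrored coordinates and identical scores.
#'
#' @param genome An [annotated_genome()].
#' @return The mirrored `annotated_genome`.
#' @export
reverse_complement_genome <- function(genome) {
  L <- genome_length(genome)
  g <- genome$genes
  if (nrow(g)) {
    new_start <- L - g$end
    new_end <- L - g$start
    g$parts <- lapply(g$parts, function(p) {
      m <- cbind(start = L - p[, "end"], end = L - p[, "start"])
      m[rev(seq_len(nrow(m))), , drop = FALSE]
    })
    g$start <- new_start
    g$end <- new_end
    g$strand <- ifelse(g$strand == "+", "-", "+")
  }
  annotated_genome(genome$seq_id, revcomp(genome$sequence), g, genome$topology)
}

#' Merge split (multi-part) gene annotations into contiguous loci
#'
#' Genes annotated in several parts -- typically loci interrupted by
#' intron-encoded homing endonucleases, with other genes nested between the
#' parts -- are collapsed to a single span from the first part's start to the
#' last part's end. Any other gene wholly contained inside a merged span is
#' kept as annotation but flagged `interior`: it creates no intergenic
#' boundary, so no insertion site can be proposed between the parts of the
#' merged locus.
#'
#' @param genome An [annotated_genome()].
#' @return The genome with multi-part genes collapsed and nested genes
#'   flagged `interior`. Idempotent.
#' @export
merge_split_genes <- function(genome) {
  g <- genome$genes
  if (!nrow(g)) return(genome)
  multi <- which(vapply(g$parts, nrow, integer(1)) > 1L)
  for (i in multi) {
    p <- g$parts[[i]]
    if (is.unsorted(p[, "start"]) || any(p[-1, "start"] < p[-nrow(p), "end"]))
      stop("gene '", g$gene_id[i],
           "': parts overlap or span the origin of a linear genome")
    hull <- c(min(p[, "start"]), max(p[, "end"]))
    g$start[i] <- hull[1]
    g$end[i] <- hull[2]
    g$parts[[i]] <- cbind(start = hull[1], end = hull[2])
  }
  # flag genes fully nested inside a merged hull
  for (i in multi) {
    nested <- g$start >= g$start[i] & g$end <= g$end[i] &
      seq_len(nrow(g)) != i
    g$interior[nested] <- TRUE
  }
  genome$genes <- normalize_gene_table(g, genome_length(genome))
  genome
}

#' Compute extended intergenic regions
#'
#' Core spans are the maximal intervals not covered by any non-interior gene
#' body, including the terminal spans before the first and after the last
#' gene on linear genomes. Each core is widened by `extension` bases into the
#' flanking genes (clamped to the genome bounds) because promoters frequently
#' overlap coding sequence ends; the default extension is 50 bp. Zero-width
#' internal cores are kept when two genes abut (the boundary is still a legal
#' search point), zero-width terminal spans are dropped. On circular genomes
#' the wrap-around gap between the last and first gene is reported as one
#' region whose coordinates continue past the sequence end (modulo the
#' length).
#'
#' @param genome An [annotated_genome()], normally after
#'   [merge_split_genes()].
#' @param extension Non-negative integer number of bases to extend into each
#'   flanking gene (default 50).
#' @return A `data.frame` of class `intergenic_regions` with columns
#'   `region_id`, `core_start`, `core_end`, `ext_start`, `ext_end`,
#'   `upstream_gene_id`, `downstream_gene_id`, ordered by `core_start`.
#' @export
extract_intergenic_regions <- function(genome, extension = 50L) {
  stopifnot(extension >= 0)
  extension <- as.integer(extension)
  L <- genome_length(genome)
  g <- genome$genes[!genome$genes$interior, , drop = FALSE]
  regions <- list()
  add <- function(cs, ce, up, dn) {
    regions[[length(regions) + 1L]] <<-
      list(core_start = cs, core_end = ce,
           upstream_gene_id = up, downstream_gene_id = dn)
  }
  if (nrow(g) == 0L) {
    add(0L, L, NA_character_, NA_character_)
  } else {
    cur_end <- 0L
    cur_gene <- NA_character_
    for (i in seq_len(nrow(g))) {
      if (g$start[i] >= cur_end) {
        # keep zero-width internal cores (abutting genes); drop the
        # zero-width leading span when the first gene starts at 0; on
        # circular genomes the pre-first-gene span belongs to the wrap
        if (!(is.na(cur_gene) &&
                (g$start[i] == cur_end || genome$topology == "circular")))
          add(cur_end, g$start[i], cur_gene, g$gene_id[i])
      }
      if (g$end[i] > cur_end) {
        cur_end <- g$end[i]
        cur_gene <- g$gene_id[i]
      }
    }
    if (genome$topology == "circular") {
      # wrap-around gap: one region from the last covered base past the
      # origin to the first gene start (coordinates continue past L)
      if (cur_end < L || g$start[1] > 0L)
        add(cur_end, g$start[1] + L, cur_gene, g$gene_id[1])
    } else if (cur_end < L) {
      add(cur_end, L, cur_gene, NA_character_)
    }
  }
  n <- length(regions)
  df <- data.frame(
    region_id = sprintf("igr_%03d", seq_len(n)),
    core_start = vapply(regions, `[[`, integer(1), "core_start"),
    core_end = vapply(regions, `[[`, integer(1), "core_end"),
    stringsAsFactors = FALSE)
  df$ext_start <- pmax(0L, df$core_start - extension)
  df$ext_end <- df$core_end + extension
  if (genome$topology == "linear") df$ext_end <- pmin(L, df$ext_end)
  df$upstream_gene_id <- vapply(regions, `[[`, character(1), "upstream_gene_id")
  df$downstream_gene_id <- vapply(regions, `[[`, character(1), "downstream_gene_id")
  attr(df, "extension") <- extension
  attr(df, "genome_length") <- L
  class(df) <- c("intergenic_regions", "data.frame")
  df
}
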