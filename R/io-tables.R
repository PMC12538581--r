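# Tabular readers/writers: BED6, GFF3, the promoter-prediction table dialect,
# PWM model files and flat key-value configs.

#' Write intervals as BED6
#'
#' @param x A `data.frame` with columns `start`, `end` (0-based half-open)
#'   and optionally `name`, `score`, `strand`; or an `intergenic_regions`
#'   table (cores are written, extended coordinates go to columns 7-8).
#' @param path Output path.
#' @param seq_id Chromosome/sequence name for column 1.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path, seq_id = "genome") {
  if (inherits(x, "intergenic_regions")) {
    df <- data.frame(chrom = seq_id, start = x$core_start, end = x$core_end,
                     name = x$region_id, score = 0L, strand = ".",
                     ext_start = x$ext_start, ext_end = x$ext_end)
  } else {
    df <- data.frame(chrom = seq_id, start = x$start, end = x$end,
                     name = if (is.null(x$name)) "." else x$name,
                     score = if (is.null(x$score)) 0 else x$score,
                     strand = if (is.null(x$strand)) "." else x$strand)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a 0-based half-open interval table
#'
#' @param path Path to a BED3+ file.
#' @return A `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand` (plus any extra numeric columns).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand",
            "ext_start", "ext_end")
  names(df) <- c(base, paste0("V", seq_len(max(0, ncol(df) - length(base)))))[
    seq_len(ncol(df))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write features as GFF3
#'
#' Used for IPRs (`type = "promoter_region"`, score column carries the IPR
#' score) and for gene tables. Coordinates are converted to GFF3's 1-based
#' inclusive convention.
#'
#' @param df A `data.frame` with `start`, `end` (0-based half-open), `strand`
#'   and an id column (`ipr_id`, `gene_id` or `name`).
#' @param path Output path.
#' @param seq_id Sequence name for column 1.
#' @param type GFF3 feature type (column 3).
#' @param source GFF3 source (column 2).
#' @param score Optional numeric vector for column 6.
#' @param attrs Optional character vector of preformatted extra attributes
#'   (appended after `ID=`).
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(df, path, seq_id = "genome", type = "region",
                       source = "iprdesign", score = NULL, attrs = NULL) {
  id <- df$ipr_id %||% df$gene_id %||% df$name %||%
    sprintf("%s_%03d", type, seq_len(nrow(df)))
  start <- df$start %||% df$span_start
  end <- df$end %||% df$span_end
  sc <- if (is.null(score)) rep(".", nrow(df)) else format(score, trim = TRUE)
  at <- paste0("ID=", id, if (is.null(attrs)) "" else paste0(";", attrs))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                   seq_id, source, type, start + 1L, end,
                   sc, df$strand %||% ".", at)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Parse a promoter-prediction table
#'
#' Reads the tabular output dialect of an external promoter predictor
#' (PhagePromoter-style). Accepted layouts, tab- or comma-separated, with an
#' optional header (auto-detected by a non-numeric score field):
#' column order `strand, position, type, sequence, score` (5+ columns) or
#' `strand, position, sequence, score` (4 columns). Positions are 1-based
#' counted on the reported strand: minus-strand rows count from the 3' end of
#' the forward sequence, and are reflected so that `start`/`end` are always
#' forward-frame 0-based half-open coordinates (`start = L - (pos - 1) - len`
#' for a minus-strand motif of length `len`).
#'
#' Rows with a score below `threshold` are dropped (the predictor's own run
#' threshold, default 0.5). Rows whose score falls outside `[0, 1]` are
#' rejected with a warning; motifs extending outside the genome raise an
#' error, as do unparsable lines (reported with their line number).
#'
#' @param path Path to the table.
#' @param genome_length Length of the target genome in bp.
#' @param threshold Minimum score kept (default 0.5).
#' @return A `data.frame` of predictions: `strand`, `start`, `end`,
#'   `motif_seq`, `score`, `source = "external_table"`.
#' @export
parse_predictions_table <- function(path, genome_length, threshold = 0.5) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(empty_predictions())
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("unparsable prediction table line ", which(nf < 4L)[1],
         ": expected >= 4 fields")
  score_col <- if (nf[1] >= 5L) 5L else 4L
  first_score <- suppressWarnings(as.numeric(trimws(fields[[1]][score_col])))
  start_row <- if (is.na(first_score)) 2L else 1L  # header detected
  out <- list()
  kept <- 0L
  for (i in seq(start_row, length(fields))) {
    f <- trimws(fields[[i]])
    if (length(f) >= 5L) {
      strand <- f[1]; pos <- f[2]; mseq <- f[4]; sc <- f[5]
    } else {
      strand <- f[1]; pos <- f[2]; mseq <- f[3]; sc <- f[4]
    }
    pos <- suppressWarnings(as.integer(pos))
    sc <- suppressWarnings(as.numeric(sc))
    if (is.na(pos) || is.na(sc) || !strand %in% c("+", "-"))
      stop("unparsable prediction table line ", i)
    if (sc < 0 || sc > 1) {
      warning("line ", i, ": score ", sc, " outside [0,1]; row rejected")
      next
    }
    len <- nchar(mseq)
    if (strand == "+") {
      start0 <- pos - 1L
    } else {
      start0 <- genome_length - (pos - 1L) - len
    }
    end0 <- start0 + len
    if (start0 < 0L || end0 > genome_length)
      stop("line ", i, ": motif footprint [", start0, ",", end0,
           ") outside genome of length ", genome_length)
    if (sc < threshold) next
    kept <- kept + 1L
    out[[kept]] <- data.frame(strand = strand, start = start0, end = end0,
                              motif_seq = toupper(mseq), score = sc,
                              source = "external_table",
                              stringsAsFactors = FALSE)
  }
  if (!kept) return(empty_predictions())
  preds <- do.call(rbind, out)
  preds <- preds[order(preds$start, preds$end, preds$strand), , drop = FALSE]
  rownames(preds) <- NULL
  preds
}

empty_predictions <- function() {
  data.frame(strand = character(0), start = integer(0), end = integer(0),
             motif_seq = character(0), score = numeric(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Write predictions back to the table dialect
#'
#' Exact inverse of [parse_predictions_table()]: forward-frame coordinates
#' are reflected back to 1-based strand-frame positions, so parsing the
#' written file reproduces the input (round-trip identity).
#'
#' @param predictions A prediction `data.frame` (forward-frame coordinates).
#' @param path Output path.
#' @param genome_length Genome length in bp (needed to reflect minus-strand
#'   positions).
#' @return Invisibly, `path`.
#' @export
write_predictions_table <- function(predictions, path, genome_length) {
  pos <- ifelse(predictions$strand == "+",
                predictions$start + 1L,
                genome_length - predictions$end + 1L)
  df <- data.frame(strand = predictions$strand, position = pos,
                   type = "promoter", sequence = predictions$motif_seq,
                   score = predictions$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a flat key-value config file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as logical/numeric where possible, comma-separated values become vectors.
#'
#' @param path Path to the config file.
#' @return For `read_config_file`, a named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    parsed <- if (!anyNA(num)) num
      else if (all(toupper(vals) %in% c("TRUE", "FALSE", "INF")))
        ifelse(toupper(vals) == "INF", Inf, as.logical(vals))
      else vals
    out[[key]] <- parsed
  }
  out
}

#' @rdname read_config_file
#' @param config Named list of scalar or vector values.
#' @export
write_config_file <- function(config, path) {
  fmt <- vapply(config, function(v) paste(format(v, trim = TRUE), collapse = ","),
                character(1))
  writeLines(sprintf("%s = %s", names(config), fmt), path)
  invisible(path)
}
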