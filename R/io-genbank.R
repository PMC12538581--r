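# Minimal single-record GenBank flat-file reader and writer.
# Only what an annotated phage record needs: LOCUS (length + topology),
# CDS/gene features with join/complement locations and a few qualifiers,
# and the ORIGIN sequence block.

#' Read an annotated genome from a GenBank flat file
#'
#' Parses a single-record GenBank file into an [annotated_genome()]. Every
#' `CDS` feature (or, in records without CDS features, every `gene` feature)
#' becomes one gene feature; multi-part `join(...)` locations are preserved
#' in the `parts` column for [merge_split_genes()]. Coordinates are converted
#' from GenBank's 1-based inclusive convention to the package's 0-based
#' half-open frame. Gene labels are taken from `/locus_tag`, then `/gene`,
#' then `/protein_id`, then an autogenerated index.
#'
#' @param path Path to a GenBank flat file containing sequence (`ORIGIN`).
#' @return An [annotated_genome()].
#' @export
read_genome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)

  locus <- grep("^LOCUS", lines, value = TRUE)
  topology <- if (length(locus) && grepl("circular", locus[1], ignore.case = TRUE))
    "circular" else "linear"
  seq_id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                        "\\s+")[[1]][1] else "unknown"

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record has no ORIGIN sequence block")
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1]][1] else length(lines) + 1L
  seqlines <- lines[(ori[1] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nchar(sequence)) stop("GenBank record has an empty sequence")

  featstart <- grep("^FEATURES", lines)
  if (!length(featstart)) stop("GenBank record has no annotations")
  flines <- lines[(featstart[1] + 1L):(ori[1] - 1L)]
  flines <- flines[!grepl("^(BASE COUNT|CONTIG)", flines)]

  feats <- parse_feature_table(flines)
  feats <- feats[vapply(feats, function(f) f$key %in% c("CDS", "gene"), logical(1))]
  if (!length(feats)) stop("GenBank record has no annotations (no CDS/gene features)")
  keys <- vapply(feats, `[[`, character(1), "key")
  if (any(keys == "CDS")) feats <- feats[keys == "CDS"]

  ids <- character(length(feats))
  for (i in seq_along(feats)) {
    q <- feats[[i]]$qualifiers
    ids[i] <- q[["locus_tag"]] %||% q[["gene"]] %||% q[["protein_id"]] %||%
      sprintf("feat_%03d", i)
  }
  ids <- make.unique(ids, sep = "_")
  genes <- gene_features(
    gene_id = ids,
    start = vapply(feats, function(f) min(f$parts[, "start"]), integer(1)),
    end = vapply(feats, function(f) max(f$parts[, "end"]), integer(1)),
    strand = vapply(feats, `[[`, character(1), "strand"),
    product = vapply(feats, function(f) f$qualifiers[["product"]] %||% "",
                     character(1)),
    parts = lapply(feats, `[[`, "parts"))
  annotated_genome(seq_id, sequence, genes, topology)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_feature_table <- function(flines) {
  feats <- list()
  cur <- NULL
  in_qualifiers <- FALSE
  for (ln in flines) {
    if (!nzchar(trimws(ln))) next
    key_field <- substr(ln, 1, 20)
    body <- trimws(substr(ln, 21, nchar(ln)))
    if (nzchar(trimws(key_field))) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- finish_feature(cur)
      cur <- list(key = trimws(key_field), location = body, quals = character(0))
      in_qualifiers <- FALSE
    } else if (startsWith(body, "/")) {
      cur$quals <- c(cur$quals, body)
      in_qualifiers <- TRUE
    } else if (!is.null(cur)) {
      if (in_qualifiers && length(cur$quals)) {
        # continuation of a (possibly quoted) qualifier value
        cur$quals[length(cur$quals)] <-
          paste0(cur$quals[length(cur$quals)], " ", body)
      } else {
        cur$location <- paste0(cur$location, body)  # wrapped join(...)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- finish_feature(cur)
  feats
}

finish_feature <- function(cur) {
  loc <- parse_gb_location(cur$location)
  quals <- list()
  for (q in cur$quals) {
    m <- regmatches(q, regexec('^/([^=]+)=?(.*)$', q))[[1]]
    if (length(m) == 3L) {
      val <- gsub('^"|"$', "", m[3])
      quals[[m[2]]] <- val
    }
  }
  list(key = cur$key, parts = loc$parts, strand = loc$strand, qualifiers = quals)
}

parse_gb_location <- function(loc) {
  loc <- gsub("[ <>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  if (grepl("complement", loc))
    stop("unsupported mixed-strand location: ", loc)
  spans <- strsplit(loc, ",")[[1]]
  parts <- t(vapply(spans, function(s) {
    ab <- as.integer(strsplit(s, "\\.\\.")[[1]])
    if (any(is.na(ab))) stop("unparsable GenBank location span: ", s)
    if (length(ab) == 1L) ab <- c(ab, ab)
    c(ab[1] - 1L, ab[2])  # 1-based inclusive -> 0-based half-open
  }, integer(2)))
  dimnames(parts) <- list(NULL, c("start", "end"))
  list(parts = parts, strand = strand)
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits a minimal single-record GenBank file (LOCUS, FEATURES with one CDS
#' per gene, ORIGIN) that [read_genome()] round-trips. Coordinates are
#' converted back to 1-based inclusive; multi-part genes are written as
#' `join(...)` locations. The LOCUS date is a fixed placeholder so repeated
#' runs produce byte-identical output.
#'
#' @param genome An [annotated_genome()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(genome, path) {
  L <- genome_length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-17s %d bp    DNA     %-9s PHG 01-JAN-2000",
                     genome$seq_id, L, genome$topology), con)
  writeLines(sprintf("DEFINITION  %s.", genome$seq_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    p <- g$parts[[i]]
    spans <- sprintf("%d..%d", p[, "start"] + 1L, p[, "end"])
    loc <- if (length(spans) > 1L)
      sprintf("join(%s)", paste(spans, collapse = ",")) else spans
    if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf('                     /locus_tag="%s"', g$gene_id[i]), con)
    if (nzchar(g$product[i]))
      writeLines(sprintf('                     /product="%s"', g$product[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  for (off in seq(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
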