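# Donor design: homology-arm construction around an insertion site, the
# RBS-preserving base-duplication rule for short downstream gaps, and the
# in-silico recombinant used to verify sequence conservation.

#' Payload cassette (RBS + coding sequence)
#'
#' @param payload_seq Payload coding sequence (DNA string, reading
#'   orientation).
#' @param rbs_seq Ribosome binding site placed upstream of the payload
#'   (default `GAGGAGGTAAATATAT`, a strong Gram-positive RBS).
#' @param name Cassette label, used for the payload annotation in the
#'   recombinant genome.
#' @return A `payload_cassette` object; `sequence` is `rbs_seq` followed by
#'   `payload_seq` in reading orientation.
#' @export
payload_cassette <- function(payload_seq, rbs_seq = "GAGGAGGTAAATATAT",
                             name = "payload") {
  payload_seq <- toupper(payload_seq)
  rbs_seq <- toupper(rbs_seq)
  stopifnot(nchar(payload_seq) > 0L,
            !grepl("[^ACGTN]", payload_seq), !grepl("[^ACGTN]", rbs_seq))
  structure(list(rbs_seq = rbs_seq, payload_seq = payload_seq, name = name,
                 sequence = paste0(rbs_seq, payload_seq)),
            class = "payload_cassette")
}

#' Design a homologous-recombination donor construct
#'
#' Builds `left arm + oriented cassette (+ duplicated context) + right arm`
#' around the insertion point. Arms start at `arm_max` (default 400 bp) and
#' are shrunk toward `arm_min` (default 200 bp) when the window would run off
#' the genome (below `arm_min` is a hard error) or, best effort, when it
#' would fully contain a gene whose product matches `avoid_keywords`
#' (a warning is raised if that cannot be avoided).
#'
#' When the intergenic distance `d` between the selected gene's stop and the
#' next gene's start (in reading direction) is below `rbs_window` (default
#' 20 bp), the last `rbs_window - d` bases of the selected gene are
#' duplicated and appended after the cassette, so the downstream gene keeps
#' its full native upstream context -- its ribosome binding site -- intact.
#'
#' For minus-strand sites the cassette (and duplicated context) is
#' reverse-complemented; arms are always reported in the forward frame.
#'
#' @param site One row of an `insertion_sites` table
#'   ([select_insertion_sites()]).
#' @param genome The reference [annotated_genome()].
#' @param cassette A [payload_cassette()].
#' @param arm_min,arm_max Homology arm length bounds in bp (default 200-400).
#' @param rbs_window_bp Downstream-gap threshold triggering base duplication
#'   (default 20).
#' @param avoid_keywords Product keywords marking genes of unknown function
#'   that arms should not fully contain.
#' @return A `donor_construct` object with the arm sequences and source
#'   spans, the oriented insert, the duplicated context and `full_seq`.
#' @export
design_donor <- function(site, genome, cassette,
                         arm_min = 200L, arm_max = 400L,
                         rbs_window_bp = 20L,
                         avoid_keywords = c("hypothetical", "unknown")) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(cassette, "payload_cassette"),
            arm_min <= arm_max, arm_min > 0)
  site <- as.list(site[1, , drop = FALSE])
  p <- as.integer(site$position)
  st <- site$strand
  L <- genome_length(genome)
  stopifnot(p >= 0L, p <= L, st %in% c("+", "-"))

  # duplicated context: last (window - d) bases of the selected gene in its
  # reading direction, restoring a full rbs_window upstream of the next gene
  d <- site$downstream_gap
  dup_reading <- ""
  if (is.finite(d) && d < rbs_window_bp) {
    n <- as.integer(rbs_window_bp - d)
    dup_reading <- if (st == "+") genome_subseq(genome, p - n, p)
      else revcomp(genome_subseq(genome, p, p + n))
  }
  insert_fwd <- if (st == "+") paste0(cassette$sequence, dup_reading)
    else revcomp(paste0(cassette$sequence, dup_reading))

  g <- genome$genes[!genome$genes$interior, , drop = FALSE]
  pat <- paste(avoid_keywords, collapse = "|")
  shrink_arm <- function(len, side) {
    # clamp to genome bounds first
    avail <- if (side == "left") p else L - p
    if (avail < arm_min)
      stop("cannot fit a ", arm_min, " bp ", side,
           " homology arm at position ", p)
    len <- min(len, avail)
    if (!nrow(g) || !nzchar(pat)) return(len)
    if (side == "left") {
      inside <- which(grepl(pat, g$product, ignore.case = TRUE) &
                        g$start >= p - len & g$end <= p)
      if (length(inside)) {
        want <- p - max(g$start[inside]) - 1L
        if (want >= arm_min) len <- want
        else warning("left arm at position ", p, " fully contains gene(s) ",
                     paste(g$gene_id[inside], collapse = ","),
                     " of unannotated function; could not avoid")
      }
    } else {
      inside <- which(grepl(pat, g$product, ignore.case = TRUE) &
                        g$start >= p & g$end <= p + len)
      if (length(inside)) {
        want <- min(g$end[inside]) - p - 1L
        if (want >= arm_min) len <- want
        else warning("right arm at position ", p, " fully contains gene(s) ",
                     paste(g$gene_id[inside], collapse = ","),
                     " of unannotated function; could not avoid")
      }
    }
    len
  }
  len_l <- shrink_arm(arm_max, "left")
  len_r <- shrink_arm(arm_max, "right")
  left_span <- c(p - len_l, p)
  right_span <- c(p, p + len_r)
  left_arm <- genome_subseq(genome, left_span[1], left_span[2])
  right_arm <- genome_subseq(genome, right_span[1], right_span[2])

  junc <- c(substr(left_arm, nchar(left_arm) - 19L, nchar(left_arm)),
            substr(right_arm, 1L, 20L))
  if (any(vapply(junc, function(j) nchar(j) >= 20 &&
                   grepl(j, cassette$sequence, fixed = TRUE), logical(1))))
    warning("payload cassette contains an arm junction sequence verbatim; ",
            "recombinant screening may be ambiguous")

  structure(list(
    site_id = site$site_id %||% "site",
    strand = st, position = p,
    left_arm = left_arm, right_arm = right_arm,
    left_span = left_span, right_span = right_span,
    duplicated_context = dup_reading,
    cassette = cassette,
    insert_seq = insert_fwd,
    arm_len_range = c(arm_min, arm_max),
    full_seq = paste0(left_arm, insert_fwd, right_arm)),
    class = "donor_construct")
}

#' @export
print.donor_construct <- function(x, ...) {
  cat(sprintf("<donor_construct> %s (%s strand) at position %d\n",
              x$site_id, x$strand, x$position))
  cat(sprintf("  left arm : %d bp [%d,%d)\n", nchar(x$left_arm),
              x$left_span[1], x$left_span[2]))
  cat(sprintf("  insert   : %d bp cassette '%s'%s\n", nchar(x$insert_seq),
              x$cassette$name,
              if (nzchar(x$duplicated_context))
                sprintf(" + %d bp duplicated context",
                        nchar(x$duplicated_context)) else ""))
  cat(sprintf("  right arm: %d bp [%d,%d)\n", nchar(x$right_arm),
              x$right_span[1], x$right_span[2]))
  invisible(x)
}

#' Apply a donor construct to the reference genome in silico
#'
#' Verifies both homology arms against the reference (first mismatching
#' offset reported on failure), inserts the oriented cassette and any
#' duplicated context at the site, shifts downstream annotations, and adds a
#' feature for the payload. The recombinant retains every original gene's
#' coding sequence verbatim; for sites designed under the short-gap
#' duplication rule the downstream gene's upstream context is also
#' conserved.
#'
#' @param genome The reference [annotated_genome()].
#' @param donor A [design_donor()] result.
#' @return The recombinant [annotated_genome()].
#' @export
apply_edit_in_silico <- function(genome, donor) {
  stopifnot(inherits(donor, "donor_construct"))
  check_arm <- function(arm, span, label) {
    ref <- genome_subseq(genome, span[1], span[2])
    if (ref != arm) {
      a <- strsplit(arm, "")[[1]]; r <- strsplit(ref, "")[[1]]
      off <- which(a != r)[1]
      stop(label, " arm mismatches reference at offset ", off - 1L,
           " (span [", span[1], ",", span[2], "))")
    }
  }
  check_arm(donor$left_arm, donor$left_span, "left")
  check_arm(donor$right_arm, donor$right_span, "right")
  p <- donor$position
  L <- genome_length(genome)
  ins <- donor$insert_seq
  shift <- nchar(ins)
  g <- genome$genes
  if (any(g$start < p & g$end > p))
    stop("insertion point ", p, " lies inside gene ",
         g$gene_id[which(g$start < p & g$end > p)[1]])
  move <- g$start >= p
  g$start[move] <- g$start[move] + shift
  g$end[move] <- g$end[move] + shift
  g$parts <- lapply(seq_len(nrow(g)), function(i) {
    pp <- genome$genes$parts[[i]]
    sel <- pp[, "start"] >= p
    pp[sel, ] <- pp[sel, , drop = FALSE] + shift
    pp
  })
  n_dup <- nchar(donor$duplicated_context)
  n_rbs <- nchar(donor$cassette$rbs_seq)
  n_pay <- nchar(donor$cassette$payload_seq)
  if (donor$strand == "+") {
    pay_start <- p + n_rbs
  } else {
    pay_start <- p + n_dup
  }
  payload_id <- make.unique(c(g$gene_id, donor$cassette$name))[nrow(g) + 1L]
  g <- rbind(g, gene_features(payload_id, pay_start, pay_start + n_pay,
                              donor$strand,
                              product = paste(donor$cassette$name,
                                              "payload cassette")))
  newseq <- paste0(substr(genome$sequence, 1L, p), ins,
                   substr(genome$sequence, p + 1L, L))
  annotated_genome(genome$seq_id, newseq, g, genome$topology)
}

#' Write donor constructs to FASTA
#'
#' One record per donor; the description carries the site id, strand,
#' insertion position and arm source spans so downstream records
#' cross-reference the ranking report.
#'
#' @param donors A list of [design_donor()] results (or a single one).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_donor_fasta <- function(donors, path) {
  if (inherits(donors, "donor_construct")) donors <- list(donors)
  seqs <- Biostrings::DNAStringSet(vapply(donors, `[[`, character(1), "full_seq"))
  names(seqs) <- vapply(donors, function(d)
    sprintf("%s strand=%s pos=%d left=[%d,%d) right=[%d,%d)",
            d$site_id, d$strand, d$position,
            d$left_span[1], d$left_span[2],
            d$right_span[1], d$right_span[2]), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
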