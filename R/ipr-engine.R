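# IPR engine: cluster promoter predictions into strand-aware Intergenic
# Promoter Regions, score and rank them, and select insertion sites.

#' Build Intergenic Promoter Regions (IPRs)
#'
#' A prediction joins an intergenic region when its footprint lies within the
#' region's extended span; a prediction whose footprint straddles two
#' extended regions is assigned to the region containing its midpoint (a
#' message is emitted). Within each region the members are partitioned by
#' strand into at most two IPRs (promoters on opposite strands compete
#' independently). The IPR score is the cumulative exponentially weighted
#' score of its members, `sum(exp(s_i))`, and the IPR span is the tight hull
#' of the member footprints.
#'
#' Optionally, `max_member_gap` splits a region's members into several IPRs
#' wherever the gap between consecutive footprints exceeds the given number
#' of bases (default `Inf`: the region itself is the cluster).
#'
#' @param regions An `intergenic_regions` table from
#'   [extract_intergenic_regions()].
#' @param predictions A prediction `data.frame` in forward coordinates
#'   ([parse_predictions_table()] or [scan_builtin_pwm()]).
#' @param scheme A [weighting_scheme()].
#' @param max_member_gap Maximum intra-IPR gap in bp before a region's
#'   members are split into separate IPRs (default `Inf`, off).
#' @return A `data.frame` of class `ipr_set`: `ipr_id`, `region_id`,
#'   `strand`, `span_start`, `span_end`, `n_members`, `ipr_score`, plus a
#'   list column `members` holding each IPR's prediction rows.
#' @export
build_iprs <- function(regions, predictions, scheme = weighting_scheme(),
                       max_member_gap = Inf) {
  stopifnot(is.data.frame(regions), is.data.frame(predictions))
  preds <- predictions
  n_amb <- 0L
  n_out <- 0L
  assign_region <- function(s, e) {
    inside <- which(regions$ext_start <= s & e <= regions$ext_end)
    if (length(inside) == 1L) return(inside)
    if (length(inside) > 1L) {
      n_amb <<- n_amb + 1L
      mid <- (s + e) %/% 2L
      hit <- inside[regions$ext_start[inside] <= mid &
                      mid < regions$ext_end[inside]]
      return(if (length(hit)) hit[1] else inside[1])
    }
    mid <- (s + e) %/% 2L
    hit <- which(regions$ext_start <= mid & mid < regions$ext_end)
    if (length(hit)) {
      n_amb <<- n_amb + 1L
      return(hit[1])
    }
    n_out <<- n_out + 1L
    NA_integer_
  }
  ridx <- if (nrow(preds))
    vapply(seq_len(nrow(preds)),
           function(i) assign_region(preds$start[i], preds$end[i]),
           integer(1))
  else integer(0)
  if (n_amb) message(n_amb, " prediction(s) overlapped several extended ",
                     "regions; assigned by footprint midpoint")
  if (n_out) message(n_out, " prediction(s) fell outside all extended ",
                     "intergenic regions and were dropped")
  keep <- which(!is.na(ridx))
  iprs <- list()
  for (ri in sort(unique(ridx[keep]))) {
    for (st in c("+", "-")) {
      rows <- keep[ridx[keep] == ri & preds$strand[keep] == st]
      if (!length(rows)) next
      rows <- rows[order(preds$start[rows])]
      grp <- if (is.finite(max_member_gap) && length(rows) > 1L) {
        gap_before <- c(0L, preds$start[rows][-1] -
                          cummax(preds$end[rows])[-length(rows)])
        cumsum(gap_before > max_member_gap)
      } else rep(0L, length(rows))
      for (gi in unique(grp)) {
        rr <- rows[grp == gi]
        m <- preds[rr, , drop = FALSE]
        rownames(m) <- NULL
        iprs[[length(iprs) + 1L]] <- list(
          region_id = regions$region_id[ri], strand = st,
          span_start = min(m$start), span_end = max(m$end),
          n_members = nrow(m),
          ipr_score = sum(weight_score(m$score, scheme)),
          members = m)
      }
    }
  }
  out <- data.frame(
    ipr_id = character(length(iprs)),
    region_id = vapply(iprs, `[[`, character(1), "region_id"),
    strand = vapply(iprs, `[[`, character(1), "strand"),
    span_start = vapply(iprs, function(x) as.integer(x$span_start), integer(1)),
    span_end = vapply(iprs, function(x) as.integer(x$span_end), integer(1)),
    n_members = vapply(iprs, `[[`, integer(1), "n_members"),
    ipr_score = vapply(iprs, `[[`, numeric(1), "ipr_score"),
    stringsAsFactors = FALSE)
  out$members <- lapply(iprs, `[[`, "members")
  if (nrow(out)) {
    tag <- stats::ave(seq_len(nrow(out)),
                      paste(out$region_id, out$strand), FUN = seq_along)
    ntag <- stats::ave(seq_len(nrow(out)),
                       paste(out$region_id, out$strand), FUN = length)
    out$ipr_id <- sprintf("ipr_%s_%s%s",
                          sub("^igr_", "", out$region_id),
                          ifelse(out$strand == "+", "fwd", "rev"),
                          ifelse(ntag > 1L, paste0("_", tag), ""))
  }
  class(out) <- c("ipr_set", "data.frame")
  out
}

#' Rank IPRs by cumulative weighted score
#'
#' Descending by `ipr_score`; ties broken deterministically by smaller
#' `span_start`. Adds a `rank` column.
#'
#' @param iprs An `ipr_set` from [build_iprs()].
#' @return The same table, reordered, with `rank`.
#' @export
rank_iprs <- function(iprs) {
  o <- order(-iprs$ipr_score, iprs$span_start)
  out <- iprs[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ipr_set", "data.frame")
  out
}

#' @export
print.ipr_set <- function(x, ...) {
  cat(sprintf("<ipr_set> %d IPR(s)\n", nrow(x)))
  cols <- intersect(c("rank", "ipr_id", "region_id", "strand", "span_start",
                      "span_end", "n_members", "ipr_score"), names(x))
  if (nrow(x)) print(utils::head(as.data.frame(x)[, cols], 12), row.names = FALSE)
  if (nrow(x) > 12) cat("  ... and", nrow(x) - 12, "more\n")
  invisible(x)
}

#' Select payload insertion sites downstream of ranked IPRs
#'
#' For each IPR (best score first) the first gene whose 5' boundary lies at
#' or after the IPR hull in the IPR's reading direction, and whose strand
#' matches the IPR, is located; the insertion site is the point immediately
#' past that gene's stop (its `end` on the plus strand, its `start` on the
#' minus strand). IPRs with no such downstream gene are skipped, as are IPRs
#' whose nearest candidate lies further than `max_distance` from the hull.
#' A gene already claimed by a better-scoring IPR is not selected twice.
#'
#' When a temporal-class table is supplied (gene to early/middle/late, from
#' external expression data), the top `per_class` sites are returned for each
#' class; otherwise the global top `top_n` sites are returned.
#'
#' @param iprs A ranked `ipr_set` ([rank_iprs()] is applied if the `rank`
#'   column is absent).
#' @param genome An [annotated_genome()].
#' @param temporal_classes Optional `data.frame`; first column gene id,
#'   second column class label (e.g. `early`, `middle`, `late`).
#' @param per_class Sites returned per temporal class (default 1).
#' @param top_n Sites returned when no class table is given (default `Inf`,
#'   i.e. all placeable IPRs).
#' @param max_distance Maximum distance in bp from the IPR hull to the
#'   selected gene's 5' boundary (default `Inf`, no cap).
#' @return A `data.frame` of class `insertion_sites`: `site_id`, `position`
#'   (0-based insertion point), `strand`, `driving_ipr`, `selected_gene_id`,
#'   `temporal_class`, `downstream_gap` (bp to the next gene start in reading
#'   direction, or to the genome edge), `ipr_score`.
#' @export
select_insertion_sites <- function(iprs, genome, temporal_classes = NULL,
                                   per_class = 1L, top_n = Inf,
                                   max_distance = Inf) {
  if (is.null(iprs$rank)) iprs <- rank_iprs(iprs)
  L <- genome_length(genome)
  g <- genome$genes[!genome$genes$interior, , drop = FALSE]
  class_of <- function(id) "unknown"
  if (!is.null(temporal_classes)) {
    tc <- stats::setNames(tolower(as.character(temporal_classes[[2]])),
                          as.character(temporal_classes[[1]]))
    class_of <- function(id) {
      v <- unname(tc[id])
      if (is.na(v)) "unknown" else v
    }
  }
  cand <- list()
  taken <- character(0)
  for (i in seq_len(nrow(iprs))) {
    st <- iprs$strand[i]
    if (st == "+") {
      hits <- which(g$strand == "+" & g$start >= iprs$span_start[i])
      if (!length(hits)) next
      j <- hits[which.min(g$start[hits])]
      dist <- max(0L, g$start[j] - iprs$span_end[i])
      pos <- g$end[j]
    } else {
      hits <- which(g$strand == "-" & g$end <= iprs$span_end[i])
      if (!length(hits)) next
      j <- hits[which.max(g$end[hits])]
      dist <- max(0L, iprs$span_start[i] - g$end[j])
      pos <- g$start[j]
    }
    if (dist > max_distance) next
    gid <- g$gene_id[j]
    if (gid %in% taken) next
    taken <- c(taken, gid)
    if (st == "+") {
      nxt <- which(g$start >= pos)
      gap <- if (length(nxt)) min(g$start[nxt]) - pos else L - pos
    } else {
      prv <- which(g$end <= pos)
      gap <- if (length(prv)) pos - max(g$end[prv]) else pos
    }
    cand[[length(cand) + 1L]] <- data.frame(
      position = pos, strand = st, driving_ipr = iprs$ipr_id[i],
      selected_gene_id = gid, temporal_class = class_of(gid),
      downstream_gap = as.integer(gap), ipr_score = iprs$ipr_score[i],
      rank = iprs$rank[i], stringsAsFactors = FALSE)
  }
  empty <- data.frame(site_id = character(0), position = integer(0),
                      strand = character(0), driving_ipr = character(0),
                      selected_gene_id = character(0),
                      temporal_class = character(0),
                      downstream_gap = integer(0), ipr_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(cand)) return(structure(empty,
                                      class = c("insertion_sites", "data.frame")))
  sites <- do.call(rbind, cand)
  if (!is.null(temporal_classes)) {
    classes <- unique(tolower(as.character(temporal_classes[[2]])))
    picked <- list()
    for (cl in classes) {
      rows <- sites[sites$temporal_class == cl, , drop = FALSE]
      if (!nrow(rows)) {
        warning("temporal class '", cl,
                "' has no placeable insertion site; class omitted")
        next
      }
      picked[[cl]] <- utils::head(rows[order(rows$rank), , drop = FALSE],
                                  per_class)
    }
    if (!length(picked)) return(structure(empty,
                                          class = c("insertion_sites", "data.frame")))
    sites <- do.call(rbind, picked)
  } else if (is.finite(top_n)) {
    sites <- utils::head(sites[order(sites$rank), , drop = FALSE], top_n)
  }
  sites <- sites[order(sites$rank), , drop = FALSE]
  sites$site_id <- sprintf("site_%02d", seq_len(nrow(sites)))
  sites$rank <- NULL
  sites <- sites[, c("site_id", "position", "strand", "driving_ipr",
                     "selected_gene_id", "temporal_class", "downstream_gap",
                     "ipr_score")]
  rownames(sites) <- NULL
  class(sites) <- c("insertion_sites", "data.frame")
  sites
}
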