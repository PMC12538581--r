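# End-to-end pipeline: config container, orchestrator and report plots.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default:
#' 50 bp intergenic extension, prediction score threshold 0.5, exponential
#' weighting, 200-400 bp homology arms, a 20 bp RBS-preservation window,
#' one insertion site per temporal class, both strands scanned.
#'
#' @param extension_bp Intergenic-region extension into flanking genes (bp).
#' @param score_threshold Minimum raw prediction score kept.
#' @param weighting Weighting scheme kind (`"exponential"`).
#' @param arm_min,arm_max Homology-arm length bounds (bp).
#' @param rbs_window_bp Downstream-gap threshold for the base-duplication
#'   rule (bp).
#' @param per_class_sites Insertion sites per temporal class.
#' @param top_n_sites Sites kept when no class table is given.
#' @param both_strands Scan/accept predictions on both strands?
#' @param predictor `"external_table"` or `"builtin_pwm"`.
#' @param rbs_seq RBS placed upstream of the payload.
#' @param max_member_gap Optional intra-IPR split gap (bp, `Inf` = off).
#' @param max_site_distance Optional cap on IPR-to-gene distance (bp).
#' @param arm_avoid_keywords Product keywords arms should not fully contain.
#' @param seed Seed for any stochastic stage (only the simulator draws
#'   random numbers).
#' @return A `pipeline_config` object (named list).
#' @export
pipeline_config <- function(extension_bp = 50L, score_threshold = 0.5,
                            weighting = "exponential",
                            arm_min = 200L, arm_max = 400L,
                            rbs_window_bp = 20L, per_class_sites = 1L,
                            top_n_sites = Inf, both_strands = TRUE,
                            predictor = c("external_table", "builtin_pwm"),
                            rbs_seq = "GAGGAGGTAAATATAT",
                            max_member_gap = Inf, max_site_distance = Inf,
                            arm_avoid_keywords = c("hypothetical", "unknown"),
                            seed = 1L) {
  predictor <- match.arg(predictor)
  stopifnot(extension_bp >= 0, score_threshold >= 0, score_threshold <= 1,
            arm_min > 0, arm_min <= arm_max, rbs_window_bp >= 0,
            per_class_sites >= 1)
  structure(list(extension_bp = as.integer(extension_bp),
                 score_threshold = score_threshold, weighting = weighting,
                 arm_min = as.integer(arm_min), arm_max = as.integer(arm_max),
                 rbs_window_bp = as.integer(rbs_window_bp),
                 per_class_sites = as.integer(per_class_sites),
                 top_n_sites = top_n_sites, both_strands = both_strands,
                 predictor = predictor, rbs_seq = rbs_seq,
                 max_member_gap = max_member_gap,
                 max_site_distance = max_site_distance,
                 arm_avoid_keywords = arm_avoid_keywords,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key-value file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Path to a `key = value` config file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- read_config_file(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()] to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  write_config_file(unclass(config), path)
}

#' Score-distribution histogram
#'
#' @param predictions A prediction table.
#' @param path Optional PNG path; when given the plot is written there.
#' @return Invisibly, `path` (or `NULL`).
#' @export
plot_score_histogram <- function(predictions, path = NULL) {
  draw <- function() {
    graphics::hist(predictions$score, breaks = seq(0, 1, by = 0.05),
                   main = "Predicted promoter scores", xlab = "score",
                   col = "steelblue", border = "white")
  }
  if (is.null(path)) { draw(); return(invisible(NULL)) }
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}

#' Raw-vs-weighted score curve
#'
#' @param scheme A [weighting_scheme()].
#' @param path Optional PNG path.
#' @return Invisibly, `path` (or `NULL`).
#' @export
plot_weighting_curve <- function(scheme = weighting_scheme(), path = NULL) {
  draw <- function() {
    s <- seq(0, 1, by = 0.01)
    graphics::plot(s, s, type = "l", col = "steelblue", lwd = 2,
                   xlab = "raw score", ylab = "contribution",
                   ylim = c(0, max(scheme$weight(1), 1)),
                   main = "Score weighting")
    graphics::lines(s, scheme$weight(s), col = "darkorange", lwd = 2)
    graphics::legend("topleft", legend = c("raw", "weighted"),
                     col = c("steelblue", "darkorange"), lwd = 2, bty = "n")
  }
  if (is.null(path)) { draw(); return(invisible(NULL)) }
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}

#' Run the full insertion-site design pipeline
#'
#' Reads the genome, merges split genes, extracts extended intergenic
#' regions, obtains promoter predictions (external table or built-in PWM
#' scan), builds and ranks IPRs, selects insertion sites, designs a donor
#' construct per site and verifies it by applying the edit in silico.
#' Writes, into `outdir`: `intergenic.bed`, `iprs.gff3`, `ipr_ranking.tsv`,
#' `insertion_sites.tsv`, `donors.fasta`, one `recombinant_<site>.gb` per
#' site, `score_histogram.png`, `weighting_curve.png` and `run.log` (a
#' config echo sufficient to reproduce the run). On any stage error the
#' partial outputs are removed and the error is re-thrown.
#'
#' @param genome An [annotated_genome()] or a GenBank file path.
#' @param predictions A prediction table `data.frame`, a table file path, or
#'   `NULL` to use the predictor named in `config`.
#' @param payload Payload CDS as a DNA string or a FASTA file path (first
#'   record used).
#' @param classes Optional temporal-class `data.frame` or TSV path
#'   (gene_id, class).
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created).
#' @param payload_name Cassette label.
#' @return Invisibly, a list with the computed objects (`genome`, `regions`,
#'   `predictions`, `iprs`, `sites`, `donors`, `recombinants`) and `files`.
#' @export
run_pipeline <- function(genome, predictions = NULL, payload,
                         classes = NULL, config = pipeline_config(),
                         outdir = "ipr_out", payload_name = "payload") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    if (is.character(genome)) genome <- read_genome(genome)
    if (is.character(payload)) {
      if (file.exists(payload) &&
          grepl("\\.(fa|fasta|fna)$", payload, ignore.case = TRUE)) {
        ps <- Biostrings::readDNAStringSet(payload)
        payload <- as.character(ps[[1]])
      }
    }
    if (is.character(classes))
      classes <- utils::read.table(classes, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
    genome <- merge_split_genes(genome)
    regions <- extract_intergenic_regions(genome, config$extension_bp)
    if (is.character(predictions))
      predictions <- parse_predictions_table(predictions,
                                             genome_length(genome),
                                             config$score_threshold)
    if (is.null(predictions)) {
      if (config$predictor != "builtin_pwm")
        stop("no predictions supplied and predictor is not 'builtin_pwm'")
      predictions <- scan_builtin_pwm(genome, threshold = config$score_threshold,
                                      both_strands = config$both_strands)
    } else {
      predictions <- predictions[predictions$score >= config$score_threshold, ,
                                 drop = FALSE]
      if (!config$both_strands)
        predictions <- predictions[predictions$strand == "+", , drop = FALSE]
    }
    scheme <- weighting_scheme(config$weighting)
    iprs <- rank_iprs(build_iprs(regions, predictions, scheme,
                                 config$max_member_gap))
    sites <- select_insertion_sites(iprs, genome, classes,
                                    per_class = config$per_class_sites,
                                    top_n = config$top_n_sites,
                                    max_distance = config$max_site_distance)
    cassette <- payload_cassette(payload, config$rbs_seq, payload_name)
    donors <- list()
    recombinants <- list()
    for (i in seq_len(nrow(sites))) {
      d <- design_donor(sites[i, ], genome, cassette,
                        arm_min = config$arm_min, arm_max = config$arm_max,
                        rbs_window_bp = config$rbs_window_bp,
                        avoid_keywords = config$arm_avoid_keywords)
      donors[[sites$site_id[i]]] <- d
      recombinants[[sites$site_id[i]]] <- apply_edit_in_silico(genome, d)
    }

    sid <- genome$seq_id
    files <- list(
      intergenic = emit(file.path(outdir, "intergenic.bed")),
      iprs = emit(file.path(outdir, "iprs.gff3")),
      ranking = emit(file.path(outdir, "ipr_ranking.tsv")),
      sites = emit(file.path(outdir, "insertion_sites.tsv")),
      donors = emit(file.path(outdir, "donors.fasta")),
      histogram = emit(file.path(outdir, "score_histogram.png")),
      curve = emit(file.path(outdir, "weighting_curve.png")),
      log = emit(file.path(outdir, "run.log")))
    write_bed(regions, files$intergenic, sid)
    write_gff3(iprs, files$iprs, sid, type = "promoter_region",
               score = iprs$ipr_score,
               attrs = sprintf("region=%s;n_members=%d;rank=%d",
                               iprs$region_id, iprs$n_members, iprs$rank))
    ranking <- as.data.frame(iprs)[, c("rank", "ipr_id", "region_id", "strand",
                                       "span_start", "span_end", "n_members",
                                       "ipr_score")]
    sel <- match(ranking$ipr_id, sites$driving_ipr)
    ranking$selected_gene <- ifelse(is.na(sel), "",
                                    sites$selected_gene_id[sel])
    ranking$temporal_class <- ifelse(is.na(sel), "",
                                     sites$temporal_class[sel])
    utils::write.table(ranking, files$ranking, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(as.data.frame(sites), files$sites, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (length(donors)) write_donor_fasta(donors, files$donors)
    else writeLines(character(0), files$donors)
    for (sidname in names(recombinants)) {
      f <- emit(file.path(outdir, sprintf("recombinant_%s.gb", sidname)))
      write_genbank(recombinants[[sidname]], f)
      files[[paste0("recombinant_", sidname)]] <- f
    }
    if (nrow(predictions)) plot_score_histogram(predictions, files$histogram)
    else { grDevices::png(files$histogram); graphics::plot.new(); grDevices::dev.off() }
    plot_weighting_curve(scheme, files$curve)
    cfg_echo <- vapply(unclass(config),
                       function(v) paste(format(v, trim = TRUE), collapse = ","),
                       character(1))
    writeLines(c(sprintf("genome: %s (%d bp, %d genes)", sid,
                         genome_length(genome), nrow(genome$genes)),
                 sprintf("predictions: %d kept", nrow(predictions)),
                 sprintf("iprs: %d; sites: %d", nrow(iprs), nrow(sites)),
                 "config:",
                 sprintf("  %s = %s", names(cfg_echo), cfg_echo)),
               files$log)
    invisible(list(genome = genome, regions = regions,
                   predictions = predictions, iprs = iprs, sites = sites,
                   donors = donors, recombinants = recombinants,
                   files = files))
  }, error = on_fail)
}
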