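# IPR engine: clustering, cumulative weighted scores, ranking, and
# insertion-site selection.

region_row <- function(core_start, core_end, ext = 50L, id = "igr_001",
                       L = 10000L) {
  data.frame(region_id = id, core_start = core_start, core_end = core_end,
             ext_start = max(0L, core_start - ext),
             ext_end = min(L, core_end + ext),
             upstream_gene_id = NA_character_,
             downstream_gene_id = NA_character_,
             stringsAsFactors = FALSE)
}

pred_row <- function(start, score, strand = "+", len = 6L) {
  data.frame(strand = strand, start = start, end = start + len,
             motif_seq = strrep("A", len), score = score,
             source = "external_table", stringsAsFactors = FALSE)
}

test_that("a single 0.921 promoter yields the worked IPR score 2.51", {
  iprs <- build_iprs(region_row(300L, 400L), pred_row(310L, 0.921))
  expect_equal(nrow(iprs), 1L)
  expect_equal(round(iprs$ipr_score, 2), 2.51)
  expect_equal(iprs$n_members, 1L)
})

test_that("regions without members yield no IPR", {
  iprs <- build_iprs(region_row(300L, 400L), pred_row(310L, 0.9)[0, ])
  expect_equal(nrow(iprs), 0L)
})

test_that("the IPR score is the direct sum of exponential weights", {
  scores <- c(0.6, 0.8, 1.0)
  preds <- do.call(rbind, lapply(seq_along(scores), function(i)
    pred_row(300L + 10L * i, scores[i])))
  iprs <- build_iprs(region_row(250L, 450L), preds)
  expect_equal(iprs$ipr_score, sum(exp(scores)))
  expect_equal(iprs$n_members, 3L)
  # additivity: dropping one member lowers the score by exactly its weight
  iprs2 <- build_iprs(region_row(250L, 450L), preds[-2, ])
  expect_equal(iprs$ipr_score - iprs2$ipr_score, exp(scores[2]))
})

test_that("members split by strand into at most two competing IPRs", {
  preds <- rbind(pred_row(310L, 0.9, "+"), pred_row(330L, 0.8, "-"),
                 pred_row(350L, 0.7, "+"))
  iprs <- build_iprs(region_row(300L, 400L), preds)
  expect_equal(nrow(iprs), 2L)
  expect_setequal(iprs$strand, c("-", "+"))
  expect_equal(iprs$ipr_score[iprs$strand == "+"], exp(0.9) + exp(0.7))
  expect_equal(iprs$ipr_score[iprs$strand == "-"], exp(0.8))
  # spans are tight hulls of member footprints
  expect_equal(iprs$span_start[iprs$strand == "+"], 310L)
  expect_equal(iprs$span_end[iprs$strand == "+"], 356L)
})

test_that("a prediction straddling two extended regions goes to its midpoint region", {
  regions <- rbind(region_row(100L, 200L, id = "igr_001"),
                   region_row(230L, 330L, id = "igr_002"))
  # footprint [195, 245): midpoint 220 lies in igr_001's extension [50, 250)
  straddler <- pred_row(195L, 0.9, len = 50L)
  expect_message(iprs <- build_iprs(regions, straddler), "midpoint")
  expect_equal(iprs$region_id, "igr_001")
})

test_that("predictions outside all extended regions are dropped with a message", {
  expect_message(iprs <- build_iprs(region_row(100L, 200L),
                                    pred_row(5000L, 0.9)),
                 "dropped")
  expect_equal(nrow(iprs), 0L)
})

test_that("the optional density splitter divides far-apart members", {
  preds <- rbind(pred_row(300L, 0.9), pred_row(310L, 0.8),
                 pred_row(900L, 0.7))
  region <- region_row(250L, 1000L)
  expect_equal(nrow(build_iprs(region, preds)), 1L)
  split <- build_iprs(region, preds, max_member_gap = 200L)
  expect_equal(nrow(split), 2L)
  expect_equal(split$n_members, c(2L, 1L))
  expect_equal(split$ipr_score, c(exp(0.9) + exp(0.8), exp(0.7)))
})

test_that("ranking reproduces the printed late > mid > early order", {
  iprs <- rbind(
    cbind(build_iprs(region_row(100L, 200L), pred_row(110L, 0.9)),
          label = "early"),
    cbind(build_iprs(region_row(300L, 400L), pred_row(310L, 0.95)),
          label = "late"),
    cbind(build_iprs(region_row(500L, 600L), pred_row(510L, 0.92)),
          label = "mid"))
  iprs$ipr_score <- c(9.02, 14.14, 12.25)
  ranked <- rank_iprs(iprs)
  expect_equal(ranked$ipr_score, c(14.14, 12.25, 9.02))
  expect_equal(ranked$label, c("late", "mid", "early"))
  expect_equal(ranked$rank, 1:3)
})

test_that("score ties break deterministically by smaller span start", {
  a <- build_iprs(region_row(500L, 600L), pred_row(510L, 0.9))
  b <- build_iprs(region_row(100L, 200L, id = "igr_002"), pred_row(110L, 0.9))
  ranked <- rank_iprs(rbind(a, b))
  expect_equal(ranked$span_start, c(110L, 510L))
})

test_that("ranking equals a brute-force sort on random IPR sets", {
  set.seed(77)
  scores <- round(stats::runif(50), 3)
  starts <- sample.int(100000L, 50)
  iprs <- data.frame(ipr_id = sprintf("i%02d", 1:50), region_id = "r",
                     strand = "+", span_start = starts,
                     span_end = starts + 30L, n_members = 1L,
                     ipr_score = scores, stringsAsFactors = FALSE)
  ranked <- rank_iprs(iprs)
  o <- order(-iprs$ipr_score, iprs$span_start)  # brute-force oracle
  expect_equal(ranked$ipr_id, iprs$ipr_id[o])
})

test_that("site selection honors orientation and picks the 3' boundary", {
  g <- toy_genome(c(400L, 800L), c(700L, 900L), c("+", "-"), L = 1000L)
  iprs <- build_iprs(region_row(250L, 450L), pred_row(310L, 0.9))
  iprs$span_start <- 300L; iprs$span_end <- 350L
  sites <- select_insertion_sites(iprs, g)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 700L)
  expect_equal(sites$selected_gene_id, "g01")
  # minus-strand mirror: nearest upstream-in-reading-direction gene
  gm <- toy_genome(c(100L, 500L), c(250L, 800L), c("-", "+"), L = 1000L)
  iprsm <- build_iprs(region_row(250L, 450L), pred_row(310L, 0.9, "-"))
  iprsm$span_start <- 300L; iprsm$span_end <- 350L
  sitesm <- select_insertion_sites(iprsm, gm)
  expect_equal(sitesm$position, 100L)
  expect_equal(sitesm$selected_gene_id, "g01")
})

test_that("IPRs with no same-orientation downstream gene are skipped", {
  g <- toy_genome(400L, 700L, "-", L = 1000L)
  iprs <- build_iprs(region_row(250L, 450L), pred_row(310L, 0.9))
  sites <- select_insertion_sites(iprs, g)
  expect_equal(nrow(sites), 0L)
})

test_that("per-class selection returns each class's top-ranked candidate", {
  sim <- simulate_genome(demo_sim_config(seed = 42))
  genome <- sim$genome
  regions <- extract_intergenic_regions(genome, 50L)
  iprs <- rank_iprs(build_iprs(regions, sim$predictions))
  sites <- select_insertion_sites(iprs, genome, sim$classes)
  expect_equal(nrow(sites), 3L)
  expect_setequal(sites$temporal_class, c("early", "middle", "late"))
  # exhaustive oracle: enumerate every IPR's candidate gene, then take the
  # best-scoring placeable IPR per class
  class_of <- stats::setNames(sim$classes$temporal_class, sim$classes$gene_id)
  best <- list()
  for (i in seq_len(nrow(iprs))) {
    cand <- oracle_select_gene(iprs$strand[i], iprs$span_start[i],
                               iprs$span_end[i], genome$genes)
    if (is.null(cand)) next
    cl <- unname(class_of[cand$gene_id])
    if (is.null(best[[cl]])) best[[cl]] <- cand$gene_id
  }
  for (cl in names(best))
    expect_equal(sites$selected_gene_id[sites$temporal_class == cl],
                 best[[cl]])
})

test_that("an empty temporal class warns and is omitted", {
  g <- toy_genome(c(400L, 800L), c(700L, 900L), c("+", "-"), L = 1000L)
  iprs <- build_iprs(region_row(250L, 450L), pred_row(310L, 0.9))
  classes <- data.frame(gene_id = c("g01", "g02"),
                        temporal_class = c("early", "late"))
  expect_warning(sites <- select_insertion_sites(iprs, g, classes),
                 "late")
  expect_equal(sites$temporal_class, "early")
})

test_that("IPR scores and spans mirror under reverse complement", {
  sim <- simulate_genome(sim_config(seed = 13, strand_pattern = "random",
    planted_iprs = list(
      list(region = 2, strand = "+", n = 3, score_mean = 0.9, score_sd = 0.05),
      list(region = 6, strand = "-", n = 2, score_mean = 0.8, score_sd = 0.05))))
  g <- sim$genome
  L <- genome_length(g)
  grc <- reverse_complement_genome(g)
  prc <- sim$predictions
  prc[, c("start", "end")] <- cbind(L - sim$predictions$end,
                                    L - sim$predictions$start)
  prc$strand <- ifelse(sim$predictions$strand == "+", "-", "+")
  fwd <- rank_iprs(build_iprs(extract_intergenic_regions(g, 50L),
                              sim$predictions))
  rev <- rank_iprs(build_iprs(extract_intergenic_regions(grc, 50L), prc))
  expect_equal(rev$ipr_score, fwd$ipr_score)
  expect_equal(rev$span_start, L - fwd$span_end)
  expect_equal(rev$span_end, L - fwd$span_start)
  expect_equal(rev$strand, ifelse(fwd$strand == "+", "-", "+"))
})
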