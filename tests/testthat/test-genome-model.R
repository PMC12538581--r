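# Genome model: GenBank coordinate conventions, split-gene merging,
# intergenic extraction.

test_that("read_genome converts GenBank 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(toy_genbank_text(), f)
  g <- read_genome(f)
  expect_s3_class(g, "annotated_genome")
  expect_equal(genome_length(g), 1000L)
  expect_equal(g$genes$gene_id, c("gA", "gB", "gC"))
  expect_equal(g$genes$start, c(0L, 400L, 800L))
  expect_equal(g$genes$end, c(300L, 700L, 1000L))
  expect_equal(g$genes$strand, c("+", "-", "+"))
  expect_equal(g$genes$product[1], "terminase")
})

test_that("read_genome preserves multi-part join locations in parts", {
  f <- withr::local_tempfile(fileext = ".gb")
  txt <- toy_genbank_text()
  txt <- append(txt, c("     CDS             join(100..200,301..400)",
                       '                     /locus_tag="gJ"'),
                after = grep('locus_tag="gC"', txt))
  writeLines(txt, f)
  g <- read_genome(f)
  j <- g$genes[g$genes$gene_id == "gJ", ]
  expect_equal(j$start, 99L)
  expect_equal(j$end, 400L)
  expect_equal(j$parts[[1]],
               cbind(start = c(99L, 300L), end = c(200L, 400L)))
})

test_that("read_genome rejects records without sequence or annotations", {
  f <- withr::local_tempfile(fileext = ".gb")
  txt <- toy_genbank_text()
  writeLines(txt[seq_len(grep("^ORIGIN", txt) - 1L)], f)
  expect_error(read_genome(f), "ORIGIN|sequence")
  writeLines(c(txt[1:4], txt[grep("^ORIGIN", txt):length(txt)]), f)
  expect_error(read_genome(f), "no annotations")
})

test_that("genbank writer round-trips through the reader", {
  sim <- simulate_genome(sim_config(genome_length = 8000L, n_genes = 4L,
                                    seed = 11))
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, f)
  back <- read_genome(f)
  expect_equal(back$sequence, sim$genome$sequence)
  expect_equal(back$genes$start, sim$genome$genes$start)
  expect_equal(back$genes$end, sim$genome$genes$end)
  expect_equal(back$genes$strand, sim$genome$genes$strand)
  expect_equal(back$genes$gene_id, sim$genome$genes$gene_id)
})

test_that("merge_split_genes collapses the split locus and flags nested genes", {
  # gp141/gp142-style pattern: A in two exons, B nested between them
  g <- toy_genome(starts = c(99L, 210L), ends = c(400L, 290L),
                  ids = c("A", "B"), L = 600L,
                  parts = list(cbind(start = c(99L, 300L),
                                     end = c(200L, 400L)), NULL))
  m <- merge_split_genes(g)
  a <- m$genes[m$genes$gene_id == "A", ]
  expect_equal(c(a$start, a$end), c(99L, 400L))
  expect_equal(nrow(a$parts[[1]]), 1L)
  expect_true(m$genes$interior[m$genes$gene_id == "B"])
  # intergenic computation sees only A's merged span there
  regions <- extract_intergenic_regions(m, extension = 0L)
  expect_false(any(regions$core_start >= 200 & regions$core_end <= 300))
  expect_true(any(regions$core_start == 400))
})

test_that("merge_split_genes is the identity without multi-part genes and is idempotent", {
  g <- toy_genome(c(0L, 400L), c(300L, 700L))
  expect_equal(merge_split_genes(g), g)
  split <- toy_genome(starts = c(99L, 210L), ends = c(400L, 290L),
                      ids = c("A", "B"), L = 600L,
                      parts = list(cbind(start = c(99L, 300L),
                                         end = c(200L, 400L)), NULL))
  once <- merge_split_genes(split)
  expect_equal(merge_split_genes(once), once)
})

test_that("two multi-part genes collapse independently to their part hulls", {
  parts1 <- cbind(start = c(10L, 120L), end = c(80L, 200L))
  parts2 <- cbind(start = c(300L, 450L, 600L), end = c(380L, 520L, 700L))
  g <- toy_genome(starts = c(10L, 300L), ends = c(200L, 700L),
                  ids = c("A", "B"), L = 800L,
                  parts = list(parts1, parts2))
  m <- merge_split_genes(g)
  # hull oracle: brute-force min/max over the original parts
  expect_equal(m$genes$start, c(min(parts1[, 1]), min(parts2[, 1])))
  expect_equal(m$genes$end, c(max(parts1[, 2]), max(parts2[, 2])))
})

test_that("merge_split_genes rejects parts wrapping a linear genome's origin", {
  g <- toy_genome(starts = 0L, ends = 900L, ids = "W", L = 1000L,
                  parts = list(cbind(start = c(800L, 0L),
                                     end = c(900L, 100L))))
  expect_error(merge_split_genes(g), "origin")
})

test_that("extract_intergenic_regions matches the worked interval examples", {
  g <- toy_genome(c(0L, 400L), c(300L, 700L), L = 1000L)
  r <- extract_intergenic_regions(g, extension = 50L)
  expect_equal(r$core_start, c(300L, 700L))
  expect_equal(r$core_end, c(400L, 1000L))
  expect_equal(r$ext_start, c(250L, 650L))
  expect_equal(r$ext_end, c(450L, 1000L))
  expect_equal(r$upstream_gene_id, c("g01", "g02"))
  expect_equal(r$downstream_gene_id, c("g02", NA))
})

test_that("abutting genes leave a zero-width core with a 2E-wide extension", {
  g <- toy_genome(c(0L, 300L), c(300L, 600L), L = 600L)
  r <- extract_intergenic_regions(g, extension = 50L)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$core_start, r$core_end), c(300L, 300L))
  expect_equal(c(r$ext_start, r$ext_end), c(250L, 350L))
})

test_that("genes tiling the whole genome yield an empty region set", {
  g <- toy_genome(c(0L, 250L, 500L), c(300L, 600L, 1000L), L = 1000L)
  r <- extract_intergenic_regions(g)
  expect_equal(nrow(r), 0L)
})

test_that("a circular genome reports the wrap-around gap as one region", {
  g <- toy_genome(c(100L, 500L), c(400L, 900L), L = 1000L,
                  topology = "circular")
  r <- extract_intergenic_regions(g, extension = 50L)
  expect_equal(nrow(r), 2L)
  wrap <- r[nrow(r), ]
  expect_equal(c(wrap$core_start, wrap$core_end), c(900L, 1100L))
  expect_equal(wrap$downstream_gene_id, "g01")
})

test_that("cores match the per-base coverage oracle and tile the genome", {
  set.seed(101)
  for (rep in 1:50) {
    L <- sample(2000:50000, 1L)
    genes <- random_gene_layout(L, sample(3:20, 1L))
    if (!nrow(genes)) next
    g <- toy_genome(genes$start, genes$end, genes$strand, L = L,
                    ids = genes$gene_id)
    r <- extract_intergenic_regions(g, extension = 50L)
    pos <- r[r$core_end > r$core_start, , drop = FALSE]
    expect_equal(pos$core_start, oracle_intergenic_cores(g)$start)
    expect_equal(pos$core_end, oracle_intergenic_cores(g)$end)
    # tiling: gene bodies + cores cover [0, L) disjointly
    mask <- integer(L)
    for (i in seq_len(nrow(g$genes)))
      mask[(g$genes$start[i] + 1L):g$genes$end[i]] <-
        mask[(g$genes$start[i] + 1L):g$genes$end[i]] + 1L
    # overlapping genes are unioned, so clamp gene coverage to 1
    mask <- pmin(mask, 1L)
    for (i in seq_len(nrow(pos)))
      mask[(pos$core_start[i] + 1L):pos$core_end[i]] <-
        mask[(pos$core_start[i] + 1L):pos$core_end[i]] + 1L
    expect_true(all(mask == 1L))
    # extension bound: each extension reaches at most E into flanking space
    expect_true(all(r$core_start - r$ext_start <= 50L))
    expect_true(all(r$ext_end - r$core_end <= 50L))
  }
})

test_that("region sets round-trip through BED with identical coordinates", {
  g <- toy_genome(c(0L, 400L), c(300L, 700L), L = 1000L)
  r <- extract_intergenic_regions(g, extension = 50L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, f, seq_id = g$seq_id)
  back <- read_bed(f)
  expect_equal(back$start, r$core_start)
  expect_equal(back$end, r$core_end)
  expect_equal(back$ext_start, r$ext_start)
  expect_equal(back$ext_end, r$ext_end)
  expect_equal(back$name, r$region_id)
})

test_that("reverse_complement_genome mirrors coordinates and strands", {
  g <- toy_genome(c(100L, 500L), c(400L, 900L), c("+", "-"), L = 1000L,
                  sequence = rand_dna(1000, seed = 5))
  rc <- reverse_complement_genome(g)
  expect_equal(rc$genes$start, c(1000L - 900L, 1000L - 400L))
  expect_equal(rc$genes$end, c(1000L - 500L, 1000L - 100L))
  expect_equal(rc$genes$strand, c("+", "-"))  # g02 flips to +, sorts first
  expect_equal(reverse_complement_genome(rc)$sequence, g$sequence)
  # reading-frame gene sequences are invariant under the mirror
  expect_equal(sort(unname(gene_sequences(rc))),
               sort(unname(gene_sequences(g))))
})
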