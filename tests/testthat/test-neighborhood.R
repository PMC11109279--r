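test_that("intergenic gap follows the start-end-1 convention", {
  expect_identical(intergenic_gap(gene_row("a", 100, 200),
                                  gene_row("b", 221, 300)), 20L)
  expect_identical(intergenic_gap(gene_row("a", 100, 200),
                                  gene_row("b", 195, 300)), -6L)
  expect_identical(intergenic_gap(gene_row("a", 100, 200),
                                  gene_row("b", 201, 300)), 0L)
  expect_error(intergenic_gap(gene_row("a", 100, 200),
                              gene_row("b", 221, 300, contig = "ctg2")),
               "different contigs")
})

test_that("gap sign distinguishes overlapping from non-overlapping genes", {
  set.seed(42)
  for (i in 1:50) {
    s1 <- sample(1:1000, 1); e1 <- s1 + sample(50:500, 1)
    s2 <- s1 + sample(1:800, 1); e2 <- s2 + sample(50:500, 1)
    g <- intergenic_gap(gene_row("a", s1, e1), gene_row("b", s2, e2))
    overlaps <- s2 <= e1
    expect_identical(g < 0, overlaps)
  }
})

test_that("GFF3 parsing yields coordinate-sorted records and flags bad rows", {
  f <- toy_gff3(withr::local_tempfile(fileext = ".gff3"), c(
    "ctg1\tsrc\tCDS\t500\t900\t.\t+\t0\tID=g2;product=beta",
    "ctg1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=g1;product=alpha",
    "ctg1\tsrc\tCDS\t1000\t1500\t.\t-\t0\tID=g3"))
  loaded <- load_annotations(f)
  expect_identical(loaded$genes$gene_id, c("g1", "g2", "g3"))
  expect_identical(loaded$genes$product, c("alpha", "beta", ""))

  bad <- toy_gff3(withr::local_tempfile(fileext = ".gff3"),
                  "ctg1\tsrc\tCDS\t400\t100\t.\t+\t0\tID=broken")
  expect_error(suppressWarnings(load_annotations(bad)), "broken")
})

test_that("anchor detection applies both thresholds to the best hit", {
  genes <- rbind(gene_row("g1", 100, 400), gene_row("g2", 500, 900))
  hits <- data.frame(query_id = "g1", subject_id = "ref",
                     percent_identity = 45, alignment_length = 100,
                     bit_score = 200, e_value = 1e-30)
  found <- find_anchor_genes(genes, hits = hits)
  expect_identical(found$gene_id, "g1")

  low <- transform(hits, percent_identity = 10)
  expect_identical(nrow(find_anchor_genes(genes, hits = low)), 0L)
  weak <- transform(hits, e_value = 1)
  expect_identical(nrow(find_anchor_genes(genes, hits = weak)), 0L)

  expect_identical(nrow(find_anchor_genes(genes[0, ], hits = hits)), 0L)
  stray <- transform(hits, query_id = "nope")
  expect_warning(res <- find_anchor_genes(genes, hits = stray), "unknown")
  expect_identical(nrow(res), 0L)
})

test_that("built-in local alignment finds the planted homolog", {
  set.seed(7)
  ref <- paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                        "M","F","P","S","T","W","Y","V"), 80,
                      replace = TRUE), collapse = "")
  decoy <- paste(sample(c("G","P","S","T"), 80, replace = TRUE),
                 collapse = "")
  genes <- rbind(gene_row("hom", 100, 400), gene_row("dec", 500, 900))
  prots <- Biostrings::AAStringSet(c(hom = ref, dec = decoy))
  found <- find_anchor_genes(genes, reference_protein = ref,
                             proteins = prots, min_identity = 90)
  expect_identical(found$gene_id, "hom")
  expect_true(found$e_value < 1e-5)
})

test_that("co-transcription follows the strand + gap-window rule", {
  expect_identical(nrow(predict_co_transcription(
    toy_unit(20))$co_transcribed), 1L)
  expect_identical(nrow(predict_co_transcription(
    toy_unit(500))$co_transcribed), 0L)
  expect_identical(nrow(predict_co_transcription(
    toy_unit(10, nb_strand = "-"))$co_transcribed), 0L)
  expect_identical(nrow(predict_co_transcription(
    toy_unit(10, nb_strand = "-"),
    require_same_strand = FALSE)$co_transcribed), 1L)
  # abutting and slightly overlapping genes count as co-transcribed
  expect_identical(nrow(predict_co_transcription(
    toy_unit(0))$co_transcribed), 1L)
  expect_identical(nrow(predict_co_transcription(
    toy_unit(-15))$co_transcribed), 1L)
})

test_that("the co-transcribed chain breaks at the first failing link", {
  genes <- rbind(
    gene_row("anchor", 1001, 1900, product = "heliorhodopsin"),
    gene_row("n1", 1911, 2500, product = "glutamine synthetase"),
    gene_row("n2", 3200, 3800, product = "NAD+ synthetase"),
    gene_row("n3", 3811, 4400, product = "TerC family protein"))
  u <- predict_co_transcription(neighborhood(genes, "anchor"))
  # n2 fails (gap 699), so n3 is unreachable even though its own gap passes
  expect_identical(u$co_transcribed$gene_id, "n1")
})

test_that("external promoter calls override the distance heuristic", {
  u <- toy_unit(500)
  calls <- data.frame(gene_id = "nbr", co_transcribed = TRUE)
  expect_identical(nrow(predict_co_transcription(
    u, promoter_calls = calls)$co_transcribed), 1L)
})

test_that("shrinking the gap window never adds co-transcribed neighbors", {
  set.seed(11)
  for (i in 1:30) {
    u <- toy_unit(sample(-30:60, 1))
    wide <- predict_co_transcription(u, gap_window = c(-20, 30))
    narrow <- predict_co_transcription(u, gap_window = c(-10, 15))
    expect_true(all(narrow$co_transcribed$gene_id %in%
                      wide$co_transcribed$gene_id))
  }
})

test_that("group classification uses nearest co-transcribed product", {
  u <- predict_co_transcription(toy_unit(20))
  expect_identical(classify_neighbor_group(u), "glutamine_synthetase")
  expect_identical(
    classify_neighbor_group(predict_co_transcription(toy_unit(500))),
    "non_co_transcription")
  u2 <- predict_co_transcription(
    toy_unit(20, product = "ABC transporter ATP-binding protein"))
  expect_identical(classify_neighbor_group(u2), "abc_transporter")
  u3 <- predict_co_transcription(toy_unit(20, product = "mystery protein"))
  expect_identical(classify_neighbor_group(u3), "other")
})

test_that("ambiguous products resolve by the keyword map priority order", {
  u <- predict_co_transcription(
    toy_unit(20, product = "glutamine synthetase / TerC family fusion"))
  expect_identical(classify_neighbor_group(u), "glutamine_synthetase")
})

test_that("cohort summary fractions and partition bookkeeping hold", {
  units <- c(lapply(1:5, function(i) toy_unit(20)),
             lapply(1:5, function(i) toy_unit(500)))
  cl <- classify_cohort(units)
  cl$anchor_id <- paste0("a", seq_len(nrow(cl)))
  s <- summarize_cohort(cl)
  expect_equal(s$fraction_co_transcribed, 0.5)
  expect_identical(s$n_with_adjacent, 5L)
  expect_identical(sum(unlist(s$per_group_count)), s$n_total_anchors)

  lone <- classify_cohort(lapply(1:4, function(i) toy_unit(500)))
  lone$anchor_id <- paste0("b", 1:4)
  s2 <- summarize_cohort(lone)
  expect_equal(s2$fraction_co_transcribed, 0)
  expect_identical(s2$per_group_count$non_co_transcription, 4L)

  expect_error(summarize_cohort(cl[0, ]), "no anchors")
})
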