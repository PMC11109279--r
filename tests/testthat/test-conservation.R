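aln_from <- function(..., ref = "REF") {
  seqs <- c(...)
  labeled_alignment(seqs, reference_id = ref)
}

test_that("reference map skips reference gap columns and round-trips", {
  a <- aln_from(REF = "ACDEF", s1 = "ACDEF")
  expect_identical(map_columns_to_reference(a), 1:5)

  b <- aln_from(REF = "AC-GT", s1 = "ACWGT")
  expect_identical(map_columns_to_reference(b), c(1L, 2L, 4L, 5L))
  cols <- map_columns_to_reference(b)
  expect_identical(b$mat["REF", cols], c("A", "C", "G", "T"))

  expect_error(labeled_alignment(c(s1 = "ACD"), reference_id = "REF"),
               "absent")
})

test_that("per-HeR frequencies count residues over the full group size", {
  a <- aln_from(REF = "A", s1 = "A", s2 = "A", s3 = "A", s4 = "G")
  p <- frequency_per_her(a, ids = paste0("s", 1:4))
  expect_equal(p$freq["A", "1"], 0.75)
  expect_equal(p$freq["G", "1"], 0.25)

  g <- aln_from(REF = "A", s1 = "-", s2 = "-")
  pg <- frequency_per_her(g, ids = c("s1", "s2"))
  expect_equal(pg$na_fraction[[1]], 1.0)
  expect_equal(sum(pg$freq[, "1"]), 0)

  one <- frequency_per_her(a, ids = "s4")
  expect_true(all(one$freq %in% c(0, 1)))
  expect_error(frequency_per_her(a, ids = character(0)), "empty")
})

test_that("frequencies plus NA fraction sum to one at every position", {
  aln <- generate_labeled_alignment(c(abc_transporter = 30,
                                      non_co_transcription = 30),
                                    L = 40, gap_rate = 0.1, seed = 2)
  p <- frequency_per_her(aln, group_label = "abc_transporter")
  expect_lt(max(abs(colSums(p$freq) + p$na_fraction - 1)), 1e-12)
})

test_that("differential flagging is strict at the threshold", {
  mk <- function(fA) {
    a <- structure(list(
      freq = matrix(c(fA, 1 - fA), 2, 1,
                    dimnames = list(c("A", "G"), "1")),
      na_fraction = 0, n_sequences = 100, group = NA_character_),
      class = "frequency_profile")
    a
  }
  up <- differential_frequency(mk(0.50), mk(0.30))   # delta = 0.20
  expect_identical(nrow(up$flags_up), 1L)
  at <- differential_frequency(mk(0.50), mk(0.31))   # delta = 0.19
  expect_identical(nrow(at$flags_up), 0L)
  same <- differential_frequency(mk(0.4), mk(0.4))
  expect_true(all(same$delta == 0))
  expect_identical(nrow(same$flags_up) + nrow(same$flags_down), 0L)
})

test_that("differential profiles are antisymmetric and theta-monotone", {
  aln <- generate_labeled_alignment(
    c(abc_transporter = 60, non_co_transcription = 60), L = 50,
    enrichment = data.frame(group = "abc_transporter", position = 10L,
                            aa = "K", delta = 0.4),
    seed = 3)
  pa <- frequency_per_her(aln, group_label = "abc_transporter")
  pb <- frequency_per_her(aln, group_label = "non_co_transcription")
  d_ab <- differential_frequency(pa, pb)
  d_ba <- differential_frequency(pb, pa)
  expect_equal(d_ab$delta, -d_ba$delta)
  expect_identical(nrow(d_ab$flags_up), nrow(d_ba$flags_down))

  loose <- differential_frequency(pa, pb, theta = 0.10)
  tight <- differential_frequency(pa, pb, theta = 0.30)
  expect_lte(nrow(tight$flags_up), nrow(loose$flags_up))
  expect_lte(nrow(tight$flags_down), nrow(loose$flags_down))
})

test_that("planted enrichment is recovered within binomial error", {
  delta <- 0.3
  n <- 400
  aln <- generate_labeled_alignment(
    c(abc_transporter = n, non_co_transcription = n), L = 60,
    enrichment = data.frame(group = "abc_transporter", position = 29L,
                            aa = "R", delta = delta),
    seed = 4)
  pa <- frequency_per_her(aln, group_label = "abc_transporter")
  pb <- frequency_per_her(aln, group_label = "non_co_transcription")
  d <- differential_frequency(pa, pb)
  se <- sqrt(0.5 * 0.5 * 2 / n)   # conservative binomial SE of a difference
  expect_lt(abs(d$delta["R", "29"] - delta), 3 * se)
})

test_that("class aggregation sums members and enforces disjointness", {
  a <- structure(list(
    freq = matrix(0, 20, 1, dimnames = list(
      c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
        "T","W","Y","V"), "1")),
    na_fraction = 0.1, n_sequences = 10, group = NA_character_),
    class = "frequency_profile")
  a$freq["D", "1"] <- 0.3
  a$freq["E", "1"] <- 0.2
  cm <- list(acidic = c("D", "E"), empty = character(0))
  agg <- aggregate_classes(a, cm)
  expect_equal(agg["acidic", "1"], 0.5)
  expect_equal(agg["empty", "1"], 0)

  expect_error(aggregate_classes(a, default_class_map()), "two classes")
  agg2 <- aggregate_classes(a, default_class_map(), resolve_overlaps = TRUE)
  expect_identical(rownames(agg2), names(default_class_map()))
})

test_that("class sums never exceed the non-gap mass", {
  set.seed(9)
  for (i in 1:10) {
    aln <- generate_labeled_alignment(
      c(abc_transporter = 25, non_co_transcription = 25), L = 30,
      gap_rate = stats::runif(1, 0, 0.3), seed = i)
    p <- frequency_per_her(aln, group_label = "abc_transporter")
    agg <- aggregate_classes(p, default_class_map(), resolve_overlaps = TRUE)
    expect_true(all(colSums(agg) <= 1 - p$na_fraction + 1e-12))
  }
})

test_that("charge conservation ranks planted ICL3 positions on top", {
  enr <- data.frame(group = rep("abc_transporter", 2),
                    position = c(229L, 233L), aa = "R", delta = 0.6)
  aln <- generate_labeled_alignment(
    c(abc_transporter = 200, non_co_transcription = 50), L = 240,
    enrichment = enr, seed = 6)
  p <- frequency_per_her(aln, group_label = "abc_transporter")
  cs <- charge_conservation_by_region(p)
  top2 <- cs$per_region$ICL3$position[1:2]
  expect_setequal(top2, c(229L, 233L))

  # fully conserved R at one position gives positive_freq exactly 1
  mono <- labeled_alignment(
    c(REF = "AR", s1 = "AR", s2 = "AR"), reference_id = "REF")
  pm <- frequency_per_her(mono, ids = c("s1", "s2"))
  cm <- charge_conservation_by_region(pm, topology_map = list(ICL3 = 2L))
  expect_equal(cm$per_position$positive_freq[2], 1.0)
})
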