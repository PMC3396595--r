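make_hit <- function(id, start, end, pattern = "m") {
  data.frame(sequence_id = id, pattern_name = pattern,
             start = start, end = end,
             matched = strrep("A", end - start), stringsAsFactors = FALSE)
}

test_that("intra-domain means full containment; straddlers are extradomain", {
  dom <- data.frame(protein_id = "P1", domain_label = "A",
                    start = 0L, end = 200L)
  cl <- classify_hits(make_hit("P1", 5L, 16L), dom)
  expect_equal(nrow(cl$intra), 1L)
  expect_equal(cl$intra$domain_label, "A")

  cl2 <- classify_hits(make_hit("P1", 195L, 206L), dom)
  expect_equal(nrow(cl2$intra), 0L)
  expect_equal(nrow(cl2$extra), 1L)

  # boundary-touching hits are contained
  cl3 <- classify_hits(make_hit("P1", 189L, 200L), dom)
  expect_equal(nrow(cl3$intra), 1L)

  # proteins without domain annotation contribute extradomain hits
  cl4 <- classify_hits(make_hit("P9", 5L, 16L), dom)
  expect_equal(nrow(cl4$extra), 1L)
})

test_that("classification partitions hits and counts domains and proteins", {
  dom <- data.frame(protein_id = c("P1", "P1", "P2"),
                    domain_label = c("A", "B", "A"),
                    start = c(0L, 300L, 10L), end = c(200L, 500L, 150L))
  hits <- rbind(make_hit("P1", 5L, 16L), make_hit("P1", 320L, 331L),
                make_hit("P1", 250L, 261L), make_hit("P2", 20L, 31L),
                make_hit("P2", 30L, 41L))
  cl <- classify_hits(hits, dom)
  expect_equal(nrow(cl$intra) + nrow(cl$extra), cl$total)
  expect_equal(nrow(cl$intra), 4L)
  expect_equal(cl$n_domains_with_hit, 3L)
  expect_equal(cl$n_proteins_with_hit, 2L)
  expect_equal(cl$per_domain$n_hits[cl$per_domain$protein_id == "P2"], 2L)

  expect_error(classify_hits(make_hit("P1", 5L, 600L), dom,
                             sequences = c(P1 = strrep("A", 500))),
               "outside sequence bounds")
  expect_error(
    classify_hits(hits, data.frame(protein_id = "P1", domain_label = "A",
                                   start = 10L, end = 5L)),
    "start < end")
  expect_error(
    classify_hits(hits, data.frame(protein_id = c("P1", "P1"),
                                   domain_label = c("A", "B"),
                                   start = c(0L, 100L), end = c(150L, 300L))),
    "overlapping")
})

test_that("flanked inserts pad with '-' at sequence ends", {
  s21 <- c(P1 = "DIDIVLPGPDGILGTADDIGN")
  rec <- extract_flanked_inserts(make_hit("P1", 7L, 18L), s21)
  expect_equal(nchar(rec$flanked), 17L)
  expect_equal(rec$flanked, "VLPGPDGILGTADDIGN")
  expect_equal(rec$left_pad, 3L)

  rec2 <- extract_flanked_inserts(make_hit("P1", 0L, 11L), s21)
  expect_true(startsWith(rec2$flanked, "---"))
  expect_equal(nchar(rec2$flanked), 17L)

  s12 <- c(P2 = "PGPDGVPNTEDD")
  rec3 <- extract_flanked_inserts(make_hit("P2", 1L, 12L), s12)
  expect_equal(rec3$flanked, "--PGPDGVPNTEDD---")
  expect_equal(rec3$core, "GPDGVPNTEDD")
  expect_equal(rec3$left_pad, 1L)
  expect_equal(rec3$right_pad, 0L)
})

test_that("consensus rule: single residue, two-letter class, wildcard", {
  recs <- rep("GADGAAGTADD", 10)
  cons <- build_consensus(recs)
  expect_equal(cons$consensus, "G-A-D-G-A-A-G-T-A-D-D")

  # ninth column split 50/50 A and T -> [AT]
  recs2 <- c(rep("GADGAAGTADD", 5), rep("GADGAAGTTDD", 5))
  expect_equal(build_consensus(recs2)$consensus,
               "G-A-D-G-A-A-G-T-[AT]-D-D")

  # a 70/30 majority stays a single letter under the defaults
  recs3 <- c(rep("GADGAAGTADD", 7), rep("GADGAAGTTDD", 3))
  expect_equal(build_consensus(recs3)$consensus, "G-A-D-G-A-A-G-T-A-D-D")

  # a column uniform over six residues falls through to the wildcard
  recs4 <- paste0(c("A", "C", "D", "E", "F", "G"), "A")
  expect_equal(build_consensus(recs4)$consensus, "x-A")

  expect_error(build_consensus(c("GAD", "GADG")), "unequal")
})

test_that("consensus recovers the majority string from profile-sampled records", {
  # each column has a >= 70% majority residue; 200 seeded draws
  majority <- "GADGAAGTADD"
  prof <- profile_from_string(majority)
  prof <- 0.72 * prof + 0.28 * matrix(1 / 20, 20, nchar(majority))
  set.seed(88)
  recs <- vapply(1:200, function(i)
    paste(vapply(seq_len(ncol(prof)), function(j)
      sample(rownames(prof), 1L, prob = prof[, j]), ""), collapse = ""), "")
  got <- build_consensus(recs)$consensus
  expect_equal(gsub("-", "", got), majority)
})

test_that("information content follows the entropy closed forms", {
  expect_equal(information_content(rep("G", 5)), log2(20))
  expect_equal(information_content(AA20), 0)
  expect_equal(information_content(c("A", "A", "T", "T")),
               log2(20) - 1)

  # permutation invariance and bounds
  set.seed(3)
  recs <- vapply(1:30, function(i)
    paste(sample(AA20, 6, replace = TRUE), collapse = ""), "")
  ic1 <- information_content(recs)
  ic2 <- information_content(sample(recs))
  expect_equal(ic1, ic2)
  expect_true(all(ic1 >= 0 & ic1 <= log2(20)))

  # Miller-Madow corrects the downward bias of plug-in entropy, so the
  # corrected IC of a sparse column is lower
  expect_lt(information_content(c("A", "T"), correction = "miller-madow"),
            information_content(c("A", "T")))
  expect_equal(information_content(c("A", "T"), correction = "miller-madow"),
               log2(20) - 1 - 1 / (2 * 2 * log(2)))
})

test_that("alignment insertion segments are gap-majority runs with their carriers", {
  gapless <- c(r1 = "ACDEF", r2 = "ACDEF", r3 = "ACDFF")
  expect_equal(nrow(detect_msa_insertions(gapless)), 0L)

  # 12-row alignment with an 11-column block present in only 3 rows
  left <- strrep("ACDE", 3)
  right <- strrep("FGHK", 3)
  block <- "GADGAAGTADD"
  rows <- c(
    stats::setNames(rep(paste0(left, strrep("-", 11), right), 9),
                    sprintf("bg%d", 1:9)),
    stats::setNames(rep(paste0(left, block, right), 3),
                    sprintf("ins%d", 1:3)))
  seg <- detect_msa_insertions(rows)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 12L)
  expect_equal(seg$end, 23L)
  expect_setequal(seg$members[[1]], c("ins1", "ins2", "ins3"))

  # an all-gap run shorter than min_run is not reported
  short <- c(r1 = "ACDEF--GHKLM", r2 = "ACDEF--GHKLM", r3 = "ACDEFAAGHKLM")
  expect_equal(nrow(detect_msa_insertions(short, min_run = 4)), 0L)
  expect_equal(nrow(detect_msa_insertions(short, min_run = 2)), 1L)

  ragged <- c(r1 = "ACDE", r2 = "ACD")
  expect_error(detect_msa_insertions(ragged), "ragged.*r2")

  # '.' gaps are normalized on read
  dotted <- c(r1 = "AC....DE", r2 = "ACGGGGDE")
  expect_equal(nrow(detect_msa_insertions(dotted, min_run = 4,
                                          gap_fraction_threshold = 0.5)), 1L)
})

test_that("planted intra/extra locations are recovered exactly", {
  # background alphabet avoids the motif's residues, so no chance hits
  bg <- background_model(stats::setNames(rep(0.25, 4),
                                         c("K", "L", "R", "S")))
  host <- generate_background_sequences(4, 700, background = bg, seed = 5)
  spec <- plant_spec("GADGAAGTADD", inserts_per_domain = 3L,
                     n_domains = 2L, domain_length = c(120L, 180L),
                     extra_rate = 2)
  planted <- plant_insertions(host, spec, seed = 17)
  hits <- scan_collection("G-x-D-G-x(5)-D-D", planted$sequences)
  cl <- classify_hits(hits, planted$domains, planted$sequences)

  truth <- planted$truth
  expect_equal(nrow(cl$intra), sum(truth$label == "intra"))
  expect_equal(nrow(cl$extra), sum(truth$label == "extra"))
  expect_setequal(paste(cl$intra$sequence_id, cl$intra$start, cl$intra$end),
                  paste(truth$protein_id[truth$label == "intra"],
                        truth$start[truth$label == "intra"],
                        truth$end[truth$label == "intra"]))
})
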