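ann_fixture <- function(n, seed) {
  set.seed(seed)
  data.frame(mir = sprintf("m%02d", seq_len(n)),
             gene = sprintf("g%02d", seq_len(n)),
             wsp_score = runif(n),
             lrs_score = runif(n),
             n_prediction_algorithms = sample(0:5, n, replace = TRUE),
             validated_in_db = FALSE,
             stringsAsFactors = FALSE)
}

test_that("rank_candidates drops validated pairs and honours dominance", {
  ann <- ann_fixture(5, 101)
  edges <- ann[, c("mir", "gene")]
  all_val <- ann; all_val$validated_in_db <- TRUE
  expect_equal(nrow(rank_candidates(edges, all_val)), 0)
  # one edge dominating every criterion ranks first
  ann$wsp_score[3] <- 10; ann$lrs_score[3] <- 10
  ann$n_prediction_algorithms[3] <- 5
  out <- rank_candidates(edges, ann)
  expect_identical(out$mir[1], "m03")
})

test_that("ordering equals a brute-force rank-sum oracle and ignores edge order", {
  ann <- ann_fixture(40, 102)
  ann$validated_in_db[sample(40, 8)] <- TRUE
  edges <- ann[, c("mir", "gene")]
  out <- rank_candidates(edges, ann)
  keep <- ann[!ann$validated_in_db, ]
  rs <- rank(keep$wsp_score) + rank(keep$lrs_score) +
    rank(keep$n_prediction_algorithms)
  oracle <- keep[order(-rs, keep$mir, keep$gene), c("mir", "gene")]
  expect_equal(out[, c("mir", "gene")], oracle, ignore_attr = TRUE)
  # permuting the input edges leaves the ranking unchanged
  out2 <- rank_candidates(edges[sample(40), ], ann)
  expect_identical(out$mir, out2$mir)
  # gene closeness breaks ties
  tie <- data.frame(mir = c("mA", "mB"), gene = c("gA", "gB"),
                    wsp_score = 1, lrs_score = 1,
                    n_prediction_algorithms = 3, validated_in_db = FALSE)
  ranked <- rank_candidates(tie[, c("mir", "gene")], tie,
                            gene_closeness = c(gA = 0.2, gB = 0.9))
  expect_identical(ranked$gene[1], "gB")
  expect_error(rank_candidates(tie[, c("mir", "gene")],
                               transform(tie, n_prediction_algorithms = 6)),
               "<= 5")
})

test_that("seed_complement reproduces the canonical site for miR-30b", {
  # mature hsa-miR-30b-5p: seed (nt 2-8) GUAAACA -> site TGTTTAC
  expect_identical(seed_complement("UGUAAACAUCCUACACUCAGCU"), "TGTTTAC")
  expect_identical(seed_complement("AAAAAAAAA"), "TTTTTTT")
  expect_error(seed_complement("UGUAAAC"), ">= 8")
  # reverse complement of the site's complement gives back the seed as DNA
  site <- seed_complement("UGUAAACAUCCUACACUCAGCU")
  rc <- paste(rev(crcmir:::RC_MAP[strsplit(site, "")[[1]]]), collapse = "")
  expect_identical(rc, "GTAAACA")
})

test_that("find_sites locates the published coordinates on a built fixture", {
  # fragment starting at coordinate 2207 carrying TGTTTAC at 2225-2231
  set.seed(103)
  left <- paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  seq <- paste0(left, "TGTTTAC", right)
  utr <- utr_sequence("SLC6A6_synthetic", seq, origin = 2207)
  hits <- find_sites(utr, "TGTTTAC")
  expect_equal(hits$start, 2225)
  expect_equal(hits$end, 2231)
  # coordinate round-trip: the slice at (start, end) is the motif
  i <- hits$start - utr$origin + 1
  expect_identical(substring(utr$sequence, i, i + 6), "TGTTTAC")
  expect_equal(nrow(find_sites(utr, "AAAAAAA")), 0)
})

test_that("find_sites matches a sliding-window oracle on random sequences", {
  set.seed(104)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G"), 300, replace = TRUE), collapse = "")
    motif <- paste(sample(c("A", "C", "G"), 7, replace = TRUE), collapse = "")
    utr <- utr_sequence(sprintf("g%d", i), s, origin = 10)
    got <- find_sites(utr, motif)$start
    oracle <- which(vapply(1:(300 - 6), function(p)
      substring(s, p, p + 6) == motif, logical(1))) + 9
    expect_equal(got, oracle)
  }
})

test_that("in-silico mutagenesis destroys the site and round-trips", {
  set.seed(105)
  left <- paste(sample(c("A", "C"), 18, replace = TRUE), collapse = "")
  right <- paste(sample(c("A", "C"), 20, replace = TRUE), collapse = "")
  utr <- utr_sequence("SLC6A6_synthetic", paste0(left, "TGTTTAC", right),
                      origin = 2207)
  mut <- apply_substitutions(utr, c("G2226T", "T2228G", "C2231A"))
  expect_equal(nrow(find_sites(mut, "TGTTTAC")), 0)
  # empty substitution list is the identity
  expect_identical(apply_substitutions(utr, character(0))$sequence,
                   utr$sequence)
  # applying and reverting restores the original
  back <- apply_substitutions(mut, c("T2226G", "G2228T", "A2231C"))
  expect_identical(back$sequence, utr$sequence)
  # reference mismatch is a hard error naming the position
  expect_error(apply_substitutions(utr, "A2226T"), "2226")
  expect_error(apply_substitutions(utr, "G9999T"), "outside")
})

test_that("mutating any single base inside a unique site removes exactly it", {
  set.seed(106)
  flank <- function(n) paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
  utr <- utr_sequence("g", paste0(flank(12), "TGTTTAC", flank(12)))
  site <- find_sites(utr, "TGTTTAC")
  expect_equal(nrow(site), 1)
  for (off in 0:6) {
    pos <- site$start + off
    ref <- substring(utr$sequence, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    mut <- apply_substitutions(utr, paste0(ref, pos, alt))
    expect_equal(nrow(find_sites(mut, "TGTTTAC")), 0)
  }
})

test_that("UTR FASTA reader parses origin tags", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">SLC6A6_synthetic origin=2207",
               "ACGTACGTACGTACGTAC", "TGTTTACACGT",
               ">other",
               "ACGTACGTAAA"), f)
  utrs <- read_utr_fasta(f)
  expect_equal(utrs$SLC6A6_synthetic$origin, 2207)
  expect_equal(utrs$other$origin, 1)
  expect_equal(find_sites(utrs$SLC6A6_synthetic, "TGTTTAC")$start, 2225)
  expect_error(utr_sequence("x", "ACGTN"), "A,C,G,T|ACGT")
})
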