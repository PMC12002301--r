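test_that("signal-peptide heuristic recovers planted signals and rejects others", {
  ok <- 0L
  for (s in 1:100) {
    mp <- make_precursor(s)
    sig <- predict_signal_peptide(mp$record$residues)
    if (!is.null(sig) && abs(sig$end - mp$truth$signal$end) <= 3) ok <- ok + 1L
  }
  expect_gte(ok, 90L)
  # no hydrophobic core
  expect_null(predict_signal_peptide(paste0("MK", strrep("D", 40))))
  # too short to call
  expect_null(predict_signal_peptide("MKLLLLLLLLA"))
  # external override is passed through
  expect_equal(predict_signal_peptide("whatever-protein", override = 23)$end, 23L)
})

test_that("cleavage-site scan is leftmost-greedy and respects the dibasic set", {
  s <- find_cleavage_sites("AAKRBB")
  expect_equal(s$position, 3L)
  expect_equal(s$basic_pair, "KR")
  # the internal RR of the natural 14-residue peptide (positions 3-4,
  # 1-based) is found after index 3
  s2 <- find_cleavage_sites("EPRRNYNRVFGPTY")
  expect_equal(s2$position, 3L)
  expect_equal(s2$basic_pair, "RR")
  expect_equal(nrow(find_cleavage_sites("AAAAAA")), 0L)
  # KRR: leftmost pair wins
  s3 <- find_cleavage_sites("AKRRA")
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$basic_pair, "KR")
  # KK only when opted in
  expect_equal(nrow(find_cleavage_sites("AAKKAA")), 0L)
  expect_equal(find_cleavage_sites("AAKKAA", dibasic = c("KR", "RR", "KK"))$basic_pair,
               "KK")
  # monobasic: single R, not adjacent to another basic, off by default
  expect_equal(nrow(find_cleavage_sites("AAARAAA")), 0L)
  sm <- find_cleavage_sites("AAARAAA", allow_monobasic = TRUE)
  expect_equal(sm$kind, "monobasic")
  expect_equal(sm$position, 3L)
})

test_that("peptide derivation reproduces the three natural products and bombesin flags", {
  # 14-residue amidated peptide with its internal-cleavage 10-residue child
  p <- derive_peptides(paste0("M", "KR", "EPRRNYNRVFGPTYG", "KR", "A"))
  parent <- p[p$role == "parent", ]
  child <- p[p$role == "child", ]
  expect_equal(parent$sequence, "EPRRNYNRVFGPTY")
  expect_equal(nchar(parent$sequence), 14L)
  expect_true(parent$amidated)
  expect_equal(child$sequence, "NYNRVFGPTY")
  expect_equal(nchar(child$sequence), 10L)
  expect_true(child$amidated)
  # 16-residue amidated product from the C-terminal precursor region
  p3 <- derive_peptides(paste0("M", "KR", "EPMPSSLALYIANLSPG", "KR", "A"))
  expect_equal(p3$sequence[p3$role == "parent"], "EPMPSSLALYIANLSP")
  expect_equal(nchar(p3$sequence[p3$role == "parent"]), 16L)
  expect_true(p3$amidated[p3$role == "parent"])
  # amphibian tetradecapeptide: N-terminal Q -> pGlu, trailing G -> amide
  pb <- derive_peptides(paste0("MAAA", "KR", "QQRLGNQWAVGHLMG", "KR", "AAA"))
  expect_equal(pb$sequence[1], "QQRLGNQWAVGHLM")
  expect_true(pb$pyroglutamate[1])
  expect_true(pb$amidated[1])
})

test_that("derivation is invariant to site order and respects the length filter", {
  prot <- paste0("M", "KR", "EPRRNYNRVFGPTYG", "KR", "A")
  sites <- find_cleavage_sites(prot)
  shuffled <- sites[c(3, 1, 2), ]
  expect_equal(derive_peptides(prot, sites = sites),
               derive_peptides(prot, sites = shuffled))
  expect_error(derive_peptides(prot, min_len = 10, max_len = 5), "min_len")
  # max_len filter drops long products
  long <- derive_peptides(paste0("M", "KR", strrep("A", 50), "G", "KR"),
                          max_len = 40)
  expect_false(any(nchar(long$sequence) > 40))
})

test_that("precursor reconstruction: segments and boundaries tile the protein", {
  for (s in c(1, 8, 21)) {
    mp <- make_precursor(s)
    prot <- mp$record$residues
    ann <- annotate_precursor(prot)
    peps <- ann$peptides[ann$peptides$role == "parent", ]
    # spans must be disjoint and orderable
    peps <- peps[order(peps$start), ]
    if (nrow(peps) > 1)
      expect_true(all(peps$start[-1] >= peps$end[-nrow(peps)]))
    # each span's text is sequence (+G if amidated)
    for (k in seq_len(nrow(peps))) {
      seg <- substr(prot, peps$start[k] + 1, peps$end[k])
      expect_equal(seg, paste0(peps$sequence[k], if (peps$amidated[k]) "G"))
    }
  }
})

test_that("motif scanning handles wildcards, anchors and the amide flag", {
  hit <- scan_motif("EPRRNYNRVFGPTYG", "GPxxG", anchor = "C_terminal")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 10L)
  expect_equal(hit$end, 15L)
  expect_equal(substr("EPRRNYNRVFGPTYG", hit$start + 1, hit$end), "GPTYG")
  # amide-flag pattern against the amidated mature peptide
  expect_equal(nrow(scan_motif("EPRRNYNRVFGPTY", "FGPxxa", amidated = TRUE)), 1L)
  expect_equal(nrow(scan_motif("EPRRNYNRVFGPTY", "FGPxxa", amidated = FALSE)), 0L)
  # N-terminal consensus
  expect_equal(nrow(scan_motif("EPRRNYNRVFGPTY", "PRxN", anchor = "anywhere")), 1L)
  expect_equal(nrow(scan_motif("AAAA", "GPxxG")), 0L)
  expect_error(scan_motif("AAAA", ""), "empty")
})

test_that("score separates planted precursors from decoys with margin", {
  planted <- vapply(1:30, function(s)
    annotate_precursor(make_precursor(s)$record$residues)$score, 0)
  decoys <- vapply(1:30, function(s)
    annotate_precursor(make_precursor(s + 4000, decoy = TRUE)$record$residues)$score, 0)
  expect_true(all(planted >= 4.5))
  expect_true(all(decoys <= 1))
  # removing the signal peptide never increases the score (additive form)
  mp <- make_precursor(2)
  full <- annotate_precursor(mp$record$residues)$score
  trimmed <- annotate_precursor(
    substr(mp$record$residues, mp$truth$signal$end + 1,
           nchar(mp$record$residues)))$score
  expect_lte(trimmed, full)
})

test_that("ranking keeps planted precursors above all decoys", {
  pr <- make_proteome(5, n_planted = 10, n_decoys = 100)
  a <- annotate_set(pr$records)
  tab <- a$annotations
  planted <- grepl("^planted", tab$id)
  expect_gt(min(tab$score[planted]), max(tab$score[!planted]))
  expect_true(all(which(planted) <= 10))
  # top_k truncation
  a2 <- annotate_set(pr$records, top_k = 10)
  expect_equal(nrow(a2$annotations), 10L)
  expect_true(all(grepl("^planted", a2$annotations$id)))
})
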