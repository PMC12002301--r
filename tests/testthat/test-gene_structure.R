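test_that("spliced alignment exactly recovers planted gene structures", {
  for (s in 1:60) {
    mp <- make_precursor(s)
    cds <- reverse_translate(mp$record$residues)
    n <- nchar(cds)
    p3 <- n - 21L - (n - 21L) %% 3L
    spec <- data.frame(cds_nt_position = c(64L, 130L, p3),
                       phase = c(1L, 1L, 0L), length = c(40L, 35L, 45L))
    g <- make_gene(cds, spec, seed = s)
    m <- spliced_align(g$cdna, g$genomic$residues, cds_offset = 50L,
                       cds_len = n)
    expect_identical(m$exons, g$model$exons)
    # splicing round-trip
    spliced <- paste(substring(g$genomic$residues, m$exons$start + 1,
                               m$exons$end), collapse = "")
    expect_identical(spliced, g$cdna)
  }
})

test_that("intron phases follow the (CDS nt before) mod 3 rule", {
  # single exon minus: no introns
  prot <- make_precursor(4)$record$residues
  cds <- reverse_translate(prot)
  for (pos in c(4L, 5L, 6L)) {
    spec <- data.frame(cds_nt_position = pos, phase = pos %% 3L, length = 40L)
    g <- make_gene(cds, spec, seed = 7)
    ph <- intron_phases(g$model)
    expect_equal(ph$phase, pos %% 3L)
    expect_equal(ph$cds_nt_before, pos)
  }
})

test_that("UTR introns get no phase", {
  prot <- make_precursor(6)$record$residues
  cds <- reverse_translate(prot)
  g <- make_gene(cds, data.frame(cds_nt_position = 66L, phase = 0L,
                                 length = 40L), seed = 6)
  # shift the CDS annotation so the intron falls upstream of the CDS
  model <- g$model
  model$cds_offset <- 120L
  model$cds_len <- nchar(cds) - 120L + 50L
  ph <- intron_phases(model)
  expect_true(is.na(ph$phase[1]))
})

test_that("unalignable and intron-less inputs are handled", {
  prot <- make_precursor(8)$record$residues
  cds <- reverse_translate(prot)
  g0 <- make_gene(cds, data.frame(cds_nt_position = integer(),
                                  phase = integer(), length = integer()),
                  seed = 8)
  m0 <- spliced_align(g0$cdna, g0$genomic$residues)
  expect_equal(nrow(m0$exons), 1L)
  expect_equal(nrow(intron_phases(m0)), 0L)
  set.seed(1)
  expect_error(spliced_align(random_dna(300), g0$genomic$residues),
               "unalignable")
})

test_that("shared introns map to identical alignment columns across species", {
  os <- make_ortholog_set(13)
  msa <- progressive_msa(os$records)
  models <- lapply(names(os$genes), function(sp) {
    g <- os$genes[[sp]]
    spliced_align(g$cdna, g$genomic$residues, cds_offset = 50L,
                  cds_len = nchar(g$cds), genomic_id = sp)
  })
  names(models) <- names(os$genes)
  tab <- map_introns_to_alignment(models, msa)
  ech <- paste0("echA", 1:3); chs <- paste0("chB", 1:4)
  # the conserved intron inside the peptide-coding region: phase 1,
  # same column in every species
  first <- tab[tab$intron_index == 1, ]
  expect_equal(unique(first$phase), 1L)
  expect_equal(length(unique(first$column)), 1L)
  expect_true(all(first$shared))
  # the group-A-specific intron is not shared with group B
  mid <- tab[tab$species %in% ech & tab$intron_index == 2, ]
  expect_equal(unique(mid$phase), 0L)
  expect_false(any(tab$species %in% chs &
                   tab$column %in% mid$column & tab$phase == 0L &
                   tab$intron_index == 2))
  # the 3'-end intron is shared by all species at one column
  last <- rbind(tab[tab$species %in% ech & tab$intron_index == 3, ],
                tab[tab$species %in% chs & tab$intron_index == 2, ])
  expect_equal(length(unique(last$column)), 1L)
  expect_equal(unique(last$phase), 0L)
  # CDS/MSA mismatch errors with the species name
  bad <- models
  bad[["echA1"]]$cds <- reverse_translate(os$records$residues[2])
  expect_error(map_introns_to_alignment(bad, msa), "echA1")
})

test_that("GFF3 export carries exon structure and CDS phase", {
  prot <- make_precursor(3)$record$residues
  cds <- reverse_translate(prot)
  g <- make_gene(cds, data.frame(cds_nt_position = 64L, phase = 1L,
                                 length = 40L), seed = 3)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g$model, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  tab <- read.delim(text = lines[-1], header = FALSE)
  expect_equal(sum(tab$V3 == "exon"), 2L)
  cdsr <- tab[tab$V3 == "CDS", ]
  expect_equal(nrow(cdsr), 2L)
  expect_equal(cdsr$V8[1], "0")        # CDS starts at a codon boundary
  expect_equal(cdsr$V8[2], as.character((3 - 64 %% 3) %% 3))
})
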