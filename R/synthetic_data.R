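# Generators that plant ground-truth precursors, genes, spectra and
# dose-response tables, so every downstream stage can be tested without
# any external downloads. All generators are pure functions of
# (seed, params): they save and restore the caller's RNG state.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.sample_aa <- function(n, exclude = character()) {
  pool <- setdiff(c("A","C","D","E","F","G","H","I","L","M",
                    "N","P","Q","S","T","V","W","Y","K","R"), exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# residue pool for the hydrophobic signal core: strongly hydrophobic,
# with tryptophan rare and no small (A/G/S/C) residues, so the planted
# cleavage position is the first small residue after the core
.sample_hydrophobic <- function(n) {
  pool <- c("I", "L", "V", "F", "M", "W")
  paste(sample(pool, n, replace = TRUE,
               prob = c(2, 4, 2, 2, 1, 0.3)), collapse = "")
}

# a linker with no basic pairs, no G at either end, no Q start
.sample_linker <- function(n) {
  .sample_aa(n, exclude = c("K", "R", "G", "Q"))
}

#' Generate a synthetic neuropeptide precursor (or decoy)
#'
#' Non-decoy output emulates the architecture of a bombesin-type
#' precursor: an N-terminal signal region (Met, a basic residue, a
#' hydrophobic core, and a small residue at the cleavage position),
#' followed by one or more dibasic-flanked peptides whose pre-processing
#' segment ends with the family motif (final G being the amide donor),
#' separated by linkers. The first peptide sits immediately after the
#' signal peptide. Decoys contain no signal region, no basic pairs and no
#' glycine-terminated cleavage-bounded segments.
#'
#' @param seed integer seed.
#' @param signal_len signal peptide length (default 21 residues).
#' @param n_peptides number of planted peptides (default 2).
#' @param motif family motif placed at the segment C-terminus (default
#'   `"RIFGPxxG"`, emulating the echinoderm family consensus RIFGPXXa
#'   plus its glycine amide donor; the final residue must be G). Any
#'   motif ending in `GPxxG` also satisfies the coarser screen motif.
#' @param peptide_len mature peptide length (default 14 residues,
#'   pre-processing segment is one longer).
#' @param linker_len linker length between peptide cassettes (default 12).
#' @param decoy generate a featureless decoy protein instead.
#' @return list with `record` (a one-row [seq_records()] data frame) and
#'   `truth` (`NULL` for decoys; otherwise signal span, planted peptide
#'   table with spans, and the seed).
#' @export
make_precursor <- function(seed, signal_len = 21L, n_peptides = 2L,
                           motif = "RIFGPxxG", peptide_len = 14L,
                           linker_len = 12L, decoy = FALSE) {
  stopifnot(signal_len >= 10L)
  core <- sub("a$", "", motif)
  if (nchar(core) + 1L > peptide_len + 1L)
    stop("motif longer than the planted peptide")
  if (substring(core, nchar(core)) != "G")
    stop("planted motif must end in G (amide donor)")
  .with_seed(seed, {
    if (decoy) {
      len <- 90L + sample.int(30L, 1L)
      aa <- strsplit(.sample_aa(len), "")[[1]]
      # no basics in the first 5 (kills the signal gate), no basic pairs
      aa[1:5][aa[1:5] %in% c("K", "R")] <- "T"
      for (i in 2:len) if (aa[i] %in% c("K", "R") && aa[i - 1L] %in% c("K", "R"))
        aa[i] <- "N"
      if (aa[len] == "G") aa[len] <- "S"
      rec <- seq_records(id = sprintf("decoy_seed%d", seed),
                         residues = paste(aa, collapse = ""))
      return(list(record = rec, truth = NULL))
    }
    signal <- paste0("M", sample(c("K", "R"), 1L),
                     .sample_hydrophobic(signal_len - 3L),
                     sample(c("A", "S"), 1L))
    parts <- signal
    peptides <- list()
    pos <- signal_len
    for (p in seq_len(n_peptides)) {
      body_len <- peptide_len + 1L - nchar(core)  # segment = body + motif core
      body <- if (body_len > 0L) .sample_linker(body_len) else ""
      fill <- vapply(strsplit(core, "")[[1]], function(ch)
        if (ch == "x") substr(.sample_linker(1L), 1L, 1L) else ch, "")
      segment <- paste0(body, paste(fill, collapse = ""))
      flank <- sample(c("KR", "RR"), 1L)
      peptides[[p]] <- data.frame(
        sequence = substr(segment, 1L, nchar(segment) - 1L),
        amidated = TRUE, pyroglutamate = substring(segment, 1L, 1L) == "Q",
        start = pos, end = pos + nchar(segment), stringsAsFactors = FALSE)
      parts <- c(parts, segment, flank)
      pos <- pos + nchar(segment) + 2L
      if (p < n_peptides) {
        link <- .sample_linker(linker_len)
        parts <- c(parts, link, sample(c("KR", "RR"), 1L))
        pos <- pos + linker_len + 2L
      }
    }
    tail_link <- .sample_linker(linker_len)
    parts <- c(parts, tail_link)
    protein <- paste(parts, collapse = "")
    rec <- seq_records(id = sprintf("planted_seed%d", seed), residues = protein)
    list(record = rec,
         truth = list(signal = list(start = 0L, end = signal_len),
                      peptides = do.call(rbind, peptides), seed = seed))
  })
}

#' Generate a synthetic proteome with planted precursors and decoys
#'
#' @param seed integer seed.
#' @param n_planted,n_decoys numbers of planted precursors and decoys.
#' @param ... passed to [make_precursor()] for the planted records.
#' @return list with `records` (a [seq_records()] data frame; planted ids
#'   start with `"planted"`) and `truths` (list of planted truths).
#' @export
make_proteome <- function(seed, n_planted = 10L, n_decoys = 500L, ...) {
  planted <- lapply(seq_len(n_planted), function(i)
    make_precursor(seed * 100003L %% 2147483647L + i, ...))
  decoys <- lapply(seq_len(n_decoys), function(i)
    make_precursor(seed * 49999L %% 2147483647L + i, decoy = TRUE))
  recs <- do.call(rbind, c(lapply(planted, `[[`, "record"),
                           lapply(decoys, `[[`, "record")))
  recs$id <- make.unique(recs$id, sep = "_")
  class(recs) <- c("seq_records", "data.frame")
  list(records = recs, truths = lapply(planted, `[[`, "truth"))
}

# deterministic reverse translation (first codon of the standard code
# for each amino acid, precomputed once)
.AA2CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  tapply(names(gc), gc, `[`, 1L)
})

#' Reverse-translate a protein into a CDS
#'
#' Deterministic codon choice (first codon of the standard genetic code
#' per residue) plus a trailing TAA stop.
#'
#' @param protein protein string.
#' @return DNA string of length `3 * (nchar(protein) + 1)`.
#' @export
reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  cods <- .AA2CODON[aa]
  if (anyNA(cods)) stop("cannot reverse-translate residue(s): ",
                        paste(unique(aa[is.na(cods)]), collapse = ""))
  paste0(paste(cods, collapse = ""), "TAA")
}

.random_dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")

#' Generate a synthetic gene by planting introns into a CDS
#'
#' Introns begin `GT` and end `AG`; the phase of each intron must equal
#' `cds_nt_position %% 3`. Flanking UTR sequence is added on both sides.
#' Boundaries are re-rolled until they are unambiguous in a `2 * anchor_k`
#' window (no alternative GT..AG placement reconstructs the same cDNA), so
#' the planted structure is the unique canonical spliced alignment.
#'
#' @param precursor_cds DNA string of the coding sequence (incl. stop).
#' @param intron_spec `data.frame` with columns `cds_nt_position` (strictly
#'   increasing, inside the CDS), `phase` (0/1/2), `length` (>= 30 nt).
#' @param seed integer seed.
#' @param utr5_len,utr3_len UTR lengths (default 50 nt each).
#' @return list with `genomic` (one-row `seq_records`, DNA), `cdna` (DNA
#'   string) and `model` (a [gene_model()] ground truth).
#' @export
make_gene <- function(precursor_cds, intron_spec, seed,
                      utr5_len = 50L, utr3_len = 50L) {
  precursor_cds <- toupper(precursor_cds)
  n <- nchar(precursor_cds)
  if (nrow(intron_spec)) {
    if (is.unsorted(intron_spec$cds_nt_position, strictly = TRUE))
      stop("intron positions must be strictly increasing")
    if (any(intron_spec$cds_nt_position <= 0 | intron_spec$cds_nt_position >= n))
      stop("intron positions must lie inside the CDS")
    if (any(intron_spec$length < 30L)) stop("introns must be >= 30 nt")
    bad <- intron_spec$phase != intron_spec$cds_nt_position %% 3L
    if (any(bad))
      stop("requested phase inconsistent with position at cds position ",
           paste(intron_spec$cds_nt_position[bad], collapse = ","))
  }
  .with_seed(seed, {
    utr5 <- .random_dna(utr5_len); utr3 <- .random_dna(utr3_len)
    cdna <- paste0(utr5, precursor_cds, utr3)
    cuts <- utr5_len + intron_spec$cds_nt_position   # cDNA coords of splits
    bounds <- c(0L, cuts, nchar(cdna))
    exon_seqs <- substring(cdna, head(bounds, -1L) + 1L, bounds[-1L])
    introns <- character(nrow(intron_spec))
    genomic <- exon_seqs[1L]
    exons <- list(c(0L, nchar(exon_seqs[1L])))
    for (k in seq_len(nrow(intron_spec))) {
      repeat {
        intr <- paste0("GT", .random_dna(intron_spec$length[k] - 4L), "AG")
        # boundary ambiguity check: the donor GT must not be re-creatable
        # by shifting sequence between exon and intron within the anchor
        # window on either side
        left <- exon_seqs[k]; right <- exon_seqs[k + 1L]
        ok <- TRUE
        for (s in 1:12) {
          # shift s to the left: exon loses s bases, intron starts earlier
          if (s < nchar(left) && s < nchar(intr)) {
            d2 <- substr(left, nchar(left) - s + 1L, nchar(left) - s + 2L)
            a2 <- substr(paste0(intr, right), nchar(intr) - s + 1L,
                         nchar(intr) - s + 2L)
            moved_tail <- substr(left, nchar(left) - s + 1L, nchar(left))
            intr_tail <- substr(intr, nchar(intr) - s + 1L, nchar(intr))
            if (d2 == "GT" && a2 == "AG" && moved_tail == intr_tail) ok <- FALSE
          }
          # shift s to the right: exon gains bases from next exon start
          if (s < nchar(right) && s < nchar(intr)) {
            d2 <- substr(paste0(left, intr), 1L + s, 2L + s)  # unused guard
            moved_head <- substr(right, 1L, s)
            intr_head <- substr(intr, 1L, s)
            da <- substr(intr, s + 1L, s + 2L)
            ac <- substr(intr, nchar(intr) - 1L, nchar(intr))
            if (moved_head == intr_head && da == "GT" && ac == "AG") ok <- FALSE
          }
        }
        if (ok) { introns[k] <- intr; break }
      }
      start <- nchar(genomic) + nchar(introns[k])
      genomic <- paste0(genomic, introns[k], exon_seqs[k + 1L])
      exons[[length(exons) + 1L]] <- c(start, start + nchar(exon_seqs[k + 1L]))
    }
    exon_mat <- do.call(rbind, exons)
    model <- gene_model(genomic_id = sprintf("gene_seed%d", seed), strand = "+",
                        exon_start = exon_mat[, 1L], exon_end = exon_mat[, 2L],
                        cds_offset = utr5_len, cds_len = n)
    grec <- seq_records(id = sprintf("gene_seed%d", seed), residues = genomic,
                        alphabet = "dna")
    list(genomic = grec, cdna = cdna, model = model)
  })
}

#' Generate replicated 4PL dose-response data with multiplicative noise
#'
#' Responses are `4PL(conc) * (1 + eps)` with `eps ~ Normal(0, cv)`. The
#' defaults emulate a potent agonist assayed in triplicate over a wide
#' concentration range.
#'
#' @param logEC50 log10 of the EC50 in molar (default `log10(1.69e-11)`).
#' @param hill Hill slope (default 1).
#' @param bottom,top response asymptotes (default 0 and 100).
#' @param concentrations molar concentrations (default `10^(-14:-6)`).
#' @param n_reps replicates per concentration (default 3).
#' @param cv multiplicative noise fraction (>= 0).
#' @param seed integer seed.
#' @return `data.frame` with columns `experiment`, `concentration`,
#'   `response`.
#' @export
make_dose_response <- function(logEC50 = log10(1.69e-11), hill = 1,
                               bottom = 0, top = 100,
                               concentrations = 10^seq(-14, -6), n_reps = 3L,
                               cv = 0.05, seed = 1L) {
  if (cv < 0) stop("cv must be >= 0")
  .with_seed(seed, {
    conc <- rep(concentrations, each = n_reps)
    mu <- bottom + (top - bottom) / (1 + 10^(hill * (logEC50 - log10(conc))))
    eps <- stats::rnorm(length(conc), 0, cv)
    data.frame(experiment = rep(seq_len(n_reps), times = length(concentrations)),
               concentration = conc, response = mu * (1 + eps))
  })
}

#' Generate a synthetic fragment-ion peak list
#'
#' Contains all singly charged b/y ions of the (modified) peptide plus
#' uniformly distributed noise peaks.
#'
#' @param peptide peptide sequence.
#' @param c_term `"amide"` or `"free_acid"`.
#' @param n_term `"free"` or `"pyroglutamate"`.
#' @param n_noise_peaks number of noise peaks (default 0).
#' @param seed integer seed.
#' @return `data.frame` with columns `mz`, `intensity`.
#' @export
make_spectrum <- function(peptide, c_term = "amide", n_term = "free",
                          n_noise_peaks = 0L, seed = 1L) {
  ions <- fragment_ions(peptide, c_term = c_term, n_term = n_term,
                        series = c("b", "y"), max_charge = 1L)
  .with_seed(seed, {
    mz <- ions$mz
    intensity <- rep(100, length(mz))
    if (n_noise_peaks > 0L) {
      lo <- min(mz) * 0.8; hi <- max(mz) * 1.2
      nmz <- stats::runif(n_noise_peaks, lo, hi)
      mz <- c(mz, nmz)
      intensity <- c(intensity, stats::runif(n_noise_peaks, 1, 40))
    }
    ord <- order(mz)
    data.frame(mz = mz[ord], intensity = intensity[ord])
  })
}

#' Generate a cross-species ortholog set with genes
#'
#' Builds a base precursor, then per-species variants by mutating linker
#' positions while keeping the planted peptide cassette intact. Group-A
#' species ("echinoderm"-like) receive three introns (phase 1 inside the
#' peptide-coding region, a group-specific phase 0, and a 3' phase 0);
#' group-B species ("chordate"-like) receive the phase-1 and 3' phase-0
#' introns only, at homologous positions, mirroring the conserved
#' architecture of bombesin-type precursor genes. Outgroup sequences are
#' unrelated precursors.
#'
#' A contrast family (a coherent clade derived from an unrelated base
#' precursor, playing the role of the closest non-orthologous peptide
#' family) and unrelated outgroup precursors complete the set, so that
#' clade-membership tests have both a contrast and a root.
#'
#' @param seed integer seed.
#' @param n_a,n_b,n_c,n_out numbers of group-A, group-B, contrast and
#'   outgroup species.
#' @param divergence per-site substitution probability outside the
#'   peptide cassette (applied per species).
#' @return list with `records` (proteins with `species`/`group` tags),
#'   `genes` (per species: `genomic`, `cdna`, `model`, `intron_spec`) and
#'   `base_truth` (the planted peptide table of the base precursor).
#' @export
make_ortholog_set <- function(seed, n_a = 3L, n_b = 4L, n_c = 3L, n_out = 2L,
                              divergence = 0.1) {
  base <- make_precursor(seed, n_peptides = 2L)
  protein <- base$record$residues
  truth <- base$truth
  pep1 <- truth$peptides[1L, ]
  .with_seed(seed + 7L, {
    keep <- rep(FALSE, nchar(protein))   # positions protected from mutation
    for (k in seq_len(nrow(truth$peptides)))
      keep[(truth$peptides$start[k] + 1L):(truth$peptides$end[k] + 2L)] <- TRUE
    keep[1:2] <- TRUE
    mutate <- function(p, rate) {
      aa <- strsplit(p, "")[[1]]
      for (i in seq_along(aa)) {
        if (!keep[i] && stats::runif(1) < rate) {
          repeat {
            sub <- substr(.sample_aa(1L, exclude = c("K", "R", "G")), 1L, 1L)
            aa2 <- aa; aa2[i] <- sub
            # do not create new basic pairs
            if (!(i > 1 && aa2[i - 1] %in% c("K","R") && sub %in% c("K","R")))
              break
          }
          aa[i] <- sub
        }
      }
      paste(aa, collapse = "")
    }
    species <- c(paste0("echA", seq_len(n_a)), paste0("chB", seq_len(n_b)))
    groups <- c(rep("echinoderm", n_a), rep("chordate", n_b))
    prots <- vapply(seq_along(species), function(i)
      mutate(protein, divergence * (1 + (groups[i] == "chordate"))), "")
    # introns: phase-1 inside peptide 1, group-A-specific phase 0 mid-CDS,
    # shared phase-0 near the 3' end
    cds_len <- 3L * (nchar(protein) + 1L)
    p1 <- 3L * pep1$start + 3L * 4L + 1L       # phase 1 inside peptide 1
    pmid <- (3L * (pep1$end + 6L)) %/% 3L * 3L # phase 0, group A only
    p3 <- cds_len - 21L - (cds_len - 21L) %% 3L  # phase 0 near 3' end
    genes <- list()
    for (i in seq_along(species)) {
      spec <- if (groups[i] == "echinoderm")
        data.frame(cds_nt_position = c(p1, pmid, p3), phase = c(1L, 0L, 0L),
                   length = c(40L, 35L, 45L))
      else
        data.frame(cds_nt_position = c(p1, p3), phase = c(1L, 0L),
                   length = c(40L, 45L))
      cds <- reverse_translate(prots[i])
      genes[[species[i]]] <- c(make_gene(cds, spec, seed = seed + 100L + i),
                               list(intron_spec = spec, cds = cds))
    }
    # contrast family: a second coherent clade from an unrelated base
    con_base <- make_precursor(seed + 555L, n_peptides = 2L)$record$residues
    keep_con <- rep(FALSE, nchar(con_base)); keep_con[1:25] <- TRUE
    mutate_free <- function(p, rate, keepv) {
      aa <- strsplit(p, "")[[1]]
      for (i in seq_along(aa)) if (!keepv[i] && stats::runif(1) < rate)
        aa[i] <- substr(.sample_aa(1L, exclude = c("K", "R", "G")), 1L, 1L)
      paste(aa, collapse = "")
    }
    cons <- vapply(seq_len(n_c), function(i)
      mutate_free(con_base, divergence, keep_con), "")
    # outgroup: a third coherent family (as elevenin-type precursors are
    # a coherent outgroup in the real analysis)
    out_base <- make_precursor(seed + 1000L, n_peptides = 1L,
                               peptide_len = 12L)$record$residues
    keep_out <- rep(FALSE, nchar(out_base)); keep_out[1:25] <- TRUE
    outs <- vapply(seq_len(n_out), function(i)
      mutate_free(out_base, divergence, keep_out), "")
    ids <- c(species, paste0("conC", seq_len(n_c)), paste0("out", seq_len(n_out)))
    recs <- seq_records(
      id = ids,
      residues = c(prots, cons, outs),
      species = ids,
      group = c(groups, rep("contrast", n_c), rep("outgroup", n_out)))
    list(records = recs, genes = genes, base_truth = truth)
  })
}
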