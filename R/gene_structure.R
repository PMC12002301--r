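# Spliced alignment of transcripts to genomic sequence (anchor-chain-
# extend), intron phase computation, and cross-species mapping of intron
# positions onto a protein alignment.

#' Construct a gene model
#'
#' @param genomic_id identifier of the genomic sequence.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end 0-based half-open genomic exon intervals,
#'   ascending and non-overlapping.
#' @param cds_offset 0-based position of the CDS start within the spliced
#'   transcript (`NA` when unannotated).
#' @param cds_len CDS length in nt (multiple of 3 including stop).
#' @param cds optional spliced CDS sequence (used for cross-species
#'   mapping against a protein alignment).
#' @return a list of class `gene_model`.
#' @export
gene_model <- function(genomic_id, strand = "+", exon_start, exon_end,
                       cds_offset = NA_integer_, cds_len = NA_integer_,
                       cds = NULL) {
  stopifnot(length(exon_start) == length(exon_end), all(exon_end > exon_start),
            strand %in% c("+", "-"))
  if (length(exon_start) > 1L) {
    if (is.unsorted(exon_start, strictly = TRUE) ||
        any(exon_start[-1L] < exon_end[-length(exon_end)]))
      stop("exons must be ascending and non-overlapping")
  }
  structure(list(genomic_id = genomic_id, strand = strand,
                 exons = data.frame(start = as.integer(exon_start),
                                    end = as.integer(exon_end)),
                 cds_offset = as.integer(cds_offset),
                 cds_len = as.integer(cds_len), cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model on '", x$genomic_id, "' (", x$strand, "): ",
      nrow(x$exons), " exon(s)", sep = "")
  if (!is.na(x$cds_offset))
    cat(", CDS offset ", x$cds_offset, " len ", x$cds_len, sep = "")
  cat("\n")
  invisible(x)
}

# maximal exact-match segments between cdna and genomic from shared k-mers
.match_segments <- function(cdna, genomic, k) {
  n <- nchar(cdna); m <- nchar(genomic)
  if (m < k || n < k) return(NULL)
  gstarts <- seq_len(m - k + 1L)
  gk <- substring(genomic, gstarts, gstarts + k - 1L)
  idx <- split(gstarts, gk)
  cstarts <- seq_len(n - k + 1L)
  ck <- substring(cdna, cstarts, cstarts + k - 1L)
  anchors <- list()
  for (i in cstarts) {
    hits <- idx[[ck[i]]]
    if (!is.null(hits))
      anchors[[length(anchors) + 1L]] <- cbind(ci = i, gi = hits)
  }
  if (!length(anchors)) return(NULL)
  a <- do.call(rbind, anchors)
  diag <- a[, "gi"] - a[, "ci"]
  segs <- list()
  ca <- strsplit(cdna, "")[[1]]; ga <- strsplit(genomic, "")[[1]]
  for (d in unique(diag)) {
    ci <- sort(a[diag == d, "ci"])
    # merge contiguous runs, then maximal extension
    brk <- c(0L, which(base::diff(ci) > 1L), length(ci))
    for (r in seq_len(length(brk) - 1L)) {
      cs <- ci[brk[r] + 1L]; ce <- ci[brk[r + 1L]] + k - 1L  # 1-based incl
      while (cs > 1L && cs + d > 1L && ca[cs - 1L] == ga[cs + d - 1L]) cs <- cs - 1L
      while (ce < length(ca) && ce + d < length(ga) &&
             ca[ce + 1L] == ga[ce + d + 1L]) ce <- ce + 1L
      segs[[length(segs) + 1L]] <- c(cs = cs, ce = ce, d = d)
    }
  }
  segs <- unique(do.call(rbind, segs))
  segs[order(segs[, "cs"], segs[, "d"]), , drop = FALSE]
}

#' Spliced alignment of a cDNA to a genomic sequence
#'
#' Exact `anchor_k`-mer matches are merged into maximal exact segments and
#' chained collinearly by dynamic programming, maximizing matched cDNA
#' coverage; genomic gaps between chained segments become introns.
#' Boundaries within the ambiguity overlap of adjacent segments are
#' shifted (by at most `anchor_k`) to satisfy GT..AG when
#' `require_gt_ag`. Full cDNA coverage is required.
#'
#' @param cdna transcript sequence (DNA string).
#' @param genomic genomic sequence (DNA string), at least as long.
#' @param anchor_k anchor length (default 12).
#' @param min_intron,max_intron allowed intron lengths (default 30 and
#'   100000 nt).
#' @param require_gt_ag require canonical splice dinucleotides (default
#'   `TRUE`).
#' @param cds_offset,cds_len optional CDS annotation of the transcript
#'   (0-based offset; length incl. stop), stored on the model.
#' @param genomic_id identifier recorded on the model.
#' @return a [gene_model()].
#' @export
spliced_align <- function(cdna, genomic, anchor_k = 12L, min_intron = 30L,
                          max_intron = 100000L, require_gt_ag = TRUE,
                          cds_offset = NA_integer_, cds_len = NA_integer_,
                          genomic_id = "genomic") {
  cdna <- toupper(cdna); genomic <- toupper(genomic)
  n <- nchar(cdna)
  if (nchar(genomic) < n) stop("genomic sequence shorter than cDNA")
  segs <- .match_segments(cdna, genomic, anchor_k)
  if (is.null(segs) || !any(segs[, "cs"] == 1L))
    stop("unalignable: no anchor chain covers the cDNA")
  ns <- nrow(segs)
  ga <- strsplit(genomic, "")[[1]]

  # b is the 1-based cDNA position of the last base of the upstream exon;
  # returns valid split positions for junction between segments i and j
  .valid_splits <- function(i, j) {
    lo <- max(segs[j, "cs"] - 1L, segs[i, "cs"])
    hi <- min(segs[i, "ce"], segs[j, "ce"] - 1L)
    if (lo > hi) return(integer())
    b <- lo:hi
    donor <- b + segs[i, "d"]            # genomic 1-based pos of last exon base
    accep <- b + segs[j, "d"] + 1L       # genomic 1-based pos of next exon base
    ok <- donor + 2L <= length(ga) & accep - 2L >= 1L
    if (require_gt_ag) {
      ok <- ok & ga[donor + 1L] == "G" & ga[donor + 2L] == "T" &
        ga[accep - 2L] == "A" & ga[accep - 1L] == "G"
    }
    b[ok]
  }

  dp <- segs[, "ce"] - segs[, "cs"] + 1L
  back <- rep(NA_integer_, ns)
  for (j in seq_len(ns)) {
    for (i in seq_len(ns)) {
      if (i == j) next
      if (segs[i, "cs"] >= segs[j, "cs"] || segs[i, "ce"] >= segs[j, "ce"]) next
      if (segs[j, "cs"] > segs[i, "ce"] + 1L) next      # uncovered cDNA gap
      ilen <- segs[j, "d"] - segs[i, "d"]
      if (ilen < min_intron || ilen > max_intron) next
      if (!length(.valid_splits(i, j))) next
      cand <- dp[i] + segs[j, "ce"] - segs[i, "ce"]
      if (cand > dp[j] ||
          (cand == dp[j] && !is.na(back[j]) && i < back[j])) {
        dp[j] <- cand; back[j] <- i
      }
    }
  }
  starts1 <- which(segs[, "cs"] == 1L)
  ends <- which(segs[, "ce"] == n)
  best <- NA_integer_; bestv <- -1L
  for (j in ends) {
    # walk back; chain must start at cs == 1
    i <- j; while (!is.na(back[i])) i <- back[i]
    if (segs[i, "cs"] == 1L && dp[j] > bestv) { bestv <- dp[j]; best <- j }
  }
  if (is.na(best) || bestv < n)
    stop("unalignable: best chain covers ", max(0L, bestv), "/", n, " nt")
  chain <- best
  while (!is.na(back[chain[1L]])) chain <- c(back[chain[1L]], chain)

  # resolve junction splits (first valid split; generator plants unique ones)
  exon_start <- integer(); exon_end <- integer()
  cur_c <- 1L
  for (t in seq_along(chain)) {
    i <- chain[t]
    if (t < length(chain)) {
      b <- .valid_splits(i, chain[t + 1L])[1L]
      exon_start <- c(exon_start, cur_c + segs[i, "d"] - 1L)  # 0-based
      exon_end <- c(exon_end, b + segs[i, "d"])
      cur_c <- b + 1L
    } else {
      exon_start <- c(exon_start, cur_c + segs[i, "d"] - 1L)
      exon_end <- c(exon_end, n + segs[i, "d"])
    }
  }
  spliced <- paste(substring(genomic, exon_start + 1L, exon_end), collapse = "")
  if (spliced != cdna)
    stop("internal error: spliced exons do not reproduce the cDNA")
  cds <- if (!is.na(cds_offset) && !is.na(cds_len))
    substr(spliced, cds_offset + 1L, cds_offset + cds_len) else NULL
  gene_model(genomic_id = genomic_id, strand = "+",
             exon_start = exon_start, exon_end = exon_end,
             cds_offset = cds_offset, cds_len = cds_len, cds = cds)
}

#' Intron table with phases for a gene model
#'
#' The phase of an intron is the number of nucleotides of the interrupted
#' codon lying 5' of it, i.e. `(CDS nt upstream of the intron) %% 3`.
#' Introns upstream of the CDS start or downstream of the stop are
#' labeled UTR and get `NA` phase.
#'
#' @param model a [gene_model()] with CDS annotation.
#' @return `data.frame` with columns `index`, `donor_pos`, `acceptor_pos`
#'   (0-based genomic), `length`, `cds_nt_before`, `phase` (`NA` for UTR
#'   introns).
#' @export
intron_phases <- function(model) {
  ex <- model$exons
  k <- nrow(ex) - 1L
  if (k < 1L)
    return(data.frame(index = integer(), donor_pos = integer(),
                      acceptor_pos = integer(), length = integer(),
                      cds_nt_before = integer(), phase = integer()))
  spliced_before <- cumsum(ex$end - ex$start)[seq_len(k)]
  cds_nt_before <- spliced_before - model$cds_offset
  phase <- ifelse(cds_nt_before <= 0L | cds_nt_before >= model$cds_len,
                  NA_integer_, cds_nt_before %% 3L)
  out <- data.frame(index = seq_len(k), donor_pos = ex$end[seq_len(k)],
                    acceptor_pos = ex$start[seq_len(k) + 1L],
                    cds_nt_before = as.integer(cds_nt_before),
                    phase = as.integer(phase))
  out$length <- out$acceptor_pos - out$donor_pos
  stopifnot(all(is.na(out$phase) | out$phase == out$cds_nt_before %% 3L))
  out[, c("index", "donor_pos", "acceptor_pos", "length",
          "cds_nt_before", "phase")]
}

#' Map intron positions from several species onto a protein alignment
#'
#' Each intron of each gene model is assigned to the alignment column
#' containing its interrupted codon (phase 1/2) or the column of the
#' preceding codon (phase 0, intron between codons). Columns where two
#' or more species carry an intron of equal phase are marked shared —
#' the orthology evidence used when comparing gene structures across
#' phyla.
#'
#' @param models named list of [gene_model()]s with `cds` sequences; names
#'   must match alignment row ids.
#' @param msa an [alignment()] of the corresponding precursor proteins.
#' @return `data.frame` with columns `species`, `intron_index`, `column`,
#'   `phase`, `shared`.
#' @export
map_introns_to_alignment <- function(models, msa) {
  rows <- list()
  for (sp in names(models)) {
    model <- models[[sp]]
    ri <- match(sp, msa$ids)
    if (is.na(ri)) stop("species '", sp, "' not present in the alignment")
    gapped <- msa$rows[ri]
    degapped <- gsub("-", "", gapped, fixed = TRUE)
    prot <- sub("\\*$", "", translate_frame(model$cds, 1L))
    if (prot != degapped)
      stop("translated CDS does not match alignment row for species '", sp, "'")
    cols_of_residue <- which(strsplit(gapped, "")[[1]] != "-")
    intr <- intron_phases(model)
    intr <- intr[!is.na(intr$phase), , drop = FALSE]
    if (!nrow(intr)) next
    for (q in seq_len(nrow(intr))) {
      c0 <- intr$cds_nt_before[q]; ph <- intr$phase[q]
      residue <- if (ph == 0L) c0 %/% 3L else c0 %/% 3L + 1L
      residue <- min(residue, length(cols_of_residue))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, intron_index = intr$index[q],
        column = cols_of_residue[residue], phase = ph,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(species = character(), intron_index = integer(),
                      column = integer(), phase = integer(),
                      shared = logical()))
  tab <- do.call(rbind, rows)
  key <- paste(tab$column, tab$phase)
  tab$shared <- ave(seq_along(key), key, FUN = length) >= 2L
  tab
}

#' Write a gene model as GFF3
#'
#' Emits gene, mRNA, exon and CDS features; the CDS `phase` column follows
#' the GFF3 convention (bases to remove from the feature start to reach
#' the first complete codon).
#'
#' @param model a [gene_model()].
#' @param path output path.
#' @param gene_id feature id stem.
#' @export
write_gff3 <- function(model, path, gene_id = "gene1") {
  ex <- model$exons
  src <- "bombemine"
  lines <- c("##gff-version 3")
  span <- c(min(ex$start), max(ex$end))
  fmt <- function(type, s, e, phase, attrs)
    paste(model$genomic_id, src, type, s + 1L, e, ".", model$strand,
          phase, attrs, sep = "\t")
  lines <- c(lines,
             fmt("gene", span[1], span[2], ".", paste0("ID=", gene_id)),
             fmt("mRNA", span[1], span[2], ".",
                 paste0("ID=", gene_id, ".t1;Parent=", gene_id)))
  for (i in seq_len(nrow(ex)))
    lines <- c(lines, fmt("exon", ex$start[i], ex$end[i], ".",
                          paste0("ID=", gene_id, ".e", i, ";Parent=",
                                 gene_id, ".t1")))
  if (!is.na(model$cds_offset)) {
    splice_len <- cumsum(ex$end - ex$start)
    prev_len <- c(0L, splice_len[-length(splice_len)])
    cds_lo <- model$cds_offset; cds_hi <- model$cds_offset + model$cds_len
    for (i in seq_len(nrow(ex))) {
      lo <- max(cds_lo, prev_len[i]); hi <- min(cds_hi, splice_len[i])
      if (lo >= hi) next
      gs <- ex$start[i] + (lo - prev_len[i])
      ge <- ex$start[i] + (hi - prev_len[i])
      phase <- (3L - (lo - cds_lo) %% 3L) %% 3L
      lines <- c(lines, fmt("CDS", gs, ge, phase,
                            paste0("ID=", gene_id, ".cds;Parent=",
                                   gene_id, ".t1")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
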