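# Prohormone-processing grammar: signal-peptide gate, convertase cleavage
# sites, mature-peptide derivation (amidation / pyroglutamate), motif
# scanning, and an additive precursor-likeness score used to rank ORFs.

#' Kyte-Doolittle hydropathy scale
#' @format named numeric vector over the 20 amino acids.
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Predict an N-terminal signal peptide (heuristic)
#'
#' A transparent, rule-based stand-in for a dedicated signal-peptide
#' predictor. The heuristic fires when (i) a basic residue (K/R) occurs in
#' the first 5 positions, and (ii) a window of `hydro_win` residues with
#' mean Kyte-Doolittle hydropathy >= `hydro_mean` lies within positions
#' 3-25. The cleavage point `c` is the first position at or after the end
#' of the first qualifying window, within `[15, 35]`, whose residue is
#' small (A/G/S/C), following the (-1) small-residue rule of signal
#' peptidase. Externally computed signal peptide calls can be supplied
#' instead via the `override` argument.
#'
#' @param protein a single protein string (>= 25 residues for a call).
#' @param hydro_win hydrophobic window length (default 8).
#' @param hydro_mean minimum mean hydropathy for the window (default 2.0).
#' @param override optional integer: externally determined signal length;
#'   returned as-is (passthrough for predictions from external tools).
#' @return `NULL`, or a list with `start = 0`, `end = c` (0-based
#'   half-open span of the signal peptide).
#' @export
predict_signal_peptide <- function(protein, hydro_win = 8L, hydro_mean = 2.0,
                                   override = NULL) {
  if (!is.null(override)) {
    stopifnot(is.numeric(override), override >= 1)
    return(list(start = 0L, end = as.integer(override)))
  }
  n <- nchar(protein)
  if (n < 25L) return(NULL)
  aa <- strsplit(protein, "")[[1]]
  if (!any(aa[1:5] %in% c("K", "R"))) return(NULL)
  kd <- unname(KYTE_DOOLITTLE[aa])
  kd[is.na(kd)] <- 0
  # qualifying windows fully inside positions 3..25
  hi <- min(25L, n)
  starts <- seq.int(3L, hi - hydro_win + 1L)
  starts <- starts[starts >= 3L]
  if (!length(starts)) return(NULL)
  means <- vapply(starts, function(s) mean(kd[s:(s + hydro_win - 1L)]), 0)
  qual <- starts[means >= hydro_mean]
  if (!length(qual)) return(NULL)
  w_end <- qual[1L] + hydro_win - 1L
  for (cc in seq.int(max(15L, w_end), min(35L, n))) {
    if (aa[cc] %in% c("A", "G", "S", "C"))
      return(list(start = 0L, end = as.integer(cc)))
  }
  NULL
}

#' Find prohormone convertase cleavage sites
#'
#' Scans a protein for dibasic cleavage sites (adjacent basic pairs from
#' `dibasic`, default KR and RR) and, optionally, monobasic sites (a
#' single R not adjacent to another basic residue). Overlapping pairs are
#' resolved leftmost-greedily (in "KRR" the pair is KR at the first two
#' positions). Cleavage is placed C-terminal to the basic pair.
#'
#' @param protein a single protein string.
#' @param dibasic character vector of allowed basic pairs, a subset of
#'   `c("KR","RR","KK","RK")`.
#' @param allow_monobasic also report single-R sites (default `FALSE`).
#' @return `data.frame` with columns `position` (0-based index of the
#'   residue after which cleavage occurs), `kind`
#'   (`"dibasic"`/`"monobasic"`), `basic_pair`.
#' @export
find_cleavage_sites <- function(protein, dibasic = c("KR", "RR"),
                                allow_monobasic = FALSE) {
  stopifnot(all(dibasic %in% c("KR", "RR", "KK", "RK")))
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  pos <- integer(); kind <- character(); pair <- character()
  in_pair <- logical(n)
  i <- 1L
  while (i < n) {
    p <- paste0(aa[i], aa[i + 1L])
    if (p %in% dibasic) {
      pos <- c(pos, i)                       # 0-based index of second residue
      kind <- c(kind, "dibasic"); pair <- c(pair, p)
      in_pair[i] <- in_pair[i + 1L] <- TRUE
      i <- i + 2L
    } else i <- i + 1L
  }
  if (allow_monobasic) {
    for (j in seq_len(n)) {
      if (aa[j] == "R" && !in_pair[j] &&
          (j == 1L || !aa[j - 1L] %in% c("K", "R")) &&
          (j == n  || !aa[j + 1L] %in% c("K", "R"))) {
        pos <- c(pos, j - 1L); kind <- c(kind, "monobasic"); pair <- c(pair, "R")
      }
    }
  }
  out <- data.frame(position = pos, kind = kind, basic_pair = pair,
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

# Pre-boundary (exclusive end of the upstream candidate segment) and
# post-boundary (start of the downstream segment) of a cleavage site, in
# 0-based residue coordinates. The basic residues belong to neither
# product (carboxypeptidase trimming).
.site_bounds <- function(site) {
  if (site$kind == "dibasic")
    c(seg_end = site$position - 1L, next_start = site$position + 1L)
  else
    c(seg_end = site$position, next_start = site$position + 1L)
}

#' Derive mature peptides from a precursor
#'
#' Applies the processing grammar: candidate segments are the intervals
#' between consecutive boundaries (end of the signal peptide, cleavage
#' sites, protein termini), with the basic residues of each site assigned
#' to neither product. A trailing glycine is removed and marks the product
#' as C-terminally amidated; a leading glutamine is flagged as a potential
#' pyroglutamate. The length filter `[min_len, max_len]` is applied after
#' glycine removal.
#'
#' A cleavage site whose upstream segment would be shorter than `min_len`
#' (but non-empty) is demoted to an *internal* site: the segment extends
#' through it, and the portion C-terminal to the demoted pair is reported
#' additionally as a `child` peptide of the full-length `parent` (partial
#' processing; the two-residue stub upstream of such a site makes it an
#' unlikely primary convertase substrate).
#'
#' @param protein a single protein string.
#' @param signal optional signal span as returned by
#'   [predict_signal_peptide()].
#' @param sites cleavage-site table from [find_cleavage_sites()] (any
#'   order; sorted internally).
#' @param min_len,max_len length filter on processed peptides.
#' @return `data.frame` with columns `sequence`, `amidated`,
#'   `pyroglutamate`, `start`, `end` (0-based half-open span on the
#'   precursor, pre-processing), `role` (`"parent"`/`"child"`),
#'   `parent_start` (span start of the parent for child rows, else `NA`).
#' @export
derive_peptides <- function(protein, signal = NULL, sites = NULL,
                            min_len = 5L, max_len = 40L) {
  if (min_len > max_len) stop("min_len > max_len")
  n <- nchar(protein)
  if (is.null(sites)) sites <- find_cleavage_sites(protein)
  sites <- sites[order(sites$position), , drop = FALSE]
  start0 <- if (!is.null(signal)) as.integer(signal$end) else 0L

  segs <- list()   # list of (start, end, trunc_starts)
  cur <- start0; trunc <- integer()
  # a short stretch at the bare protein N-terminus is an unprocessed
  # leader, not a peptide stub: it never demotes the first site
  processed_start <- !is.null(signal)
  if (nrow(sites)) for (k in seq_len(nrow(sites))) {
    b <- .site_bounds(sites[k, ])
    if (b[["seg_end"]] < cur) next           # site inside signal/previous pair
    len <- b[["seg_end"]] - cur
    if (processed_start && len > 0L && len < min_len) {
      # demoted internal site: candidate child starts after the pair
      trunc <- c(trunc, b[["next_start"]])
    } else {
      segs[[length(segs) + 1L]] <- list(start = cur, end = b[["seg_end"]],
                                        trunc = trunc)
      cur <- b[["next_start"]]; trunc <- integer()
      processed_start <- TRUE
    }
  }
  if (n > cur)
    segs[[length(segs) + 1L]] <- list(start = cur, end = n, trunc = trunc)

  rows <- list()
  process <- function(s, e, role, parent_start) {
    seq <- substr(protein, s + 1L, e)
    amid <- FALSE
    if (nchar(seq) && substring(seq, nchar(seq)) == "G") {
      amid <- TRUE
      seq <- substr(seq, 1L, nchar(seq) - 1L)
    }
    pglu <- nchar(seq) > 0L && substring(seq, 1L, 1L) == "Q"
    if (nchar(seq) < min_len || nchar(seq) > max_len) return(NULL)
    data.frame(sequence = seq, amidated = amid, pyroglutamate = pglu,
               start = s, end = e, role = role, parent_start = parent_start,
               stringsAsFactors = FALSE)
  }
  for (sg in segs) {
    if (sg$end <= sg$start) next
    rows[[length(rows) + 1L]] <- process(sg$start, sg$end, "parent", NA_integer_)
    for (ts in sg$trunc)
      if (ts > sg$start && ts < sg$end)
        rows[[length(rows) + 1L]] <- process(ts, sg$end, "child", sg$start)
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(sequence = character(), amidated = logical(),
                      pyroglutamate = logical(), start = integer(),
                      end = integer(), role = character(),
                      parent_start = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Scan a sequence for a peptide motif
#'
#' Motif patterns are amino-acid strings where lowercase `x` matches any
#' residue; a trailing lowercase `a` requires the match to sit at the
#' amidated C-terminus (only satisfiable when `amidated = TRUE`, in which
#' case C-terminal anchoring is implied).
#'
#' @param sequence the (peptide or segment) sequence to scan.
#' @param pattern motif such as `"GPxxG"`, `"PRxN"` or `"FGPxxa"`.
#' @param anchor `"anywhere"`, `"C_terminal"` or `"N_terminal"`.
#' @param amidated whether the scanned sequence is C-terminally amidated.
#' @return `data.frame` of matches with 0-based half-open `start`, `end`.
#' @export
scan_motif <- function(sequence, pattern,
                       anchor = c("anywhere", "C_terminal", "N_terminal"),
                       amidated = FALSE) {
  anchor <- match.arg(anchor)
  if (!nzchar(pattern)) stop("empty motif pattern")
  empty <- data.frame(start = integer(), end = integer())
  needs_amide <- grepl("a$", pattern)
  if (needs_amide) {
    pattern <- sub("a$", "", pattern)
    if (!amidated) return(empty)
    anchor <- "C_terminal"
  }
  if (grepl("[^A-Zx]", pattern)) stop("motif pattern must be amino acids plus 'x'")
  rx <- gsub("x", ".", pattern, fixed = TRUE)
  if (anchor == "C_terminal") rx <- paste0(rx, "$")
  if (anchor == "N_terminal") rx <- paste0("^", rx)
  m <- gregexpr(rx, sequence)[[1]]
  if (m[1] == -1L) return(empty)
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Annotate one protein with the full processing grammar
#'
#' Runs [predict_signal_peptide()], [find_cleavage_sites()],
#' [derive_peptides()] and [scan_motif()] and computes an additive
#' precursor-likeness score:
#' \deqn{2\,[signal] + 2\,[\ge 1\ amidated\ cleavage-bounded\ peptide] +
#'       1\,[motif\ hit] + 0.5\,[peptide\ adjacent\ to\ signal\ end]}
#' The score is a transparent ranking device for candidate precursors;
#' an externally computed score can be substituted downstream where a
#' trained model is available.
#'
#' @param protein a single protein string.
#' @param id record identifier carried into the output.
#' @param motif motif pattern scored as the family signature (default
#'   `"GPxxG"`, scanned C-terminally against pre-processing segments).
#' @param dibasic,allow_monobasic passed to [find_cleavage_sites()].
#' @param min_len,max_len passed to [derive_peptides()].
#' @param signal_override optional externally determined signal length.
#' @return a list of class `precursor_annotation` with elements `id`,
#'   `protein`, `signal`, `sites`, `peptides`, `motif_hits`, `score`.
#' @export
annotate_precursor <- function(protein, id = "prot", motif = "GPxxG",
                               dibasic = c("KR", "RR"), allow_monobasic = FALSE,
                               min_len = 5L, max_len = 40L,
                               signal_override = NULL) {
  signal <- predict_signal_peptide(protein, override = signal_override)
  sites <- find_cleavage_sites(protein, dibasic, allow_monobasic)
  peps <- derive_peptides(protein, signal, sites, min_len, max_len)

  boundary_pos <- sites$position  # used to test cleavage-bounded-ness
  bounded <- function(k) {
    # a peptide counts as cleavage-bounded when at least one of its ends
    # abuts a convertase site (termini alone do not qualify)
    s <- peps$start[k]; e <- peps$end[k]
    up <- any(vapply(seq_len(nrow(sites)), function(j)
      .site_bounds(sites[j, ])[["next_start"]] == s, TRUE))
    dn <- any(vapply(seq_len(nrow(sites)), function(j)
      .site_bounds(sites[j, ])[["seg_end"]] == e, TRUE))
    isTRUE(up) || isTRUE(dn)
  }

  motif_hits <- list()
  has_motif <- FALSE
  if (nrow(peps)) for (k in seq_len(nrow(peps))) {
    seg <- substr(protein, peps$start[k] + 1L, peps$end[k])
    hit <- scan_motif(seg, motif, anchor = "C_terminal")
    if (nrow(hit)) {
      has_motif <- TRUE
      motif_hits[[length(motif_hits) + 1L]] <-
        data.frame(pattern = motif, start = peps$start[k] + hit$start,
                   end = peps$start[k] + hit$end, stringsAsFactors = FALSE)
    }
  }
  motif_hits <- if (length(motif_hits)) do.call(rbind, motif_hits)
                else data.frame(pattern = character(), start = integer(),
                                end = integer(), stringsAsFactors = FALSE)

  has_amid_bounded <- nrow(peps) > 0 && nrow(sites) > 0 &&
    any(vapply(seq_len(nrow(peps)), function(k)
      peps$amidated[k] && bounded(k), TRUE))
  adjacent <- !is.null(signal) && nrow(peps) > 0 &&
    any(peps$start == signal$end)

  score <- 2 * (!is.null(signal)) + 2 * has_amid_bounded + 1 * has_motif +
    0.5 * adjacent

  structure(list(id = id, protein = protein, signal = signal, sites = sites,
                 peptides = peps, motif_hits = motif_hits, score = score),
            class = "precursor_annotation")
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat("precursor_annotation '", x$id, "' (", nchar(x$protein), " aa)\n", sep = "")
  if (!is.null(x$signal))
    cat("  signal peptide: residues 1-", x$signal$end, "\n", sep = "")
  cat("  cleavage sites:", nrow(x$sites), " peptides:", nrow(x$peptides),
      " score:", x$score, "\n")
  invisible(x)
}

#' Annotate and rank a set of proteins
#'
#' @param records a `seq_records` data frame of proteins (or any data
#'   frame with `id` and `residues`).
#' @param top_k retain at most this many candidates after ranking by
#'   score (default 5000).
#' @param ... passed to [annotate_precursor()].
#' @return list with `annotations` (a score-ranked `data.frame`: `id`,
#'   `length`, `signal_end`, `n_sites`, `n_peptides`, `score`) and
#'   `peptides` (one row per derived peptide with `parent` id, `species`,
#'   `group` tags carried over).
#' @export
annotate_set <- function(records, top_k = 5000L, ...) {
  anns <- lapply(seq_len(nrow(records)), function(i)
    annotate_precursor(records$residues[i], id = records$id[i], ...))
  tab <- data.frame(
    id = vapply(anns, `[[`, "", "id"),
    length = vapply(anns, function(a) nchar(a$protein), 0L),
    signal_end = vapply(anns, function(a)
      if (is.null(a$signal)) NA_integer_ else a$signal$end, 0L),
    n_sites = vapply(anns, function(a) nrow(a$sites), 0L),
    n_peptides = vapply(anns, function(a) nrow(a$peptides), 0L),
    score = vapply(anns, `[[`, 0, "score"),
    stringsAsFactors = FALSE)
  ord <- order(-tab$score, tab$id)
  tab <- tab[ord, , drop = FALSE][seq_len(min(top_k, nrow(tab))), , drop = FALSE]
  rownames(tab) <- NULL
  keep <- tab$id
  pep_rows <- lapply(anns, function(a) {
    if (!nrow(a$peptides) || !(a$id %in% keep)) return(NULL)
    p <- a$peptides
    p$parent <- a$id
    i <- match(a$id, records$id)
    p$species <- if ("species" %in% names(records)) records$species[i] else NA
    p$group <- if ("group" %in% names(records)) records$group[i] else NA
    p
  })
  pep_rows <- Filter(Negate(is.null), pep_rows)
  peptides <- if (length(pep_rows)) do.call(rbind, pep_rows)
              else data.frame()
  rownames(peptides) <- NULL
  list(annotations = tab, peptides = peptides)
}
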