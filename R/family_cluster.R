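# Grouping of predicted peptides from distinct precursors (and species)
# into candidate families by shared terminal residues, the screen used to
# surface conserved neuropeptide families from bulk predictions.

#' Count identical residues in a terminal window
#'
#' Peptides are compared over their last (`terminus = "C"`) or first
#' (`terminus = "N"`) `k` residues, position by position, without gaps.
#' When a peptide is shorter than `k` the window shrinks to the shorter
#' length.
#'
#' @param a,b peptide sequences.
#' @param terminus `"C"` or `"N"`.
#' @param k window length (default 6).
#' @return integer count of identical positions.
#' @export
terminal_identity <- function(a, b, terminus = c("C", "N"), k = 6L) {
  terminus <- match.arg(terminus)
  w <- min(k, nchar(a), nchar(b))
  if (w == 0L) return(0L)
  wa <- if (terminus == "C") substr(a, nchar(a) - w + 1L, nchar(a))
        else substr(a, 1L, w)
  wb <- if (terminus == "C") substr(b, nchar(b) - w + 1L, nchar(b))
        else substr(b, 1L, w)
  sum(strsplit(wa, "")[[1]] == strsplit(wb, "")[[1]])
}

#' Cluster peptides into terminal-similarity families
#'
#' Two peptides are linked when they come from distinct precursors (and
#' distinct species if `cross_species_only`) and share at least `m`
#' identical residues in their terminal `k`-window (for peptides shorter
#' than `k` the threshold scales as `ceiling(m * len / k)`). Families are
#' connected components (single linkage) with at least two members,
#' sorted by size then consensus.
#'
#' @param peptides `data.frame` with columns `sequence`, `parent` and
#'   optionally `species` (as produced by [annotate_set()]).
#' @param terminus `"C"` or `"N"`.
#' @param k window length (default 6).
#' @param m minimum identical positions (default 4).
#' @param cross_species_only require members of an edge to come from
#'   different species.
#' @return list of families; each a list with `members` (row indices into
#'   `peptides`), `sequences`, `parents`, `terminus`, `consensus`
#'   (strict-majority residue per window position, else `x`).
#' @export
cluster_families <- function(peptides, terminus = c("C", "N"), k = 6L, m = 4L,
                             cross_species_only = FALSE) {
  terminus <- match.arg(terminus)
  stopifnot(m >= 1L, m <= k)
  n <- nrow(peptides)
  if (!n) return(list())
  from <- integer(); to <- integer()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (peptides$parent[i] == peptides$parent[j]) next
    if (cross_species_only &&
        identical(peptides$species[i], peptides$species[j])) next
    w <- min(k, nchar(peptides$sequence[i]), nchar(peptides$sequence[j]))
    thr <- if (w < k) ceiling(m * w / k) else m
    if (terminal_identity(peptides$sequence[i], peptides$sequence[j],
                          terminus, k) >= thr) {
      from <- c(from, i); to <- c(to, j)
    }
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = n, directed = FALSE)
  comp <- igraph::components(g)
  fams <- list()
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) < 2L) next
    seqs <- peptides$sequence[members]
    w <- min(k, min(nchar(seqs)))
    wins <- if (terminus == "C")
      substr(seqs, nchar(seqs) - w + 1L, nchar(seqs)) else substr(seqs, 1L, w)
    cons <- vapply(seq_len(w), function(p) {
      ch <- substr(wins, p, p)
      tb <- sort(table(ch), decreasing = TRUE)
      if (tb[1] > length(ch) / 2) names(tb)[1] else "x"
    }, "")
    fams[[length(fams) + 1L]] <- list(
      members = members, sequences = seqs,
      parents = peptides$parent[members], terminus = terminus,
      consensus = paste(cons, collapse = ""))
  }
  ord <- order(-vapply(fams, function(f) length(f$members), 0L),
               vapply(fams, `[[`, "", "consensus"))
  fams[ord]
}

#' Write a family report as TSV
#'
#' @param families output of [cluster_families()].
#' @param peptides the peptide table the families index into.
#' @param path output path.
#' @export
write_family_report <- function(families, peptides, path) {
  rows <- list()
  for (f in seq_along(families)) {
    fam <- families[[f]]
    rows[[f]] <- data.frame(
      family_id = f, member = fam$sequences, parent = fam$parents,
      species = if ("species" %in% names(peptides))
        peptides$species[fam$members] else NA,
      terminus = fam$terminus, consensus = fam$consensus,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = integer(), member = character(),
               parent = character(), species = character(),
               terminus = character(), consensus = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
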