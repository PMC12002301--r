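# Pairwise and progressive multiple alignment of peptides/precursors,
# and the group-aware conserved-column rule used to compare echinoderm
# and chordate bombesin-type peptides.

#' Load a named substitution matrix
#'
#' @param name matrix name available in Biostrings (e.g. `"BLOSUM62"`).
#' @return numeric substitution matrix.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

.score_fun <- function(matrix = NULL, match = 1, mismatch = -1) {
  if (is.character(matrix)) matrix <- substitution_matrix(matrix)
  function(x, y) {
    if (is.null(matrix)) return(if (x == y) match else mismatch)
    if (x %in% rownames(matrix) && y %in% colnames(matrix)) matrix[x, y]
    else 0  # unknown residue scores 0 against everything
  }
}

# numeric substitution table over an explicit alphabet, for the C++
# kernels: residues are 1-based codes into S; residues unknown to the
# matrix score 0 against everything
.code_table <- function(alphabet, matrix = NULL, match = 1, mismatch = -1) {
  if (is.character(matrix)) matrix <- substitution_matrix(matrix)
  k <- length(alphabet)
  if (is.null(matrix)) {
    S <- base::matrix(mismatch, k, k)
    diag(S) <- match
  } else {
    S <- base::matrix(0, k, k)
    known <- alphabet %in% rownames(matrix)
    if (any(known))
      S[known, known] <- matrix[alphabet[known], alphabet[known]]
  }
  dimnames(S) <- list(alphabet, alphabet)
  S
}

.encode <- function(chars, alphabet) match(chars, alphabet)

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' A gap of length L costs `gap_open + (L - 1) * gap_extend` (both
#' negative). Traceback ties are broken deterministically: diagonal over
#' up (gap in `b`) over left (gap in `a`). Residues absent from the
#' substitution matrix score 0 against everything.
#'
#' @param a,b sequences to align (non-empty; `b` may be empty for the
#'   degenerate all-gap case).
#' @param matrix substitution matrix or its Biostrings name; `NULL` uses
#'   `match`/`mismatch` scoring.
#' @param match,mismatch scores used when `matrix` is `NULL`.
#' @param gap_open,gap_extend affine gap parameters (default -10 / -1).
#' @return list of class `alignment` with `ids`, `rows` (gapped strings),
#'   `score`, `matrix_name`, `gap_open`, `gap_extend`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", match = 1, mismatch = -1,
                         gap_open = -10, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  alphabet <- unique(c(av, bv, "A"))
  S <- .code_table(alphabet, matrix, match, mismatch)
  res <- cpp_nw_affine(.encode(av, alphabet), .encode(bv, alphabet), S,
                       gap_open, gap_extend)
  ops <- res$ops
  ga <- gb <- character(length(ops))
  i <- j <- 0L
  for (t in seq_along(ops)) {
    if (ops[t] == 1L) { i <- i + 1L; j <- j + 1L; ga[t] <- av[i]; gb[t] <- bv[j] }
    else if (ops[t] == 2L) { i <- i + 1L; ga[t] <- av[i]; gb[t] <- "-" }
    else { j <- j + 1L; ga[t] <- "-"; gb[t] <- bv[j] }
  }
  structure(list(ids = c("a", "b"),
                 rows = c(paste(ga, collapse = ""), paste(gb, collapse = "")),
                 score = res$score,
                 matrix_name = if (is.character(matrix)) matrix else
                   if (is.null(matrix)) "match/mismatch" else "custom",
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment of", length(x$rows), "sequence(s), width",
      nchar(x$rows[1]), "\n")
  for (i in seq_along(x$rows))
    cat(sprintf("  %-12s %s\n", x$ids[i], x$rows[i]))
  if (!is.null(x$score)) cat("  score:", x$score, "\n")
  invisible(x)
}

# profile-profile alignment; profiles are character matrices (rows =
# sequences, cols = alignment columns); S is a coded substitution table
.align_profiles <- function(A, B, alphabet, S, gap_open, gap_extend) {
  Ac <- matrix(.encode(A, alphabet), nrow(A)); Ac[A == "-"] <- 0L
  Bc <- matrix(.encode(B, alphabet), nrow(B)); Bc[B == "-"] <- 0L
  Ac[is.na(Ac)] <- 0L; Bc[is.na(Bc)] <- 0L
  ops <- cpp_profile_align(Ac, Bc, S, gap_open, gap_extend)
  n <- ncol(A); m <- ncol(B)
  out <- matrix("-", nrow(A) + nrow(B), length(ops))
  i <- j <- 0L
  ra <- seq_len(nrow(A)); rb <- nrow(A) + seq_len(nrow(B))
  for (t in seq_along(ops)) {
    if (ops[t] != 3L) { i <- i + 1L; out[ra, t] <- A[, i] }
    if (ops[t] != 2L) { j <- j + 1L; out[rb, t] <- B[, j] }
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' Guide order comes from UPGMA (average-linkage [stats::hclust()]) on
#' pairwise Needleman-Wunsch identity distances; profiles are merged
#' pairwise in that order. The result is deterministic regardless of
#' input order: sequences are processed in id order internally and output
#' rows follow the input order.
#'
#' @param records a `seq_records` data frame, or a named character vector
#'   of sequences.
#' @inheritParams global_align
#' @return an `alignment` object.
#' @export
progressive_msa <- function(records, matrix = "BLOSUM62", match = 1,
                            mismatch = -1, gap_open = -10, gap_extend = -1) {
  if (is.character(records))
    records <- data.frame(id = names(records), residues = unname(records),
                          stringsAsFactors = FALSE)
  if (nrow(records) < 2L) stop("need at least 2 sequences")
  ord <- order(records$id)
  ids <- records$id[ord]; seqs <- records$residues[ord]
  k <- length(ids)
  alphabet <- unique(c(unlist(strsplit(seqs, "")), "A"))
  S <- .code_table(alphabet, matrix, match, mismatch)
  D <- base::matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    al <- global_align(seqs[i], seqs[j], matrix = matrix, match = match,
                       mismatch = mismatch, gap_open = gap_open,
                       gap_extend = gap_extend)
    r1 <- strsplit(al$rows[1], "")[[1]]; r2 <- strsplit(al$rows[2], "")[[1]]
    D[i, j] <- D[j, i] <- 1 - sum(r1 == r2) / length(r1)
  }
  profiles <- lapply(seqs, function(s) matrix(strsplit(s, "")[[1]], nrow = 1))
  names(profiles) <- NULL
  members <- as.list(seq_len(k))
  if (k == 2L) {
    merged <- .align_profiles(profiles[[1]], profiles[[2]], alphabet, S,
                              gap_open, gap_extend)
    row_ids <- ids
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    prof_by_node <- list(); ids_by_node <- list()
    for (s in seq_len(nrow(hc$merge))) {
      pick <- function(x) {
        if (x < 0) list(p = profiles[[-x]], i = ids[-x])
        else list(p = prof_by_node[[x]], i = ids_by_node[[x]])
      }
      L <- pick(hc$merge[s, 1]); R <- pick(hc$merge[s, 2])
      # deterministic orientation: lexicographically smaller first id left
      if (min(R$i) < min(L$i)) { tmp <- L; L <- R; R <- tmp }
      merged_s <- .align_profiles(L$p, R$p, alphabet, S, gap_open, gap_extend)
      prof_by_node[[s]] <- merged_s
      ids_by_node[[s]] <- c(L$i, R$i)
    }
    merged <- prof_by_node[[nrow(hc$merge)]]
    row_ids <- ids_by_node[[nrow(hc$merge)]]
  }
  rows <- apply(merged, 1, paste, collapse = "")
  # restore input order
  out_idx <- match(records$id, row_ids)
  structure(list(ids = records$id, rows = rows[out_idx], score = NULL,
                 matrix_name = if (is.character(matrix)) matrix else "custom",
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment")
}

#' Build an alignment object from pre-aligned rows
#'
#' @param ids sequence ids.
#' @param rows equal-length gapped strings.
#' @return an `alignment` object.
#' @export
alignment <- function(ids, rows) {
  stopifnot(length(ids) == length(rows),
            length(unique(nchar(rows))) == 1L)
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 score = NULL, matrix_name = NA_character_,
                 gap_open = NA_real_, gap_extend = NA_real_),
            class = "alignment")
}

#' Read / write aligned FASTA
#'
#' @param path file path.
#' @return `read_alignment`: an `alignment` object.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  alignment(ids = sub("\\s.*$", "", names(set)),
            rows = toupper(as.character(set)))
}

#' @rdname read_alignment
#' @param msa an `alignment` object.
#' @export
write_alignment <- function(msa, path) {
  set <- Biostrings::BStringSet(msa$rows)
  names(set) <- msa$ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Group-aware conserved columns
#'
#' Reports alignment columns where some residue occurs in at least one
#' group-A row (e.g. echinoderm species) and at least `min_b` group-B
#' rows (e.g. chordate species) — the rule used to highlight residues
#' conserved between an echinoderm peptide and several chordate peptides.
#'
#' @param msa an `alignment` object.
#' @param group_a_ids,group_b_ids disjoint subsets of `msa$ids`.
#' @param min_b minimum number of group-B rows carrying the residue
#'   (default 3, "several").
#' @return `data.frame` with columns `column` (1-based), `residue`,
#'   `n_a`, `n_b`.
#' @export
conserved_columns <- function(msa, group_a_ids, group_b_ids, min_b = 3L) {
  if (!length(group_a_ids) || !length(group_b_ids)) stop("empty group")
  if (length(intersect(group_a_ids, group_b_ids))) stop("groups must be disjoint")
  stopifnot(all(c(group_a_ids, group_b_ids) %in% msa$ids), min_b >= 2L)
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  rownames(mat) <- msa$ids
  A <- mat[group_a_ids, , drop = FALSE]
  B <- mat[group_b_ids, , drop = FALSE]
  out <- list()
  for (j in seq_len(ncol(mat))) {
    res <- setdiff(unique(A[, j]), "-")
    for (r in res) {
      nb <- sum(B[, j] == r)
      if (nb >= min_b)
        out[[length(out) + 1L]] <- data.frame(
          column = j, residue = r, n_a = sum(A[, j] == r), n_b = nb,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(column = integer(), residue = character(),
                      n_a = integer(), n_b = integer()))
  do.call(rbind, out)
}
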