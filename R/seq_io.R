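#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet GENETIC_CODE
NULL

.DNA_ALPHABET  <- c("A", "C", "G", "T", "N")
.AA_ALPHABET   <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Create a set of sequence records
#'
#' A sequence record set is a plain `data.frame` with columns `id`,
#' `description`, `residues`, `species` and `group`. It is the common
#' currency passed between pipeline stages.
#'
#' @param id character vector of unique record identifiers.
#' @param residues character vector of sequences (uppercase enforced).
#' @param description optional free-text descriptions.
#' @param species,group optional per-record tags used by the clustering and
#'   conservation stages (e.g. `group = "echinoderm"`).
#' @param alphabet `"dna"` (A/C/G/T/N) or `"protein"` (20 amino acids + X).
#' @return a `data.frame` of class `seq_records`.
#' @export
seq_records <- function(id, residues, description = "", species = NA_character_,
                        group = NA_character_, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id))
    stop("duplicate record id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(residues)))
    stop("empty sequence for record(s): ", paste(id[!nzchar(residues)], collapse = ", "))
  ok <- .AA_ALPHABET
  if (alphabet == "dna") ok <- .DNA_ALPHABET
  for (i in seq_along(residues)) {
    chars <- unique(strsplit(residues[[i]], "")[[1]])
    bad <- setdiff(chars, ok)
    if (length(bad))
      stop("record '", id[[i]], "' contains characters outside the ", alphabet,
           " alphabet: ", paste(bad, collapse = ""))
  }
  out <- data.frame(id = id, description = rep_len(as.character(description), length(id)),
                    residues = residues,
                    species = rep_len(as.character(species), length(id)),
                    group = rep_len(as.character(group), length(id)),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; this wrapper
#' normalizes case, splits headers into id/description, and enforces the
#' declared alphabet and id uniqueness.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return a `seq_records` data frame (input order preserved).
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id = id, residues = as.character(set), description = desc,
              alphabet = alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param records a `seq_records` data frame (or anything with `id`,
#'   `residues`, `description` columns).
#' @param path output path.
#' @param width line wrap width (default 60 columns).
#' @export
write_fasta <- function(records, path, width = 60L) {
  hdr <- ifelse(nzchar(records$description),
                paste(records$id, records$description), records$id)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param dna a single DNA string over A/C/G/T/N.
#' @return the reverse complement string.
#' @export
revcomp <- function(dna) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(dna)), "")[[1]]),
        collapse = "")
}

#' Translate a DNA string in a given reading frame
#'
#' Frames +1/+2/+3 read the forward strand from offsets 0/1/2; frames
#' -1/-2/-3 read the reverse complement likewise. The standard genetic code
#' is used; stop codons are rendered `*`; any codon containing a non-ACGT
#' character translates to `X`; a trailing partial codon is dropped.
#'
#' @param dna a single DNA string.
#' @param frame integer in `c(1, 2, 3, -1, -2, -3)`.
#' @return the protein string (possibly containing `*`).
#' @export
translate_frame <- function(dna, frame = 1L) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  dna <- toupper(dna)
  if (frame < 0) dna <- revcomp(dna)
  off <- abs(frame) - 1L
  n <- nchar(dna) - off
  if (n < 3L) return("")
  starts <- seq.int(off + 1L, off + n - n %% 3L, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Extract open reading frames from all six frames
#'
#' An ORF is a maximal stop-free stretch of the translation (stop-to-stop;
#' an initiating methionine is *not* required, so that precursors whose
#' true start lies upstream of the first Met in a sequence fragment are
#' still recovered). Coordinates are 0-based half-open on the forward
#' strand of the input, stop codon excluded.
#'
#' @param dna a single DNA string.
#' @param min_aa minimum ORF length in residues (>= 1).
#' @param parent_id identifier recorded in the output table.
#' @return a `data.frame` with columns `parent_id`, `frame`, `nt_start`,
#'   `nt_end`, `length_aa`, `protein`.
#' @export
six_frame_orfs <- function(dna, min_aa = 20L, parent_id = "seq") {
  stopifnot(min_aa >= 1L)
  L <- nchar(dna)
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    prot <- translate_frame(dna, frame)
    if (!nzchar(prot)) next
    # maximal stop-free stretches
    pieces <- strsplit(prot, "*", fixed = TRUE)[[1]]
    aa_start <- 0L  # 0-based residue index of current piece within prot
    for (p in pieces) {
      len <- nchar(p)
      if (len >= min_aa) {
        off <- abs(frame) - 1L
        s <- off + 3L * aa_start          # 0-based nt on translated strand
        e <- s + 3L * len
        if (frame > 0) {
          nt_start <- s; nt_end <- e
        } else {
          nt_start <- L - e; nt_end <- L - s
        }
        out[[length(out) + 1L]] <- data.frame(
          parent_id = parent_id, frame = frame,
          nt_start = nt_start, nt_end = nt_end,
          length_aa = len, protein = p, stringsAsFactors = FALSE)
      }
      aa_start <- aa_start + nchar(p) + 1L  # +1 for the stop
    }
  }
  if (!length(out))
    return(data.frame(parent_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      length_aa = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write an ORF table as TSV
#'
#' @param orfs output of [six_frame_orfs()].
#' @param path output path.
#' @export
write_orf_table <- function(orfs, path) {
  utils::write.table(orfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
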