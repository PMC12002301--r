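# Independent oracles used by the tests. These deliberately re-derive
# quantities from first principles (atomic masses, exhaustive enumeration,
# codon-table lookups) rather than calling the package's own code paths.

# --- elemental-composition residue masses -----------------------------------
# atomic monoisotopic masses (CODATA/IUPAC)
.at <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
         O = 15.9949146221, S = 31.97207069)

# residue (i.e. dehydrated) elemental compositions of the 20 amino acids
.aa_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0))

oracle_residue_mass <- function(aa) {
  f <- .aa_formula[[aa]]
  sum(f * .at[names(f)])
}

# neutral peptide mass from elemental composition; modifications applied
# as elemental deltas: amide = -O -H +N +H2 (OH -> NH2); pGlu = -N -H3
oracle_peptide_mass <- function(peptide, c_term = "free_acid",
                                n_term = "free") {
  aa <- strsplit(peptide, "")[[1]]
  m <- sum(vapply(aa, oracle_residue_mass, 0)) +
    2 * .at["H"] + .at["O"]                      # + water
  if (c_term == "amide")
    m <- m - .at["O"] - .at["H"] + .at["N"] + 2 * .at["H"]
  if (n_term == "pyroglutamate")
    m <- m - .at["N"] - 3 * .at["H"]
  unname(m)
}

# --- exhaustive global alignment (linear gap = open == extend) --------------
# enumerates all alignments of a and b recursively; oracle for short
# sequences only
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- nchar(a); m <- nchar(b)
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    memo[[key]] <- best
    best
  }
  rec(n, m)
}

# --- random additive tree distances (oracle for NJ recovery) ----------------
random_additive_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1)
  tr
}

# --- misc -------------------------------------------------------------------
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
random_peptide <- function(n) paste(sample(names(.aa_formula), n, TRUE),
                                    collapse = "")

# Robinson-Foulds distance as a bare number
rf_dist <- function(t1, t2)
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)))
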