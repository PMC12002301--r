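# Peptide mass and b/y fragment-ion prediction with C-terminal amidation
# and N-terminal pyroglutamate, plus tolerance-based matching of observed
# peak lists — the in-silico half of MS confirmation of predicted
# neuropeptides.

# Monoisotopic and average residue masses (Da) for the 20 amino acids.
#' Residue mass tables
#' @format named numeric vectors (Da), one value per residue.
#' @export
RESIDUE_MASS_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

#' @rdname RESIDUE_MASS_MONO
#' @export
RESIDUE_MASS_AVG <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167,
  V =  99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

.MASS <- list(
  mono = list(residues = RESIDUE_MASS_MONO, water = 18.010565,
              amide = -0.98402, pglu = -17.02655),
  average = list(residues = RESIDUE_MASS_AVG, water = 18.0153,
                 amide = -0.9847, pglu = -17.0305))
.PROTON <- 1.007276

.residue_masses <- function(peptide, kind) {
  tab <- .MASS[[kind]]$residues
  aa <- strsplit(peptide, "")[[1]]
  m <- tab[aa]
  if (anyNA(m))
    stop("unknown residue(s): ", paste(unique(aa[is.na(m)]), collapse = ""))
  unname(m)
}

.term_delta <- function(c_term, n_term, kind) {
  d <- 0
  if (c_term == "amide") d <- d + .MASS[[kind]]$amide
  if (n_term == "pyroglutamate") d <- d + .MASS[[kind]]$pglu
  d
}

#' Neutral peptide mass
#'
#' `mass = sum(residue masses) + water + delta(c_term) + delta(n_term)`.
#' The amide delta is -0.98402 Da (mono; -OH replaced by -NH2) and the
#' pyroglutamate delta is -17.02655 Da (mono; NH3 loss on cyclization of
#' an N-terminal Gln).
#'
#' @param peptide peptide sequence (canonical residues).
#' @param c_term `"free_acid"` or `"amide"`.
#' @param n_term `"free"` or `"pyroglutamate"` (requires first residue Q).
#' @param kind `"mono"` or `"average"`.
#' @return neutral mass in Da.
#' @export
peptide_mass <- function(peptide, c_term = c("free_acid", "amide"),
                         n_term = c("free", "pyroglutamate"),
                         kind = c("mono", "average")) {
  c_term <- match.arg(c_term); n_term <- match.arg(n_term)
  kind <- match.arg(kind)
  if (!nzchar(peptide)) stop("empty peptide")
  if (n_term == "pyroglutamate" && substring(peptide, 1L, 1L) != "Q")
    stop("pyroglutamate requires an N-terminal Q")
  sum(.residue_masses(peptide, kind)) + .MASS[[kind]]$water +
    .term_delta(c_term, n_term, kind)
}

#' Theoretical b/y fragment ions
#'
#' Neutral `b_i` is the sum of the first `i` residue masses (plus the
#' N-terminal modification delta); neutral `y_j` is the sum of the last
#' `j` residue masses plus water (plus the C-terminal delta). Observed
#' m/z is `(neutral + z * 1.007276) / z`. Complementary pairs satisfy
#' `b_i + y_(n-i) = neutral peptide mass`.
#'
#' @inheritParams peptide_mass
#' @param series subset of `c("b", "y")`.
#' @param max_charge maximum charge state (>= 1; default 2).
#' @return `data.frame` with columns `series`, `index`, `charge`, `mz`.
#' @export
fragment_ions <- function(peptide, c_term = c("free_acid", "amide"),
                          n_term = c("free", "pyroglutamate"),
                          series = c("b", "y"), max_charge = 2L,
                          kind = "mono") {
  c_term <- match.arg(c_term); n_term <- match.arg(n_term)
  stopifnot(max_charge >= 1L, all(series %in% c("b", "y")))
  rm <- .residue_masses(peptide, kind)
  n <- length(rm)
  if (n < 2L)
    return(data.frame(series = character(), index = integer(),
                      charge = integer(), mz = numeric()))
  dn <- if (n_term == "pyroglutamate") .MASS[[kind]]$pglu else 0
  dc <- if (c_term == "amide") .MASS[[kind]]$amide else 0
  out <- list()
  idx <- seq_len(n - 1L)
  if ("b" %in% series) {
    neutral <- cumsum(rm)[idx] + dn
    for (z in seq_len(max_charge))
      out[[length(out) + 1L]] <- data.frame(
        series = "b", index = idx, charge = z,
        mz = (neutral + z * .PROTON) / z, stringsAsFactors = FALSE)
  }
  if ("y" %in% series) {
    neutral <- cumsum(rev(rm))[idx] + .MASS[[kind]]$water + dc
    for (z in seq_len(max_charge))
      out[[length(out) + 1L]] <- data.frame(
        series = "y", index = idx, charge = z,
        mz = (neutral + z * .PROTON) / z, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Match an observed peak list against a peptide's fragment ions
#'
#' Greedy nearest-peak assignment: theoretical ions are matched to the
#' closest unused observed peak within `tol_ppm`. Coverage is the
#' fraction of the `n - 1` inter-residue bonds supported by at least one
#' matched ion (`b_i` supports bond `i`, `y_j` supports bond `n - j`).
#'
#' @param peaks `data.frame` with columns `mz`, `intensity`.
#' @inheritParams fragment_ions
#' @param tol_ppm match tolerance in parts per million (> 0).
#' @return list of class `spectrum_match` with `matched` (data frame:
#'   `series`, `index`, `charge`, `theo_mz`, `obs_mz`, `ppm_error`) and
#'   `coverage`.
#' @export
match_spectrum <- function(peaks, peptide, c_term = c("free_acid", "amide"),
                           n_term = c("free", "pyroglutamate"),
                           tol_ppm = 10, max_charge = 1L) {
  c_term <- match.arg(c_term); n_term <- match.arg(n_term)
  stopifnot(tol_ppm > 0)
  ions <- fragment_ions(peptide, c_term, n_term, max_charge = max_charge)
  nb <- nchar(peptide) - 1L
  if (!nrow(peaks) || !nrow(ions)) {
    return(structure(list(matched = data.frame(), coverage = 0),
                     class = "spectrum_match"))
  }
  used <- rep(FALSE, nrow(peaks))
  rows <- list()
  for (k in seq_len(nrow(ions))) {
    d <- abs(peaks$mz - ions$mz[k]) / ions$mz[k] * 1e6
    d[used] <- Inf
    w <- which.min(d)
    if (d[w] <= tol_ppm) {
      used[w] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        series = ions$series[k], index = ions$index[k],
        charge = ions$charge[k], theo_mz = ions$mz[k],
        obs_mz = peaks$mz[w],
        ppm_error = (peaks$mz[w] - ions$mz[k]) / ions$mz[k] * 1e6,
        stringsAsFactors = FALSE)
    }
  }
  matched <- if (length(rows)) do.call(rbind, rows) else data.frame()
  bonds <- logical(nb)
  if (nrow(matched)) {
    bidx <- matched$index[matched$series == "b"]
    yidx <- nb + 1L - matched$index[matched$series == "y"]
    bonds[unique(c(bidx, yidx))] <- TRUE
  }
  structure(list(matched = matched, coverage = mean(bonds)),
            class = "spectrum_match")
}

#' @export
print.spectrum_match <- function(x, ...) {
  cat("spectrum_match:", nrow(x$matched), "ion(s) matched, bond coverage",
      sprintf("%.1f%%", 100 * x$coverage), "\n")
  invisible(x)
}
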