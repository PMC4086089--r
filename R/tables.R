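# Reference tables: amino-acid codes, radii, reference areas, scales and
# propensities used across the package. All are standard published constants.

#' @keywords internal
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

#' @keywords internal
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

names(AA1) <- AA3

WATER_CODES <- c("HOH", "DOD", "WAT", "H2O")

NUCLEIC_CODES <- c("DA","DC","DG","DT","DI","DU","A","C","G","U","I")

#' Convert three-letter residue codes to one-letter codes
#'
#' Unknown codes map to `"X"`.
#'
#' @param x character vector of three-letter codes.
#' @return character vector of one-letter codes.
#' @export
aa_three_to_one <- function(x) {
  out <- AA1[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' @keywords internal
aa_one_to_three <- function(x) {
  out <- names(AA1)[match(toupper(x), AA1)]
  out[is.na(out)] <- "UNK"
  out
}

# van der Waals radii (A) by element; used for SASA sphere sampling.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, FE = 1.80, ZN = 1.39, MG = 1.73, K = 2.75,
               NA. = 2.27, CA = 2.31, CL = 1.75)

#' @keywords internal
vdw_radius <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  r <- VDW_RADII[el]
  r[is.na(r)] <- 1.80
  unname(r)
}

# Theoretical maximum solvent-accessible surface areas (A^2) per residue type
# (Tien et al. 2013, theoretical column); denominators for relative SASA.
MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector over the 20 one-letter amino-acid codes; positive
#' values are hydrophobic. Used for interface hydrophobicity and for the
#' burial propensity predictor.
#' @export
KYTE_DOOLITTLE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
                    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Chou-Fasman conformational propensities (helix, strand) per residue.
CF_HELIX <- c(A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
              Q = 1.11, E = 1.51, G = 0.57, H = 1.00, I = 1.08,
              L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
              S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06)

CF_STRAND <- c(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
               Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
               L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
               S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)

#' Fetch a substitution matrix by name
#'
#' Returns the scoring matrix extended with an `X` row/column (score 0 against
#' everything, -1 on the diagonal is not used; unknown residues neither reward
#' nor penalize matches).
#'
#' @param name matrix name, currently `"BLOSUM62"`.
#' @return integer matrix with amino-acid one-letter row/column names.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (!identical(name, "BLOSUM62")) {
    stop("unknown substitution matrix: ", name)
  }
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  keep <- c(AA1, "X")
  m <- m[keep, keep]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  attr(m, "name") <- name
  m
}

# Conservative exchange partners used by the homolog generator: for each
# residue, substitutions are drawn from its highest-scoring BLOSUM62 partners
# so that mutated fixtures look like plausible homologs rather than random
# strings.
#' @keywords internal
exchange_partners <- function(mat = substitution_matrix(), k = 4) {
  partners <- lapply(AA1, function(a) {
    scores <- mat[a, AA1]
    scores <- scores[names(scores) != a]
    names(sort(scores, decreasing = TRUE))[seq_len(k)]
  })
  names(partners) <- AA1
  partners
}
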