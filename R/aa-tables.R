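#' @keywords internal
"_PACKAGE"

## Residue and chemistry lookup tables shared across modules.

#' Three-letter to one-letter amino-acid code map (20 standard residues)
#' @keywords internal
AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA1_TO_3 <- structure(names(AA3_TO_1), names = unname(AA3_TO_1))

#' Deoxyribonucleotide residue names
#' @keywords internal
DNA_RES <- c("DA", "DT", "DG", "DC", "DI", "DU")

#' Ribonucleotide residue names
#' @keywords internal
RNA_RES <- c("A", "U", "G", "C", "I")

## Theoretical maximum accessible surface area (A^2) per residue type,
## Gly-X-Gly tripeptide scale (Tien et al. 2013, theoretical values).
## Used to normalise Shrake-Rupley areas into relative accessibility.
MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  E = 223.0, Q = 225.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

## Van der Waals radii (A) by element; Bondi values, P from Bondi 1964.
## Hydrogens are ignored throughout (crystal structures rarely include them).
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  ZN = 1.39, MG = 1.73, FE = 1.47, MN = 1.39, CU = 1.40,
  "NA" = 2.27, K = 2.75, CA = 2.31
)
DEFAULT_VDW <- 1.70

## Five-factor numerical descriptors of amino-acid physico-chemical
## properties (Atchley et al. 2005), summarising ~500 published indices;
## packaged as the chemical-distance basis. Rows are residues, columns the
## five factors (polarity/accessibility, secondary structure propensity,
## size, codon composition, charge).
AA_FACTORS <- matrix(
  c(-0.591, -1.302, -0.733,  1.570, -0.146,
    -1.343,  0.465, -0.862, -1.020, -0.255,
     1.050,  0.302, -3.656, -0.259, -3.242,
     1.357, -1.453,  1.477,  0.113, -0.837,
    -1.006, -0.590,  1.891, -0.397,  0.412,
    -0.384,  1.652,  1.330,  1.045,  2.064,
     0.336, -0.417, -1.673, -1.474, -0.078,
    -1.239, -0.547,  2.131,  0.393,  0.816,
     1.831, -0.561,  0.533, -0.277,  1.648,
    -1.019, -0.987, -1.505,  1.266, -0.912,
    -0.663, -1.524,  2.219, -1.005,  1.212,
     0.945,  0.828,  1.299, -0.169,  0.933,
     0.189,  2.081, -1.628,  0.421, -1.392,
     0.931, -0.179, -3.005, -0.503, -1.853,
     1.538, -0.055,  1.502,  0.440,  2.897,
    -0.228,  1.399, -4.760,  0.670, -2.647,
    -0.032,  0.326,  2.213,  0.908,  1.313,
    -1.337, -0.279, -0.544,  1.242, -1.262,
    -0.595,  0.009,  0.672, -2.128, -0.184,
     0.260,  0.830,  3.097, -0.838,  1.512),
  nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  paste0("factor", 1:5))
)

## Common crystallographic buffer / cryoprotectant het codes removed from
## the ligand set. Halide and metal ions are deliberately retained: they
## often play a functional role and mutations at their binding sites can
## be severe.
DEFAULT_BUFFER_LIST <- c(
  "HOH", "DOD", "GOL", "EDO", "PEG", "PG4", "SO4", "PO4", "ACT",
  "DMS", "MPD", "TRS", "FMT", "NO3", "EPE", "MES", "BME", "IMD", "ACE"
)

## Het codes treated as metal ions (kept as ligands).
METAL_IONS <- c("ZN", "MG", "MN", "FE", "FE2", "CU", "CO", "NI", "CA",
                "NA", "K", "CD", "HG", "CL", "BR", "IOD", "F")

STRUCT_CLASSES <- c("Surface", "Core", "DNA contact", "Ligand contact",
                    "Protein contact")

## BLOSUM62 fetched once from Biostrings' packaged data.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
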