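## Per-residue structural context: shortest distances to interaction
## partners and relative solvent accessibility.

residue_atom_idx <- function(entry, chain, resno) {
  which(entry$atoms$chain == chain & entry$atoms$resno == resno &
          entry$atoms$category %in% c("protein", "dna", "rna"))
}

#' Shortest distances from one residue to each partner category
#'
#' Minimum Euclidean distances over all non-hydrogen atom pairs between
#' the residue and: any low molecular-weight ligand (SLD), protein atoms
#' of other chains, DNA chains and RNA chains. SCD, the distance to the
#' nearest other macromolecule of any kind, is their minimum. Absent
#' partner categories give `Inf`.
#'
#' @param entry a [parse_structure()] result.
#' @param chain,resno residue identifier.
#' @param exclude_ligands optional character vector of het codes ignored
#'   when computing the ligand distance (drug-exclusion re-analysis).
#' @param exclude_drug_like if TRUE, ligands flagged drug-like at parse
#'   time are ignored as well.
#' @return list with elements `SLD`, `D_protein`, `D_dna`, `D_rna`, `SCD`.
#' @export
residue_distances <- function(entry, chain, resno,
                              exclude_ligands = character(),
                              exclude_drug_like = FALSE) {
  idx <- residue_atom_idx(entry, chain, resno)
  if (!length(idx)) stop("residue ", chain, resno, " not in ",
                         entry$structure_id)
  at <- entry$atoms
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  other <- at[-idx, ]

  lig <- other$category == "ligand" &
    !(toupper(other$res) %in% toupper(exclude_ligands)) &
    !(exclude_drug_like & other$drug_like)
  sld <- min_cross_dist(xyz, as.matrix(other[lig, c("x", "y", "z")]))
  dp <- min_cross_dist(xyz, as.matrix(
    other[other$category == "protein" & other$chain != chain,
          c("x", "y", "z")]))
  dd <- min_cross_dist(xyz, as.matrix(
    other[other$category == "dna" & other$chain != chain, c("x", "y", "z")]))
  dr <- min_cross_dist(xyz, as.matrix(
    other[other$category == "rna" & other$chain != chain, c("x", "y", "z")]))
  list(SLD = sld, D_protein = dp, D_dna = dd, D_rna = dr,
       SCD = min(dp, dd, dr))
}

#' Relative solvent accessibility of a residue
#'
#' Shrake-Rupley accessible surface of the residue's atoms (probe
#' 1.4 A, 960 sphere points), with, by default, every atom of the entry
#' (ligands and partner chains included) acting as occluder, divided by
#' the residue type's theoretical maximum accessible area and expressed
#' in percent. Values can exceed 100 for extended conformations.
#'
#' @inheritParams residue_distances
#' @param occluders `"all"` (whole complex, default) or `"chain"` (the
#'   residue's own chain only).
#' @param n_points sphere points per atom.
#' @return list with `RSA` (percent), `area` (A^2) and `low_confidence`
#'   (TRUE when the residue has fewer than 4 atoms).
#' @export
relative_sasa <- function(entry, chain, resno, occluders = c("all", "chain"),
                          n_points = 960) {
  occluders <- match.arg(occluders)
  idx <- residue_atom_idx(entry, chain, resno)
  if (!length(idx)) stop("residue ", chain, resno, " not in ",
                         entry$structure_id)
  at <- entry$atoms
  env <- if (occluders == "all") at else at[at$chain == chain, ]
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  radii <- vdw_radius(at$element[idx])
  areas <- shrake_rupley(xyz, radii,
                         occ_coords = as.matrix(env[, c("x", "y", "z")]),
                         occ_radii = vdw_radius(env$element),
                         probe = 1.4, n_points = n_points)
  res1 <- AA3_TO_1[at$res[idx[1]]]
  max_asa <- if (!is.na(res1)) MAX_ASA[[res1]] else mean(MAX_ASA)
  list(RSA = 100 * sum(areas) / max_asa, area = sum(areas),
       low_confidence = length(idx) < 4L)
}

#' Full structural context of one residue in one template
#'
#' Bundles [residue_distances()] and [relative_sasa()].
#' @inheritParams residue_distances
#' @param rsa_occluders passed to [relative_sasa()] as `occluders`.
#' @return list with the distance elements plus `RSA`.
#' @export
residue_context <- function(entry, chain, resno,
                            exclude_ligands = character(),
                            exclude_drug_like = FALSE,
                            rsa_occluders = "all") {
  d <- residue_distances(entry, chain, resno, exclude_ligands,
                         exclude_drug_like)
  s <- relative_sasa(entry, chain, resno, occluders = rsa_occluders)
  c(d, list(RSA = s$RSA, rsa_low_confidence = s$low_confidence))
}
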