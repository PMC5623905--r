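## Low-level geometry: minimum inter-atomic distances and
## Shrake-Rupley accessible surface areas.

#' Minimum Euclidean distance between two atom coordinate sets
#'
#' @param a,b numeric matrices with three columns (x, y, z).
#' @return smallest pairwise distance, or `Inf` if either set is empty.
#' @keywords internal
min_cross_dist <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  ## |a-b|^2 = |a|^2 + |b|^2 - 2 a.b, vectorised over the cross product
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Quasi-uniform points on the unit sphere (golden-section spiral)
#'
#' @param n number of points.
#' @return an `n` x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area
#'
#' Computes the solvent-accessible surface area of each query atom by
#' rolling a spherical probe over its van der Waals surface: test points
#' are distributed quasi-uniformly on the probe-expanded sphere of every
#' query atom and counted as accessible when no occluding atom's expanded
#' sphere covers them.
#'
#' @param coords numeric matrix (n x 3) of query atom centres.
#' @param radii van der Waals radii of the query atoms (length n).
#' @param occ_coords,occ_radii occluding environment (may include the
#'   query atoms themselves; self-occlusion is excluded by coordinate
#'   identity). Defaults to the query set.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points test points per atom (>= 960 recommended).
#' @return numeric vector of per-atom accessible areas in Angstrom^2.
#' @export
shrake_rupley <- function(coords, radii, occ_coords = coords,
                          occ_radii = radii, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  occ_coords <- as.matrix(occ_coords)
  stopifnot(ncol(coords) == 3, length(radii) == nrow(coords),
            ncol(occ_coords) == 3, length(occ_radii) == nrow(occ_coords))
  pts <- sphere_points(n_points)
  areas <- numeric(nrow(coords))
  occ_r2 <- (occ_radii + probe)^2
  max_occ <- if (length(occ_radii)) max(occ_radii) else 0
  for (i in seq_len(nrow(coords))) {
    r_i <- radii[i] + probe
    centre <- coords[i, ]
    ## candidate occluders: expanded spheres that can reach atom i's shell
    dv <- sweep(occ_coords, 2, centre)
    d2 <- rowSums(dv^2)
    reach <- (r_i + max_occ + probe)^2
    cand <- which(d2 < reach & d2 > 1e-12)  # drop self / duplicates
    test <- sweep(pts * r_i, 2, centre, "+")
    if (length(cand)) {
      free <- rep(TRUE, n_points)
      for (j in cand) {
        if (!any(free)) break
        dj <- sweep(test[free, , drop = FALSE], 2, occ_coords[j, ])
        free[free] <- rowSums(dj^2) >= occ_r2[j]
      }
      n_free <- sum(free)
    } else {
      n_free <- n_points
    }
    areas[i] <- 4 * pi * r_i^2 * n_free / n_points
  }
  areas
}

#' Van der Waals radius lookup from element symbols
#' @keywords internal
vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- DEFAULT_VDW
  unname(r)
}

#' Infer element symbol from a PDB atom name
#' @keywords internal
element_from_name <- function(atom_name, res_name = NULL) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", atom_name)))
  el <- substr(nm, 1L, 1L)
  ## two-letter elements for common ions written as whole-residue atoms
  two <- nm %in% names(VDW_RADII) & nchar(nm) == 2L
  el[two] <- nm[two]
  if (!is.null(res_name)) {
    ion <- toupper(res_name) %in% METAL_IONS & nm == toupper(res_name)
    el[ion] <- toupper(res_name)[ion]
  }
  el
}
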