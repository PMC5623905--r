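## Chemical dissimilarity of amino-acid substitutions: Euclidean
## distance in the packaged five-factor descriptor space, and BLOSUM62
## substitution similarity.

check_residues <- function(x) {
  bad <- setdiff(x, rownames(AA_FACTORS))
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
}

#' Chemical distance of a substitution
#'
#' Mean Euclidean distance between the five-factor descriptor vector of
#' the wild-type residue and those of the observed alternative residues
#' (averaged when a position has several observed substitutions).
#'
#' @param ref_aa one-letter wild-type residue.
#' @param alt_aa character vector of alternative residues.
#' @param factors descriptor matrix (rows: residues, 5 columns); the
#'   packaged table can be replaced.
#' @return mean distance (0 when alt equals ref).
#' @export
chemical_distance <- function(ref_aa, alt_aa, factors = AA_FACTORS) {
  stopifnot(length(ref_aa) == 1L)
  check_residues(c(ref_aa, alt_aa))
  v <- factors[ref_aa, ]
  mean(vapply(alt_aa, function(a) sqrt(sum((v - factors[a, ])^2)), 0))
}

#' BLOSUM62 similarity of a substitution
#'
#' Mean BLOSUM62 matrix entry between the wild-type residue and the
#' observed alternatives.
#'
#' @inheritParams chemical_distance
#' @param matrix substitution matrix (defaults to BLOSUM62).
#' @return mean substitution score.
#' @export
blosum_similarity <- function(ref_aa, alt_aa, matrix = NULL) {
  stopifnot(length(ref_aa) == 1L)
  check_residues(c(ref_aa, alt_aa))
  if (is.null(matrix)) matrix <- blosum62_matrix()
  mean(vapply(alt_aa, function(a) matrix[ref_aa, a], 0))
}

#' Per-position chemical profile of a variant set
#'
#' Groups variants by (gene, position) and computes, per position, the
#' average chemical distance and average BLOSUM62 score between the
#' wild-type residue and all observed substitutions.
#'
#' @param variants variant data.frame.
#' @return data.frame with gene_id, position, ref_aa, n_alt,
#'   chem_distance, blosum.
#' @export
substitution_profile <- function(variants) {
  sp <- split(variants, paste(variants$gene_id, variants$position))
  out <- lapply(sp, function(d) {
    alts <- unique(d$alt_aa)
    data.frame(gene_id = d$gene_id[1], position = d$position[1],
               ref_aa = d$ref_aa[1], n_alt = length(alts),
               chem_distance = chemical_distance(d$ref_aa[1], alts),
               blosum = blosum_similarity(d$ref_aa[1], alts),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
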