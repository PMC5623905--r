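## Homology-template search over a library of structure chains, variant
## position mapping through pairwise global alignments, and template
## quality scoring.

#' Build a searchable structure-chain library
#'
#' Extracts every protein chain sequence from a set of parsed structures.
#'
#' @param entries list of [parse_structure()] results (or file paths,
#'   which are parsed on the fly).
#' @return a `structure_library`: list with `chains` (data.frame:
#'   structure_id, chain, seq, resolution, r_value) and `entries` (the
#'   parsed structures, named by structure_id).
#' @export
structure_library <- function(entries) {
  entries <- lapply(entries, function(e)
    if (inherits(e, "structure_entry")) e else parse_structure(e))
  names(entries) <- vapply(entries, `[[`, "", "structure_id")
  chains <- do.call(rbind, lapply(entries, function(e) {
    pc <- e$chains$chain[e$chains$type == "protein"]
    if (!length(pc)) return(NULL)
    data.frame(structure_id = e$structure_id, chain = pc,
               seq = vapply(pc, function(ch) chain_sequence(e, ch)$seq, ""),
               resolution = e$resolution, r_value = e$r_value,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(chains = chains, entries = entries),
            class = "structure_library")
}

## global pairwise alignment, EMBOSS-style affine gap convention
align_global <- function(target, template, gap_open = 10, gap_extend = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(target), Biostrings::AAString(template),
    type = "global", substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  list(target = as.character(Biostrings::alignedPattern(aln)),
       template = as.character(Biostrings::alignedSubject(aln)))
}

## identity / coverage statistics of one gapped alignment pair
alignment_stats <- function(aln_target, aln_template, target_len,
                            template_len) {
  a <- strsplit(aln_target, "")[[1]]
  b <- strsplit(aln_template, "")[[1]]
  cols <- a != "-" | b != "-"            # non-double-gap columns
  aligned <- a != "-" & b != "-"
  n_id <- sum(a == b & aligned)
  list(seq_id = n_id / sum(cols),
       cov = sum(aligned) / target_len,
       aligned_length = sum(aligned),
       shorter = min(target_len, template_len))
}

#' Search a structure library for homology templates of a gene
#'
#' Globally aligns the gene's protein sequence against every protein
#' chain in the library and keeps chains passing the template filters:
#' sequence identity above `identity_threshold` and alignment coverage
#' above half the shorter sequence's length (or an aligned region longer
#' than `min_aligned_length` residues). When an external search backend
#' supplies e-values, hits at or above `evalue_threshold` are excluded.
#'
#' @param gene list or one-row data.frame with `gene_id` and `protein`
#'   (one-letter sequence).
#' @param library a [structure_library()].
#' @param identity_threshold identity fraction, exclusive lower bound
#'   (default 0.35; 0.90 for the high-identity re-analysis).
#' @param coverage_factor fraction of the shorter sequence that must be
#'   aligned (default 0.5, exclusive).
#' @param min_aligned_length alternative aligned-length bound (default 50,
#'   exclusive).
#' @param evalues optional named numeric vector of e-values keyed by
#'   `structure_id.chain`, from a pluggable external search.
#' @param evalue_threshold e-value cutoff (hits must be strictly below).
#' @param gap_open,gap_extend affine gap penalties.
#' @return data.frame of template hits sorted by decreasing identity
#'   (ties by structure then chain id) with columns gene_id,
#'   structure_id, chain, seq_id, cov, aligned_length, evalue,
#'   resolution, r_value, aln_target, aln_template.
#' @export
search_templates <- function(gene, library, identity_threshold = 0.35,
                             coverage_factor = 0.5, min_aligned_length = 50,
                             evalues = NULL, evalue_threshold = 1e-5,
                             gap_open = 10, gap_extend = 0.5) {
  stopifnot(inherits(library, "structure_library"))
  target <- gene$protein
  rows <- lapply(seq_len(nrow(library$chains)), function(i) {
    ch <- library$chains[i, ]
    aln <- align_global(target, ch$seq, gap_open, gap_extend)
    st <- alignment_stats(aln$target, aln$template, nchar(target),
                          nchar(ch$seq))
    ev <- if (!is.null(evalues))
      unname(evalues[paste0(ch$structure_id, ".", ch$chain)]) else NA_real_
    pass <- st$seq_id > identity_threshold &&
      (st$aligned_length > coverage_factor * st$shorter ||
         st$aligned_length > min_aligned_length) &&
      (is.null(evalues) || is.na(ev) || ev < evalue_threshold)
    if (!pass) return(NULL)
    data.frame(gene_id = gene$gene_id, structure_id = ch$structure_id,
               chain = ch$chain, seq_id = st$seq_id, cov = st$cov,
               aligned_length = st$aligned_length, evalue = ev,
               resolution = ch$resolution, r_value = ch$r_value,
               aln_target = aln$target, aln_template = aln$template,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits)) return(empty_hits())
  hits[order(-hits$seq_id, hits$structure_id, hits$chain), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(gene_id = character(), structure_id = character(),
             chain = character(), seq_id = numeric(), cov = numeric(),
             aligned_length = integer(), evalue = numeric(),
             resolution = numeric(), r_value = numeric(),
             aln_target = character(), aln_template = character(),
             stringsAsFactors = FALSE)
}

#' Map target sequence positions through a template alignment
#'
#' Walks the gapped alignment columns: each 1-based target position is
#' translated to the index of the aligned template residue; positions
#' facing a gap in the template row come back unmapped (the spec of the
#' method discards such templates for those variants).
#'
#' @param hit one row of a [search_templates()] result.
#' @param positions integer vector of 1-based target positions.
#' @return data.frame with columns position, template_index (NA when
#'   unmapped), mapped.
#' @export
map_positions <- function(hit, positions) {
  a <- strsplit(hit$aln_target, "")[[1]]
  b <- strsplit(hit$aln_template, "")[[1]]
  tpos <- cumsum(a != "-")
  bpos <- cumsum(b != "-")
  out <- data.frame(position = positions, template_index = NA_integer_,
                    mapped = FALSE)
  for (k in seq_along(positions)) {
    col <- match(positions[k], tpos)   # first column carrying this residue
    if (is.na(col) || a[col] == "-") next
    if (b[col] != "-") {
      out$template_index[k] <- bpos[col]
      out$mapped[k] <- TRUE
    }
  }
  out
}

#' Template quality score
#'
#' Combines the four template attributes on a common 0-1 scale: sequence
#' identity, target coverage, a resolution sigmoid
#' `res = 1/(1 + exp(1.5*resolution - 4))` and `r = 1 - R-value`. The
#' combination is a (configurable) weighted mean, monotone increasing in
#' identity and coverage and decreasing in resolution and R-value.
#' Missing resolution or R-value contributes a neutral 0.5 term.
#'
#' @param hit one row of a [search_templates()] result (needs seq_id,
#'   cov, resolution, r_value).
#' @param weights numeric length-4 weights for (seq_id, cov, res, r).
#' @return score in \[0, 1\].
#' @export
template_score <- function(hit, weights = c(1, 1, 1, 1)) {
  stopifnot(length(weights) == 4, all(weights >= 0), sum(weights) > 0)
  res <- ifelse(is.na(hit$resolution), 0.5,
                1 / (1 + exp(1.5 * hit$resolution - 4)))
  r <- ifelse(is.na(hit$r_value), 0.5, 1 - hit$r_value)
  as.numeric(cbind(hit$seq_id, hit$cov, res, r) %*% weights) / sum(weights)
}
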