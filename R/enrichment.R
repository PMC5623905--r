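## Protein-level combined scores and differential pathway / GO-term
## scoring between disease-associated and neutral variant sets.

#' Combined protein-level score
#'
#' For each template, the candidate scores of the gene's variants mapped
#' in that template are averaged; the combined score is the maximum of
#' these per-template means. The mean realizes the normalisation in
#' which a few high-scoring candidate mutations outrank many low-scoring
#' ones. A gene with no mapped variant scores 0.
#'
#' @param contexts per-template context rows of one gene (an
#'   `annotated_variants$contexts` subset) with columns structure_id,
#'   chain, score.
#' @param gene_id id stored on the result.
#' @return list with gene_id, combined (score), n_variants,
#'   best_template.
#' @export
protein_combined_score <- function(contexts, gene_id = NULL) {
  if (is.null(contexts) || nrow(contexts) == 0L)
    return(list(gene_id = gene_id, combined = 0, n_variants = 0L,
                best_template = NA_character_))
  tpl <- paste(contexts$structure_id, contexts$chain, sep = ".")
  means <- tapply(contexts$score, tpl, mean)
  best <- which.max(means)
  list(gene_id = if (is.null(gene_id)) contexts$gene_id[1] else gene_id,
       combined = unname(means[best]),
       n_variants = length(unique(contexts$variant)),
       best_template = names(means)[best])
}

#' Combined scores for every gene of an annotated set
#'
#' @param annotated an [annotate_variants()] result.
#' @param genes optional gene universe; genes without mapped variants get
#'   score 0.
#' @return data.frame with gene_id, combined, n_variants, best_template.
#' @export
protein_scores <- function(annotated, genes = NULL) {
  ctx <- annotated$contexts
  ids <- unique(if (is.null(genes)) annotated$variants$gene_id else
    genes$gene_id)
  rows <- lapply(ids, function(g) {
    sub <- if (is.null(ctx)) NULL else ctx[ctx$gene_id == g, , drop = FALSE]
    as.data.frame(protein_combined_score(sub, g), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-pathway normalized scores
#'
#' Sums the combined protein scores of each pathway's members present in
#' the score table and divides by the number of such members. Pathways
#' with no represented member are omitted (and listed in the `omitted`
#' attribute). Duplicate membership rows are ignored.
#'
#' @param scores data.frame from [protein_scores()] (gene_id, combined).
#' @param annotation annotation table (gene_id, term_id, namespace
#'   optional).
#' @return named numeric vector of pathway scores.
#' @export
pathway_scores <- function(scores, annotation) {
  stopifnot(nrow(annotation) > 0)
  ann <- unique(annotation[c("gene_id", "term_id")])
  ann <- ann[ann$gene_id %in% scores$gene_id, , drop = FALSE]
  omitted <- setdiff(unique(annotation$term_id), unique(ann$term_id))
  s <- scores$combined[match(ann$gene_id, scores$gene_id)]
  res <- tapply(s, ann$term_id, mean)   # sum / n members present
  out <- as.numeric(res)
  names(out) <- names(res)
  attr(out, "omitted") <- omitted
  out
}

#' Differential pathway ranking
#'
#' For every pathway present on both sides, the differential score is
#' the disease-side normalized score minus the neutral-side one;
#' pathways are ranked by decreasing differential (ties lexicographic)
#' and the top k returned.
#'
#' @param disease_scores,neutral_scores named vectors from
#'   [pathway_scores()].
#' @param k number of top pathways (the full ranking is returned when k
#'   exceeds the shared universe).
#' @return data.frame with term_id, disease, neutral, differential,
#'   sorted by decreasing differential.
#' @export
differential_ranking <- function(disease_scores, neutral_scores, k = 20) {
  shared <- intersect(names(disease_scores), names(neutral_scores))
  stopifnot(length(shared) > 0)
  d <- data.frame(term_id = shared,
                  disease = as.numeric(disease_scores[shared]),
                  neutral = as.numeric(neutral_scores[shared]),
                  stringsAsFactors = FALSE)
  d$differential <- d$disease - d$neutral
  d <- d[order(-d$differential, d$term_id), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, k)
}

#' Randomized gene-set control for enrichment
#'
#' Draws random genes and plants in each a number of variants sampled
#' i.i.d. from the empirical per-gene count distribution of a reference
#' set, using the missense randomization of [randomize_dataset()].
#'
#' @param genes gene universe table (gene_id, protein, cds).
#' @param count_distribution integer vector of per-gene variant counts
#'   (the empirical distribution sampled from).
#' @param n_genes number of random genes (sampling of genes is without
#'   replacement when the universe suffices, with replacement otherwise,
#'   flagged by a message).
#' @param seed integer seed.
#' @return variant data.frame labelled `randomized:control`.
#' @export
random_gene_control <- function(genes, count_distribution, n_genes = 10000,
                                seed = 1L) {
  rng <- make_rng(seed, "control")
  replace <- n_genes > nrow(genes)
  if (replace) message("gene universe smaller than n_genes; sampling with replacement")
  gidx <- sample_int_rng(rng, nrow(genes), n_genes, replace = replace)
  counts <- sample_rng(rng, as.integer(count_distribution), n_genes,
                       replace = TRUE)
  keep <- counts > 0
  if (!any(keep)) return(data.frame())
  pseudo <- data.frame(
    gene_id = rep(genes$gene_id[gidx][keep], counts[keep]),
    position = 1L, ref_aa = "A", alt_aa = "V",
    dataset_label = "control", stringsAsFactors = FALSE)
  randomize_dataset(pseudo, genes, seed = seed + 1L,
                    label_suffix = "control")
}
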