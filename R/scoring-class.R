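## Logistic interaction weights, per-variant candidate scores, and the
## five-class exclusive spatial assignment aggregated over all templates.

#' Logistic contact weights and interaction score
#'
#' `lig_cont = 1/(1 + exp(SLD - 10))`, `chain_cont = 1/(1 + exp(SCD - 10))`;
#' an absent distance (NA or Inf) gives weight 0. The interaction score
#' IS is the larger of the two weights.
#'
#' @param SLD shortest residue-ligand distance (A).
#' @param SCD shortest distance to any other macromolecular chain (A).
#' @return list with lig_cont, chain_cont, IS.
#' @export
interaction_weights <- function(SLD, SCD) {
  w <- function(d) if (is.null(d) || is.na(d) || !is.finite(d)) 0 else
    1 / (1 + exp(d - 10))
  lig <- w(SLD)
  ch <- w(SCD)
  list(lig_cont = lig, chain_cont = ch, IS = max(lig, ch))
}

#' Candidate score of a mapped variant in one template
#'
#' Combines the template quality score with the interaction score:
#' `candidate = template_score * IS`. All components are retained for
#' audit.
#'
#' @param hit one row of a [search_templates()] result.
#' @param ctx a [residue_context()] (needs SLD and SCD).
#' @param ts_weights weights passed to [template_score()].
#' @param combine function(template_score, IS) -> score; the default is
#'   the product.
#' @return list with seq_id, cov, res, r, lig_cont, chain_cont, IS,
#'   template_score and score.
#' @export
candidate_score <- function(hit, ctx, ts_weights = c(1, 1, 1, 1),
                            combine = `*`) {
  ts <- template_score(hit, ts_weights)
  iw <- interaction_weights(ctx$SLD, ctx$SCD)
  res <- if (is.na(hit$resolution)) 0.5 else
    1 / (1 + exp(1.5 * hit$resolution - 4))
  r <- if (is.na(hit$r_value)) 0.5 else 1 - hit$r_value
  list(seq_id = hit$seq_id, cov = hit$cov, res = res, r = r,
       lig_cont = iw$lig_cont, chain_cont = iw$chain_cont, IS = iw$IS,
       template_score = ts, score = combine(ts, iw$IS))
}

#' Exclusive five-class spatial assignment
#'
#' A variant is assigned to the contact class of its closest interaction
#' partner when that partner lies within the contact threshold; exact
#' distance ties fall to the configured priority (rarest class first).
#' Without any contact, relative accessibility below the core cutoff
#' gives Core, otherwise Surface. Both thresholds are strict.
#'
#' @param SLD,D_protein,D_dna minimum distances over templates (A; NA or
#'   Inf when the partner category is absent).
#' @param RSA relative accessibility (percent).
#' @param contact_threshold contact distance in A (default 5).
#' @param core_rsa core accessibility cutoff in percent (default 16).
#' @param tie_priority order used on exact distance ties.
#' @return one of "Ligand contact", "DNA contact", "Protein contact",
#'   "Core", "Surface".
#' @export
classify_exclusive <- function(SLD, D_protein, D_dna, RSA,
                               contact_threshold = 5, core_rsa = 16,
                               tie_priority = c("DNA", "Ligand", "Protein")) {
  d <- c(DNA = as_dist(D_dna), Ligand = as_dist(SLD),
         Protein = as_dist(D_protein))[tie_priority]
  in_contact <- d < contact_threshold
  if (any(in_contact)) {
    winner <- names(d)[which.min(d)]   # first index wins ties => priority
    return(paste(winner, "contact"))
  }
  if (!is.na(RSA) && RSA < core_rsa) "Core" else "Surface"
}

as_dist <- function(x) if (is.null(x) || is.na(x)) Inf else x

#' Aggregate per-template contexts into one annotated variant
#'
#' Category-wise minimum distances are taken across templates; the
#' accessibility used for the Core/Surface decision comes from the
#' template providing the overall minimum distance, or from the
#' best-scoring template when no contact exists. The contact multiset
#' lists every category within the contact threshold in any template
#' (the non-exclusive view).
#'
#' @param contexts data.frame with one row per template holding SLD,
#'   D_protein, D_dna, RSA, template_score, score.
#' @param contact_threshold,core_rsa,tie_priority see
#'   [classify_exclusive()].
#' @return list with structural_class, min_SLD, min_D_protein, min_D_dna,
#'   RSA, best_score, contacts (character vector), n_templates.
#' @export
aggregate_over_templates <- function(contexts, contact_threshold = 5,
                                     core_rsa = 16,
                                     tie_priority = c("DNA", "Ligand", "Protein")) {
  if (is.null(contexts) || nrow(contexts) == 0L)
    return(list(structural_class = "Unmapped", min_SLD = Inf,
                min_D_protein = Inf, min_D_dna = Inf, RSA = NA_real_,
                best_score = 0, contacts = character(), n_templates = 0L))
  min_or_inf <- function(x) if (all(!is.finite(x))) Inf else min(x, na.rm = TRUE)
  m_sld <- min_or_inf(contexts$SLD)
  m_dp <- min_or_inf(contexts$D_protein)
  m_dd <- min_or_inf(contexts$D_dna)
  overall <- min(m_sld, m_dp, m_dd)
  rsa_row <- if (is.finite(overall) && overall < contact_threshold) {
    cand <- pmin(replace_na_inf(contexts$SLD), replace_na_inf(contexts$D_protein),
                 replace_na_inf(contexts$D_dna))
    which.min(cand)
  } else {
    which.max(contexts$template_score)
  }
  rsa <- contexts$RSA[rsa_row]
  cls <- classify_exclusive(m_sld, m_dp, m_dd, rsa, contact_threshold,
                            core_rsa, tie_priority)
  contacts <- character()
  if (any(contexts$SLD < contact_threshold, na.rm = TRUE))
    contacts <- c(contacts, "Ligand")
  if (any(contexts$D_dna < contact_threshold, na.rm = TRUE))
    contacts <- c(contacts, "DNA")
  if (any(contexts$D_protein < contact_threshold, na.rm = TRUE))
    contacts <- c(contacts, "Protein")
  list(structural_class = cls, min_SLD = m_sld, min_D_protein = m_dp,
       min_D_dna = m_dd, RSA = rsa, best_score = max(contexts$score),
       contacts = contacts, n_templates = nrow(contexts))
}

replace_na_inf <- function(x) ifelse(is.na(x), Inf, x)

#' Annotate a variant set against a structure library
#'
#' The full per-variant pipeline: template search for each gene, mapping
#' of variant positions through the alignments (gap-mapped templates are
#' dropped for that variant), per-template distance and accessibility
#' context, candidate scoring, and aggregation over all templates.
#'
#' @param variants variant data.frame (gene_id, position, ref_aa, alt_aa,
#'   dataset_label).
#' @param genes gene table (gene_id, protein, cds).
#' @param library a [structure_library()].
#' @param identity_threshold,coverage_factor,min_aligned_length template
#'   filters, see [search_templates()].
#' @param contact_threshold,core_rsa,tie_priority classification
#'   parameters, see [classify_exclusive()].
#' @param ts_weights template-score weights.
#' @param rsa_occluders accessibility environment, see [relative_sasa()].
#' @return an `annotated_variants` object: list with `variants` (the
#'   input plus structural_class, min distances, RSA, best_score,
#'   contacts, n_templates), `contexts` (per variant x template rows) and
#'   the classification parameters.
#' @export
annotate_variants <- function(variants, genes, library,
                              identity_threshold = 0.35,
                              coverage_factor = 0.5,
                              min_aligned_length = 50,
                              contact_threshold = 5, core_rsa = 16,
                              tie_priority = c("DNA", "Ligand", "Protein"),
                              ts_weights = c(1, 1, 1, 1),
                              rsa_occluders = "all") {
  stopifnot(inherits(library, "structure_library"))
  hits_by_gene <- list()
  ctx_rows <- list()
  ann_rows <- vector("list", nrow(variants))

  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi, ]
    gid <- v$gene_id
    if (is.null(hits_by_gene[[gid]])) {
      g <- genes[genes$gene_id == gid, ]
      hits_by_gene[[gid]] <- if (nrow(g)) search_templates(
        list(gene_id = gid, protein = g$protein), library,
        identity_threshold = identity_threshold,
        coverage_factor = coverage_factor,
        min_aligned_length = min_aligned_length) else empty_hits()
    }
    hits <- hits_by_gene[[gid]]
    ctxs <- list()
    if (nrow(hits)) for (hi in seq_len(nrow(hits))) {
      hit <- hits[hi, ]
      mp <- map_positions(hit, v$position)
      if (!mp$mapped[1]) next
      entry <- library$entries[[hit$structure_id]]
      cs <- chain_sequence(entry, hit$chain)
      resno <- cs$resno[mp$template_index[1]]
      ctx <- residue_context(entry, hit$chain, resno,
                             rsa_occluders = rsa_occluders)
      sc <- candidate_score(hit, ctx, ts_weights)
      ctxs[[length(ctxs) + 1L]] <- data.frame(
        variant = vi, gene_id = gid, position = v$position,
        structure_id = hit$structure_id, chain = hit$chain, resno = resno,
        SLD = ctx$SLD, D_protein = ctx$D_protein, D_dna = ctx$D_dna,
        D_rna = ctx$D_rna, SCD = ctx$SCD, RSA = ctx$RSA,
        seq_id = hit$seq_id, template_score = sc$template_score,
        lig_cont = sc$lig_cont, chain_cont = sc$chain_cont, IS = sc$IS,
        score = sc$score, stringsAsFactors = FALSE)
    }
    ctx_df <- if (length(ctxs)) do.call(rbind, ctxs) else NULL
    agg <- aggregate_over_templates(ctx_df, contact_threshold, core_rsa,
                                    tie_priority)
    ann_rows[[vi]] <- data.frame(
      v, structural_class = agg$structural_class,
      min_SLD = agg$min_SLD, min_D_protein = agg$min_D_protein,
      min_D_dna = agg$min_D_dna, RSA = agg$RSA,
      best_score = agg$best_score,
      contacts = paste(agg$contacts, collapse = "+"),
      n_templates = agg$n_templates,
      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(ctx_df)) ctx_rows[[length(ctx_rows) + 1L]] <- ctx_df
  }

  structure(list(
    variants = do.call(rbind, ann_rows),
    contexts = if (length(ctx_rows)) do.call(rbind, ctx_rows) else NULL,
    params = list(contact_threshold = contact_threshold,
                  core_rsa = core_rsa, tie_priority = tie_priority)
  ), class = "annotated_variants")
}

#' @export
print.annotated_variants <- function(x, ...) {
  cat("<annotated_variants>", nrow(x$variants), "variants\n")
  print(table(x$variants$structural_class))
  invisible(x)
}

#' Re-classify after excluding a set of ligands
#'
#' Recomputes the ligand distances of every per-template context with the
#' given het codes removed from the ligand universe (e.g. DrugBank-listed
#' drugs), then re-runs the aggregation and classification. A change log
#' lists every variant whose exclusive class flipped.
#'
#' @param annotated an [annotate_variants()] result.
#' @param library the same [structure_library()] it was computed from.
#' @param excluded_het character vector of het codes to ignore.
#' @return list with `annotated` (updated object) and `changes`
#'   (data.frame: gene_id, position, from, to).
#' @export
reclassify_excluding_ligands <- function(annotated, library, excluded_het) {
  stopifnot(inherits(annotated, "annotated_variants"))
  p <- annotated$params
  ctx <- annotated$contexts
  if (length(excluded_het) && !is.null(ctx)) {
    for (i in seq_len(nrow(ctx))) {
      entry <- library$entries[[ctx$structure_id[i]]]
      d <- residue_distances(entry, ctx$chain[i], ctx$resno[i],
                             exclude_ligands = excluded_het)
      ctx$SLD[i] <- d$SLD
      iw <- interaction_weights(d$SLD, d$SCD)
      ctx$lig_cont[i] <- iw$lig_cont
      ctx$IS[i] <- iw$IS
      ctx$score[i] <- ctx$template_score[i] * iw$IS
    }
  }
  vars <- annotated$variants
  changes <- list()
  for (vi in seq_len(nrow(vars))) {
    sub <- if (is.null(ctx)) NULL else ctx[ctx$variant == vi, , drop = FALSE]
    agg <- aggregate_over_templates(sub, p$contact_threshold, p$core_rsa,
                                    p$tie_priority)
    if (vars$structural_class[vi] != agg$structural_class)
      changes[[length(changes) + 1L]] <- data.frame(
        gene_id = vars$gene_id[vi], position = vars$position[vi],
        from = vars$structural_class[vi], to = agg$structural_class,
        stringsAsFactors = FALSE)
    vars$structural_class[vi] <- agg$structural_class
    vars$min_SLD[vi] <- agg$min_SLD
    vars$RSA[vi] <- agg$RSA
    vars$best_score[vi] <- agg$best_score
    vars$contacts[vi] <- paste(agg$contacts, collapse = "+")
  }
  annotated$variants <- vars
  annotated$contexts <- ctx
  list(annotated = annotated,
       changes = if (length(changes)) do.call(rbind, changes) else
         data.frame(gene_id = character(), position = integer(),
                    from = character(), to = character()))
}
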