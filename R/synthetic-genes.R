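## Synthetic genes (protein + consistent coding sequence), planted
## variant sets over known structural classes, and annotation tables
## with planted pathway enrichments.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

codon_at <- function(cds, position) substr(cds, 3 * position - 2, 3 * position)

#' Generate a synthetic gene set
#'
#' Draws random protein sequences and back-translates each through
#' uniformly chosen synonymous codons, appending a stop codon, so that
#' the coding sequence translates exactly to the protein under the
#' standard genetic code.
#'
#' @param n_genes number of genes.
#' @param length_range inclusive protein-length interval.
#' @param seed integer seed; fixed seed gives identical sequences.
#' @param prefix gene id prefix.
#' @return data.frame with gene_id, protein, cds.
#' @export
make_gene_set <- function(n_genes, length_range = c(60, 120), seed = 1L,
                          prefix = "G") {
  stopifnot(n_genes >= 1)
  rng <- make_rng(seed, "genes")
  by_aa <- split(names(GENETIC_CODE_TABLE), GENETIC_CODE_TABLE)
  stops <- by_aa[["*"]]
  recs <- lapply(seq_len(n_genes), function(i) {
    L <- if (length_range[1] == length_range[2]) length_range[1] else
      sample_int_rng(rng, length_range[2] - length_range[1] + 1L, 1L) +
        length_range[1] - 1L
    prot <- sample_rng(rng, names(MAX_ASA), L, replace = TRUE)
    codons <- vapply(prot, function(a) {
      cands <- by_aa[[a]]
      cands[sample_int_rng(rng, length(cands), 1L)]
    }, "")
    stop_codon <- stops[sample_int_rng(rng, length(stops), 1L)]
    data.frame(gene_id = sprintf("%s%03d", prefix, i),
               protein = paste(prot, collapse = ""),
               cds = paste(c(codons, stop_codon), collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

## all single-nucleotide neighbours of a codon with the resulting residue
codon_neighbours <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (p in 1:3) for (b in setdiff(bases, substr(codon, p, p))) {
    nc <- codon
    substr(nc, p, p) <- b
    out[[length(out) + 1L]] <- data.frame(
      codon = nc, pos_in_codon = p, base = b,
      aa = unname(GENETIC_CODE_TABLE[nc]), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plant variants with known structural classes
#'
#' Emits variants whose positions carry a requested intended class in a
#' planted-truth table. The reference residue is read from the gene
#' sequence; the alternative residue is drawn among residues reachable by
#' one nucleotide change of the underlying codon (missense only).
#'
#' @param genes [make_gene_set()] table.
#' @param truth planted-truth table from [make_toy_complex()] (columns
#'   chain, resno, class).
#' @param n_per_class named integer vector, e.g.
#'   `c("Ligand contact" = 10, Surface = 5)`.
#' @param chain_gene named character: gene_id for each truth chain id.
#'   Defaults to pairing chains with genes in order.
#' @param dataset_label label stored on the emitted variants.
#' @param seed integer seed.
#' @return data.frame of variants (gene_id, position, ref_aa, alt_aa,
#'   dataset_label, intended_class, intended_distance, chain).
#' @export
plant_variants <- function(genes, truth, n_per_class, chain_gene = NULL,
                           dataset_label = "planted", seed = 1L) {
  rng <- make_rng(seed, "plant")
  chains <- unique(truth$chain)
  if (is.null(chain_gene))
    chain_gene <- stats::setNames(genes$gene_id[seq_along(chains)], chains)
  out <- list()
  for (cl in names(n_per_class)) {
    n <- n_per_class[[cl]]
    pool <- truth[!is.na(truth$class) & truth$class == cl, , drop = FALSE]
    if (nrow(pool) < n)
      stop("class exhausted: ", cl, " has ", nrow(pool),
           " designated residues, ", n, " requested")
    pick <- pool[sample_int_rng(rng, nrow(pool), n), , drop = FALSE]
    for (k in seq_len(n)) {
      gid <- chain_gene[[pick$chain[k]]]
      g <- genes[genes$gene_id == gid, ]
      pos <- pick$resno[k]
      ref <- substr(g$protein, pos, pos)
      nb <- codon_neighbours(codon_at(g$cds, pos))
      nb <- nb[nb$aa != ref & nb$aa != "*", , drop = FALSE]
      if (!nrow(nb))
        stop("no missense neighbour for codon of ", gid, " position ", pos)
      alt <- nb$aa[sample_int_rng(rng, nrow(nb), 1L)]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gid, position = pos, ref_aa = ref, alt_aa = alt,
        dataset_label = dataset_label, intended_class = cl,
        intended_distance = pick$distance[k], chain = pick$chain[k],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Protein-to-pathway annotation table with planted enrichment
#'
#' Builds `n_pathways` gene sets of the requested sizes. The first
#' `length(planted)` pathways are planted: their members are taken from
#' `planted_enriched` first (the proteins expected to carry high combined
#' scores), topped up at random, so that downstream differential scoring
#' should rank them first.
#'
#' @param proteins character vector of gene ids.
#' @param n_pathways number of pathways.
#' @param sizes integer vector (recycled) of pathway sizes.
#' @param planted_enriched subset of `proteins` forming the planted
#'   signal; empty for a null table.
#' @param n_planted number of planted pathways (default 1 when
#'   `planted_enriched` is non-empty).
#' @param namespace annotation namespace tag (e.g. "pathway", "GO_BP").
#' @param seed integer seed.
#' @return data.frame with gene_id, term_id, namespace.
#' @export
make_annotation_db <- function(proteins, n_pathways = 10, sizes = 5,
                               planted_enriched = character(),
                               n_planted = if (length(planted_enriched)) 1L else 0L,
                               namespace = "pathway", seed = 1L) {
  stopifnot(all(planted_enriched %in% proteins), n_planted <= n_pathways)
  rng <- make_rng(seed, "annot")
  sizes <- rep_len(sizes, n_pathways)
  rows <- list()
  for (i in seq_len(n_pathways)) {
    id <- sprintf("PW%03d", i)
    if (i <= n_planted) {
      base <- planted_enriched[seq_len(min(length(planted_enriched), sizes[i]))]
      fill <- setdiff(proteins, base)
      extra <- if (sizes[i] > length(base))
        sample_rng(rng, fill, sizes[i] - length(base)) else character()
      members <- c(base, extra)
    } else {
      members <- sample_rng(rng, setdiff(proteins, planted_enriched),
                            min(sizes[i], length(setdiff(proteins, planted_enriched))))
    }
    rows[[i]] <- data.frame(gene_id = members, term_id = id,
                            namespace = namespace, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
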