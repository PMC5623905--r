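## End-to-end orchestration: a run configuration, a synthetic demo study
## with known ground truth, and the full pipeline from variant tables to
## statistics, enrichment and networks.

#' Pipeline run configuration
#'
#' @param identity_threshold template identity filter (default 0.35;
#'   0.90 for the high-identity re-analysis).
#' @param coverage_factor,min_aligned_length coverage filters.
#' @param contact_threshold contact distance, A (default 5).
#' @param core_rsa core accessibility cutoff, percent (default 16).
#' @param B bootstrap resamples (default 1000).
#' @param n_perm proximity-test permutations (default 10000).
#' @param network_identity identity filter for complex networks
#'   (default 0.90).
#' @param ligand_exclude het codes excluded in the drug-free
#'   re-classification (empty: skip that stage).
#' @param seed master seed; stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(identity_threshold = 0.35, coverage_factor = 0.5,
                       min_aligned_length = 50, contact_threshold = 5,
                       core_rsa = 16, B = 1000, n_perm = 10000,
                       network_identity = 0.90,
                       ligand_exclude = character(), seed = 1L) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 1,
            contact_threshold >= 0, core_rsa >= 0, core_rsa <= 100,
            B >= 1, n_perm >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Template hits for a set of genes
#'
#' @param genes gene table.
#' @param library a [structure_library()].
#' @param ... passed to [search_templates()].
#' @return row-bound hit table.
#' @export
all_hits <- function(genes, library, ...) {
  do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    search_templates(list(gene_id = genes$gene_id[i],
                          protein = genes$protein[i]), library, ...)))
}

#' Run the full annotation and comparison pipeline
#'
#' Removes neutral overlap from the disease set, creates randomized
#' controls, annotates all sets against the structure library, and
#' produces class distributions with bootstrap SDs, rank-sum distance
#' comparisons, a template-count-matched control, differential pathway
#' scores (when an annotation table is given) and the mutated-complex
#' network. A manifest records seeds, parameters and counts at every
#' filtering step.
#'
#' @param genes gene table (gene_id, protein, cds).
#' @param disease,neutral variant data.frames.
#' @param library a [structure_library()].
#' @param annotation optional protein-to-pathway table.
#' @param config a [run_config()].
#' @return list of stage results plus `manifest`.
#' @export
run_all <- function(genes, disease, neutral, library, annotation = NULL,
                    config = run_config()) {
  cfg <- config
  note <- function(...) message(sprintf(...))

  ov <- remove_neutral_overlap(disease, neutral)
  note("overlap removal: %d disease variants kept, %d removed",
       nrow(ov$variants), ov$removed)
  disease <- ov$variants

  rand_disease <- randomize_dataset(disease, genes, seed = cfg$seed + 11L)
  rand_neutral <- randomize_dataset(neutral, genes, seed = cfg$seed + 12L)

  ann <- lapply(list(disease = disease, neutral = neutral,
                     randomized_disease = rand_disease,
                     randomized_neutral = rand_neutral),
                function(v) annotate_variants(
                  v, genes, library,
                  identity_threshold = cfg$identity_threshold,
                  coverage_factor = cfg$coverage_factor,
                  min_aligned_length = cfg$min_aligned_length,
                  contact_threshold = cfg$contact_threshold,
                  core_rsa = cfg$core_rsa))
  for (nm in names(ann))
    note("annotated %s: %d variants, %d mapped", nm,
         nrow(ann[[nm]]$variants),
         sum(ann[[nm]]$variants$structural_class != "Unmapped"))

  dist_cls <- lapply(ann, class_fractions)
  boot <- lapply(ann, bootstrap_sd, B = cfg$B, seed = cfg$seed + 21L)

  finite <- function(x) x[is.finite(x)]
  dtests <- list(
    ligand = ranksum_test(finite(ann$disease$variants$min_SLD),
                          finite(ann$neutral$variants$min_SLD)),
    protein = ranksum_test(finite(ann$disease$variants$min_D_protein),
                           finite(ann$neutral$variants$min_D_protein)))

  matched <- tryCatch({
    ms <- matched_template_sampling(
      ann$neutral$variants$n_templates,
      ann$disease$variants$n_templates,
      seed = cfg$seed + 31L, allow_replacement = TRUE)
    sampled <- ann$neutral$variants[ms$indices, , drop = FALSE]
    list(sampling = ms, fractions = class_fractions(sampled))
  }, error = function(e) list(error = conditionMessage(e)))

  enrich <- NULL
  if (!is.null(annotation)) {
    sc_d <- protein_scores(ann$disease, genes)
    sc_n <- protein_scores(ann$neutral, genes)
    enrich <- differential_ranking(pathway_scores(sc_d, annotation),
                                   pathway_scores(sc_n, annotation))
  }

  hits <- all_hits(genes, library,
                   identity_threshold = cfg$identity_threshold,
                   coverage_factor = cfg$coverage_factor,
                   min_aligned_length = cfg$min_aligned_length)
  mutated <- unique(ann$disease$variants$gene_id[
    ann$disease$variants$structural_class != "Unmapped"])
  network <- build_network(hits, mutated,
                           identity_threshold = cfg$network_identity)

  reclass <- NULL
  if (length(cfg$ligand_exclude))
    reclass <- reclassify_excluding_ligands(ann$disease, library,
                                            cfg$ligand_exclude)

  manifest <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("snv3d")),
      error = function(e) NA_character_),
    seed = cfg$seed, parameters = unclass(cfg),
    counts = list(
      genes = nrow(genes), disease_in = nrow(disease) + ov$removed,
      overlap_removed = ov$removed, disease = nrow(disease),
      neutral = nrow(neutral),
      mapped = vapply(ann, function(a)
        sum(a$variants$structural_class != "Unmapped"), 0L),
      template_hits = nrow(hits)))

  list(annotated = ann, class_distributions = dist_cls,
       bootstrap_sd = boot, distance_tests = dtests, matched = matched,
       enrichment = enrich, hits = hits, network = network,
       reclassified = reclass, manifest = manifest)
}

#' Self-contained synthetic demonstration study
#'
#' Generates genes, multi-chain complexes with planted interaction
#' partners and burial cages, a disease-like variant set enriched in
#' contact and core classes, a surface-heavy neutral set, and an
#' annotation table whose first pathway collects the ligand-contact
#' genes. All ground truth is returned alongside.
#'
#' @param n_genes genes to simulate (>= 4).
#' @param seed integer seed.
#' @param dir directory for the structure files (default: a session
#'   temporary directory).
#' @return list with genes, library, truth, disease, neutral,
#'   annotation, enriched_genes.
#' @export
demo_study <- function(n_genes = 6, seed = 1L, dir = tempfile("snv3d")) {
  stopifnot(n_genes >= 4)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ## each complex pairs one "main" gene (chain A, with planted partners
  ## and cages) with a dedicated partner gene (chain B); every gene maps
  ## to exactly one chain, so planted classes are never masked by a
  ## second homologous template
  main <- make_gene_set(n_genes, length_range = c(40, 48), seed = seed,
                        prefix = "G")
  partners <- make_gene_set(n_genes, length_range = c(30, 36),
                            seed = seed + 1L, prefix = "P")
  genes <- rbind(main, partners)

  truths <- list()
  entries <- list()
  for (i in seq_len(n_genes)) {
    spec <- complex_spec(
      chain_seqs = c(main$protein[i], partners$protein[i]),
      ligand_placements = data.frame(chain = "A", resno = c(5, 26),
                                     target = c(3.0, 3.6)),
      dna_placements = data.frame(chain = "A", resno = 12, target = 3.2),
      partner_chain_placements = data.frame(chain = "A", resno = 19,
                                            target = 4.0),
      core_placements = data.frame(chain = "A", resno = c(33, 38)),
      resolution = 1.8 + 0.1 * i, r_value = 0.18 + 0.005 * i,
      seed = seed + i)
    sid <- sprintf("SYN%d", i)
    tc <- make_toy_complex(spec, file.path(dir, paste0(sid, ".pdb")),
                           structure_id = sid)
    tr <- tc$truth
    tr$structure_id <- sid
    tr$gene_id <- ifelse(tr$chain == "A", main$gene_id[i],
                         partners$gene_id[i])
    truths[[sid]] <- tr
    entries[[sid]] <- parse_structure(tc$path)
  }
  truth <- do.call(rbind, truths)
  library <- structure_library(entries)

  ## disease-like set: planted over the known classes of chain A, plus
  ## one surface variant per partner gene (so complexes have mutations
  ## in both subunits); neutral set: surface positions only
  disease <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    sid <- sprintf("SYN%d", i)
    tr_a <- truths[[sid]][truths[[sid]]$chain == "A", ]
    tr_b <- truths[[sid]][truths[[sid]]$chain == "B", ]
    rbind(
      plant_variants(genes, tr_a,
                     c("Ligand contact" = 2, "DNA contact" = 1,
                       "Protein contact" = 1, "Core" = 2, "Surface" = 2),
                     chain_gene = stats::setNames(main$gene_id[i], "A"),
                     dataset_label = "disease", seed = seed + 100 + i),
      plant_variants(genes, tr_b, c("Surface" = 1),
                     chain_gene = stats::setNames(partners$gene_id[i], "B"),
                     dataset_label = "disease", seed = seed + 150 + i))
  }))
  neutral <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    sid <- sprintf("SYN%d", i)
    tr_a <- truths[[sid]][truths[[sid]]$chain == "A", ]
    plant_variants(genes, tr_a, c("Surface" = 5),
                   chain_gene = stats::setNames(main$gene_id[i], "A"),
                   dataset_label = "benign", seed = seed + 200 + i)
  }))

  enriched <- unique(disease$gene_id[disease$intended_class == "Ligand contact"])
  annotation <- make_annotation_db(genes$gene_id, n_pathways = 8,
                                   sizes = 3,
                                   planted_enriched = enriched[1:min(3, length(enriched))],
                                   seed = seed + 300)
  list(genes = genes, library = library, truth = truth, disease = disease,
       neutral = neutral, annotation = annotation,
       enriched_genes = enriched, dir = dir)
}
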