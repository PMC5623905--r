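# Logistic contact weights, candidate scores, the exclusive five-class
# rule set, aggregation over templates, and ligand-exclusion
# re-classification.

test_that("contact weights are the stated sigmoids with absent -> 0", {
  expect_equal(interaction_weights(10, Inf)$lig_cont, 0.5)
  expect_equal(interaction_weights(Inf, 10)$chain_cont, 0.5)
  expect_close(interaction_weights(8, Inf)$lig_cont, 1 / (1 + exp(-2)), 1e-12)
  expect_equal(interaction_weights(NA, NA)$IS, 0)
  expect_equal(interaction_weights(Inf, Inf)$IS, 0)
  w <- interaction_weights(6, 9)
  expect_equal(w$IS, max(w$lig_cont, w$chain_cont))
})

test_that("candidate score is template score times interaction score", {
  perfect <- data.frame(seq_id = 1, cov = 1, resolution = 1e-12, r_value = 0)
  ctx <- list(SLD = 10, SCD = Inf)
  sc <- candidate_score(perfect, ctx)
  expect_close(sc$score, template_score(perfect) * 0.5, 1e-9)
  # far from everything: candidate ~ 0
  far <- candidate_score(perfect, list(SLD = 40, SCD = 50))
  expect_lt(far$score, 1e-9)
  # monotone decreasing in SLD
  s <- vapply(c(3, 6, 9), function(d)
    candidate_score(perfect, list(SLD = d, SCD = Inf))$score, 0)
  expect_true(all(diff(s) < 0))
})

test_that("exclusive classification follows distance then accessibility", {
  expect_equal(classify_exclusive(3.0, 7.0, Inf, RSA = 50), "Ligand contact")
  expect_equal(classify_exclusive(4.0, Inf, 3.0, RSA = 50), "DNA contact")
  expect_equal(classify_exclusive(Inf, 4.9, Inf, RSA = 5), "Protein contact")
  expect_equal(classify_exclusive(Inf, Inf, Inf, RSA = 10), "Core")
  expect_equal(classify_exclusive(Inf, Inf, Inf, RSA = 40), "Surface")
  # strict thresholds
  expect_equal(classify_exclusive(5.0, Inf, Inf, RSA = 40), "Surface")
  expect_equal(classify_exclusive(Inf, Inf, Inf, RSA = 16), "Surface")
  expect_equal(classify_exclusive(Inf, Inf, Inf, RSA = 15.999), "Core")
  # exact ties: rarest class wins under the documented priority
  expect_equal(classify_exclusive(3.0, 3.0, 3.0, RSA = 50), "DNA contact")
  expect_equal(classify_exclusive(3.0, 3.0, Inf, RSA = 50), "Ligand contact")
  # configurable priority
  expect_equal(classify_exclusive(3.0, 3.0, Inf, RSA = 50,
                                  tie_priority = c("Protein", "Ligand", "DNA")),
               "Protein contact")
})

test_that("aggregation takes category minima and the right RSA source", {
  ctx <- data.frame(
    SLD = c(12, 4.5), D_protein = c(20, 30), D_dna = c(Inf, Inf),
    RSA = c(50, 8), template_score = c(0.9, 0.6), score = c(0.1, 0.4))
  agg <- aggregate_over_templates(ctx)
  expect_equal(agg$structural_class, "Ligand contact")
  expect_equal(agg$min_SLD, 4.5)
  expect_equal(agg$RSA, 8)         # template with the overall minimum
  expect_equal(agg$best_score, 0.4)
  expect_equal(agg$contacts, "Ligand")

  # no contact anywhere: RSA from the best-scoring template
  ctx2 <- data.frame(SLD = c(30, 25), D_protein = c(40, 35),
                     D_dna = c(Inf, Inf), RSA = c(50, 8),
                     template_score = c(0.9, 0.6), score = c(0, 0))
  expect_equal(aggregate_over_templates(ctx2)$RSA, 50)
  expect_equal(aggregate_over_templates(ctx2)$structural_class, "Surface")

  # contact multiset collects every sub-threshold category across templates
  ctx3 <- data.frame(SLD = c(4, 30), D_protein = c(30, 4.5),
                     D_dna = c(Inf, Inf), RSA = c(50, 50),
                     template_score = c(0.9, 0.6), score = c(0.2, 0.1))
  agg3 <- aggregate_over_templates(ctx3)
  expect_setequal(agg3$contacts, c("Ligand", "Protein"))
  expect_equal(agg3$structural_class, "Ligand contact")

  expect_equal(aggregate_over_templates(NULL)$structural_class, "Unmapped")
})

test_that("classes recovered on the toy complex match the planted truth", {
  tc <- toy_entry(seed = 34)
  genes <- data.frame(
    gene_id = c("gA", "gB"), protein = tc$spec$chain_seqs,
    cds = vapply(tc$spec$chain_seqs, function(p) {
      by_aa <- split(names(Biostrings::GENETIC_CODE),
                     Biostrings::GENETIC_CODE)
      paste(c(vapply(strsplit(p, "")[[1]], function(a) by_aa[[a]][1], ""),
              "TAA"), collapse = "")
    }, ""))
  lib <- structure_library(list(tc$entry))
  v <- plant_variants(genes, tc$truth,
                      c("Ligand contact" = 1, "DNA contact" = 1,
                        "Protein contact" = 1, "Core" = 1, "Surface" = 3),
                      chain_gene = c(A = "gA", B = "gB"), seed = 3)
  ann <- annotate_variants(v, genes, lib)
  expect_equal(ann$variants$structural_class, ann$variants$intended_class)
  # exclusive classes partition the mapped set
  fr <- class_fractions(ann)
  expect_equal(sum(fr$fractions), 1, tolerance = 1e-9)
})

test_that("excluding a ligand reclassifies its contacts and logs flips", {
  # ligand at 3 A from a residue buried inside a cage: excluding the
  # ligand must flip Ligand contact -> Core
  spec <- complex_spec(
    chain_lengths = 40,
    ligand_placements = data.frame(chain = "A", resno = 20, target = 3.0,
                                   het = "SAM"),
    core_placements = data.frame(chain = "A", resno = 30),
    seed = 9)
  path <- tempfile(fileext = ".pdb")
  tc <- make_toy_complex(spec, path)
  e <- parse_structure(path)
  # manually add a cage around the ligand-contact residue so that its
  # accessibility is core-like once the ligand is discounted
  lines <- readLines(path)
  pts <- snv3d:::sphere_points(80) * 5
  ca <- e$atoms[e$atoms$chain == "A" & e$atoms$resno == 20 &
                  e$atoms$atom == "CA", c("x", "y", "z")]
  # cage centred at the bulged residue, one extra UNK residue
  cage <- sweep(pts, 2, as.numeric(ca) + c(0, 0, 1.5), "+")
  cage_lines <- sprintf(
    "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    9000 + seq_len(80), sprintf("C%02d", seq_len(80)), "UNK", "A", 42L,
    cage[, 1], cage[, 2], cage[, 3])
  writeLines(append(lines, cage_lines, after = length(lines) - 1), path)
  e <- parse_structure(path)
  lib <- structure_library(list(e))
  genes <- data.frame(
    gene_id = "gA", protein = spec$chain_seqs[1],
    cds = paste(c(vapply(strsplit(spec$chain_seqs[1], "")[[1]], function(a)
      split(names(Biostrings::GENETIC_CODE),
            Biostrings::GENETIC_CODE)[[a]][1], ""), "TAA"), collapse = ""))
  v <- data.frame(gene_id = "gA", position = 20,
                  ref_aa = substr(genes$protein, 20, 20),
                  alt_aa = "A", dataset_label = "d")
  if (v$ref_aa == "A") v$alt_aa <- "V"
  ann <- annotate_variants(v, genes, lib)
  expect_equal(ann$variants$structural_class, "Ligand contact")

  rc <- reclassify_excluding_ligands(ann, lib, "SAM")
  expect_equal(rc$annotated$variants$structural_class, "Core")
  expect_equal(rc$changes$from, "Ligand contact")
  expect_equal(rc$changes$to, "Core")

  # empty exclusion list is the identity transformation
  rc0 <- reclassify_excluding_ligands(ann, lib, character())
  expect_equal(rc0$annotated$variants, ann$variants)
  expect_equal(nrow(rc0$changes), 0)
  # a retained ligand keeps its contacts
  rc1 <- reclassify_excluding_ligands(ann, lib, "XYZ")
  expect_equal(rc1$annotated$variants$structural_class, "Ligand contact")
})
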