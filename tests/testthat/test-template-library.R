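# Template search filters, alignment position mapping, and the
# template quality score.

make_lib_entry <- function(seqs, sid, dir = tempdir(), resolution = 2.0,
                           r_value = 0.2, seed = 1) {
  spec <- complex_spec(chain_seqs = seqs, resolution = resolution,
                       r_value = r_value, seed = seed)
  path <- file.path(dir, paste0(sid, ".pdb"))
  make_toy_complex(spec, path, structure_id = sid)
  parse_structure(path)
}

mutate_seq <- function(s, frac, seed = 1) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), round(frac * length(v)))
  v[idx] <- vapply(v[idx], function(a) sample(setdiff(names(snv3d:::MAX_ASA), a), 1), "")
  paste(v, collapse = "")
}

test_that("template filters keep identity hits and drop remote homologs", {
  target <- make_gene_set(1, c(80, 80), seed = 51)$protein
  lib <- structure_library(list(
    make_lib_entry(target, "IDEN", seed = 1),
    make_lib_entry(mutate_seq(target, 0.70, 2), "REMO", seed = 2),
    make_lib_entry(mutate_seq(target, 0.30, 3), "HOMO", seed = 3)))
  hits <- search_templates(list(gene_id = "g", protein = target), lib)
  expect_true("IDEN" %in% hits$structure_id)
  expect_true("HOMO" %in% hits$structure_id)   # ~70% identity
  expect_false("REMO" %in% hits$structure_id)  # ~30% identity
  iden <- hits[hits$structure_id == "IDEN" & hits$chain == "A", ]
  expect_equal(iden$seq_id, 1.0)
  expect_equal(iden$cov, 1.0)
  # sorted by identity, descending
  expect_equal(hits$seq_id, sort(hits$seq_id, decreasing = TRUE))
})

test_that("coverage arithmetic follows the shorter-sequence rule", {
  stats <- snv3d:::alignment_stats
  # 40 aligned residues inside a 120-residue target vs a long template:
  # fails both the half-of-shorter and the >50 aligned-length branch
  a40 <- paste0(strrep("A", 40), strrep("-", 80))
  b40 <- paste0(strrep("A", 40), strrep("B", 80))
  st <- stats(paste0(a40, strrep("B", 80)), paste0(b40, strrep("-", 80)),
              target_len = 120, template_len = 120)
  expect_equal(st$aligned_length, 40)
  expect_lt(st$aligned_length, 0.5 * st$shorter)
  expect_false(st$aligned_length > 0.5 * st$shorter ||
                 st$aligned_length > 50)
  # a 60-residue aligned region passes via the aligned-length branch
  st60 <- stats(paste0(strrep("A", 60), strrep("B", 60)),
                paste0(strrep("A", 60), strrep("-", 60)),
                target_len = 120, template_len = 60)
  expect_equal(st60$aligned_length, 60)
  expect_true(st60$aligned_length > 0.5 * st60$shorter ||
                st60$aligned_length > 50)
  # identity on every aligned column but gaps counted in the denominator
  st_id <- stats("AB-D", "ABCD", 3, 4)
  expect_equal(st_id$seq_id, 3 / 4)
})

test_that("search equals a brute-force align-and-filter oracle", {
  target <- make_gene_set(1, c(70, 70), seed = 61)$protein
  fracs <- seq(0.05, 0.95, length.out = 10)
  entries <- lapply(seq_along(fracs), function(i)
    make_lib_entry(mutate_seq(target, fracs[i], i),
                   sprintf("LIB%02d", i), seed = i))
  lib <- structure_library(entries)
  hits <- search_templates(list(gene_id = "g", protein = target), lib)

  # oracle: align every chain independently, recompute the three filters
  oracle_pass <- character()
  for (i in seq_len(nrow(lib$chains))) {
    ch <- lib$chains[i, ]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(target), Biostrings::AAString(ch$seq),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    at <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    bt <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    aligned <- at != "-" & bt != "-"
    seq_id <- sum(at == bt & aligned) / sum(at != "-" | bt != "-")
    alen <- sum(aligned)
    shorter <- min(nchar(target), nchar(ch$seq))
    if (seq_id > 0.35 && (alen > 0.5 * shorter || alen > 50))
      oracle_pass <- c(oracle_pass, paste0(ch$structure_id, ".", ch$chain))
  }
  expect_setequal(paste0(hits$structure_id, ".", hits$chain), oracle_pass)
})

test_that("e-values from an external backend filter hits", {
  target <- make_gene_set(1, c(60, 60), seed = 71)$protein
  lib <- structure_library(list(make_lib_entry(target, "EV01", seed = 1)))
  ev_bad <- c(EV01.A = 1e-4)
  ev_good <- c(EV01.A = 1e-9)
  expect_equal(nrow(search_templates(list(gene_id = "g", protein = target),
                                     lib, evalues = ev_bad)), 0)
  expect_gt(nrow(search_templates(list(gene_id = "g", protein = target),
                                  lib, evalues = ev_good)), 0)
})

test_that("positions map through alignment columns; gaps unmap", {
  hit <- data.frame(aln_target = "AB-D", aln_template = "ABCD")
  mp <- map_positions(hit, 1:3)
  expect_equal(mp$template_index, c(1L, 2L, 4L))   # D sits in column 4
  expect_true(all(mp$mapped))

  hit2 <- data.frame(aln_target = "ABCD", aln_template = "AB-D")
  mp2 <- map_positions(hit2, 1:4)
  expect_false(mp2$mapped[3])                       # C faces a gap
  expect_equal(mp2$template_index[c(1, 2, 4)], c(1L, 2L, 3L))

  # identity alignment: the map is the identity
  hit3 <- data.frame(aln_target = "WXYZ", aln_template = "WXYZ")
  expect_equal(map_positions(hit3, 1:4)$template_index, 1:4)
})

test_that("mapping composed with the inverse alignment is the identity", {
  set.seed(81)
  target <- make_gene_set(1, c(50, 50), seed = 81)$protein
  tmpl <- mutate_seq(target, 0.2, 81)
  aln <- snv3d:::align_global(target, tmpl)
  hit <- data.frame(aln_target = aln$target, aln_template = aln$template)
  inv <- data.frame(aln_target = aln$template, aln_template = aln$target)
  mp <- map_positions(hit, 1:nchar(target))
  mapped <- mp[mp$mapped, ]
  back <- map_positions(inv, mapped$template_index)
  expect_equal(back$template_index, mapped$position)
})

test_that("template score components and monotonicity match the model", {
  hit <- function(seq_id = 1, cov = 1, resolution = 2, r_value = 0.2)
    data.frame(seq_id = seq_id, cov = cov, resolution = resolution,
               r_value = r_value)
  # sigmoid midpoint: res(8/3) = 0.5
  expect_equal(template_score(hit(1, 1, 8 / 3, 0)),
               mean(c(1, 1, 0.5, 1)))
  # perfect template at vanishing resolution: (1+1+1/(1+exp(-4))+1)/4
  expect_close(template_score(hit(1, 1, 1e-9, 0)),
               (1 + 1 + 1 / (1 + exp(-4)) + 1) / 4, 1e-6)
  expect_close(template_score(hit(1, 1, 1e-9, 0)), 0.9955, 5e-4)
  # R-value enters linearly with weight 1/4
  expect_equal(template_score(hit(r_value = 0)) -
                 template_score(hit(r_value = 1)), 0.25)
  # monotone in each attribute
  expect_gt(template_score(hit(seq_id = 0.9)),
            template_score(hit(seq_id = 0.5)))
  expect_gt(template_score(hit(resolution = 1.5)),
            template_score(hit(resolution = 3.5)))
  # missing metadata contributes neutral terms
  expect_equal(template_score(hit(1, 1, NA, NA)),
               mean(c(1, 1, 0.5, 0.5)))
})
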