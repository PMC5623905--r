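## Variant data sets: validated loading, neutral-overlap removal, and
## randomized controls with per-gene count conservation.

VARIANT_COLUMNS <- c("gene_id", "position", "ref_aa", "alt_aa",
                     "dataset_label")

#' Load and validate a variant table
#'
#' Accepts a data.frame or TSV path with columns gene_id,
#' position (or position_1based), ref_aa, alt_aa, dataset_label. Rows
#' violating the variant invariants are rejected with row-numbered
#' diagnostics rather than aborting the load; exact duplicates of
#' (gene, position, alt) are collapsed to one row with a multiplicity
#' count.
#'
#' @param x data.frame or path to a tab-separated file.
#' @param genes gene table (gene_id, protein, cds) used to check the
#'   reference residue and position range.
#' @return list with `variants` (accepted, deduplicated, with
#'   `multiplicity`), `rejected` (row, reason) and `n_accepted`.
#' @export
load_variants <- function(x, genes) {
  df <- if (is.character(x))
    utils::read.delim(x, stringsAsFactors = FALSE) else as.data.frame(x)
  if ("position_1based" %in% names(df) && !"position" %in% names(df))
    names(df)[names(df) == "position_1based"] <- "position"
  missing_cols <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- df[VARIANT_COLUMNS]
  df$position <- as.integer(df$position)

  aa <- names(MAX_ASA)
  reason <- rep(NA_character_, nrow(df))
  gi <- match(df$gene_id, genes$gene_id)
  reason[is.na(gi)] <- "unknown gene"
  ok <- is.na(reason)
  bad_aa <- ok & (!df$ref_aa %in% aa | !df$alt_aa %in% aa)
  reason[bad_aa] <- "invalid residue code"
  ok <- is.na(reason)
  out_of_range <- ok & (is.na(df$position) | df$position < 1 |
                          df$position > nchar(genes$protein[gi]))
  reason[out_of_range] <- "position out of range"
  ok <- is.na(reason)
  same <- ok & df$ref_aa == df$alt_aa
  reason[same] <- "not a substitution"
  ok <- is.na(reason)
  refseq <- substr(genes$protein[gi], df$position, df$position)
  mism <- ok & refseq != df$ref_aa
  reason[mism] <- "ref mismatch"
  ok <- is.na(reason)

  rejected <- data.frame(row = which(!ok), reason = reason[!ok],
                         stringsAsFactors = FALSE)
  acc <- df[ok, , drop = FALSE]
  if (nrow(acc)) {
    key <- paste(acc$gene_id, acc$position, acc$alt_aa, acc$dataset_label)
    mult <- as.integer(table(key)[key])
    acc$multiplicity <- mult
    acc <- acc[!duplicated(key), , drop = FALSE]
    rownames(acc) <- NULL
  } else {
    acc$multiplicity <- integer(0)
  }
  list(variants = acc, rejected = rejected, n_accepted = nrow(acc))
}

#' Remove disease variants that also occur in a neutral set
#'
#' Drops from the disease set every variant whose exact
#' (gene, position, ref, alt) combination is present in the neutral set.
#'
#' @param disease,neutral variant data.frames.
#' @return list with `variants` (filtered disease set) and `removed`
#'   (number of rows dropped).
#' @export
remove_neutral_overlap <- function(disease, neutral) {
  key <- function(v) paste(v$gene_id, v$position, v$ref_aa, v$alt_aa)
  drop <- key(disease) %in% key(neutral)
  list(variants = disease[!drop, , drop = FALSE], removed = sum(drop))
}

## enumerate all missense-producing (nucleotide position, alt base)
## pairs of one coding sequence (stop codon excluded: stop-loss changes
## are not missense)
missense_sites <- function(protein, cds) {
  L <- nchar(protein)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (k in seq_len(L)) {
    codon <- codon_at(cds, k)
    aa_old <- substr(protein, k, k)
    for (p in 1:3) for (b in setdiff(bases, substr(codon, p, p))) {
      nc <- codon
      substr(nc, p, p) <- b
      aa_new <- unname(GENETIC_CODE_TABLE[nc])
      if (!is.na(aa_new) && aa_new != aa_old && aa_new != "*")
        out[[length(out) + 1L]] <- c(nt_pos = 3L * (k - 1L) + p, base = b,
                                     position = k, alt_aa = aa_new)
    }
  }
  if (!length(out))
    return(data.frame(nt_pos = integer(), base = character(),
                      position = integer(), alt_aa = character()))
  m <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  m$nt_pos <- as.integer(m$nt_pos)
  m$position <- as.integer(m$position)
  m
}

#' Randomized control variant set
#'
#' For each gene of the input set, introduces the same number of variants
#' at random positions of the coding nucleotide sequence: a uniformly
#' drawn nucleotide position and alternative base, rejection-resampled
#' until the codon change is missense (neither synonymous nor
#' stop-related). Per-gene variant counts are conserved exactly;
#' recurrent sites are permitted (sampling with replacement).
#'
#' @param variants input variant data.frame.
#' @param genes gene table covering every gene of `variants`.
#' @param seed integer seed.
#' @param label_suffix parent label recorded as `randomized:<parent>`.
#' @return data.frame of randomized variants.
#' @export
randomize_dataset <- function(variants, genes, seed = 1L,
                              label_suffix = NULL) {
  counts <- table(variants$gene_id)
  missing_genes <- setdiff(names(counts), genes$gene_id)
  if (length(missing_genes))
    stop("no gene record for: ", paste(missing_genes, collapse = ", "))
  rng <- make_rng(seed, "randomize")
  parent <- if (is.null(label_suffix)) {
    u <- unique(variants$dataset_label)
    if (length(u) == 1L) u else "mixed"
  } else label_suffix
  out <- list()
  for (gid in names(counts)) {
    g <- genes[genes$gene_id == gid, ]
    sites <- missense_sites(g$protein, g$cds)
    if (!nrow(sites))
      stop("gene ", gid, " admits no missense change")
    idx <- sample_int_rng(rng, nrow(sites), counts[[gid]], replace = TRUE)
    pos <- sites$position[idx]
    out[[gid]] <- data.frame(
      gene_id = gid, position = pos,
      ref_aa = substr(g$protein, pos, pos), alt_aa = sites$alt_aa[idx],
      dataset_label = paste0("randomized:", parent),
      nt_pos = sites$nt_pos[idx], alt_base = sites$base[idx],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read variant tables as TSV
#' @param variants variant data.frame.
#' @param path file path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
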