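## PDB-format i/o. Reading goes through bio3d::read.pdb; the resolution
## and R-value REMARK records, which bio3d does not surface, are read
## directly. Writing (synthetic complexes only) emits fixed-width
## ATOM/HETATM/TER records.

format_atom_name <- function(name) {
  ## standard PDB convention: 1-2 char element names start in column 14
  ifelse(nchar(name) <= 3, sprintf(" %-3s", name), sprintf("%-4s", name))
}

#' Write an atom table as a PDB-format file
#' @param atoms data.frame with columns atom, res, chain, resno, x, y, z,
#'   het (logical: HETATM record).
#' @keywords internal
write_pdb_entry <- function(atoms, path, structure_id = "TOY1",
                            resolution = 2.0, r_value = 0.20) {
  lines <- c(
    sprintf("HEADER    SYNTHETIC COMPLEX                       01-JAN-20   %-4s",
            structure_id),
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution),
    sprintf("REMARK   3   R VALUE            (WORKING SET) : %.3f", r_value)
  )
  ## polymer chains first (with TER), then het groups
  serial <- 0L
  body <- character(0)
  emit <- function(df, record) {
    out <- character(nrow(df))
    for (k in seq_len(nrow(df))) {
      serial <<- serial + 1L
      el <- element_from_name(df$atom[k], df$res[k])
      out[k] <- sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        record, serial, format_atom_name(df$atom[k]),
                        df$res[k], df$chain[k], df$resno[k],
                        df$x[k], df$y[k], df$z[k], 1, 0, el)
    }
    out
  }
  for (ch in unique(atoms$chain[!atoms$het])) {
    df <- atoms[atoms$chain == ch & !atoms$het, ]
    body <- c(body, emit(df, "ATOM"))
    serial <- serial + 1L
    last <- df[nrow(df), ]
    body <- c(body, sprintf("TER   %5d      %-3s %1s%4d",
                            serial, last$res, last$chain, last$resno))
  }
  het <- atoms[atoms$het, ]
  if (nrow(het)) body <- c(body, emit(het, "HETATM"))
  writeLines(c(lines, body, "END"), path)
  invisible(path)
}

#' Parse a PDB-format structure into an annotated atom table
#'
#' Reads the first model, keeps alternate location A (or blank), types
#' polymer chains as protein/DNA/RNA by residue alphabet, and builds the
#' ligand set from HETATM groups: common crystallographic buffer
#' components are removed, metal ions are kept, and het codes on
#' `drug_list` are kept but flagged drug-like so they can be excluded in
#' a re-analysis. Modified amino acids (HETATM with a standard residue
#' name, or listed in MODRES) are treated as chain residues, not ligands.
#'
#' @param path PDB-format file.
#' @param buffer_list het codes dropped entirely.
#' @param drug_list het codes flagged as drug-like.
#' @return a `structure_entry`: list with `structure_id`, `atoms` (one row
#'   per atom with a `category` column: protein/dna/rna/ligand),
#'   `chains` (per-chain polymer type), `ligands`, `resolution`, `r_value`.
#' @export
parse_structure <- function(path, buffer_list = DEFAULT_BUFFER_LIST,
                            drug_list = character()) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  if (!any(at$type == "ATOM")) stop("no ATOM records in ", path)

  lines <- readLines(path, n = 200L)
  res_line <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  resolution <- if (length(res_line)) {
    v <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1",
                                         res_line[1])))
    if (is.na(v)) NA_real_ else v
  } else NA_real_
  rv_line <- grep("^REMARK   3   R VALUE", lines, value = TRUE)
  r_value <- if (length(rv_line)) {
    v <- suppressWarnings(as.numeric(sub(".*:\\s*([0-9.]+).*", "\\1", rv_line[1])))
    if (is.na(v)) NA_real_ else v
  } else NA_real_
  header <- grep("^HEADER", lines, value = TRUE)
  structure_id <- if (length(header) && nchar(header[1]) >= 66)
    trimws(substr(header[1], 63, 66)) else
      toupper(sub("\\.(pdb|ent)$", "", basename(path)))
  modres <- unique(trimws(substr(grep("^MODRES", lines, value = TRUE), 25, 27)))

  resname <- trimws(at$resid)
  is_aa <- resname %in% c(names(AA3_TO_1), "UNK")
  is_mod <- resname %in% modres
  is_dna <- resname %in% DNA_RES
  is_rna <- resname %in% RNA_RES & at$type == "ATOM"

  category <- rep(NA_character_, nrow(at))
  category[at$type == "ATOM" & is_aa] <- "protein"
  category[is_dna] <- "dna"
  category[is_rna] <- "rna"
  ## HETATM: modified residues belong to chains; buffers dropped
  het_idx <- at$type == "HETATM" & is.na(category)
  category[het_idx & (is_aa | is_mod)] <- "protein"
  het_idx <- at$type == "HETATM" & is.na(category)
  drop <- het_idx & resname %in% toupper(buffer_list)
  category[het_idx & !drop] <- "ligand"
  unknown <- at$type == "ATOM" & is.na(category) & !drop
  if (any(unknown)) {
    warning("unknown residue codes kept as chain residues: ",
            paste(unique(resname[unknown]), collapse = ", "))
    category[unknown] <- "protein"
  }
  keep <- !is.na(category)
  at <- at[keep, ]
  resname <- resname[keep]
  category <- category[keep]

  element <- ifelse(!is.na(at$elesy) & at$elesy != "", toupper(at$elesy),
                    element_from_name(at$elety, resname))
  ## hydrogens are ignored throughout
  hyd <- element %in% c("H", "D")
  at <- at[!hyd, ]; resname <- resname[!hyd]; category <- category[!hyd]
  element <- element[!hyd]

  atoms <- data.frame(
    record = at$type, chain = at$chain, resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    res = resname, atom = trimws(at$elety), element = element,
    x = at$x, y = at$y, z = at$z, category = category,
    drug_like = category == "ligand" & resname %in% toupper(drug_list),
    stringsAsFactors = FALSE
  )

  ## per-chain polymer typing by majority alphabet (exclusive)
  poly <- atoms[atoms$category != "ligand", ]
  chains <- do.call(rbind, lapply(split(poly, poly$chain), function(d) {
    data.frame(chain = d$chain[1],
               type = names(sort(table(d$category), decreasing = TRUE))[1],
               n_res = length(unique(paste(d$resno, d$icode))))
  }))
  rownames(chains) <- NULL
  if (!is.null(chains)) {
    retype <- match(atoms$chain, chains$chain)
    poly_mask <- atoms$category != "ligand"
    atoms$category[poly_mask] <- chains$type[retype[poly_mask]]
  }

  lig <- atoms[atoms$category == "ligand", ]
  ligands <- if (nrow(lig)) {
    u <- unique(lig[c("chain", "resno", "res", "drug_like")])
    u$is_metal <- u$res %in% METAL_IONS
    rownames(u) <- NULL
    u
  } else {
    data.frame(chain = character(), resno = integer(), res = character(),
               drug_like = logical(), is_metal = logical())
  }

  structure(list(structure_id = structure_id, atoms = atoms,
                 chains = chains, ligands = ligands,
                 resolution = resolution, r_value = r_value,
                 path = path),
            class = "structure_entry")
}

#' @export
print.structure_entry <- function(x, ...) {
  cat("<structure_entry>", x$structure_id, "\n",
      nrow(x$atoms), "atoms;",
      nrow(x$chains), "chains (",
      paste(sprintf("%s:%s", x$chains$chain, x$chains$type), collapse = ", "),
      ");", nrow(x$ligands), "ligand groups\n",
      "resolution", x$resolution, "A; R-value", x$r_value, "\n")
  invisible(x)
}

#' One-letter sequence of a polymer chain in a structure entry
#' @param entry a `structure_entry`.
#' @param chain chain id.
#' @return list with `seq` (1-letter string, protein chains only) and
#'   `resno` (residue numbers in sequence order).
#' @export
chain_sequence <- function(entry, chain) {
  d <- entry$atoms[entry$atoms$chain == chain &
                     entry$atoms$category == "protein", ]
  if (!nrow(d)) stop("no protein chain ", chain, " in ", entry$structure_id)
  key <- paste(d$resno, d$icode)
  first <- !duplicated(key)
  resno <- d$resno[first]
  res <- d$res[first]
  o <- order(resno)
  aa <- AA3_TO_1[res[o]]
  aa[is.na(aa)] <- "X"
  list(seq = paste(aa, collapse = ""), resno = resno[o])
}
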