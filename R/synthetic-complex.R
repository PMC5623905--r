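## Synthetic multi-chain complexes with partners planted at controlled
## distances from designated residues. Every residue is built from a
## five-atom template (N, CA, C, O + one pseudo side-chain atom CB) so
## distance minima and accessible-surface computations run over realistic
## atom counts without a chemistry engine.

# local-frame atom template of one pseudo-residue, CA at the origin,
# side chain pointing along +z (the outward normal used for placements)
RES_ATOM_TEMPLATE <- data.frame(
  atom = c("N", "CA", "C", "O", "CB"),
  x = c(-1.2, 0, 1.2, 1.9, 0),
  y = c(0.8, 0, 0.8, 1.7, 0),
  z = c(0, 0, 0, 0.2, 1.5)
)

CA_SPACING <- 3.8    # along-chain CA-CA distance, A
CHAIN_SPACING <- 30  # lateral offset between main chains, A
BULGE_Z <- 9         # designated contact residues protrude this far, A
CAGE_RADIUS <- 5     # burial cage radius around planted core residues, A
CAGE_ATOMS <- 80

#' Specification of a synthetic protein complex
#'
#' Describes a toy multi-chain complex in which small-molecule ligands,
#' DNA duplexes and partner protein chains are placed at controlled
#' minimum distances from designated residues. Placement tables are data
#' frames with columns `chain` (main-chain id), `resno` (1-based residue
#' index) and `target` (intended minimum inter-atomic distance, A);
#' `ligand_placements` may add a `het` column (3-letter het code; codes in
#' the metal-ion list yield single-atom ions).
#'
#' @param chain_seqs character vector of one-letter main-chain sequences
#'   (chains are lettered A, B, ... in order). If omitted, random
#'   sequences of `chain_lengths` residues are drawn.
#' @param chain_lengths integer vector, used when `chain_seqs` is missing.
#' @param ligand_placements,dna_placements,partner_chain_placements
#'   placement tables as described above (NULL for none).
#' @param core_placements data frame with columns `chain`, `resno`:
#'   residues to bury inside a same-chain atom cage so that their relative
#'   accessibility falls below the core threshold.
#' @param resolution,r_value crystallographic metadata written into the
#'   REMARK 2 / REMARK 3 header records.
#' @param seed integer; all randomness (sequences, jitter) derives from it.
#' @return an object of class `complex_spec`.
#' @export
complex_spec <- function(chain_seqs = NULL, chain_lengths = NULL,
                         ligand_placements = NULL, dna_placements = NULL,
                         partner_chain_placements = NULL,
                         core_placements = NULL,
                         resolution = 2.0, r_value = 0.20, seed = 1L) {
  if (is.null(chain_seqs)) {
    if (is.null(chain_lengths)) stop("need chain_seqs or chain_lengths")
    rng <- make_rng(seed, "chains")
    chain_seqs <- vapply(chain_lengths, function(L)
      paste(sample_rng(rng, names(MAX_ASA), L, replace = TRUE),
            collapse = ""), "")
  }
  norm_pl <- function(p, het = FALSE) {
    if (is.null(p) || nrow(as.data.frame(p)) == 0L) return(NULL)
    p <- as.data.frame(p)
    stopifnot(all(c("chain", "resno") %in% names(p)))
    if (!"target" %in% names(p)) p$target <- NA_real_
    if (het && !"het" %in% names(p)) p$het <- "LIG"
    p
  }
  spec <- structure(list(
    chain_seqs = chain_seqs,
    chain_ids = LETTERS[seq_along(chain_seqs)],
    ligand_placements = norm_pl(ligand_placements, het = TRUE),
    dna_placements = norm_pl(dna_placements),
    partner_chain_placements = norm_pl(partner_chain_placements),
    core_placements = norm_pl(core_placements),
    resolution = resolution, r_value = r_value, seed = as.integer(seed)
  ), class = "complex_spec")
  validate_complex_spec(spec)
  spec
}

validate_complex_spec <- function(spec) {
  lens <- nchar(spec$chain_seqs)
  names(lens) <- spec$chain_ids
  take <- function(p, kind) {
    if (is.null(p)) return(NULL)
    data.frame(kind = kind, chain = p$chain, resno = p$resno,
               target = if ("target" %in% names(p)) p$target else NA_real_)
  }
  all_pl <- rbind(take(spec$ligand_placements, "Ligand"),
                  take(spec$dna_placements, "DNA"),
                  take(spec$partner_chain_placements, "Protein"),
                  take(spec$core_placements, "Core"))
  if (is.null(all_pl) || nrow(all_pl) == 0L) return(invisible(spec))
  bad <- !all_pl$chain %in% spec$chain_ids
  if (any(bad)) stop("placement on unknown chain: ", all_pl$chain[bad][1])
  out <- all_pl$resno < 1 | all_pl$resno > lens[all_pl$chain]
  if (any(out)) stop("placement residue outside chain: ",
                     all_pl$chain[out][1], all_pl$resno[out][1])
  tg <- all_pl$target
  if (any(!is.na(tg) & tg <= 0)) stop("target distances must be positive")
  if (any(!is.na(tg) & tg < 2))
    stop("infeasible geometry: target below 2 A cannot keep ",
         "non-designated residues 8 A clear of the partner")
  ## designated residues on one chain must be spaced so partners and
  ## burial cages cannot touch each other's residues
  for (ch in unique(all_pl$chain)) {
    p <- all_pl[all_pl$chain == ch, ]
    rs <- sort(unique(p$resno[p$kind != "Core"]))
    if (length(rs) > 1 && min(diff(rs)) < 2)
      stop("infeasible geometry: designated residues ",
           paste(rs[which.min(diff(rs)) + 0:1], collapse = " and "),
           " on chain ", ch, " closer than 2 positions")
    cr <- sort(unique(p$resno[p$kind == "Core"]))
    other <- unique(p$resno[p$kind != "Core"])
    too_close <- (length(cr) && length(other) &&
                    min(abs(outer(cr, other, "-"))) < 3) ||
      (length(cr) > 1 && min(diff(cr)) < 3)
    if (too_close)
      stop("infeasible geometry: core residue on chain ", ch,
           " within 2 positions of another planted residue")
  }
  n_per_res <- table(paste(all_pl$chain, all_pl$resno)[all_pl$kind != "Core"])
  if (any(n_per_res > 3))
    stop("infeasible geometry: more than 3 partners on one residue")
  invisible(spec)
}

## partner tilt directions for up to three placements on one residue
placement_directions <- function(k) {
  if (k == 1) return(matrix(c(0, 0, 1), 1))
  tilt <- 25 * pi / 180
  az <- 2 * pi * (seq_len(k) - 1) / k
  cbind(sin(tilt) * cos(az), sin(tilt) * sin(az), rep(cos(tilt), k))
}

## orthonormal frame whose third axis is u
frame_for <- function(u) {
  w <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- w - sum(w * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cbind(e1, e2, u)
}

## local-frame partner templates: contact atom exactly at the origin, all
## other atoms with positive offset along +z so the realized minimum
## distance equals the target exactly
ligand_template <- function(het) {
  if (toupper(het) %in% METAL_IONS) {
    data.frame(atom = toupper(het), res = toupper(het),
               x = 0, y = 0, z = 0, resno_off = 0)
  } else {
    data.frame(atom = c("C1", "O1", "C2", "N1"), res = het,
               x = c(0, 1.25, -1.30, 0.10),
               y = c(0, 0, 0.20, 1.30),
               z = c(0, 0.45, 0.60, 0.75), resno_off = 0)
  }
}

dna_template <- function() {
  nt <- function(j, strand) {
    if (strand == 1) {
      data.frame(
        atom = c("P", "C1'", "N1"),
        x = (j - 1) * 4.0 + c(-1.5, 0, if (j == 1) 0 else 0.6),
        y = c(0, 0.8, 0),
        z = if (j == 1) c(1.6, 0.9, 0) else c(1.6, 0.9, 0.8),
        resno_off = j, strand = 1L)
    } else {
      data.frame(
        atom = c("P", "C1'", "N9"),
        x = (j - 1) * 4.0 + c(2.0, 1.2, 0.5),
        y = c(1.2, 0.5, 0),
        z = c(3.2, 2.6, 2.0),
        resno_off = j, strand = 2L)
    }
  }
  tpl <- do.call(rbind, c(lapply(0:2, nt, strand = 1),
                          lapply(0:2, nt, strand = 2)))
  tpl$res <- rep(c("DA", "DT", "DG", "DT", "DA", "DC"), each = 3)
  tpl
}

partner_chain_template <- function() {
  ## three residues receding along +z; CB of residue 0 (the contact atom)
  ## points back toward the designated residue and sits at the origin
  do.call(rbind, lapply(0:2, function(j) {
    ca <- c(0, 0, 1.5 + 3.8 * j)
    data.frame(
      atom = c("N", "CA", "C", "O", "CB"), res = "ALA",
      x = ca[1] + c(-1.2, 0, 1.2, 1.9, 0),
      y = ca[2] + c(0.8, 0, 0.8, 1.7, 0),
      z = ca[3] + c(0, 0, 0, -0.2, -1.5),
      resno_off = j)
  }))
}

#' Build a synthetic complex and its planted ground truth
#'
#' Writes a PDB-format file realizing a [complex_spec()]: main protein
#' chains as extended strands, designated contact residues bulged outward
#' with their partner (ligand, DNA duplex, or a short protein chain)
#' placed along the outward normal so that the minimum inter-atomic
#' distance to the designated residue equals the target exactly; planted
#' core residues buried in a same-chain atom cage. Identical spec and
#' seed give a byte-identical file.
#'
#' @param spec a [complex_spec()].
#' @param path output file path (PDB format).
#' @param structure_id id written in the HEADER record and the truth table.
#' @return invisibly, a list with `path`, `spec` and `truth`: one row per
#'   main-chain residue with the intended structural class (`NA` for
#'   residues adjacent to planted features, whose class is deliberately
#'   not asserted) and the intended minimum distance.
#' @export
make_toy_complex <- function(spec, path, structure_id = "TOY1") {
  stopifnot(inherits(spec, "complex_spec"))
  rng <- make_rng(spec$seed, "jitter")
  lens <- nchar(spec$chain_seqs)

  atoms <- list()   # data.frames: atom, res, chain, resno, x, y, z, het
  add <- function(df) atoms[[length(atoms) + 1L]] <<- df

  ## --- main chains ------------------------------------------------------
  pl_all <- rbind(
    if (!is.null(spec$ligand_placements))
      cbind(kind = "Ligand", spec$ligand_placements[c("chain", "resno", "target")],
            het = spec$ligand_placements$het),
    if (!is.null(spec$dna_placements))
      cbind(kind = "DNA", spec$dna_placements[c("chain", "resno", "target")],
            het = NA),
    if (!is.null(spec$partner_chain_placements))
      cbind(kind = "Protein",
            spec$partner_chain_placements[c("chain", "resno", "target")],
            het = NA)
  )
  core <- spec$core_placements
  designated <- unique(rbind(
    if (!is.null(pl_all)) pl_all[c("chain", "resno")],
    if (!is.null(core)) core[c("chain", "resno")]
  ))

  for (ci in seq_along(spec$chain_ids)) {
    ch <- spec$chain_ids[ci]
    seq1 <- strsplit(spec$chain_seqs[ci], "")[[1]]
    bulged <- if (is.null(pl_all)) integer() else
      pl_all$resno[pl_all$chain == ch]
    for (i in seq_along(seq1)) {
      d <- RES_ATOM_TEMPLATE
      d$x <- d$x + CA_SPACING * (i - 1)
      d$y <- d$y + CHAIN_SPACING * (ci - 1)
      d$z <- d$z + if (i %in% bulged) BULGE_Z else 0
      add(data.frame(atom = d$atom, res = unname(AA1_TO_3[seq1[i]]), chain = ch,
                     resno = i, x = d$x, y = d$y, z = d$z, het = FALSE))
    }
    ## burial cages appended as one extra same-chain pseudo-residue each
    ## (UNK, many atoms): invisible to inter-chain distances, but they
    ## occlude the caged residue so its accessibility drops below the
    ## core threshold, while barely diluting the chain's identity
    ccore <- if (is.null(core)) integer() else core$resno[core$chain == ch]
    if (length(ccore)) {
      pts <- sphere_points(CAGE_ATOMS) * CAGE_RADIUS
      next_resno <- length(seq1)
      for (r in ccore) {
        next_resno <- next_resno + 1L
        centre <- c(CA_SPACING * (r - 1), CHAIN_SPACING * (ci - 1), 0)
        cage <- sweep(pts, 2, centre, "+") +
          matrix(runif_rng(rng, 3 * CAGE_ATOMS, -0.05, 0.05), ncol = 3)
        add(data.frame(
          atom = sprintf("C%02d", seq_len(CAGE_ATOMS)),
          res = "UNK", chain = ch, resno = next_resno,
          x = cage[, 1], y = cage[, 2], z = cage[, 3], het = FALSE))
      }
    }
  }

  ## --- partners ---------------------------------------------------------
  partner_objects <- list()  # for clash / separation checks
  free_ids <- setdiff(c(LETTERS, letters, as.character(0:9)), spec$chain_ids)
  next_id <- 1L
  take_id <- function(n = 1L) {
    ids <- free_ids[next_id:(next_id + n - 1L)]
    next_id <<- next_id + n
    ids
  }
  truth_extra <- list()

  if (!is.null(pl_all)) {
    key <- paste(pl_all$chain, pl_all$resno)
    for (res_key in unique(key)) {
      rows <- pl_all[key == res_key, , drop = FALSE]
      dirs <- placement_directions(nrow(rows))
      ci <- match(rows$chain[1], spec$chain_ids)
      cb <- c(CA_SPACING * (rows$resno[1] - 1), CHAIN_SPACING * (ci - 1),
              BULGE_Z + 1.5)   # designated residue's CB (outermost atom)
      for (m in seq_len(nrow(rows))) {
        u <- dirs[m, ]
        R <- frame_for(u)
        tpl <- switch(rows$kind[m],
                      Ligand = ligand_template(rows$het[m]),
                      DNA = dna_template(),
                      Protein = partner_chain_template())
        loc <- as.matrix(tpl[c("x", "y", "z")])
        ## rigid jitter on non-contact atoms, contact atom pinned
        jit <- matrix(runif_rng(rng, 3 * nrow(loc), -0.04, 0.04), ncol = 3)
        contact <- which(loc[, 1] == 0 & loc[, 2] == 0 & loc[, 3] == 0)[1]
        jit[contact, ] <- 0
        glob <- (loc + jit) %*% t(R)
        glob <- sweep(glob, 2, cb + rows$target[m] * u, "+")
        if (rows$kind[m] == "DNA") {
          ids <- take_id(2)
          chain_vec <- ids[tpl$strand]
          resno_vec <- tpl$resno_off + 1L
          is_het <- FALSE
        } else if (rows$kind[m] == "Protein") {
          ids <- take_id(1)
          chain_vec <- ids
          resno_vec <- tpl$resno_off + 1L
          is_het <- FALSE
        } else {
          ids <- take_id(1)
          chain_vec <- ids
          resno_vec <- 1L
          is_het <- TRUE
        }
        obj <- data.frame(atom = tpl$atom, res = tpl$res, chain = chain_vec,
                          resno = resno_vec, x = glob[, 1], y = glob[, 2],
                          z = glob[, 3], het = is_het)
        add(obj)
        partner_objects[[length(partner_objects) + 1L]] <- list(
          kind = rows$kind[m], chain = rows$chain[m], resno = rows$resno[m],
          target = rows$target[m], coords = glob)
      }
    }
  }

  atoms <- do.call(rbind, atoms)

  ## --- feasibility checks ----------------------------------------------
  if (length(partner_objects) > 1) {
    for (i in seq_along(partner_objects)[-1]) for (j in seq_len(i - 1)) {
      d <- min_cross_dist(partner_objects[[i]]$coords,
                          partner_objects[[j]]$coords)
      if (d < 1.5)
        stop("infeasible geometry: ", partner_objects[[i]]$kind,
             " partner at ", partner_objects[[i]]$chain,
             partner_objects[[i]]$resno, " clashes with ",
             partner_objects[[j]]$kind, " partner at ",
             partner_objects[[j]]$chain, partner_objects[[j]]$resno,
             " (", format(d, digits = 3), " A)")
    }
  }
  for (po in partner_objects) {
    res_xyz <- as.matrix(atoms[atoms$chain == po$chain &
                               atoms$resno == po$resno & !atoms$het,
                               c("x", "y", "z")])
    realized <- min_cross_dist(res_xyz, po$coords)
    if (abs(realized - po$target) > 0.05)
      stop("placement failed: realized ", format(realized, digits = 4),
           " vs target ", po$target)
  }

  ## --- truth table ------------------------------------------------------
  truth <- do.call(rbind, lapply(seq_along(spec$chain_ids), function(ci) {
    data.frame(chain = spec$chain_ids[ci],
               resno = seq_len(lens[ci]),
               class = "Surface", distance = NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(core))
    truth$class[match(paste(core$chain, core$resno),
                      paste(truth$chain, truth$resno))] <- "Core"
  if (!is.null(pl_all)) {
    key_t <- paste(truth$chain, truth$resno)
    for (res_key in unique(paste(pl_all$chain, pl_all$resno))) {
      rows <- pl_all[paste(pl_all$chain, pl_all$resno) == res_key, ]
      best <- which.min(rows$target)
      i <- match(res_key, key_t)
      truth$class[i] <- if (rows$target[best] < 5) {
        paste0(rows$kind[best], " contact")
      } else {
        "Surface"
      }
      truth$distance[i] <- rows$target[best]
    }
  }
  ## residues adjacent to planted features: class not asserted
  if (!is.null(designated) && nrow(designated)) {
    for (k in seq_len(nrow(designated))) {
      ch <- designated$chain[k]; r <- designated$resno[k]
      is_core <- !is.null(core) &&
        any(core$chain == ch & core$resno == r)
      pad <- if (is_core) 2L else 1L
      nb <- truth$chain == ch & abs(truth$resno - r) <= pad &
        truth$resno != r
      truth$class[nb] <- NA_character_
    }
  }

  write_pdb_entry(atoms, path, structure_id = structure_id,
                  resolution = spec$resolution, r_value = spec$r_value)
  invisible(list(path = path, spec = spec, truth = truth))
}
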