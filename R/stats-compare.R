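## Statistical machinery: class-fraction bootstraps, rank-sum distance
## comparisons, template-count-matched control sampling, and the spatial
## pair-proximity permutation test.

#' Structural class fractions of a variant set
#'
#' Fractions are computed over mapped variants only; unmapped variants
#' are counted separately.
#'
#' @param annotated an `annotated_variants` object or its `variants`
#'   data.frame (needs a `structural_class` column).
#' @return list with `fractions` (named over the five classes, summing to
#'   1), `n` (mapped variants) and `n_unmapped`.
#' @export
class_fractions <- function(annotated) {
  v <- if (inherits(annotated, "annotated_variants"))
    annotated$variants else annotated
  cls <- v$structural_class
  mapped <- cls != "Unmapped"
  if (!any(mapped)) stop("no mapped variants")
  tab <- table(factor(cls[mapped], levels = STRUCT_CLASSES))
  fr <- as.numeric(tab) / sum(mapped)
  names(fr) <- STRUCT_CLASSES
  list(fractions = fr, n = sum(mapped), n_unmapped = sum(!mapped))
}

#' Bootstrap standard deviation of class fractions
#'
#' Resamples the mapped variant set with replacement `B` times and
#' reports the standard deviation of each class fraction over the
#' resamples.
#'
#' @inheritParams class_fractions
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return named numeric vector of per-class SDs.
#' @export
bootstrap_sd <- function(annotated, B = 1000, seed = 1L) {
  v <- if (inherits(annotated, "annotated_variants"))
    annotated$variants else annotated
  cls <- v$structural_class[v$structural_class != "Unmapped"]
  n <- length(cls)
  stopifnot(n >= 2)
  rng <- make_rng(seed, "bootstrap")
  idx <- matrix(sample_int_rng(rng, n, n * B, replace = TRUE), nrow = B)
  fr <- vapply(seq_len(B), function(b) {
    as.numeric(table(factor(cls[idx[b, ]], levels = STRUCT_CLASSES))) / n
  }, numeric(length(STRUCT_CLASSES)))
  stats::setNames(apply(fr, 1, stats::sd), STRUCT_CLASSES)
}

#' Two-sided rank-sum comparison of two distance distributions
#'
#' Mann-Whitney/Wilcoxon rank-sum test: the exact null distribution is
#' used when both samples have at most 25 observations and carry no ties;
#' otherwise the tie-corrected normal approximation (with continuity
#' correction). Two samples that are completely tied give p = 1.
#'
#' @param a,b numeric vectors.
#' @return list with `p_value`, `statistic` (rank-sum W of `a`) and
#'   `method`.
#' @export
ranksum_test <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1L)
    return(list(p_value = 1, statistic = length(a) * length(b) / 2,
                method = "degenerate (all values tied)"))
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) <= 25 && length(b) <= 25
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       method = if (exact) "exact" else "normal approximation")
}

#' Template-count-matched control sampling
#'
#' Draws a control set from a neutral pool so that the histogram of
#' per-variant template counts matches a target histogram bin-for-bin
#' (bins are exact integer counts). When a bin of the pool is exhausted,
#' neighbouring bins (+-1, then +-2) are used and logged; sampling is
#' without replacement unless `allow_replacement`.
#'
#' @param pool_counts integer vector: template counts of the pool
#'   variants (names or indices identify them).
#' @param target_counts integer vector: template counts of the target
#'   (e.g. disease) set.
#' @param seed integer seed.
#' @param allow_replacement fall back to sampling with replacement when a
#'   bin and its neighbours cannot supply enough variants.
#' @return list with `indices` (positions into the pool), `fallbacks`
#'   (data.frame of bin substitutions) and `matched_exactly`.
#' @export
matched_template_sampling <- function(pool_counts, target_counts, seed = 1L,
                                      allow_replacement = FALSE) {
  rng <- make_rng(seed, "matched")
  available <- rep(TRUE, length(pool_counts))
  picked <- integer(0)
  fallbacks <- list()
  for (bin in sort(unique(target_counts))) {
    need <- sum(target_counts == bin)
    for (delta in c(0, 1, -1, 2, -2)) {
      if (need == 0) break
      cand <- which(available & pool_counts == bin + delta)
      if (!length(cand)) next
      take <- cand[sample_int_rng(rng, length(cand), min(need, length(cand)))]
      picked <- c(picked, take)
      available[take] <- FALSE
      if (delta != 0)
        fallbacks[[length(fallbacks) + 1L]] <- data.frame(
          bin = bin, used_bin = bin + delta, n = length(take))
      need <- need - length(take)
    }
    if (need > 0) {
      if (!allow_replacement)
        stop("pool exhausted for template-count bin ", bin,
             " (", need, " variants short)")
      cand <- which(pool_counts %in% (bin + -2:2))
      if (!length(cand)) stop("no pool variants near bin ", bin)
      take <- cand[sample_int_rng(rng, length(cand), need, replace = TRUE)]
      picked <- c(picked, take)
      fallbacks[[length(fallbacks) + 1L]] <- data.frame(
        bin = bin, used_bin = NA_integer_, n = need)
    }
  }
  list(indices = picked,
       fallbacks = if (length(fallbacks)) do.call(rbind, fallbacks) else
         data.frame(bin = integer(), used_bin = integer(), n = integer()),
       matched_exactly = !length(fallbacks))
}

#' Spatial proximity of a mutated residue set within one complex
#'
#' Tests whether mutated residues lie closer to each other than random
#' residue sets of the same per-chain composition. The statistic is the
#' mean pairwise distance between residue representative atoms (C-beta;
#' C-alpha for glycine or when C-beta is absent); the null draws, for
#' each chain, the same number of residues uniformly without replacement;
#' the p-value uses add-one smoothing:
#' `p = (1 + #\{null <= observed\}) / (n_perm + 1)`.
#'
#' @param entry a [parse_structure()] result.
#' @param residues data.frame with columns chain, resno (>= 2 rows).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param representative "CB" (default) or "min" for full-atom minimum
#'   distances.
#' @return list with `p_value`, `observed` (mean pairwise distance, A)
#'   and `null_mean`.
#' @export
pair_proximity_test <- function(entry, residues, n_perm = 10000, seed = 1L,
                                representative = c("CB", "min")) {
  representative <- match.arg(representative)
  if (nrow(residues) < 2) stop("need at least 2 mutated residues")
  at <- entry$atoms[entry$atoms$category == "protein", ]
  rep_coords <- function(d) {
    cb <- d[d$atom == "CB", , drop = FALSE]
    if (nrow(cb)) unlist(cb[1, c("x", "y", "z")]) else {
      ca <- d[d$atom == "CA", , drop = FALSE]
      if (nrow(ca)) unlist(ca[1, c("x", "y", "z")]) else
        colMeans(d[, c("x", "y", "z")])
    }
  }
  split_res <- split(at, paste(at$chain, at$resno))
  reps <- t(vapply(split_res, rep_coords, numeric(3)))
  info <- do.call(rbind, lapply(split_res, function(d)
    data.frame(chain = d$chain[1], resno = d$resno[1])))
  key <- paste(info$chain, info$resno)

  want <- paste(residues$chain, residues$resno)
  if (!all(want %in% key))
    stop("residues not in structure: ",
         paste(want[!want %in% key], collapse = ", "))
  obs_idx <- match(want, key)

  atom_sets <- if (representative == "min")
    lapply(split_res, function(d) as.matrix(d[, c("x", "y", "z")])) else NULL
  mean_pair <- function(idx) {
    if (representative == "CB") return(mean(stats::dist(reps[idx, , drop = FALSE])))
    vals <- numeric(0)
    for (i in seq_len(length(idx) - 1)) for (j in (i + 1):length(idx))
      vals <- c(vals, min_cross_dist(atom_sets[[idx[i]]], atom_sets[[idx[j]]]))
    mean(vals)
  }
  observed <- mean_pair(obs_idx)

  rng <- make_rng(seed, "proximity")
  per_chain <- table(residues$chain)
  chain_pool <- lapply(names(per_chain), function(ch) which(info$chain == ch))
  names(chain_pool) <- names(per_chain)
  null_vals <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- unlist(lapply(names(per_chain), function(ch) {
      pool <- chain_pool[[ch]]
      pool[sample_int_rng(rng, length(pool), per_chain[[ch]])]
    }), use.names = FALSE)
    null_vals[i] <- mean_pair(idx)
  }
  list(p_value = (1 + sum(null_vals <= observed)) / (n_perm + 1),
       observed = observed, null_mean = mean(null_vals))
}
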