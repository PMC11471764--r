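#' Build a region scheme for pathway encoding
#'
#' A region scheme assigns every possible non-covalent residue pair to
#' exactly one of `N_r` regions, by the unordered pair of secondary-structure
#' element labels of the two residues; anything outside the named list falls
#' into a catch-all "rest" region.
#'
#' Three flavours:
#' * `"ci2"` -- the five regions used for the chymotrypsin-inhibitor family:
#'   N-terminus--beta3, alpha--loop2, beta1--beta2, beta2--beta3, rest.
#'   Expects element labels `N-terminus`, `alpha`, `beta1..3`, `loop1..2`.
#' * `"barnase"` -- regions enumerated from the 45 unordered pairs of the
#'   nine elements (N-terminus, alpha1..3, beta1..3, loop1..2), keeping the
#'   pairs populated by native contacts; if more than 29 remain, the 29 most
#'   populated are kept and the remainder merged into rest, giving N_r = 30.
#' * `"generic"` -- all unordered pairs (including self-pairs) of the element
#'   labels present in the annotation, plus rest.
#'
#' @param structure A `calpha_structure` whose `ss` column carries the
#'   element label of every residue.
#' @param family `"generic"`, `"ci2"` or `"barnase"`.
#' @param contacts Native contact list (needed to find populated pairs for
#'   `"barnase"`); defaults to [contact_list()] at 7 Angstrom.
#' @return A `region_scheme`: list with `n_regions`, `labels`, the
#'   per-residue `elements`, and the pair-label map.
#' @examples
#' s <- make_toy("lattice", n = 27, ss_segments = 3)
#' default_region_scheme(s)
#' @export
default_region_scheme <- function(structure,
                                  family = c("generic", "ci2", "barnase"),
                                  contacts = NULL) {
  family <- match.arg(family)
  elements <- structure$ss
  if (all(is.na(elements))) {
    stop("structure has no secondary-structure labels; attach an annotation ",
         "with set_ss() (TSV with columns residue_id, label)", call. = FALSE)
  }
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  if (family == "ci2") {
    named <- c("N-terminus|beta3" = "N-terminus-beta3",
               "alpha|loop2"      = "alpha-loop2",
               "beta1|beta2"      = "beta1-beta2",
               "beta2|beta3"      = "beta2-beta3")
    labels <- c(unname(named), "rest")
    map <- stats::setNames(seq_along(named), names(named))
  } else if (family == "barnase") {
    elems <- c("N-terminus", "alpha1", "alpha2", "alpha3",
               "beta1", "beta2", "beta3", "loop1", "loop2")
    if (is.null(contacts)) contacts <- contact_list(structure)
    nc <- contacts[contacts$class == "noncovalent", ]
    keys <- pair_key(elements[nc$i], elements[nc$j])
    all_pairs <- outer(elems, elems, pair_key)
    all_pairs <- unique(all_pairs[upper.tri(all_pairs, diag = TRUE)])
    counts <- table(factor(keys, levels = all_pairs))
    populated <- names(counts)[counts > 0]
    populated <- populated[order(-counts[populated], populated)]
    if (length(populated) > 29L) populated <- populated[1:29]
    labels <- c(gsub("\\|", "-", populated), "rest")
    map <- stats::setNames(seq_along(populated), populated)
  } else {
    elems <- unique(elements[!is.na(elements)])
    all_pairs <- outer(elems, elems, pair_key)
    all_pairs <- unique(all_pairs[upper.tri(all_pairs, diag = TRUE)])
    labels <- c(gsub("\\|", "-", all_pairs), "rest")
    map <- stats::setNames(seq_along(all_pairs), all_pairs)
  }
  structure(
    list(n_regions = length(labels), labels = labels,
         elements = elements, map = map, family = family),
    class = "region_scheme"
  )
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("<region_scheme> (", x$family, ") N_r = ", x$n_regions, " regions:\n",
      sep = "")
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Region index of residue pairs under a scheme
#'
#' @param scheme A `region_scheme`.
#' @param i,j Residue indices (vectors).
#' @return Integer region indices; pairs with unlabeled residues or outside
#'   the named list get the catch-all rest region.
#' @export
assign_region <- function(scheme, i, j) {
  a <- scheme$elements[i]; b <- scheme$elements[j]
  key <- paste(pmin(a, b), pmax(a, b), sep = "|")
  idx <- unname(scheme$map[key])
  idx[is.na(idx)] <- scheme$n_regions
  idx
}

#' Encode a bond-breaking trajectory region-wise
#'
#' The ordered breaking events are mapped to one-hot region indicator rows:
#' an `N_b x N_r` matrix whose row t marks the region of the t-th broken
#' bond, flattened row-wise to a length `N_b * N_r` vector for family-level
#' covariance. Trajectories shorter than `n_bonds` are padded with all-zero
#' rows (logged); longer ones are truncated.
#'
#' @param traj An `unfolding_trajectory`.
#' @param scheme A `region_scheme`.
#' @param n_bonds Common event count `N_b` for the family (default: the
#'   trajectory length). The published protocol uses 110 for the CI2 family
#'   and 200 for Barnase.
#' @param protein_id Identifier carried through to family comparisons.
#' @return A `pathway_encoding`: list with `matrix` (`N_b x N_r`), `flat`,
#'   `regions` (per-event region index), `n_b`, `n_r`, `n_padded`,
#'   `protein_id`.
#' @export
encode_pathway <- function(traj, scheme, n_bonds = NULL, protein_id = "protein") {
  ev <- tibble::as_tibble(traj)
  if (is.null(n_bonds)) n_bonds <- nrow(ev)
  regions <- assign_region(scheme, ev$i, ev$j)
  if (length(regions) > n_bonds) regions <- regions[seq_len(n_bonds)]
  n_padded <- n_bonds - length(regions)
  if (n_padded > 0) {
    message(protein_id, ": trajectory has ", length(regions),
            " events; padding ", n_padded, " all-zero rows to N_b = ", n_bonds)
  }
  m <- matrix(0L, n_bonds, scheme$n_regions)
  m[cbind(seq_along(regions), regions)] <- 1L
  structure(
    list(matrix = m, flat = as.vector(t(m)), regions = regions,
         n_b = n_bonds, n_r = scheme$n_regions, n_padded = n_padded,
         protein_id = protein_id),
    class = "pathway_encoding"
  )
}

#' Compare unfolding pathways across a family
#'
#' Stacks the flattened region-wise encodings of `N_p` proteins into an
#' `N_p x (N_b * N_r)` matrix and computes the between-protein covariance
#' and correlation matrices over the encoding positions. Similar
#' bond-breaking sequences give correlations near 1.
#'
#' @param encodings List of `pathway_encoding` objects sharing `(N_b, N_r)`.
#' @return A `family_comparison`: list with `covariance`, `correlation`
#'   (both `N_p x N_p`, named by protein), and `protein_ids`.
#' @export
family_covariance <- function(encodings) {
  stopifnot(length(encodings) >= 2L)
  nb <- vapply(encodings, function(e) e$n_b, numeric(1))
  nr <- vapply(encodings, function(e) e$n_r, numeric(1))
  if (length(unique(nb)) > 1L || length(unique(nr)) > 1L) {
    stop("encodings disagree on (N_b, N_r); re-encode with a common scheme ",
         "and bond count", call. = FALSE)
  }
  ids <- vapply(encodings, function(e) e$protein_id, character(1))
  x <- do.call(rbind, lapply(encodings, function(e) e$flat))
  rownames(x) <- ids
  cv <- stats::cov(t(x))
  cr <- stats::cor(t(x))
  structure(list(covariance = cv, correlation = cr, protein_ids = ids),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  cat("<family_comparison> ", length(x$protein_ids), " proteins\n", sep = "")
  cat("  mean off-diagonal pathway correlation: ",
      signif(mean(x$correlation[upper.tri(x$correlation)]), 4), "\n", sep = "")
  if (!is.null(x$tm_scores)) {
    cat("  mean off-diagonal TM-score: ",
        signif(mean(x$tm_scores[upper.tri(x$tm_scores)]), 4), "\n", sep = "")
  }
  invisible(x)
}

# Kabsch superposition: rotation R and translations minimizing
# || (A - centA) R - (B - centB) ||; returns the rotated/translated copy of A.
kabsch_superpose <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(a0, b0))
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = r, fit = function(x) sweep(sweep(x, 2, ca) %*% r, 2, cb, "+"))
}

#' TM-score of two structures on a supplied residue correspondence
#'
#' Template-modeling score
#' `TM = max over superpositions (1/L) sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L - 15)^{1/3} - 1.8` (floored at 0.5) and `L` the length of
#' the designated reference structure. The superposition is optimized by the
#' standard iterative-cut Kabsch refinement over the given correspondence:
#' seeds of several fragment lengths are superimposed, scored over all
#' pairs, and iteratively re-fit on the pairs closer than a growing distance
#' cut until the retained set is stable. The alignment itself must be
#' supplied (e.g. from a sequence alignment); no alignment search is done.
#'
#' @param structure_a,structure_b `calpha_structure` objects (or `N x 3`
#'   coordinate matrices).
#' @param correspondence Two-column matrix/data frame of residue indices
#'   (column 1 into `structure_a`, column 2 into `structure_b`). Defaults to
#'   the identity correspondence when lengths match.
#' @param reference `"b"` (default) or `"a"`: whose length normalizes the
#'   score.
#' @return TM-score in (0, 1]; 1 for identical structures.
#' @examples
#' s <- make_toy("helix", n = 20)
#' tm_score(s, s)
#' @export
tm_score <- function(structure_a, structure_b, correspondence = NULL,
                     reference = c("b", "a")) {
  reference <- match.arg(reference)
  xa <- if (is.matrix(structure_a)) structure_a else coords_matrix(structure_a)
  xb <- if (is.matrix(structure_b)) structure_b else coords_matrix(structure_b)
  if (is.null(correspondence)) {
    if (nrow(xa) != nrow(xb)) {
      stop("structures differ in length; supply a correspondence",
           call. = FALSE)
    }
    correspondence <- cbind(seq_len(nrow(xa)), seq_len(nrow(xb)))
  }
  correspondence <- as.matrix(correspondence)
  np <- nrow(correspondence)
  if (np < 3L) stop("need at least 3 corresponding pairs", call. = FALSE)
  a <- xa[correspondence[, 1], , drop = FALSE]
  b <- xb[correspondence[, 2], , drop = FALSE]
  l_ref <- if (reference == "b") nrow(xb) else nrow(xa)
  d0 <- max(1.24 * (max(l_ref, 16) - 15)^(1 / 3) - 1.8, 0.5)

  score_of <- function(fit) {
    d <- sqrt(rowSums((fit(a) - b)^2))
    sum(1 / (1 + (d / d0)^2)) / l_ref
  }
  refine <- function(seed_idx) {
    best <- -Inf
    idx <- seed_idx
    for (d_cut in c(d0, d0 + 1, d0 + 2, d0 + 3)) {
      for (iter in 1:20) {
        if (length(idx) < 3L) break
        sup <- kabsch_superpose(a[idx, , drop = FALSE], b[idx, , drop = FALSE])
        best <- max(best, score_of(sup$fit))
        d <- sqrt(rowSums((sup$fit(a) - b)^2))
        new_idx <- which(d < d_cut)
        if (length(new_idx) < 3L) new_idx <- sort(order(d)[1:3])
        if (identical(new_idx, idx)) break
        idx <- new_idx
      }
    }
    best
  }
  seeds <- list(seq_len(np))
  for (len in unique(pmax(3L, c(np %/% 2L, np %/% 4L)))) {
    if (len >= np) next
    starts <- unique(round(seq(1, np - len + 1, length.out = 6)))
    for (s0 in starts) seeds <- c(seeds, list(s0:(s0 + len - 1L)))
  }
  max(vapply(seeds, refine, numeric(1)))
}

#' Add pairwise TM-scores to a family comparison
#'
#' @param comparison A `family_comparison`.
#' @param structures List of `calpha_structure` objects in the same order as
#'   the encodings that built the comparison.
#' @param correspondences Optional list-of-lists of correspondences; default
#'   identity (structures of equal length, e.g. a synthetic family).
#' @return The comparison with a `tm_scores` matrix added.
#' @export
add_tm_scores <- function(comparison, structures, correspondences = NULL) {
  np <- length(comparison$protein_ids)
  stopifnot(length(structures) == np)
  tm <- diag(1, np)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      corr <- if (!is.null(correspondences)) correspondences[[i]][[j]] else NULL
      tm[i, j] <- tm[j, i] <- tm_score(structures[[i]], structures[[j]], corr)
    }
  }
  dimnames(tm) <- dimnames(comparison$correlation)
  comparison$tm_scores <- tm
  comparison
}
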