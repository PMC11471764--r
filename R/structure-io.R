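#' Read a C-alpha trace from a PDB file
#'
#' Parses ATOM records of a PDB file (via [bio3d::read.pdb()]) and returns a
#' one-row-per-residue tibble holding the C-alpha coordinates and B-factors
#' for a single chain. Only the first model of multi-model files is used;
#' hetero atoms and waters are ignored. Alternate locations are resolved by
#' keeping the highest-occupancy record (ties go to altloc "A"); insertion
#' codes are kept in file order.
#'
#' Residues are indexed 1..N internally in chain order; consecutive entries
#' are treated as backbone neighbours even across numbering gaps (a warning
#' is emitted when a gap is detected).
#'
#' @param pdb_source Path to a PDB file, or a character vector of PDB-format
#'   text lines.
#' @param chain Chain identifier to extract (single letter). Mandatory when
#'   the file has more than one chain.
#' @param ss Optional secondary-structure annotation: a data frame with
#'   columns `residue_id` and `label`, attached as the `ss` column.
#' @return A `calpha_structure`: a tibble with columns `residue` (1-based
#'   index), `residue_id` (author numbering), `x`, `y`, `z` (Angstrom),
#'   `b_factor` (Angstrom^2), `chain`, and `ss` (label or `NA`).
#' @examples
#' pdb <- make_toy("helix", n = 12)
#' path <- tempfile(fileext = ".pdb")
#' write_calpha_pdb(pdb, path)
#' read_calpha(path, chain = "A")
#' @export
read_calpha <- function(pdb_source, chain = NULL, ss = NULL) {
  path <- pdb_source
  if (length(pdb_source) > 1L || grepl("\n", pdb_source[1]) ||
      grepl("^(ATOM|HETATM|HEADER|REMARK|MODEL)", pdb_source[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb_source, "\n", fixed = TRUE)), path)
    on.exit(unlink(path), add = TRUE)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  atoms <- tibble::as_tibble(pdb$atom)
  atoms <- dplyr::filter(atoms, .data$type == "ATOM", .data$elety == "CA")
  if (nrow(atoms) == 0L) {
    stop("no CA ATOM records found in PDB source", call. = FALSE)
  }
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      stop("PDB source has multiple chains (", paste(chains, collapse = ", "),
           "); supply `chain`", call. = FALSE)
    }
    chain <- chains[1]
  }
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "), call. = FALSE)
  }
  atoms <- dplyr::filter(atoms, .data$chain == !!chain)

  # altloc resolution: keep highest occupancy, ties -> 'A' (then file order)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms <- atoms |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::group_by(.data$resno, .data$insert) |>
    dplyr::arrange(dplyr::desc(.data$o),
                   .data$alt != "A", .data$alt, .data$.file_order,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.file_order)

  gaps <- diff(atoms$resno)
  if (any(gaps > 1L)) {
    warning("chain '", chain, "' has ", sum(gaps > 1L),
            " numbering gap(s); consecutive entries are treated as ",
            "backbone neighbours", call. = FALSE)
  }

  out <- tibble::tibble(
    residue = seq_len(nrow(atoms)),
    residue_id = atoms$resno,
    x = atoms$x, y = atoms$y, z = atoms$z,
    b_factor = atoms$b,
    chain = chain,
    ss = NA_character_
  )
  out <- new_calpha_structure(out)
  if (!is.null(ss)) out <- set_ss(out, ss)
  out
}

new_calpha_structure <- function(df) {
  stopifnot(all(c("residue", "x", "y", "z") %in% names(df)))
  if (nrow(df) < 3L) stop("a structure needs at least 3 residues", call. = FALSE)
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  class(df) <- c("calpha_structure", class(tibble::tibble()))
  df
}

#' Attach a secondary-structure annotation to a structure
#'
#' @param structure A `calpha_structure`.
#' @param ss A data frame with columns `residue_id` and `label` (e.g. read
#'   from a two-column TSV), or a character vector of length N in residue
#'   order.
#' @return The structure with its `ss` column filled in.
#' @export
set_ss <- function(structure, ss) {
  if (is.character(ss) && length(ss) == nrow(structure)) {
    structure$ss <- ss
    return(structure)
  }
  stopifnot(is.data.frame(ss), all(c("residue_id", "label") %in% names(ss)))
  idx <- match(structure$residue_id, ss$residue_id)
  structure$ss <- ss$label[idx]
  structure
}

#' Extract the N x 3 coordinate matrix of a structure
#' @param structure A `calpha_structure`.
#' @return Numeric matrix with one row per residue.
#' @export
coords_matrix <- function(structure) {
  m <- as.matrix(structure[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Write a C-alpha structure as a minimal PDB file
#'
#' Emits one CA ATOM record per residue so that fixtures and intermediate
#' states round-trip through [read_calpha()].
#'
#' @param structure A `calpha_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calpha_pdb <- function(structure, path) {
  chain <- structure$chain %||% "A"
  if (all(is.na(chain))) chain <- "A"
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    structure$residue, substr(chain, 1, 1), structure$residue_id,
    structure$x, structure$y, structure$z, 1.00,
    ifelse(is.na(structure$b_factor), 0, structure$b_factor)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Enumerate the elastic-network bond list of a structure
#'
#' Backbone pairs (consecutive residues, always bonded) and non-covalent
#' contact pairs: residues i, j with |i - j| > 1 whose native C-alpha
#' separation is below the cutoff.
#'
#' @param structure A `calpha_structure`.
#' @param r_c Contact cutoff distance in Angstrom (default 7).
#' @return A tibble with columns `i`, `j` (1-based residue indices, i < j),
#'   `dist` (native separation, Angstrom) and `class`
#'   (`"backbone"` or `"noncovalent"`).
#' @examples
#' s <- make_toy("lattice", n = 27)
#' contact_list(s)
#' @export
contact_list <- function(structure, r_c = 7) {
  stopifnot(r_c > 0)
  xyz <- coords_matrix(structure)
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  backbone <- (j - i) == 1L
  keep <- backbone | d[idx] < r_c
  tibble::tibble(
    i = i[keep], j = j[keep], dist = d[idx][keep],
    class = ifelse(backbone[keep], "backbone", "noncovalent")
  ) |>
    dplyr::arrange(.data$i, .data$j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
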