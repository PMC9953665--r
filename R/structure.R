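## PDB-format coordinate parsing, inter-chain contact and metal-coordination
## detection, and joining of variant positions to interface tables.

#' Parse PDB-format coordinates
#'
#' Reads ATOM/HETATM records (fixed columns). Multi-model files are reduced
#' to one model (default the first); alternate locations keep the
#' highest-occupancy conformer of each atom.
#'
#' @param input path to a PDB file, or the file's lines as a character
#'   vector.
#' @param model model number to keep (default: first encountered).
#' @return object of class `StructureModel`: data.frame `atoms` with
#'   `chain`, `resnum`, `resname`, `atom`, `element`, `x`, `y`, `z`,
#'   `occupancy`, `het`; plus `model_id`.
#' @export
load_structure <- function(input, model = NULL) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input)
           else input
  cur_model <- 0L
  rows <- list()
  for (li in seq_along(lines)) {
    ln <- lines[li]
    tag <- substr(ln, 1, 6)
    if (startsWith(tag, "MODEL")) {
      cur_model <- suppressWarnings(as.integer(substr(ln, 7, 14)))
      if (is.na(cur_model)) stop("malformed MODEL record at line ", li)
      next
    }
    if (tag %in% c("ATOM  ", "HETATM")) {
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      resnum <- suppressWarnings(as.integer(substr(ln, 23, 26)))
      if (anyNA(c(x, y, z)) || is.na(resnum))
        stop("malformed coordinate record at line ", li)
      occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
      elem <- trimws(substr(ln, 77, 78))
      atom <- trimws(substr(ln, 13, 16))
      if (elem == "")   # infer element from the atom name when absent
        elem <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atom)
      rows[[length(rows) + 1L]] <- data.frame(
        model = cur_model, chain = substr(ln, 22, 22), resnum = resnum,
        resname = trimws(substr(ln, 18, 20)), atom = atom,
        altloc = substr(ln, 17, 17),
        element = toupper(elem), x = x, y = y, z = z,
        occupancy = ifelse(is.na(occ), 1, occ),
        het = tag == "HETATM", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no ATOM/HETATM record found")
  atoms <- do.call(rbind, rows)
  keep_model <- if (is.null(model)) atoms$model[1L] else model
  atoms <- atoms[atoms$model == keep_model, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("requested model not present")
  # altloc: keep the highest-occupancy conformer per (chain, resnum, atom)
  key <- paste(atoms$chain, atoms$resnum, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occupancy)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms$model <- NULL
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = keep_model),
            class = "StructureModel")
}

pair_distances <- function(a, b) {
  dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Inter-chain residue contacts
#'
#' A residue pair on different chains is a contact when any heavy-atom
#' (element != H) pair between them lies within `cutoff`; the minimum
#' distance is reported. Pairs are ordered canonically (chain_i < chain_j or
#' equal chain with resnum_i < resnum_j).
#'
#' @param s a `StructureModel`.
#' @param cutoff distance in Angstrom (default 4.0).
#' @param structure_id provenance label for the output rows.
#' @return `ContactTable` data.frame: `chain_i`, `resnum_i`, `resname_i`,
#'   `chain_j`, `resnum_j`, `resname_j`, `min_distance`, `kind`, `structure`.
#' @export
inter_chain_contacts <- function(s, cutoff = 4.0, structure_id = NA_character_) {
  empty <- data.frame(chain_i = character(0), resnum_i = integer(0),
                      resname_i = character(0), chain_j = character(0),
                      resnum_j = integer(0), resname_j = character(0),
                      min_distance = numeric(0), kind = character(0),
                      structure = character(0), stringsAsFactors = FALSE)
  heavy <- s$atoms[s$atoms$element != "H" & !s$atoms$het, , drop = FALSE]
  chains <- sort(unique(heavy$chain))   # canonical (chain_i < chain_j) order
  if (length(chains) < 2L) return(empty)
  out <- list()
  for (ci in seq_along(chains)) for (cj in seq_along(chains)) {
    if (cj <= ci) next
    a <- heavy[heavy$chain == chains[ci], , drop = FALSE]
    b <- heavy[heavy$chain == chains[cj], , drop = FALSE]
    d <- pair_distances(a, b)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    key <- paste(a$resnum[hit[, 1]], b$resnum[hit[, 2]], sep = "|")
    for (kk in unique(key)) {
      idx <- which(key == kk)
      i1 <- hit[idx[1], 1]; j1 <- hit[idx[1], 2]
      out[[length(out) + 1L]] <- data.frame(
        chain_i = chains[ci], resnum_i = a$resnum[i1],
        resname_i = a$resname[i1], chain_j = chains[cj],
        resnum_j = b$resnum[j1], resname_j = b$resname[j1],
        min_distance = min(d[hit[idx, 1, drop = FALSE] +
                             (hit[idx, 2, drop = FALSE] - 1L) * nrow(d)]),
        kind = "interface", structure = structure_id,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chain_i, res$resnum_i, res$chain_j, res$resnum_j), ] ->
    res
  rownames(res) <- NULL
  class(res) <- c("ContactTable", "data.frame")
  res
}

#' Metal-coordinating residues
#'
#' A residue coordinates a metal when any of its side/backbone N, O or S
#' atoms lies within `cutoff` of a metal atom (HETATM with element in
#' `metals`).
#'
#' @param s a `StructureModel`.
#' @param metals element symbols treated as metals.
#' @param cutoff coordination distance in Angstrom (default 2.8).
#' @param structure_id provenance label.
#' @return `ContactTable` rows with `kind = "metal-coordination"`; `chain_j`/
#'   `resnum_j` identify the metal atom.
#' @export
metal_coordination <- function(s, metals = c("ZN", "FE", "CA", "MG", "MN",
                                             "CU", "NI", "CO"),
                               cutoff = 2.8, structure_id = NA_character_) {
  empty <- data.frame(chain_i = character(0), resnum_i = integer(0),
                      resname_i = character(0), chain_j = character(0),
                      resnum_j = integer(0), resname_j = character(0),
                      min_distance = numeric(0), kind = character(0),
                      structure = character(0), stringsAsFactors = FALSE)
  metal_atoms <- s$atoms[s$atoms$het & toupper(s$atoms$element) %in% metals, ,
                         drop = FALSE]
  donors <- s$atoms[!s$atoms$het & s$atoms$element %in% c("N", "O", "S"), ,
                    drop = FALSE]
  if (nrow(metal_atoms) == 0L || nrow(donors) == 0L) return(empty)
  d <- pair_distances(donors, metal_atoms)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  key <- paste(donors$chain[hit[, 1]], donors$resnum[hit[, 1]],
               metal_atoms$chain[hit[, 2]], metal_atoms$resnum[hit[, 2]],
               sep = "|")
  out <- list()
  for (kk in unique(key)) {
    idx <- which(key == kk)
    i1 <- hit[idx[1], 1]; j1 <- hit[idx[1], 2]
    out[[length(out) + 1L]] <- data.frame(
      chain_i = donors$chain[i1], resnum_i = donors$resnum[i1],
      resname_i = donors$resname[i1], chain_j = metal_atoms$chain[j1],
      resnum_j = metal_atoms$resnum[j1], resname_j = metal_atoms$resname[j1],
      min_distance = min(d[cbind(hit[idx, 1], hit[idx, 2])]),
      kind = "metal-coordination", structure = structure_id,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chain_i, res$resnum_i), ]
  rownames(res) <- NULL
  class(res) <- c("ContactTable", "data.frame")
  res
}

#' Join variant positions to interface contacts across structures
#'
#' Maps each contact residue to a preproinsulin position via a numbering map
#' and reports, for every mapped position hit by a variant, per-structure
#' presence marks (the `x` columns of the paper-style interface tables).
#'
#' @param contacts a `ContactTable` or list of them (rows must carry their
#'   `structure` label).
#' @param numbering_map data.frame with `chain`, `resnum`, `prepro` giving
#'   the preproinsulin position of each structure residue.
#' @param variant_positions integer preproinsulin positions carrying
#'   variants.
#' @return data.frame: `prepro_position`, `region`, `chain_index`, one
#'   logical column per structure, and `unmapped_residues` attribute listing
#'   contact residues absent from the map.
#' @export
variant_interface_table <- function(contacts, numbering_map, variant_positions) {
  if (is.data.frame(contacts)) contacts <- list(contacts)
  all_ct <- do.call(rbind, lapply(contacts, as.data.frame))
  if (is.null(all_ct) || nrow(all_ct) == 0L) {
    out <- data.frame(prepro_position = integer(0), region = character(0),
                      chain_index = integer(0))
    attr(out, "unmapped_residues") <- character(0)
    return(out)
  }
  res_long <- rbind(
    data.frame(chain = all_ct$chain_i, resnum = all_ct$resnum_i,
               structure = all_ct$structure, stringsAsFactors = FALSE),
    data.frame(chain = all_ct$chain_j, resnum = all_ct$resnum_j,
               structure = all_ct$structure, stringsAsFactors = FALSE))
  m <- merge(res_long, numbering_map, by = c("chain", "resnum"),
             all.x = TRUE, sort = FALSE)
  unmapped <- unique(paste0(m$chain[is.na(m$prepro)], ":",
                            m$resnum[is.na(m$prepro)]))
  if (length(unmapped) > 0L && any(is.na(m$prepro)))
    warning("contact residues missing from the numbering map: ",
            paste(unmapped, collapse = ", "))
  m <- m[!is.na(m$prepro), , drop = FALSE]
  structures <- unique(all_ct$structure)
  pos <- sort(unique(intersect(m$prepro, variant_positions)))
  if (length(pos) == 0L) {
    out <- data.frame(prepro_position = integer(0), region = character(0),
                      chain_index = integer(0))
    for (st in structures) out[[st]] <- logical(0)
    attr(out, "unmapped_residues") <- unmapped
    return(out)
  }
  ch <- prepro_to_chain(pos)
  out <- data.frame(prepro_position = pos, region = ch$region,
                    chain_index = ch$chain_index, stringsAsFactors = FALSE)
  for (st in structures)
    out[[st]] <- vapply(pos, function(p)
      any(m$prepro == p & m$structure == st), logical(1))
  attr(out, "unmapped_residues") <- unmapped
  out
}

#' Write a contact table TSV
#' @param contacts a `ContactTable`.
#' @param path output path.
#' @export
write_contacts_tsv <- function(contacts, path) {
  write_tsv_report(as.data.frame(contacts), path,
                   c("chain_i", "resnum_i", "resname_i", "chain_j", "resnum_j",
                     "resname_j", "min_distance", "kind", "structure"))
}
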