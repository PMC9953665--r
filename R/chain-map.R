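## Preproinsulin <-> mature-chain numbering and protein-level utilities.

#' Default preproinsulin chain map
#'
#' Regions of the 110-residue preproinsulin: signal peptide 1-24, B-chain
#' 25-54, dibasic B/C linker 55-56, C-peptide 57-87, dibasic C/A linker 88-89,
#' A-chain 90-110 (1-based inclusive). Alternate species maps can be supplied
#' with the same columns.
#'
#' @return data.frame with columns `region`, `start`, `end`.
#' @export
chain_map <- function() {
  map <- data.frame(
    region = c("signal", "B", "BC_link", "C", "CA_link", "A"),
    start = c(1L, 25L, 55L, 57L, 88L, 90L),
    end = c(24L, 54L, 56L, 87L, 89L, 110L),
    stringsAsFactors = FALSE)
  validate_chain_map(map)
  map
}

validate_chain_map <- function(map) {
  stopifnot(all(c("region", "start", "end") %in% names(map)))
  if (any(map$start[-1L] != map$end[-nrow(map)] + 1L) || map$start[1L] != 1L)
    stop("chain map regions must be disjoint, ordered and cover 1..end")
  invisible(map)
}

#' Convert a preproinsulin position to chain numbering
#'
#' @param position 1-based preproinsulin residue index (vectorised).
#' @param map a chain map (see [chain_map()]).
#' @return data.frame with `position`, `region`, `chain_index`
#'   (chain-local 1-based index, e.g. 34 -> B/10).
#' @export
prepro_to_chain <- function(position, map = chain_map()) {
  validate_chain_map(map)
  if (any(position < map$start[1L]) || any(position > map$end[nrow(map)]))
    stop("position outside 1..", map$end[nrow(map)])
  i <- findInterval(position, map$start)
  data.frame(position = as.integer(position), region = map$region[i],
             chain_index = as.integer(position - map$start[i] + 1L),
             stringsAsFactors = FALSE)
}

#' Convert chain numbering back to a preproinsulin position
#'
#' Inverse of [prepro_to_chain()].
#' @param region region label(s) from the map.
#' @param chain_index chain-local 1-based index (vectorised with `region`).
#' @param map a chain map.
#' @return integer preproinsulin position(s).
#' @export
chain_to_prepro <- function(region, chain_index, map = chain_map()) {
  validate_chain_map(map)
  i <- match(region, map$region)
  if (anyNA(i)) stop("unknown region label")
  pos <- map$start[i] + as.integer(chain_index) - 1L
  if (any(pos > map$end[i]) || any(chain_index < 1L))
    stop("chain index outside region")
  as.integer(pos)
}

#' Human preproinsulin amino-acid sequence
#'
#' The 110-residue primary translation product (UniProt P01308), assembled as
#' signal peptide (1-24), B-chain (25-54), RR linker (55-56), C-peptide
#' (57-87), KR linker (88-89) and A-chain (90-110).
#'
#' @return single amino-acid string of length 110.
#' @export
preproinsulin_sequence <- function() {
  paste0("MALWMRLLPLLALLALWGPDPAAA",          # signal 1-24
         "FVNQHLCGSHLVEALYLVCGERGFFYTPKT",    # B 25-54
         "RR",                                # 55-56
         "EAEDLQVGQVELGGGPGAGSLQPLALEGSLQ",   # C 57-87
         "KR",                                # 88-89
         "GIVEQCCTSICSLYQLENYCN")             # A 90-110
}

#' Find dibasic (K/R pair) cleavage sites in a protein
#'
#' Reports every 1-based index `i` where residues `i` and `i+1` are both K or
#' R; overlapping pairs are all reported.
#'
#' @param protein amino-acid string.
#' @return integer vector of positions.
#' @export
find_dibasic_sites <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  if (length(aa) < 2L) return(integer(0))
  basic <- aa %in% c("K", "R")
  which(basic[-length(basic)] & basic[-1L])
}

#' Length of the longest common N-terminal prefix of two proteins
#'
#' @param protein_a,protein_b amino-acid strings.
#' @return integer prefix length.
#' @export
longest_common_nterminal_prefix <- function(protein_a, protein_b) {
  a <- strsplit(protein_a, "")[[1L]]
  b <- strsplit(protein_b, "")[[1L]]
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}
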