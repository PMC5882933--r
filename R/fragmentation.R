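## Fragmentation: capped fragments, concaps, and two-body (Gconcap) pairs.
##
## The chain is cut through backbone peptide bonds. Fragment i (i = 2..N-1
## per continuous segment) contains residues i-1, i, i+1 in full; concap i
## (i = 2..N-2) contains residues i, i+1 in full. Every cut C-N bond is
## saturated by a hydrogen link atom placed along the cut-bond direction at
## the donor element's standard X-H bond length. With full-residue caps the
## multiplicity identity (#fragments - #concaps = 1 per atom) holds exactly,
## which is what makes the concap deduction in the charge assembly exact.

# index of a named backbone atom within residue r
bb_atom <- function(structure, r, name) {
  i <- which(structure$atoms$residue_index == r & structure$atoms$name == name)
  if (length(i) != 1L)
    stop(sprintf("residue %d has no unique atom '%s'", r, name))
  i
}

atom_pos <- function(structure, idx) {
  unlist(structure$atoms[idx, c("x", "y", "z")], use.names = FALSE)
}

#' Place a hydrogen link atom along a cut bond
#'
#' The link H sits on the donor->removed unit vector at the standard bond
#' length for the donor element (C-H 1.090 A, N-H 1.010 A).
#'
#' @param donor_pos,removed_pos 3-vectors (Angstrom).
#' @param donor_element "C" or "N".
#' @return 3-vector position of the link hydrogen.
#' @export
place_link_hydrogen <- function(donor_pos, removed_pos, donor_element) {
  if (!donor_element %in% names(.LINK_BOND))
    stop("no link-atom bond length for donor element ", donor_element)
  v <- removed_pos - donor_pos
  if (vnorm(v) < 1e-8) stop("zero-length cut-bond vector")
  donor_pos + .LINK_BOND[[donor_element]] * vunit(v)
}

# build the link-atom record for the cut bond donor_idx -- removed_idx
.link_record <- function(structure, donor_idx, removed_idx) {
  pos <- place_link_hydrogen(atom_pos(structure, donor_idx),
                             atom_pos(structure, removed_idx),
                             structure$atoms$element[donor_idx])
  data.frame(x = pos[1], y = pos[2], z = pos[3],
             donor_idx = donor_idx, removed_idx = removed_idx,
             label = paste0("H@", donor_idx, "-", removed_idx),
             stringsAsFactors = FALSE)
}

.no_links <- function() {
  data.frame(x = numeric(), y = numeric(), z = numeric(),
             donor_idx = integer(), removed_idx = integer(),
             label = character(), stringsAsFactors = FALSE)
}

new_subsystem <- function(structure, id, kind, residues, links,
                          center = residues) {
  atom_idx <- residue_atoms(structure, residues)
  net <- sum(vapply(residues, function(r) {
    residue_formal_charge(
      structure$atoms$resname[match(r, structure$atoms$residue_index)],
      structure$variants[r])
  }, numeric(1)))
  structure(list(id = id, kind = kind, center = center,
                 residues = residues, atom_idx = atom_idx,
                 link_atoms = links, net_charge = net),
            class = "Subsystem")
}

#' @export
print.Subsystem <- function(x, ...) {
  cat(sprintf("Subsystem %s [%s]: residues %s, %d atoms + %d link H, q=%+d\n",
              x$id, x$kind, paste(x$residues, collapse = ","),
              length(x$atom_idx), nrow(x$link_atoms), x$net_charge))
  invisible(x)
}

# cut at the peptide bond C(r-1) - N(r): donor is N(r) (removing C(r-1))
# or donor C(r) removing N(r+1), depending on side
.cut_nside <- function(structure, r) {
  .link_record(structure, bb_atom(structure, r, "N"),
               bb_atom(structure, r - 1L, "C"))
}
.cut_cside <- function(structure, r) {
  .link_record(structure, bb_atom(structure, r, "C"),
               bb_atom(structure, r + 1L, "N"))
}

#' Build the capped fragments of a structure
#'
#' One fragment per residue i = 2..N-1 of each continuous segment, spanning
#' residues i-1..i+1 with link hydrogens at the two distal peptide-bond
#' cuts (absent at the segment termini). A segment with fewer than three
#' residues falls back, with a warning, to a single whole-segment fragment.
#'
#' @param structure a Structure.
#' @return list of Subsystem objects of kind "fragment".
#' @export
build_fragments <- function(structure) {
  frags <- list()
  for (seg in chain_segments(structure)) {
    s <- seg[1]; e <- seg[length(seg)]
    if (length(seg) < 3L) {
      warning(sprintf(paste0("segment %d-%d has fewer than 3 residues; ",
                             "using a single whole-segment fragment"), s, e))
      frags[[length(frags) + 1L]] <-
        new_subsystem(structure, sprintf("frag_%d", s), "fragment",
                      seg, .no_links(), center = s)
      next
    }
    for (i in (s + 1L):(e - 1L)) {
      links <- .no_links()
      if (i - 1L > s) links <- rbind(links, .cut_nside(structure, i - 1L))
      if (i + 1L < e) links <- rbind(links, .cut_cside(structure, i + 1L))
      frags[[length(frags) + 1L]] <-
        new_subsystem(structure, sprintf("frag_%d", i), "fragment",
                      (i - 1L):(i + 1L), links, center = i)
    }
  }
  frags
}

#' Build the concaps of a structure
#'
#' One concap per residue i = 2..N-2 of each continuous segment, spanning
#' residues i, i+1 with link hydrogens at both peptide-bond cuts. Each
#' concap link atom coincides geometrically with the equivalent link atom of
#' a neighboring fragment (matched by cut-bond label at fitting time).
#'
#' @param structure a Structure.
#' @return list of Subsystem objects of kind "concap".
#' @export
build_concaps <- function(structure) {
  caps <- list()
  for (seg in chain_segments(structure)) {
    s <- seg[1]; e <- seg[length(seg)]
    if (length(seg) < 4L) next
    for (i in (s + 1L):(e - 2L)) {
      links <- rbind(.cut_nside(structure, i), .cut_cside(structure, i + 1L))
      caps[[length(caps) + 1L]] <-
        new_subsystem(structure, sprintf("concap_%d", i), "concap",
                      i:(i + 1L), links, center = i)
    }
  }
  caps
}

#' Find spatially close non-neighboring residue pairs
#'
#' All residue pairs (i, j) with j >= i+3 whose minimum interatomic distance
#' (all atoms, hydrogens included) is at most `lambda`, sorted by (i, j).
#'
#' @param structure a Structure.
#' @param lambda distance threshold, Angstrom.
#' @return list of `list(i, j, dist)` entries.
#' @export
find_two_body_pairs <- function(structure, lambda) {
  stopifnot(lambda >= 0)
  pairs <- list()
  if (structure$nres < 4L || lambda <= 0) return(pairs)
  xyz <- coords(structure)
  ridx <- structure$atoms$residue_index
  d <- sqrt(cross_dist2(xyz, xyz))
  for (i in seq_len(structure$nres - 3L)) {
    for (j in (i + 3L):structure$nres) {
      dmin <- min(d[ridx == i, ridx == j])
      if (dmin <= lambda)
        pairs[[length(pairs) + 1L]] <- list(i = i, j = j, dist = dmin)
    }
  }
  pairs
}

# capped single residue: residue r with link H at each existing backbone cut
.capped_residue <- function(structure, r, id) {
  seg <- Find(function(s) r %in% s, chain_segments(structure))
  links <- .no_links()
  if (r > seg[1]) links <- rbind(links, .cut_nside(structure, r))
  if (r < seg[length(seg)]) links <- rbind(links, .cut_cside(structure, r))
  new_subsystem(structure, id, "monomer", r, links, center = r)
}

#' Build the two-body (Gconcap) subsystems for a pair list
#'
#' For each pair (i, j) builds three capped subsystems: the combined
#' Gconcap A_iA_j and the isolated monomers A_i, A_j, each saturated with
#' link hydrogens at its backbone cuts.
#'
#' @param structure a Structure.
#' @param pairs output of [find_two_body_pairs()].
#' @return list of `list(i, j, dist, pair, mono_i, mono_j)` entries.
#' @export
build_pair_subsystems <- function(structure, pairs) {
  lapply(pairs, function(p) {
    mi <- .capped_residue(structure, p$i, sprintf("mono_%d", p$i))
    mj <- .capped_residue(structure, p$j, sprintf("mono_%d", p$j))
    comb <- new_subsystem(structure, sprintf("pair_%d_%d", p$i, p$j),
                          "pair", c(p$i, p$j),
                          rbind(mi$link_atoms, mj$link_atoms),
                          center = c(p$i, p$j))
    list(i = p$i, j = p$j, dist = p$dist,
         pair = comb, mono_i = mi, mono_j = mj)
  })
}

#' Background point charges for an embedded subsystem calculation
#'
#' Positions and reference charges of every parent atom NOT in the
#' subsystem. Link atoms never appear as background. Extra charges (e.g.
#' PB-induced surface charges) can be appended by the caller.
#'
#' @param structure a Structure.
#' @param subsystem a Subsystem.
#' @param reference a ChargeSet aligned to `structure`.
#' @return data.frame with columns x, y, z, q.
#' @export
background_charges <- function(structure, subsystem, reference) {
  idx <- setdiff(seq_len(n_atoms(structure)), subsystem$atom_idx)
  a <- structure$atoms[idx, , drop = FALSE]
  data.frame(x = a$x, y = a$y, z = a$z, q = reference$charges[idx])
}

#' Per-atom fragment/concap multiplicity check
#'
#' For every parent atom counts the fragments and concaps containing it;
#' the difference must be exactly 1 for the concap deduction to be exact.
#'
#' @param structure a Structure.
#' @param fragments,concaps subsystem lists.
#' @return integer vector of per-atom multiplicities.
#' @export
multiplicity_check <- function(structure, fragments, concaps) {
  m <- integer(n_atoms(structure))
  for (f in fragments) m[f$atom_idx] <- m[f$atom_idx] + 1L
  for (cc in concaps) m[cc$atom_idx] <- m[cc$atom_idx] - 1L
  m
}
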