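## Structure / ChargeSet data model and PDB/PQR io.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

element_from_name <- function(name) {
  el <- sub("^[0-9]*", "", trimws(name))
  el <- substr(el, 1, 1)
  if (!all(el %in% .ELEMENTS)) {
    stop("cannot infer element for atom name(s): ",
         paste(unique(name[!el %in% .ELEMENTS]), collapse = ", "))
  }
  el
}

# Terminus variant of one residue inferred from the atoms it carries.
infer_variant <- function(atom_names) {
  if ("OXT" %in% atom_names) {
    if ("HXT" %in% atom_names) "cneu" else "czwit"
  } else if ("H3" %in% atom_names) {
    "nzwit"
  } else if ("H1" %in% atom_names) {
    "nneu"
  } else "mid"
}

#' Construct a Structure object
#'
#' A `Structure` bundles an ordered atom table (one row per atom), the
#' partition of atoms into residues (1-based contiguous `residue_index`),
#' per-residue terminus variants, and chain breaks (residue indices i with no
#' peptide bond i -> i+1).
#'
#' @param atoms data.frame with columns serial, name, element, resname,
#'   residue_index, x, y, z and optionally radius.
#' @param chain_breaks integer vector of residue indices followed by a break.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, chain_breaks = integer()) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resname", "residue_index",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  ridx <- atoms$residue_index
  nres <- if (nrow(atoms)) max(ridx) else 0L
  if (nrow(atoms) && !identical(sort(unique(ridx)), seq_len(nres)))
    stop("residue indices must be contiguous 1..N")
  if (!"radius" %in% names(atoms)) atoms$radius <- vdw_radius(atoms$element)
  variants <- vapply(seq_len(nres), function(i) {
    infer_variant(atoms$name[ridx == i])
  }, character(1))
  structure(list(atoms = atoms, nres = nres,
                 chain_breaks = as.integer(chain_breaks),
                 variants = variants),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues (%s)%s\n",
              nrow(x$atoms), x$nres,
              paste(x$atoms$resname[!duplicated(x$atoms$residue_index)],
                    collapse = "-"),
              if (length(x$chain_breaks))
                sprintf(", %d chain break(s)", length(x$chain_breaks))
              else ""))
  invisible(x)
}

#' Number of atoms / residues
#' @param structure a Structure.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(structure) structure$nres

#' Atom coordinates as a matrix
#' @param structure a Structure.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Parent-atom indices of one residue
#' @param structure a Structure.
#' @param i residue index.
#' @export
residue_atoms <- function(structure, i) {
  which(structure$atoms$residue_index %in% i)
}

# continuous segments (runs of residues with no chain break inside)
chain_segments <- function(structure) {
  brk <- sort(structure$chain_breaks)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, structure$nres)
  Map(function(s, e) s:e, starts, ends)
}

#' Total formal charge of a structure
#' @param structure a Structure.
#' @export
formal_charge <- function(structure) {
  sum(vapply(seq_len(structure$nres), function(i) {
    residue_formal_charge(
      structure$atoms$resname[match(i, structure$atoms$residue_index)],
      structure$variants[i])
  }, numeric(1)))
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records of standard amino-acid residues. Non amino-acid
#' HETATM records are dropped with a warning listing them. Alternate
#' locations are resolved to the highest-occupancy conformer. Residues are
#' renumbered contiguously 1..N in file order; chain breaks are recorded
#' where the chain identifier changes or the C(i)-N(i+1) distance is
#' >= 1.8 Angstrom.
#'
#' @param path PDB file path.
#' @return a [new_structure()] Structure.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)

  fld <- function(a, b) trimws(substr(lines, a, b))
  resname <- fld(18, 20)
  bad <- !(resname %in% .AA3)
  if (any(bad)) {
    warning("dropping ", sum(bad), " non amino-acid record(s): ",
            paste(unique(resname[bad]), collapse = ", "))
    lines <- lines[!bad]
    if (!length(lines)) stop("no amino-acid atoms in ", path)
    resname <- resname[!bad]
  }
  fld <- function(a, b) trimws(substr(lines, a, b))
  name <- fld(13, 16)
  altloc <- fld(17, 17)
  chain <- fld(22, 22)
  resseq <- fld(23, 26)
  icode <- fld(27, 27)
  x <- as.numeric(fld(31, 38))
  y <- as.numeric(fld(39, 46))
  z <- as.numeric(fld(47, 54))
  occ <- suppressWarnings(as.numeric(fld(55, 60)))
  occ[is.na(occ)] <- 1
  el <- fld(77, 78)
  no_el <- el == ""
  if (any(no_el)) el[no_el] <- element_from_name(name[no_el])

  # resolve altlocs: keep highest occupancy per (chain, resseq, icode, name)
  key <- paste(chain, resseq, icode, name, sep = "|")
  ord <- order(key, -occ)
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])
  df <- data.frame(name = name[sel], element = el[sel],
                   resname = resname[sel], chain = chain[sel],
                   resseq = resseq[sel], icode = icode[sel],
                   x = x[sel], y = y[sel], z = z[sel],
                   stringsAsFactors = FALSE)

  rkey <- paste(df$chain, df$resseq, df$icode, sep = "|")
  ridx <- match(rkey, unique(rkey))
  df$residue_index <- ridx
  df$serial <- seq_len(nrow(df))
  nres <- max(ridx)

  # backbone completeness
  for (i in seq_len(nres)) {
    nm <- df$name[ridx == i]
    miss <- setdiff(c("N", "CA", "C"), nm)
    if (length(miss))
      stop(sprintf("residue %d (%s) is missing backbone atom(s): %s",
                   i, df$resname[match(i, ridx)],
                   paste(miss, collapse = ", ")))
  }

  # chain breaks: chain id change or long C-N distance
  breaks <- integer()
  for (i in seq_len(nres - 1L)) {
    ci <- which(ridx == i & df$name == "C")
    ni <- which(ridx == i + 1L & df$name == "N")
    chain_change <- df$chain[match(i, ridx)] != df$chain[match(i + 1L, ridx)]
    d <- sqrt(sum((c(df$x[ci], df$y[ci], df$z[ci]) -
                   c(df$x[ni], df$y[ni], df$z[ni]))^2))
    if (chain_change || d >= 1.8) breaks <- c(breaks, i)
  }

  atoms <- df[, c("serial", "name", "element", "resname", "residue_index",
                  "x", "y", "z")]
  atoms$radius <- vdw_radius(atoms$element)
  new_structure(atoms, breaks)
}

#' Write a Structure to a PDB file
#' @param structure a Structure.
#' @param path output path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  fmt_name <- function(n) {
    # PDB convention: atom names of <4 chars start in column 14
    ifelse(nchar(n) >= 4, substr(n, 1, 4), sprintf(" %-3s", n))
  }
  lines <- sprintf(
    "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, fmt_name(a$name), a$resname, a$residue_index,
    a$x, a$y, a$z, 1.00, 0.00, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Construct a ChargeSet
#'
#' Per-atom partial charges aligned to a Structure's atom order, with
#' provenance recording how they were obtained.
#'
#' @param charges numeric vector, elementary charge units.
#' @param provenance one of "force_field", "ee_gmfcc", "mock_reference".
#' @return object of class `ChargeSet`.
#' @export
charge_set <- function(charges,
                       provenance = c("force_field", "ee_gmfcc",
                                      "mock_reference")) {
  provenance <- match.arg(provenance)
  charges <- as.numeric(charges)
  if (!all(is.finite(charges))) stop("non-finite charges")
  structure(list(charges = charges, provenance = provenance,
                 total = sum(charges)),
            class = "ChargeSet")
}

#' @export
print.ChargeSet <- function(x, ...) {
  cat(sprintf("ChargeSet: %d charges, total %+0.6f e (%s)\n",
              length(x$charges), x$total, x$provenance))
  invisible(x)
}

#' Look up reference charges for every atom of a structure
#'
#' Maps each atom through a (residue name, terminus variant, atom name)
#' charge table and verifies that each residue's charges sum to its formal
#' charge within 1e-6.
#'
#' @param structure a Structure.
#' @param table a data.frame as returned by [reference_charge_table()], or a
#'   path to a whitespace-separated file with columns res, variant, atom,
#'   charge.
#' @param provenance provenance tag for the returned set.
#' @return a [charge_set()].
#' @export
load_reference_charges <- function(structure,
                                   table = reference_charge_table(),
                                   provenance = "force_field") {
  if (is.character(table)) {
    table <- utils::read.table(table, header = TRUE,
                               stringsAsFactors = FALSE)
  }
  a <- structure$atoms
  variant <- structure$variants[a$residue_index]
  key <- paste(a$resname, variant, a$name)
  tkey <- paste(table$res, table$variant, table$atom)
  hit <- match(key, tkey)
  if (any(is.na(hit))) {
    bad <- unique(paste0(a$resname[is.na(hit)], "[", variant[is.na(hit)],
                         "]:", a$name[is.na(hit)]))
    stop("unmapped (residue, atom) pairs in charge table: ",
         paste(bad, collapse = ", "))
  }
  q <- table$charge[hit]
  for (i in seq_len(structure$nres)) {
    idx <- a$residue_index == i
    f <- residue_formal_charge(a$resname[which(idx)[1]],
                               structure$variants[i])
    if (abs(sum(q[idx]) - f) > 1e-6)
      stop(sprintf("residue %d charge sum %.6f != formal %.1f",
                   i, sum(q[idx]), f))
  }
  charge_set(q, provenance)
}

#' Write structure + charges as a PQR file
#'
#' Whitespace-delimited PQR records (x, y, z, charge, radius) with fixed
#' field widths; round-trips through [read_pqr()] at 1e-4 precision.
#'
#' @param structure a Structure.
#' @param charges a ChargeSet aligned to `structure`.
#' @param path output path.
#' @export
write_pqr <- function(structure, charges, path) {
  a <- structure$atoms
  if (length(charges$charges) != nrow(a))
    stop("charges not aligned to structure")
  if (nrow(a) && (!("radius" %in% names(a)) || any(!is.finite(a$radius)) ||
                  any(a$radius <= 0))) {
    bad <- which(!is.finite(a$radius) | a$radius <= 0)
    stop("missing/invalid radius for atom(s): ",
         paste(a$name[bad], collapse = ", "))
  }
  lines <- if (nrow(a)) sprintf(
    "ATOM  %5d %-4s %3s %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
    a$serial, a$name, a$resname, a$residue_index,
    a$x, a$y, a$z, charges$charges, a$radius) else character()
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PQR file
#' @param path PQR path.
#' @return list with `structure` (a Structure) and `charges` (a ChargeSet).
#' @export
read_pqr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(lines)) {
    atoms <- data.frame(serial = integer(), name = character(),
                        element = character(), resname = character(),
                        residue_index = integer(), x = numeric(),
                        y = numeric(), z = numeric(), radius = numeric())
    return(list(structure = new_structure(atoms),
                charges = charge_set(numeric(), "force_field")))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  m <- do.call(rbind, parts)
  atoms <- data.frame(
    serial = as.integer(m[, 2]), name = m[, 3], resname = m[, 4],
    residue_index = as.integer(m[, 5]),
    x = as.numeric(m[, 6]), y = as.numeric(m[, 7]), z = as.numeric(m[, 8]),
    radius = as.numeric(m[, 10]), stringsAsFactors = FALSE)
  atoms$element <- element_from_name(atoms$name)
  list(structure = new_structure(atoms),
       charges = charge_set(as.numeric(m[, 9]), "force_field"))
}
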