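## Bundled reference tables: Amber-like mock atomic charges (internally
## consistent: per-residue sums are exactly the formal charge) and van der
## Waals radii. The charges are approximate force-field-like values used as
## embedding background and as the self-consistent ground truth of the mock
## backend; they are not a fitted force field.

# base side-chain formal charges of the supported residues
.RES_FORMAL <- c(ALA = 0, GLY = 0, SER = 0, VAL = 0, GLU = -1, LYS = 1)

.SUPPORTED_RES <- names(.RES_FORMAL)

# mid-chain atom charge sets (amide N-H, carbonyl C=O backbone)
.MID_CHARGES <- list(
  ALA = c(N = -0.4157, H = 0.2719, CA = 0.0337, HA = 0.0823,
          C = 0.5973, O = -0.5679, CB = -0.1825,
          HB1 = 0.0603, HB2 = 0.0603, HB3 = 0.0603),
  GLY = c(N = -0.4157, H = 0.2719, CA = -0.0252,
          HA2 = 0.0698, HA3 = 0.0698, C = 0.5973, O = -0.5679),
  SER = c(N = -0.4157, H = 0.2719, CA = -0.0249, HA = 0.0843,
          C = 0.5973, O = -0.5679, CB = 0.2117,
          HB2 = 0.0352, HB3 = 0.0352, OG = -0.6546, HG = 0.4275),
  VAL = c(N = -0.4157, H = 0.2719, CA = -0.0875, HA = 0.0969,
          C = 0.5973, O = -0.5679, CB = 0.2985, HB = -0.0297,
          CG1 = -0.3192, HG11 = 0.0791, HG12 = 0.0791, HG13 = 0.0791,
          CG2 = -0.3192, HG21 = 0.0791, HG22 = 0.0791, HG23 = 0.0791),
  GLU = c(N = -0.5163, H = 0.2936, CA = 0.0397, HA = 0.1105,
          C = 0.5366, O = -0.5819, CB = 0.0560,
          HB2 = -0.0173, HB3 = -0.0173, CG = 0.0136,
          HG2 = -0.0425, HG3 = -0.0425, CD = 0.8054,
          OE1 = -0.8188, OE2 = -0.8188),
  LYS = c(N = -0.3479, H = 0.2747, CA = -0.2400, HA = 0.1426,
          C = 0.7341, O = -0.5894, CB = -0.0094,
          HB2 = 0.0362, HB3 = 0.0362, CG = 0.0187,
          HG2 = 0.0103, HG3 = 0.0103, CD = -0.0479,
          HD2 = 0.0621, HD3 = 0.0621, CE = -0.0143,
          HE2 = 0.1135, HE3 = 0.1135, NZ = -0.3854,
          HZ1 = 0.3400, HZ2 = 0.3400, HZ3 = 0.3400)
)

# atom whose charge absorbs the exactness correction per residue
.REPAIR_ATOM <- c(ALA = "CB", GLY = "CA", SER = "CB", VAL = "CB",
                  GLU = "CB", LYS = "CB")

.variant_levels <- c("mid", "nneu", "nzwit", "cneu", "czwit")

# Build the charge set of a (residue, variant) pair; sums are repaired to
# the exact formal charge of that variant.
.variant_charges <- function(res, variant) {
  q <- .MID_CHARGES[[res]]
  target <- .RES_FORMAL[[res]]
  if (variant == "nneu") {
    q <- q[setdiff(names(q), "H")]
    q <- c(q, H1 = 0.33, H2 = 0.33)
    q[["N"]] <- q[["N"]] - 0.33 * 2 + 0.2719
  } else if (variant == "nzwit") {
    q <- q[setdiff(names(q), "H")]
    q <- c(q, H1 = 0.33, H2 = 0.33, H3 = 0.33)
    target <- target + 1
  } else if (variant == "cneu") {
    q <- c(q, OXT = -0.55, HXT = 0.44)
  } else if (variant == "czwit") {
    q[["O"]] <- -0.80
    q <- c(q, OXT = -0.80)
    target <- target - 1
  }
  rep_atom <- .REPAIR_ATOM[[res]]
  q[[rep_atom]] <- q[[rep_atom]] + (target - sum(q))
  q
}

#' Bundled reference charge table
#'
#' Returns the Amber-like mock reference charge table as a data frame with
#' columns `res`, `variant`, `atom`, `charge`. Variants cover mid-chain
#' residues plus neutral/zwitterionic N- and C-termini. Per (res, variant)
#' group the charges sum exactly to the group's formal charge.
#'
#' @param path optional file to also write the table to (whitespace-separated
#'   text, readable by [load_reference_charges()]).
#' @return data.frame of per-atom charges.
#' @export
reference_charge_table <- function(path = NULL) {
  rows <- list()
  for (res in .SUPPORTED_RES) {
    for (variant in .variant_levels) {
      q <- .variant_charges(res, variant)
      rows[[length(rows) + 1L]] <- data.frame(
        res = res, variant = variant, atom = names(q),
        charge = round(unname(q), 6), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  }
  tab
}

#' Formal charge of a residue variant
#' @keywords internal
residue_formal_charge <- function(res, variant = "mid") {
  f <- .RES_FORMAL[[res]]
  if (variant == "nzwit") f <- f + 1
  if (variant == "czwit") f <- f - 1
  f
}

#' van der Waals radius lookup
#'
#' Radii are keyed by element with optional `(res, atom)` overrides supplied
#' through `overrides` (a data.frame with columns res, atom, radius).
#'
#' @param element character vector of element symbols.
#' @param overrides optional override table.
#' @param res,atom parallel vectors used only when `overrides` is given.
#' @return numeric radii in Angstrom.
#' @export
vdw_radius <- function(element, overrides = NULL, res = NULL, atom = NULL) {
  r <- unname(.DEFAULT_VDW[element])
  if (any(is.na(r))) {
    stop("unrecognized element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  if (!is.null(overrides) && nrow(overrides) > 0) {
    key <- paste(res, atom)
    okey <- paste(overrides$res, overrides$atom)
    hit <- match(key, okey)
    r[!is.na(hit)] <- overrides$radius[hit[!is.na(hit)]]
  }
  r
}

#' Write the bundled radius table to a text file
#' @param path output path.
#' @export
write_radius_table <- function(path) {
  utils::write.table(
    data.frame(element = names(.DEFAULT_VDW), radius = unname(.DEFAULT_VDW)),
    path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
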