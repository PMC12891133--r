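# Low-level chemistry layer: SMILES validation, canonicalization, molecular
# graphs and SMARTS matching, all backed by OpenBabel via ChemmineR/ChemmineOB.
#
# OpenBabel's SMILES reader is permissive and silently repairs some malformed
# strings (e.g. unbalanced parentheses), so a syntactic well-formedness gate
# runs first; it rejects strings no SMILES grammar accepts, and everything it
# passes is still parsed and canonicalized by OpenBabel.

SMILES_ALLOWED <- "^[]A-Za-z0-9@+[()=#$:/\\\\%.*-]+$"

smiles_well_formed <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("\\s", s)) return(FALSE)
  if (!grepl(SMILES_ALLOWED, s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depth <- 0L; in_br <- FALSE
  ring_open <- character(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_br) {
      if (ch == "[") return(FALSE)
      if (ch == "]") in_br <- FALSE
    } else if (ch == "[") {
      in_br <- TRUE
    } else if (ch == "]") {
      return(FALSE)
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) return(FALSE)
      id <- paste0(chars[i + 1L], chars[i + 2L])
      ring_open <- toggle_ring(ring_open, id)
      i <- i + 2L
    } else if (grepl("[0-9]", ch)) {
      ring_open <- toggle_ring(ring_open, ch)
    }
    i <- i + 1L
  }
  depth == 0L && !in_br && length(ring_open) == 0L
}

toggle_ring <- function(open, id) {
  if (id %in% open) setdiff(open, id) else c(open, id)
}

# SMARTS patterns use a richer grammar than SMILES (logical operators, atom
# primitives), so only balance of brackets/parentheses is checked here; the
# SMARTS engine itself is the final arbiter.
smarts_well_formed <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("\\s", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  par <- 0L; br <- 0L
  for (ch in chars) {
    if (ch == "(") par <- par + 1L
    if (ch == ")") { par <- par - 1L; if (par < 0L) return(FALSE) }
    if (ch == "[") { br <- br + 1L; if (br > 1L) return(FALSE) }
    if (ch == "]") { br <- br - 1L; if (br < 0L) return(FALSE) }
  }
  par == 0L && br == 0L
}

# Canonical SMILES via OpenBabel; NA for strings that fail the syntax gate or
# come back empty. Vectorized; round-trips (canonical of canonical) are fixed
# points, which the standardization idempotence tests rely on.
canonicalize_smiles <- function(smiles,
                                options = data.frame(names = "", args = "",
                                                     stringsAsFactors = FALSE)) {
  out <- rep(NA_character_, length(smiles))
  ok <- vapply(smiles, smiles_well_formed, logical(1), USE.NAMES = FALSE)
  if (!any(ok)) return(out)
  idx <- which(ok)
  txt <- paste0(smiles[idx], "\tm", seq_along(idx), "\n", collapse = "")
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = txt, options = options),
    error = function(e) ""
  )
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && nzchar(parts[1])) {
      k <- suppressWarnings(as.integer(sub("^m", "", trimws(parts[2]))))
      if (!is.na(k) && k >= 1 && k <= length(idx)) out[idx[k]] <- parts[1]
    }
  }
  out
}

ob_op <- function(smiles, op) {
  canonicalize_smiles(smiles, options = data.frame(names = op, args = "", stringsAsFactors = FALSE))
}

# InChI round-trip: SMILES -> standard InChI -> SMILES. Standard InChI merges
# mobile-hydrogen tautomers, so the round-trip yields one fixed protomer per
# mobile-H group. Returns NA on failure (caller then keeps its input).
inchi_roundtrip <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_character_)
    inchi <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHI", source = paste0(s, "\tx\n"))),
      error = function(e) ""
    )
    inchi <- strsplit(inchi, "\n", fixed = TRUE)[[1]]
    inchi <- inchi[grepl("^InChI=", inchi)]
    if (length(inchi) == 0) return(NA_character_)
    back <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("INCHI", "CAN", source = paste0(inchi[1], "\n"))),
      error = function(e) ""
    )
    back <- strsplit(back, "\t", fixed = TRUE)[[1]][1]
    back <- sub("\n.*$", "", back)
    if (!nzchar(back) || is.na(back)) NA_character_ else back
  }, character(1), USE.NAMES = FALSE)
}

# Standard valences used to infer implicit hydrogen counts on the kekulized
# graphs OpenBabel emits; only needed for fingerprint atom invariants.
DEFAULT_VALENCE <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3,
  Si = 4, Se = 2, As = 3
)

METAL_ELEMENTS <- c(
  "Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba", "Al", "Ga",
  "In", "Tl", "Sn", "Pb", "Bi", "Fe", "Co", "Ni", "Cu", "Zn", "Mn", "Cr",
  "V", "Ti", "Sc", "Y", "Zr", "Nb", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd",
  "W", "Re", "Os", "Ir", "Pt", "Au", "Hg"
)

# Molfile charge codes (field 6): 1..3 -> +3..+1, 5..7 -> -1..-3.
charge_from_code <- function(code) {
  ifelse(code == 0, 0L,
    ifelse(code <= 3, 4L - as.integer(code),
      ifelse(code >= 5 & code <= 7, 4L - as.integer(code), 0L)))
}

# Parse one or more SMILES into light molecular graphs:
# list(elem, charge, nh, degree, bonds = matrix(a1, a2, order)).
# The V2000 connection tables OpenBabel emits are read directly here
# (fixed-width fields); this stays robust for single-atom molecules,
# whose molblocks trip up higher-level SDF readers.
mol_graphs <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  txt <- paste0(smiles, "\tm", seq_along(smiles), "\n", collapse = "")
  sdftxt <- suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", source = txt))
  recs <- strsplit(sdftxt, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[grepl("V2000", recs)]
  if (length(recs) != length(smiles)) {
    ls_stop("parse_error", "molecule table conversion lost records (%d of %d)",
            length(recs), length(smiles))
  }
  lapply(recs, function(rec) {
    lines <- strsplit(rec, "\n", fixed = TRUE)[[1]]
    cl <- grep("V2000", lines, fixed = TRUE)[1]
    natoms <- as.integer(substr(lines[cl], 1, 3))
    nbonds <- as.integer(substr(lines[cl], 4, 6))
    atom_lines <- lines[(cl + 1):(cl + natoms)]
    elem <- trimws(substr(atom_lines, 32, 34))
    chg <- charge_from_code(suppressWarnings(as.integer(substr(atom_lines, 37, 39))))
    chg[is.na(chg)] <- 0L
    nb <- matrix(numeric(0), ncol = 3)
    if (nbonds > 0) {
      bond_lines <- lines[(cl + natoms + 1):(cl + natoms + nbonds)]
      nb <- cbind(as.integer(substr(bond_lines, 1, 3)),
                  as.integer(substr(bond_lines, 4, 6)),
                  as.integer(substr(bond_lines, 7, 9)))
    }
    for (ln in grep("^M  CHG", lines, value = TRUE)) {
      v <- as.integer(strsplit(trimws(sub("^M  CHG\\s*[0-9]+", "", ln)), "\\s+")[[1]])
      if (length(v) >= 2) {
        pos <- v[seq(1, length(v), by = 2)]
        val <- v[seq(2, length(v), by = 2)]
        chg[pos] <- val
      }
    }
    ord <- ifelse(nb[, 3] == 4, 1.5, nb[, 3])
    n <- length(elem)
    degree <- integer(n); bosum <- numeric(n)
    if (nrow(nb) > 0) {
      for (r in seq_len(nrow(nb))) {
        a <- nb[r, 1]; b <- nb[r, 2]
        degree[a] <- degree[a] + 1L; degree[b] <- degree[b] + 1L
        bosum[a] <- bosum[a] + ord[r]; bosum[b] <- bosum[b] + ord[r]
      }
    }
    dv <- unname(DEFAULT_VALENCE[elem]); dv[is.na(dv)] <- 0
    eff <- dv + chg
    eff[elem == "C" & chg > 0] <- (dv - chg)[elem == "C" & chg > 0]
    nh <- pmax(0, round(eff - bosum))
    list(elem = elem, charge = as.integer(chg), nh = as.integer(nh),
         degree = degree, n = n,
         bonds = cbind(a1 = nb[, 1], a2 = nb[, 2], order = ord))
  })
}

#' Count SMARTS substructure matches
#'
#' Matches a SMARTS pattern against each molecule and returns the number of
#' distinct matches, using OpenBabel's SMARTS engine. Used by the synthetic
#' benchmark generator (motif planting/screening) and by tests as the
#' substructure oracle.
#'
#' @param smiles Character vector of SMILES strings.
#' @param smarts A single SMARTS pattern.
#' @return Integer vector of match counts, one per input molecule.
#' @export
smarts_match_count <- function(smiles, smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1)
  if (!smarts_well_formed(smarts)) {
    ls_stop("invalid_motif", "motif does not parse as a substructure pattern: %s", smarts)
  }
  if (length(smiles) == 0) return(integer(0))
  txt <- paste0(smiles, "\tm", seq_along(smiles), "\n", collapse = "")
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", txt, function(mol) {
      ChemmineOB::smartsSearch_OB(list(mol), smarts, uniqueMatches = TRUE)
    }),
    error = function(e) ls_stop("invalid_motif", "motif rejected by SMARTS engine: %s", smarts)
  )
  if (length(res) != length(smiles)) {
    ls_stop("parse_error", "SMARTS matching lost records")
  }
  vapply(res, function(x) as.integer(x[[1]]), integer(1))
}
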