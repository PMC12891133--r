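# Binding-energy aggregation and candidate prioritization from tabulated
# MM-PBSA components and docking scores, plus hydrogen-bond interaction
# records and the docking-box configuration writer.

STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                       "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                       "THR", "TRP", "TYR", "VAL")

#' Read a binding-energy component table (TSV)
#'
#' Expects columns \code{ligand}, \code{dE_vdw}, \code{dE_ele},
#' \code{dG_solv}; optional \code{*_sd} uncertainty columns.
#'
#' @param path Input TSV path.
#' @export
read_energy_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ligand", "dE_vdw", "dE_ele", "dG_solv")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) ls_stop("missing_component", "energy table lacks column(s): %s",
                                paste(miss, collapse = ", "))
  df
}

#' Aggregate binding-energy components into gas-phase and total energies
#'
#' Adds \code{dG_gas = dE_vdw + dE_ele} and
#' \code{dG_total = dG_gas + dG_solv} (kcal/mol) at full precision, plus
#' display columns rounded to two decimals (round-half-even). When
#' per-component uncertainties are present, quadrature-propagated
#' uncertainties are reported in separate \code{*_sd_prop} columns.
#'
#' @param rows data.frame with columns \code{ligand}, \code{dE_vdw},
#'   \code{dE_ele}, \code{dG_solv} (kcal/mol) and optional \code{*_sd}.
#' @return The input with derived columns appended.
#' @examples
#' aggregate_energy_components(data.frame(
#'   ligand = "Linolenic acid", dE_vdw = -28.5, dE_ele = -18.5, dG_solv = 15.5))
#' @export
aggregate_energy_components <- function(rows) {
  need <- c("ligand", "dE_vdw", "dE_ele", "dG_solv")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0) ls_stop("missing_component", "missing component column(s): %s",
                                paste(miss, collapse = ", "))
  if (nrow(rows) == 0) ls_stop("empty_input", "energy table is empty")
  vals <- as.matrix(rows[, c("dE_vdw", "dE_ele", "dG_solv")])
  if (any(!is.finite(vals))) ls_stop("missing_component", "non-finite energy component")
  rows$dG_gas <- rows$dE_vdw + rows$dE_ele
  rows$dG_total <- rows$dG_gas + rows$dG_solv
  rows$dG_gas_2dp <- round(rows$dG_gas, 2)
  rows$dG_total_2dp <- round(rows$dG_total, 2)
  if (all(c("dE_vdw_sd", "dE_ele_sd") %in% names(rows))) {
    rows$dG_gas_sd_prop <- sqrt(rows$dE_vdw_sd^2 + rows$dE_ele_sd^2)
    if ("dG_solv_sd" %in% names(rows)) {
      rows$dG_total_sd_prop <- sqrt(rows$dG_gas_sd_prop^2 + rows$dG_solv_sd^2)
    }
  }
  rows
}

#' Rank candidates by a binding-energy column
#'
#' Ascending order: the most negative (strongest-binding) candidate gets
#' rank 1. Ties break alphabetically by ligand name; input order is
#' irrelevant.
#'
#' @param rows data.frame with a \code{ligand} column.
#' @param key Name of the energy column to rank on.
#' @return The rows reordered with a \code{rank} column prepended.
#' @export
rank_candidates <- function(rows, key = "dG_total") {
  if (!key %in% names(rows)) ls_stop("missing_key", "ranking key not present: %s", key)
  if (any(!is.finite(rows[[key]]))) ls_stop("missing_key", "ranking key has missing values")
  ord <- order(rows[[key]], as.character(rows$ligand))
  out <- rows[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Parse hydrogen-bond interaction annotations
#'
#' Each record has the form \code{"Ligand name: RES###[, RES###...]"} with
#' three-letter residue codes from the 20 standard amino acids.
#'
#' @param annotations Character vector of annotation records.
#' @return data.frame with columns \code{ligand}, \code{residue},
#'   \code{position}; one row per (ligand, residue) token.
#' @examples
#' collect_interactions("Linolenic acid: ASP79")
#' @export
collect_interactions <- function(annotations) {
  out <- list()
  for (ann in annotations) {
    parts <- strsplit(ann, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) ls_stop("malformed_token", "annotation lacks 'ligand: tokens' form: %s", ann)
    ligand <- trimws(parts[1])
    tokens <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0) ls_stop("malformed_token", "no residue tokens in: %s", ann)
    for (tok in tokens) {
      if (!grepl("^[A-Z]{3}[0-9]+$", tok)) {
        ls_stop("malformed_token", "malformed residue token: %s", tok)
      }
      res <- substr(tok, 1, 3)
      if (!res %in% STANDARD_RESIDUES) {
        ls_stop("unknown_residue", "unknown residue code: %s", res)
      }
      pos <- as.integer(substr(tok, 4, nchar(tok)))
      if (pos <= 0) ls_stop("malformed_token", "residue position must be positive: %s", tok)
      out[[length(out) + 1]] <- data.frame(ligand = ligand, residue = res,
                                           position = pos, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Construct a docking-box configuration
#'
#' @param center Numeric length-3 vector (x, y, z), in Angstrom.
#' @param size Numeric length-3 vector of positive edge lengths, in Angstrom.
#' @export
vina_box <- function(center, size) {
  stopifnot(length(center) == 3, length(size) == 3)
  if (any(!is.finite(c(center, size))) || any(size <= 0)) {
    ls_stop("invalid_box", "box sizes must be positive and finite")
  }
  structure(list(center_x = center[1], center_y = center[2], center_z = center[3],
                 size_x = size[1], size_y = size[2], size_z = size[3]),
            class = "vina_box")
}

#' Emit a docking-box configuration as text
#'
#' One \code{key = value} line per field in fixed order
#' (\code{center_x..center_z}, \code{size_x..size_z}); values are rendered
#' at their input precision.
#'
#' @param box A \code{\link{vina_box}}.
#' @return A single string of six lines.
#' @export
emit_vina_box_config <- function(box) {
  stopifnot(inherits(box, "vina_box"))
  keys <- c("center_x", "center_y", "center_z", "size_x", "size_y", "size_z")
  paste(vapply(keys, function(k) {
    sprintf("%s = %s", k, format(box[[k]], trim = TRUE, scientific = FALSE))
  }, character(1)), collapse = "\n")
}

#' Parse a docking-box configuration text
#' @param text Six `key = value` lines (as emitted by
#'   \code{\link{emit_vina_box_config}}).
#' @export
parse_vina_box_config <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*(\\w+)\\s*=\\s*(-?[0-9.]+)\\s*$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- as.numeric(m[3])
  }
  vina_box(c(kv$center_x, kv$center_y, kv$center_z),
           c(kv$size_x, kv$size_y, kv$size_z))
}

#' Write an aggregated energy table as TSV
#' @param rows Aggregated energy table.
#' @param path Output path.
#' @export
write_energy_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
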