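# Dataset curation: reading molecule tables, SMILES standardization,
# class balancing and train/test splitting.

STANDARD_ACTIONS <- c("strip_fragments", "remove_metal", "neutralize_charges",
                      "canonicalize_tautomer", "remove_explicit_H", "canonicalize")

#' Standardize a single SMILES string
#'
#' Applies the curation cascade in a fixed order: keep the largest organic
#' fragment, delete metal atoms, neutralize formal charges (net-charged
#' species only; zwitterionic groups such as nitro are preserved), normalize
#' mobile-hydrogen tautomers via an InChI round-trip, drop explicit
#' hydrogens, and emit canonical SMILES. The cascade is idempotent: feeding
#' the output back in reproduces it with only the \code{canonicalize} action.
#'
#' @param raw_smiles A single SMILES string.
#' @return A list with elements \code{std_smiles} (canonical SMILES, or
#'   \code{NA} on failure), \code{actions} (character vector of applied
#'   actions) and \code{failure} (\code{NA} or a reason such as
#'   \code{"parse_error"}).
#' @examples
#' standardize_molecule("CC(=O)[O-].[Na+]")$std_smiles  # "CC(=O)O"
#' @export
standardize_molecule <- function(raw_smiles) {
  stopifnot(is.character(raw_smiles), length(raw_smiles) == 1)
  actions <- character(0)
  fail <- function(reason) list(std_smiles = NA_character_, actions = actions, failure = reason)

  if (!smiles_well_formed(raw_smiles)) return(fail("parse_error"))
  s <- canonicalize_smiles(raw_smiles)
  if (is.na(s)) return(fail("parse_error"))

  # largest organic fragment
  frags <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (length(frags) > 1) {
    s <- pick_largest_organic(frags)
    actions <- c(actions, "strip_fragments")
  }

  # covalently bound metals
  g <- mol_graphs(s)[[1]]
  if (any(g$elem %in% METAL_ELEMENTS)) {
    s2 <- remove_metal_atoms(g)
    if (!is.na(s2)) {
      s <- s2
      frags <- strsplit(s, ".", fixed = TRUE)[[1]]
      if (length(frags) > 1) s <- pick_largest_organic(frags)
      actions <- c(actions, "remove_metal")
    }
  }

  s2 <- ob_op(s, "neutralize")
  if (!is.na(s2) && s2 != s) {
    s <- s2
    actions <- c(actions, "neutralize_charges")
  }

  s2 <- inchi_roundtrip(s)
  if (!is.na(s2) && s2 != s) {
    s <- s2
    actions <- c(actions, "canonicalize_tautomer")
  }

  if (grepl("[H]", s, fixed = TRUE)) {
    s2 <- canonicalize_smiles(s, options = data.frame(names = "d", args = "", stringsAsFactors = FALSE))
    if (!is.na(s2) && s2 != s) {
      s <- s2
      actions <- c(actions, "remove_explicit_H")
    }
  }

  s2 <- canonicalize_smiles(s)
  if (is.na(s2)) return(fail("parse_error"))
  list(std_smiles = s2, actions = c(actions, "canonicalize"), failure = NA_character_)
}

pick_largest_organic <- function(frags) {
  gs <- mol_graphs(frags)
  sizes <- vapply(gs, function(g) g$n, numeric(1))
  organic <- vapply(gs, function(g) any(g$elem == "C"), logical(1))
  cand <- if (any(organic)) which(organic) else seq_along(frags)
  frags[cand[which.max(sizes[cand])]]
}

# Rebuild a molecule with its metal atoms deleted, via a minimal V2000
# molblock handed back to OpenBabel for canonicalization.
remove_metal_atoms <- function(g) {
  keep <- which(!(g$elem %in% METAL_ELEMENTS))
  if (length(keep) == 0) return(NA_character_)
  remap <- match(seq_len(g$n), keep)
  b <- g$bonds
  if (nrow(b) > 0) {
    b <- b[!is.na(remap[b[, 1]]) & !is.na(remap[b[, 2]]), , drop = FALSE]
  }
  atoms <- vapply(keep, function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, g$elem[i])
  }, character(1))
  bonds <- if (nrow(b) > 0) {
    vapply(seq_len(nrow(b)), function(r) {
      sprintf("%3d%3d%3d  0  0  0  0", remap[b[r, 1]], remap[b[r, 2]],
              as.integer(round(ifelse(b[r, 3] == 1.5, 4, b[r, 3]))))
    }, character(1))
  } else character(0)
  chg <- which(g$charge[keep] != 0)
  chglines <- if (length(chg) > 0) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf(" %3d %3d", chg, g$charge[keep][chg]), collapse = ""))
  } else character(0)
  block <- paste(c("m1", "  ligandscreen", "",
                   sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                           length(keep), length(bonds)),
                   atoms, bonds, chglines, "M  END", "$$$$", ""), collapse = "\n")
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", source = block)),
    error = function(e) ""
  )
  res <- strsplit(res, "[\t\n]")[[1]][1]
  if (is.na(res) || !nzchar(res)) NA_character_ else res
}

#' Read a molecule table from CSV, SMILES or SDF
#'
#' @param path Path to the input file.
#' @param format One of \code{"csv"} (columns \code{smiles} required;
#'   \code{id}, \code{label}, \code{source} optional), \code{"smi"}
#'   (\code{smiles<TAB>id} lines) or \code{"sdf"}.
#' @param label_field For SDF input, the data field holding the activity label.
#' @return A \code{data.frame} with columns \code{id}, \code{smiles},
#'   \code{label} (\code{active}/\code{inactive}/\code{unknown}) and
#'   \code{source}. Records sharing a canonical SMILES are flagged in the
#'   \code{"duplicates"} attribute (a data.frame of canonical SMILES and ids),
#'   never dropped.
#' @export
parse_smiles_table <- function(path, format = c("csv", "smi", "sdf"), label_field = "label") {
  format <- match.arg(format)
  if (!file.exists(path)) ls_stop("unreadable_file", "cannot read input file: %s", path)
  tbl <- switch(format,
    csv = parse_csv_molecules(path),
    smi = parse_smi_molecules(path),
    sdf = parse_sdf_molecules(path, label_field)
  )
  if (nrow(tbl) == 0) ls_stop("empty_input", "no molecule records in %s", path)
  if (anyDuplicated(tbl$id)) tbl$id <- make.unique(tbl$id, sep = "_dup")
  can <- canonicalize_smiles(tbl$smiles)
  dup <- data.frame(canonical = character(0), ids = character(0), stringsAsFactors = FALSE)
  grp <- split(tbl$id, can)
  grp <- grp[vapply(grp, length, integer(1)) > 1]
  if (length(grp) > 0) {
    dup <- data.frame(canonical = names(grp),
                      ids = vapply(grp, paste, character(1), collapse = ";"),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  attr(tbl, "duplicates") <- dup
  class(tbl) <- c("molecule_table", "data.frame")
  tbl
}

parse_csv_molecules <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nms <- tolower(names(df))
  smi_col <- which(nms == "smiles")
  if (length(smi_col) == 0) ls_stop("missing_column", "CSV lacks a smiles column: %s", path)
  id <- if ("id" %in% nms) as.character(df[[which(nms == "id")[1]]]) else sprintf("mol_%d", seq_len(nrow(df)))
  lab <- if ("label" %in% nms) map_labels(df[[which(nms == "label")[1]]]) else rep("unknown", nrow(df))
  src <- if ("source" %in% nms) as.character(df[[which(nms == "source")[1]]]) else rep("", nrow(df))
  data.frame(id = id, smiles = as.character(df[[smi_col[1]]]), label = lab,
             source = src, stringsAsFactors = FALSE)
}

parse_smi_molecules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("mol_%d", i)
    }, character(1)),
    smiles = vapply(parts, `[`, character(1), 1),
    label = "unknown", source = "", stringsAsFactors = FALSE
  )
}

parse_sdf_molecules <- function(path, label_field) {
  sdf <- ChemmineR::read.SDFset(path)
  smi <- as.character(suppressWarnings(ChemmineR::sdf2smiles(sdf)))
  ids <- ChemmineR::sdfid(sdf)
  ids[!nzchar(ids)] <- sprintf("mol_%d", which(!nzchar(ids)))
  lab <- vapply(seq_along(sdf), function(i) {
    db <- ChemmineR::datablock(sdf[[i]])
    if (label_field %in% names(db)) db[[label_field]] else NA_character_
  }, character(1))
  data.frame(id = as.character(ids), smiles = smi, label = map_labels(lab),
             source = "", stringsAsFactors = FALSE)
}

map_labels <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("1", "active", "true")] <- "active"
  out[x %in% c("0", "inactive", "false")] <- "inactive"
  out
}

#' Standardize every record of a molecule table
#'
#' @param tbl A molecule table (from \code{\link{parse_smiles_table}} or the
#'   synthetic generator).
#' @return The table with an added \code{std_smiles} column (\code{NA} where
#'   standardization failed) and a per-record \code{"standardization_report"}
#'   attribute listing the actions applied and any failure reason.
#' @export
standardize_records <- function(tbl) {
  res <- lapply(tbl$smiles, standardize_molecule)
  tbl$std_smiles <- vapply(res, `[[`, character(1), "std_smiles")
  attr(tbl, "standardization_report") <- data.frame(
    id = tbl$id,
    actions = vapply(res, function(r) paste(r$actions, collapse = ";"), character(1)),
    failure = vapply(res, `[[`, character(1), "failure"),
    stringsAsFactors = FALSE
  )
  tbl
}

#' Balance actives against a decoy pool
#'
#' Returns all actives plus exactly as many decoys, sampled uniformly without
#' replacement from the pool; deterministic under \code{seed}.
#'
#' @param actives,decoy_pool Molecule tables.
#' @param seed Integer seed.
#' @export
balance_dataset <- function(actives, decoy_pool, seed = 42) {
  na <- nrow(actives)
  if (nrow(decoy_pool) < na) {
    ls_stop("pool_too_small", "decoy pool (%d) smaller than actives (%d)", nrow(decoy_pool), na)
  }
  pick <- with_stream(seed, "balance_dataset", sample(nrow(decoy_pool), na))
  actives$label <- "active"
  neg <- decoy_pool[sort(pick), , drop = FALSE]
  neg$label <- "inactive"
  out <- rbind(as.data.frame(actives), as.data.frame(neg))
  rownames(out) <- NULL
  class(out) <- c("molecule_table", "data.frame")
  out
}

#' Split a dataset into train and test ids
#'
#' Draws \code{floor(ratio * n)} training records; when stratified, the
#' per-class training fraction is within one record of \code{ratio}.
#'
#' @param dataset A data.frame with \code{id} and (if stratified) \code{label}.
#' @param ratio Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @param stratified Stratify by \code{label}?
#' @return An object of class \code{dataset_split}: list with \code{train},
#'   \code{test}, \code{ratio}, \code{seed}.
#' @export
split_dataset <- function(dataset, ratio = 0.8, seed = 42, stratified = TRUE) {
  n <- nrow(dataset)
  if (n == 0) ls_stop("empty_input", "cannot split an empty dataset")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    ls_stop("invalid_ratio", "ratio must be in (0,1), got %s", format(ratio))
  }
  n_train <- floor(ratio * n)
  ids <- as.character(dataset$id)
  if (stratified) {
    lab <- as.character(dataset$label)
    counts <- table(lab)
    if (any(counts == 1)) {
      ls_stop("single_record_class", "stratified split needs >1 record per class")
    }
    base <- floor(ratio * counts)
    frac <- ratio * counts - base
    rem <- n_train - sum(base)
    if (rem > 0) {
      bump <- names(sort(frac, decreasing = TRUE))[seq_len(rem)]
      base[bump] <- base[bump] + 1
    }
    train <- with_stream(seed, "split_dataset", {
      unlist(lapply(names(counts), function(cl) {
        pool <- ids[lab == cl]
        pool[sample(length(pool), base[[cl]])]
      }), use.names = FALSE)
    })
  } else {
    train <- with_stream(seed, "split_dataset", ids[sample(n, n_train)])
  }
  structure(list(train = sort(train), test = sort(setdiff(ids, train)),
                 ratio = ratio, seed = seed),
            class = "dataset_split")
}

#' Write/read a molecule table as CSV (`id,smiles,label,source`)
#' @param tbl Molecule table.
#' @param path Output path.
#' @export
write_molecule_csv <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl)[, c("id", "smiles", "label", "source")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a dataset split as JSON
#' @param split A \code{dataset_split}.
#' @param path Output path.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(
    list(train = split$train, test = split$test, ratio = split$ratio, seed = split$seed),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a dataset split from JSON
#' @param path Input path.
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.character(x$train), test = as.character(x$test),
                 ratio = x$ratio, seed = x$seed), class = "dataset_split")
}
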