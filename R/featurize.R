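# Molecular descriptors, fingerprints and Tanimoto similarity.
#
# Descriptors and MACCS keys come from OpenBabel; the hashed fingerprints
# (circular, path, atom-pair, topological-torsion and the 2048-bit
# path/circular hybrid used for chemical-space clustering) are computed here
# on the molecular graph, with a fixed platform-independent string hash, so
# bit positions are stable across machines and sessions.

#' Fingerprint bit lengths by type
#' @export
FP_LENGTHS <- c(morgan1024 = 1024L, rdkit_path = 2048L, maccs166 = 166L,
                atompairs1024 = 1024L, toptorsion1024 = 1024L, extended2048 = 2048L)

#' The five fingerprint types used for model evaluation
#' @export
MODEL_FP_TYPES <- c("morgan1024", "rdkit_path", "maccs166", "atompairs1024", "toptorsion1024")

#' Compute the six molecular descriptors
#'
#' Molecular weight (Da), topological polar surface area (A^2), hydrogen-bond
#' donor and acceptor counts, logP and molar refractivity (the molecular
#' volume proxy), via OpenBabel.
#'
#' @param std_smiles Character vector of standardized SMILES.
#' @return data.frame with columns MolWt, TPSA, NumHDonors, NumHAcceptors,
#'   MolLogP, MolMR; one row per molecule.
#' @examples
#' compute_descriptors("CCO")  # MolWt ~46.07, one donor, one acceptor
#' @export
compute_descriptors <- function(std_smiles) {
  bad <- is.na(canonicalize_smiles(std_smiles))
  if (any(bad)) {
    ls_stop("featurization_error", "unparseable SMILES at position(s) %s",
            paste(which(bad), collapse = ","))
  }
  txt <- paste0(std_smiles, "\tm", seq_along(std_smiles), "\n", collapse = "")
  p <- do.call(rbind, ChemmineOB::forEachMol("SMILES", txt, ChemmineOB::prop_OB))
  if (nrow(p) != length(std_smiles)) ls_stop("featurization_error", "descriptor computation lost records")
  out <- data.frame(
    MolWt = as.numeric(p$MW),
    TPSA = as.numeric(p$TPSA),
    NumHDonors = as.integer(p$HBD),
    NumHAcceptors = as.integer(p$HBA1),
    MolLogP = as.numeric(p$logP),
    MolMR = as.numeric(p$MR)
  )
  if (any(!is.finite(as.matrix(out)))) {
    ls_stop("featurization_error", "non-finite descriptor value")
  }
  out
}

#' Per-class summary of descriptor distributions
#'
#' @param descriptors data.frame from \code{\link{compute_descriptors}}.
#' @param labels Character vector of class labels aligned with rows.
#' @return data.frame with one row per (descriptor, class): count, mean, sd
#'   and quartiles.
#' @export
summarize_descriptor_distributions <- function(descriptors, labels) {
  stopifnot(nrow(descriptors) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    ls_stop("empty_class", "need records from at least two classes")
  }
  rows <- lapply(names(descriptors), function(d) {
    do.call(rbind, lapply(classes, function(cl) {
      x <- descriptors[[d]][labels == cl]
      data.frame(descriptor = d, class = cl, count = length(x),
                 mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
                 q25 = unname(stats::quantile(x, 0.25)),
                 median = unname(stats::median(x)),
                 q75 = unname(stats::quantile(x, 0.75)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- molecular-graph feature enumeration ----

graph_adjacency <- function(g) {
  adj <- vector("list", g$n)
  b <- g$bonds
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      a1 <- b[r, 1]; a2 <- b[r, 2]; o <- b[r, 3]
      adj[[a1]] <- rbind(adj[[a1]], c(a2, o))
      adj[[a2]] <- rbind(adj[[a2]], c(a1, o))
    }
  }
  adj
}

bond_sym <- function(o) c("1" = "-", "2" = "=", "3" = "#", "1.5" = ":")[as.character(o)]

n_pi_bonds <- function(g) {
  npi <- integer(g$n)
  b <- g$bonds
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      if (b[r, 3] >= 1.5) {
        npi[b[r, 1]] <- npi[b[r, 1]] + 1L
        npi[b[r, 2]] <- npi[b[r, 2]] + 1L
      }
    }
  }
  npi
}

# Circular (Morgan-style) features, radius 0..2 by default.
morgan_features <- function(g, radius = 2) {
  adj <- graph_adjacency(g)
  id <- vapply(seq_len(g$n), function(a) {
    hash_string(paste("mg0", g$elem[a], g$degree[a], g$charge[a], g$nh[a], sep = "|"))
  }, numeric(1))
  feats <- paste0("r0:", unique(id))
  for (r in seq_len(radius)) {
    id <- vapply(seq_len(g$n), function(a) {
      nb <- adj[[a]]
      env <- if (is.null(nb)) "" else {
        paste(sort(paste0(nb[, 2], ":", id[nb[, 1]])), collapse = ",")
      }
      hash_string(paste("mg", r, id[a], env, sep = "|"))
    }, numeric(1))
    feats <- c(feats, paste0("r", r, ":", unique(id)))
  }
  unique(feats)
}

# All simple linear paths of min_len..max_len bonds, as canonical
# element/bond strings (lexicographically smaller of the two directions).
path_features <- function(g, min_len = 1, max_len = 7) {
  adj <- graph_adjacency(g)
  feats <- new.env(hash = TRUE, parent = emptyenv())
  walk <- function(atom, visited, elems, bonds) {
    depth <- length(bonds)
    if (depth >= min_len) {
      fwd <- path_string(elems, bonds)
      rev_ <- path_string(rev(elems), rev(bonds))
      assign(if (fwd <= rev_) fwd else rev_, TRUE, envir = feats)
    }
    if (depth >= max_len) return(invisible())
    nb <- adj[[atom]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), c(elems, g$elem[nxt]), c(bonds, bond_sym(nb[r, 2])))
    }
    invisible()
  }
  for (a in seq_len(g$n)) walk(a, a, g$elem[a], character(0))
  ls(feats)
}

path_string <- function(elems, bonds) {
  out <- elems[1]
  for (i in seq_along(bonds)) out <- paste0(out, bonds[i], elems[i + 1])
  out
}

# Topological distances by breadth-first search from every atom.
topo_distances <- function(g) {
  adj <- graph_adjacency(g)
  d <- matrix(NA_integer_, g$n, g$n)
  for (s in seq_len(g$n)) {
    dist_s <- rep(NA_integer_, g$n)
    dist_s[s] <- 0L
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (a in frontier) {
        nb <- adj[[a]]
        if (is.null(nb)) next
        for (r in seq_len(nrow(nb))) {
          v <- nb[r, 1]
          if (is.na(dist_s[v])) {
            dist_s[v] <- dist_s[a] + 1L
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
    d[s, ] <- dist_s
  }
  d
}

atompair_features <- function(g) {
  if (g$n < 2) return(character(0))
  npi <- n_pi_bonds(g)
  inv <- paste0(g$elem, g$degree, npi)
  d <- topo_distances(g)
  feats <- character(0)
  for (i in seq_len(g$n - 1)) {
    for (j in (i + 1):g$n) {
      if (is.na(d[i, j])) next
      pair <- sort(c(inv[i], inv[j]))
      feats <- c(feats, paste("ap", pair[1], pair[2], d[i, j], sep = "|"))
    }
  }
  unique(feats)
}

torsion_features <- function(g) {
  adj <- graph_adjacency(g)
  npi <- n_pi_bonds(g)
  inv <- paste0(g$elem, g$degree, npi)
  feats <- new.env(hash = TRUE, parent = emptyenv())
  walk <- function(atom, visited) {
    if (length(visited) == 4) {
      fwd <- paste(inv[visited], collapse = "~")
      rev_ <- paste(inv[rev(visited)], collapse = "~")
      assign(paste0("tt|", if (fwd <= rev_) fwd else rev_), TRUE, envir = feats)
      return(invisible())
    }
    nb <- adj[[atom]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt))
    }
    invisible()
  }
  for (a in seq_len(g$n)) walk(a, a)
  ls(feats)
}

features_to_bits <- function(feats, nbits, tag) {
  bits <- integer(nbits)
  if (length(feats) > 0) {
    idx <- (hash_strings(paste0(tag, "#", feats)) %% nbits) + 1
    bits[unique(idx)] <- 1L
  }
  bits
}

#' Compute a molecular fingerprint
#'
#' @param std_smiles A single standardized SMILES string.
#' @param type One of \code{morgan1024} (circular, radius 2),
#'   \code{rdkit_path} (linear paths up to 7 bonds, 2048 bits),
#'   \code{maccs166} (OpenBabel MACCS keys), \code{atompairs1024},
#'   \code{toptorsion1024}, or \code{extended2048} (path + circular hybrid
#'   used for chemical-space clustering).
#' @return Object of class \code{fingerprint}: list with \code{type} and an
#'   integer 0/1 \code{bits} vector of the mandated length.
#' @export
compute_fingerprint <- function(std_smiles, type) {
  structure(list(type = type, bits = fingerprint_matrix(std_smiles, type)[1, ]),
            class = "fingerprint")
}

#' Compute fingerprints for a set of molecules
#'
#' @param std_smiles Character vector of standardized SMILES.
#' @param type Fingerprint type (see \code{\link{compute_fingerprint}}).
#' @return Integer 0/1 matrix, one row per molecule, with the fingerprint
#'   type in attribute \code{"fp_type"}.
#' @export
fingerprint_matrix <- function(std_smiles, type) {
  if (!type %in% names(FP_LENGTHS)) {
    ls_stop("unknown_type", "unknown fingerprint type: %s", type)
  }
  bad <- is.na(canonicalize_smiles(std_smiles))
  if (any(bad)) {
    ls_stop("featurization_error", "unparseable SMILES at position(s) %s",
            paste(which(bad), collapse = ","))
  }
  nbits <- FP_LENGTHS[[type]]
  if (type == "maccs166") {
    txt <- paste0(std_smiles, "\tm", seq_along(std_smiles), "\n", collapse = "")
    rows <- ChemmineOB::forEachMol("SMILES", txt, function(mol) {
      as.integer(ChemmineOB::fingerprint_OB(list(mol), "MACCS"))
    })
    if (length(rows) != length(std_smiles)) ls_stop("featurization_error", "fingerprinting lost records")
    m <- do.call(rbind, rows)
    out <- m[, seq_len(166), drop = FALSE]
  } else {
    # fingerprints are computed on the canonical form, making them invariant
    # to the atom ordering of the input string
    can <- canonicalize_smiles(std_smiles)
    gs <- mol_graphs(can)
    out <- t(vapply(gs, function(g) {
      switch(type,
        morgan1024 = features_to_bits(morgan_features(g), nbits, "mg"),
        rdkit_path = features_to_bits(path_features(g), nbits, "pt"),
        atompairs1024 = features_to_bits(atompair_features(g), nbits, "ap"),
        toptorsion1024 = features_to_bits(torsion_features(g), nbits, "tt"),
        extended2048 = features_to_bits(
          c(paste0("P", path_features(g)), paste0("M", morgan_features(g))),
          nbits, "ex")
      )
    }, integer(nbits)))
  }
  rownames(out) <- names(std_smiles)
  attr(out, "fp_type") <- type
  out
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} on the set bits; defined as 1 when both
#' vectors are empty. Errors if the two fingerprints are of different types.
#'
#' @param a,b \code{fingerprint} objects (or plain 0/1 vectors).
#' @return Similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  ta <- if (inherits(a, "fingerprint")) a$type else NULL
  tb <- if (inherits(b, "fingerprint")) b$type else NULL
  if (!is.null(ta) && !is.null(tb) && ta != tb) {
    ls_stop("type_mismatch", "fingerprint types differ: %s vs %s", ta, tb)
  }
  va <- if (inherits(a, "fingerprint")) a$bits else a
  vb <- if (inherits(b, "fingerprint")) b$bits else b
  stopifnot(length(va) == length(vb))
  inter <- sum(va & vb)
  uni <- sum(va | vb)
  if (uni == 0) 1 else inter / uni
}

# Pairwise Tanimoto for the rows of a 0/1 matrix; all-zero pairs get 1.
tanimoto_matrix <- function(m) {
  m <- matrix(as.numeric(m), nrow = nrow(m))
  inter <- tcrossprod(m)
  pop <- rowSums(m)
  uni <- outer(pop, pop, "+") - inter
  s <- ifelse(uni == 0, 1, inter / uni)
  s
}
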