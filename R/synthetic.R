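# Seeded synthetic inputs with the statistical structure the pipeline
# assumes: a balanced active/decoy benchmark with a planted structural motif,
# an unlabeled screening library with a minority of planted actives, and
# per-ligand binding-energy component tables.
#
# Actives are fatty-acid-like: a carboxylic-acid head on an unsaturated
# aliphatic chain of at least eight carbons, so lipophilic-chain features
# give every fingerprint type a learnable, chemically meaningful signal.
# Decoys are decorated aromatic, heterocyclic and sugar scaffolds drawn from
# a built-in list and are verified not to contain the motif.

#' Default planted motif: unsaturated eight-carbon carboxylic-acid chain
#' @export
DEFAULT_MOTIF <- "C=CCCCCCC(=O)O"

ACTIVE_TAIL_UNITS <- c("C", "CC", "C=CC", "C(C)C")

DECOY_SCAFFOLDS <- c(
  "c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "c1ccoc1", "c1ccsc1",
  "c1cncnc1", "OCC1OC(O)C(O)C(O)C1O", "OC1CCCCC1", "NC(=O)c1ccccc1",
  "Oc1ccc2ccccc2c1"
)

DECOY_PREFIXES <- c("", "C", "CC", "CCC", "O", "OC", "N", "NC", "Cl", "F", "COC")

#' Configuration for the synthetic benchmark generator
#'
#' @param n_actives,n_decoys Nonnegative record counts.
#' @param motif Substructure pattern planted in every active and absent from
#'   every decoy (before label noise).
#' @param label_noise Fraction in [0,1] of labels flipped independently.
#' @param seed Integer seed; identical configurations yield identical output.
#' @export
synthetic_config <- function(n_actives, n_decoys, motif = DEFAULT_MOTIF,
                             label_noise = 0, seed = 42) {
  if (!is.numeric(n_actives) || !is.numeric(n_decoys) ||
      n_actives < 0 || n_decoys < 0 ||
      n_actives != round(n_actives) || n_decoys != round(n_decoys)) {
    ls_stop("invalid_config", "n_actives and n_decoys must be nonnegative integers")
  }
  if (!is.numeric(label_noise) || label_noise < 0 || label_noise > 1) {
    ls_stop("invalid_config", "label_noise must lie in [0,1]")
  }
  # the motif must parse as a substructure pattern
  smarts_match_count("CCO", motif)
  structure(list(n_actives = as.integer(n_actives), n_decoys = as.integer(n_decoys),
                 motif = motif, label_noise = label_noise, seed = seed),
            class = "synthetic_config")
}

# The motif doubles as the planted core, so it must itself be a valid SMILES
# fragment (the default is). Random aliphatic tails are prepended for
# structural variety; candidates that fail to parse fall back to the bare core.
gen_active_smiles <- function(n, core = DEFAULT_MOTIF) {
  if (n == 0) return(character(0))
  if (is.na(canonicalize_smiles(core))) {
    ls_stop("invalid_motif", "motif must be a valid SMILES fragment to plant: %s", core)
  }
  out <- vapply(seq_len(n), function(i) {
    k <- sample(0:5, 1)
    tail <- if (k > 0) paste(sample(ACTIVE_TAIL_UNITS, k, replace = TRUE), collapse = "") else ""
    paste0(tail, core)
  }, character(1))
  out[is.na(canonicalize_smiles(out))] <- core
  out
}

gen_decoy_smiles <- function(n, motif) {
  if (n == 0) return(character(0))
  draw <- function(m) {
    paste0(sample(DECOY_PREFIXES, m, replace = TRUE),
           sample(DECOY_SCAFFOLDS, m, replace = TRUE))
  }
  out <- draw(n)
  for (round in 1:5) {
    hits <- smarts_match_count(out, motif) > 0
    if (!any(hits)) break
    out[hits] <- draw(sum(hits))
  }
  hits <- smarts_match_count(out, motif) > 0
  out[hits] <- "c1ccccc1"
  out
}

#' Generate a labeled synthetic benchmark set
#'
#' Every active contains the planted motif and no decoy does; labels are then
#' flipped independently with probability \code{label_noise}. All emitted
#' SMILES are canonical (they round-trip unchanged).
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return A molecule table (\code{id}, \code{smiles}, \code{label},
#'   \code{source}) of \code{n_actives + n_decoys} records.
#' @export
gen_benchmark_set <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_stream(config$seed, "gen_benchmark_set", {
    act <- gen_active_smiles(config$n_actives, config$motif)
    dec <- gen_decoy_smiles(config$n_decoys, config$motif)
    smiles <- canonicalize_smiles(c(act, dec))
    stopifnot(!anyNA(smiles))
    lab <- c(rep("active", config$n_actives), rep("inactive", config$n_decoys))
    if (config$label_noise > 0 && length(lab) > 0) {
      flip <- stats::runif(length(lab)) < config$label_noise
      lab[flip] <- ifelse(lab[flip] == "active", "inactive", "active")
    }
    out <- data.frame(
      id = c(sprintf("act_%04d", seq_len(config$n_actives)),
             sprintf("dec_%04d", seq_len(config$n_decoys))),
      smiles = smiles, label = lab,
      source = c(rep("synthetic_active", config$n_actives),
                 rep("synthetic_decoy", config$n_decoys)),
      stringsAsFactors = FALSE
    )
    class(out) <- c("molecule_table", "data.frame")
    out
  })
}

#' Generate an unlabeled screening library with planted actives
#'
#' @param n Library size.
#' @param n_planted_actives Number of motif-bearing molecules hidden in the
#'   library (must not exceed \code{n}).
#' @param seed Integer seed.
#' @param motif Planted motif (default \code{\link{DEFAULT_MOTIF}}).
#' @return List with \code{records} (molecule table, labels all
#'   \code{unknown}) and \code{truth} (named 0/1 vector by id, for test
#'   assertions only).
#' @export
gen_screen_library <- function(n, n_planted_actives, seed = 42, motif = DEFAULT_MOTIF) {
  if (n_planted_actives > n) {
    ls_stop("invalid_config", "n_planted_actives (%d) exceeds n (%d)", n_planted_actives, n)
  }
  with_stream(seed, "gen_screen_library", {
    act <- gen_active_smiles(n_planted_actives, motif)
    dec <- gen_decoy_smiles(n - n_planted_actives, motif)
    smiles <- if (n > 0) canonicalize_smiles(c(act, dec)) else character(0)
    truth <- c(rep(1L, n_planted_actives), rep(0L, n - n_planted_actives))
    ord <- if (n > 0) sample(n) else integer(0)
    ids <- sprintf("lib_%04d", seq_len(n))
    records <- data.frame(id = ids, smiles = smiles[ord],
                          label = rep("unknown", n),
                          source = rep("synthetic_library", n),
                          stringsAsFactors = FALSE)
    class(records) <- c("molecule_table", "data.frame")
    list(records = records, truth = stats::setNames(truth[ord], ids))
  })
}

#' Specification for a synthetic binding-energy component table
#'
#' @param ligands Character vector of ligand names (nonempty).
#' @param ranges Named list with elements \code{dE_vdw}, \code{dE_ele},
#'   \code{dG_solv}, each \code{c(min, max)} in kcal/mol.
#' @param sd_range Range for the per-component uncertainties (kcal/mol).
#' @param seed Integer seed.
#' @export
synthetic_energy_spec <- function(ligands,
                                  ranges = list(dE_vdw = c(-35, -10),
                                                dE_ele = c(-20, -1),
                                                dG_solv = c(5, 35)),
                                  sd_range = c(0.5, 3.5), seed = 42) {
  if (length(ligands) == 0) ls_stop("empty_input", "ligand list must be nonempty")
  need <- c("dE_vdw", "dE_ele", "dG_solv")
  if (!all(need %in% names(ranges))) ls_stop("invalid_config", "ranges must cover %s", paste(need, collapse = ", "))
  for (nm in need) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) ls_stop("invalid_config", "range for %s must satisfy min <= max", nm)
  }
  structure(list(ligands = as.character(ligands), ranges = ranges,
                 sd_range = sd_range, seed = seed),
            class = "synthetic_energy_spec")
}

#' Generate a synthetic binding-energy component table
#'
#' One row per ligand with van der Waals, electrostatic and solvation
#' components (plus uncertainties) drawn uniformly from the configured
#' ranges; the exact draws are the returned values, so downstream sums are
#' checkable against them.
#'
#' @param spec A \code{\link{synthetic_energy_spec}}.
#' @return data.frame with columns \code{ligand}, \code{dE_vdw},
#'   \code{dE_ele}, \code{dG_solv} and matching \code{*_sd} columns.
#' @export
gen_energy_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_energy_spec"))
  n <- length(spec$ligands)
  with_stream(spec$seed, "gen_energy_table", {
    draw <- function(r) stats::runif(n, r[1], r[2])
    data.frame(
      ligand = spec$ligands,
      dE_vdw = draw(spec$ranges$dE_vdw),
      dE_vdw_sd = draw(spec$sd_range),
      dE_ele = draw(spec$ranges$dE_ele),
      dE_ele_sd = draw(spec$sd_range),
      dG_solv = draw(spec$ranges$dG_solv),
      dG_solv_sd = draw(spec$sd_range),
      stringsAsFactors = FALSE
    )
  })
}
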