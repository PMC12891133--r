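test_that("salt stripping and neutralization recover the parent acid", {
  r <- standardize_molecule("CC(=O)[O-].[Na+]")
  oracle <- ligandscreen:::canonicalize_smiles("CC(=O)O")
  expect_identical(r$std_smiles, oracle)
  expect_true(all(c("strip_fragments", "neutralize_charges") %in% r$actions))
  expect_true(is.na(r$failure))
})

test_that("already-clean molecules pass through with only canonicalization", {
  r <- standardize_molecule("CCO")
  expect_identical(r$std_smiles, "CCO")
  expect_identical(r$actions, "canonicalize")
})

test_that("unparseable SMILES fail with parse_error and are retained", {
  r <- standardize_molecule("C((")
  expect_true(is.na(r$std_smiles))
  expect_identical(r$failure, "parse_error")

  tbl <- data.frame(id = c("a", "b"), smiles = c("CCO", "C(("),
                    label = "unknown", source = "", stringsAsFactors = FALSE)
  out <- standardize_records(tbl)
  expect_equal(nrow(out), 2)
  rep <- attr(out, "standardization_report")
  expect_identical(rep$failure, c(NA_character_, "parse_error"))
})

test_that("standardization handles metals, explicit hydrogens and zwitterions", {
  r <- standardize_molecule("C([H])([H])([H])O")
  expect_identical(r$std_smiles, "CO")
  # nitro group (balanced internal charges) must survive neutralization
  r2 <- standardize_molecule("c1ccccc1[N+](=O)[O-]")
  expect_false(is.na(r2$std_smiles))
  g <- ligandscreen:::mol_graphs(r2$std_smiles)[[1]]
  expect_equal(sum(g$elem == "N"), 1)
  expect_equal(sum(g$elem == "O"), 2)
})

test_that("standardization is idempotent on the synthetic set and on salts", {
  smi <- c(bench_small()$smiles[1:10], "CC(=O)[O-].[Na+]", "C[NH3+].[Cl-]",
           "OC(=O)c1ccccc1")
  for (s in smi) {
    once <- standardize_molecule(s)$std_smiles
    twice <- standardize_molecule(once)
    expect_identical(twice$std_smiles, once)
  }
})

test_that("molecule tables are parsed with label mapping and duplicate flags", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,label,source",
               "m1,CCO,1,src",
               "m2,OCC,active,src",
               "m3,c1ccccc1,0,src"), path)
  tbl <- parse_smiles_table(path, "csv")
  expect_equal(nrow(tbl), 3)
  expect_identical(tbl$label, c("active", "active", "inactive"))
  dup <- attr(tbl, "duplicates")
  expect_equal(nrow(dup), 1)          # CCO and OCC share a canonical form
  expect_identical(dup$ids, "m1;m2")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,structure", "m1,CCO"), bad)
  expect_error(parse_smiles_table(bad, "csv"), class = "ligandscreen_missing_column")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,smiles,label,source", empty)
  expect_error(parse_smiles_table(empty, "csv"), class = "ligandscreen_empty_input")
})

test_that("molecule tables round-trip through CSV and SMI formats", {
  b <- bench_small()[1:5, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_molecule_csv(b, path)
  back <- parse_smiles_table(path, "csv")
  expect_identical(back$smiles, b$smiles)
  expect_identical(back$label, b$label)

  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(paste(b$smiles, b$id, sep = "\t"), smi)
  back2 <- parse_smiles_table(smi, "smi")
  expect_identical(back2$smiles, b$smiles)
  expect_identical(back2$id, b$id)
})

test_that("balancing draws exactly as many decoys as actives", {
  actives <- data.frame(id = sprintf("a%03d", 1:490), smiles = "CCO",
                        label = "active", source = "", stringsAsFactors = FALSE)
  pool <- data.frame(id = sprintf("d%04d", 1:2000), smiles = "c1ccccc1",
                     label = "unknown", source = "", stringsAsFactors = FALSE)
  out <- balance_dataset(actives, pool, seed = 1)
  expect_equal(sum(out$label == "inactive"), 490)
  expect_equal(sum(out$label == "active"), 490)
  expect_identical(out, balance_dataset(actives, pool, seed = 1))
  expect_false(identical(out$id, balance_dataset(actives, pool, seed = 2)$id))
  expect_error(balance_dataset(actives[1:10, ], pool[1:8, ], seed = 1),
               class = "ligandscreen_pool_too_small")
})

test_that("train/test split honors size, disjointness and stratification", {
  d <- data.frame(id = sprintf("m%04d", 1:980),
                  label = rep(c("active", "inactive"), each = 490))
  sp <- split_dataset(d, ratio = 0.8, seed = 3)
  expect_equal(length(sp$train), 784)   # floor(0.8 * 980)
  expect_equal(length(sp$test), 196)
  expect_length(intersect(sp$train, sp$test), 0)

  d10 <- data.frame(id = letters[1:10], label = rep(c("x", "y"), 5))
  sp10 <- split_dataset(d10, ratio = 0.8, seed = 1)
  expect_equal(length(sp10$train), 8)
  expect_setequal(c(sp10$train, sp10$test), letters[1:10])

  d200 <- data.frame(id = sprintf("m%03d", 1:200),
                     label = rep(c("active", "inactive"), each = 100))
  sp200 <- split_dataset(d200, ratio = 0.8, seed = 2, stratified = TRUE)
  lab <- setNames(d200$label, d200$id)
  expect_equal(unname(table(lab[sp200$train])), c(80L, 80L), ignore_attr = TRUE)

  expect_error(split_dataset(d, ratio = 1.2), class = "ligandscreen_invalid_ratio")
  expect_error(split_dataset(data.frame(id = "a", label = "x"), stratified = TRUE),
               class = "ligandscreen_single_record_class")
})

test_that("split invariants hold across many random sizes and seeds", {
  set.seed(99)
  for (trial in 1:200) {
    n <- sample(5:400, 1)
    ratio <- runif(1, 0.2, 0.9)
    d <- data.frame(id = sprintf("m%05d", seq_len(n)),
                    label = sample(c("a", "b"), n, replace = TRUE))
    strat <- all(table(d$label) > 1)
    sp <- split_dataset(d, ratio = ratio, seed = sample(1e6, 1), stratified = strat)
    expect_equal(length(sp$train), floor(ratio * n))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), d$id)
  }
})

test_that("splits serialize to JSON and back", {
  d <- data.frame(id = letters[1:10], label = rep(c("x", "y"), 5))
  sp <- split_dataset(d, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_json(sp, path)
  back <- read_split_json(path)
  expect_identical(back$train, sp$train)
  expect_identical(back$test, sp$test)
  expect_equal(back$ratio, sp$ratio)
})
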