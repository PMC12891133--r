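test_that("screening returns ranked, thresholded hits for every molecule", {
  b <- bench_small()
  b$std_smiles <- b$smiles
  sp <- split_dataset(b, ratio = 0.8, seed = 1)
  tm <- train_screening_model(b, sp, "morgan1024", "gradient_boosting",
                              grid = data.frame(max_depth = 3), folds = 3, seed = 1)
  lib <- gen_screen_library(40, 5, seed = 2)
  hits <- screen_library(tm, lib$records)
  expect_equal(nrow(hits), 40)
  expect_identical(hits$rank, seq_len(40))
  expect_true(all(diff(hits$score) <= 0))                       # sorted by score
  expect_identical(hits$class == "positive", hits$score >= 0.5) # class iff threshold
  strict <- screen_library(tm, lib$records, threshold = 1.1)
  expect_true(all(strict$class == "negative"))
  expect_error(screen_library(tm, lib$records, fingerprint_type = "maccs166"),
               class = "ligandscreen_fp_type_mismatch")
  path <- withr::local_tempfile(fileext = ".csv")
  write_hits_csv(hits, path)
  expect_equal(nrow(read.csv(path)), 40)
})

test_that("energy aggregation is exact, commutative and order-insensitive", {
  rows <- data.frame(ligand = c("b", "a"), dE_vdw = c(-3L, -10L),
                     dE_ele = c(-2L, 4L), dG_solv = c(1L, 2L))
  agg <- aggregate_energy_components(rows)
  expect_equal(agg$dG_gas, c(-5, -6))
  expect_equal(agg$dG_total, c(-4, -4))
  # commutative in component order
  agg2 <- aggregate_energy_components(rows[, c("ligand", "dG_solv", "dE_ele", "dE_vdw")])
  expect_identical(agg2$dG_total, agg$dG_total)

  zero <- aggregate_energy_components(data.frame(ligand = "x", dE_vdw = 0,
                                                 dE_ele = 0, dG_solv = 0))
  expect_identical(zero$dG_gas, 0)
  expect_identical(zero$dG_total, 0)

  expect_error(aggregate_energy_components(data.frame(ligand = "x", dE_vdw = 1)),
               class = "ligandscreen_missing_component")
  expect_error(aggregate_energy_components(rows[0, ]), class = "ligandscreen_empty_input")
})

test_that("uncertainties propagate in quadrature in separate columns", {
  rows <- data.frame(ligand = "x", dE_vdw = -1, dE_vdw_sd = 3, dE_ele = -1,
                     dE_ele_sd = 4, dG_solv = 1, dG_solv_sd = 12)
  agg <- aggregate_energy_components(rows)
  expect_equal(agg$dG_gas_sd_prop, 5)     # sqrt(9 + 16)
  expect_equal(agg$dG_total_sd_prop, 13)  # sqrt(25 + 144)
})

test_that("candidate ranking is ascending with alphabetical ties and shuffle-proof", {
  rows <- data.frame(ligand = c("Ganolucidic Acid E", "Tetracosanoic acid", "Linolenic acid"),
                     vina = c(-6.0, -5.8, -6.5))
  rk <- rank_candidates(rows, key = "vina")
  expect_identical(rk$ligand[1], "Linolenic acid")
  expect_equal(rk$vina[1], -6.5)
  expect_identical(rank_candidates(rows[c(3, 1, 2), ], key = "vina"), rk)

  one <- rank_candidates(data.frame(ligand = "only", e = -1), key = "e")
  expect_equal(one$rank, 1)

  tie <- rank_candidates(data.frame(ligand = c("zeta", "alpha"), e = c(-2, -2)), key = "e")
  expect_identical(tie$ligand, c("alpha", "zeta"))
  expect_setequal(rk$ligand, rows$ligand)  # output is a permutation of input
  expect_error(rank_candidates(rows, key = "nope"), class = "ligandscreen_missing_key")
})

test_that("hydrogen-bond annotations parse into validated interaction records", {
  one <- collect_interactions("Linolenic acid: ASP79")
  expect_equal(nrow(one), 1)
  expect_identical(one$residue, "ASP")
  expect_equal(one$position, 79)

  two <- collect_interactions("Ganolucidic Acid E: SER66, THR68")
  expect_equal(nrow(two), 2)
  expect_identical(two$residue, c("SER", "THR"))

  all3 <- collect_interactions(readLines(
    system.file("extdata", "hbond_annotations.txt", package = "ligandscreen")))
  expect_equal(nrow(all3), 5)
  expect_true(all(all3$position > 0))

  expect_error(collect_interactions("X: XX9a"), class = "ligandscreen_malformed_token")
  expect_error(collect_interactions("X: ZZZ12"), class = "ligandscreen_unknown_residue")
})

test_that("docking-box configuration renders at input precision and round-trips", {
  box <- vina_box(c(49.137, 21.547, 32.93), c(44.25, 47.25, 43.5))
  txt <- emit_vina_box_config(box)
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(lines, 6)
  expect_identical(lines[1], "center_x = 49.137")
  expect_identical(lines[3], "center_z = 32.93")
  back <- parse_vina_box_config(txt)
  expect_equal(unclass(back), unclass(box))

  simple <- emit_vina_box_config(vina_box(c(0, 0, 0), c(10, 10, 10)))
  expect_true(all(grepl("= (0|10)$", strsplit(simple, "\n")[[1]])))

  expect_error(vina_box(c(0, 0, 0), c(-1, 10, 10)), class = "ligandscreen_invalid_box")

  shipped <- parse_vina_box_config(paste(readLines(
    system.file("extdata", "vina_box.txt", package = "ligandscreen")), collapse = "\n"))
  expect_equal(shipped$size_y, 47.25)
})
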