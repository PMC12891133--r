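# Independent oracles and shared fixtures. The oracles are deliberately
# brute-force (loops, explicit pair counting) so they share no code with the
# implementation paths they check.

# exhaustive bit-set Tanimoto
tanimoto_oracle <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    if (a[i] == 1 || b[i] == 1) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

# Mann-Whitney AUC by exhaustive pair counting (ties count 1/2)
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    if (p > q) wins <- wins + 1
    else if (p == q) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# direct hand evaluation of each metric formula from the four counts
metrics_hand_oracle <- function(TP, FP, TN, FN) {
  n <- TP + FP + TN + FN
  SE <- if (TP + FN == 0) 0 else TP / (TP + FN)
  SP <- if (TN + FP == 0) 0 else TN / (TN + FP)
  P <- if (TP + FP == 0) 0 else TP / (TP + FP)
  F1 <- if (P + SE == 0) 0 else 2 * P * SE / (P + SE)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  list(SE = SE, SP = SP, ACC = (TP + TN) / n, MCC = MCC, P = P, F1 = F1,
       BA = (SE + SP) / 2)
}

# exhaustive argmax of mean Tanimoto similarity to the other cluster members
representative_oracle <- function(fp_matrix) {
  m <- nrow(fp_matrix)
  if (m == 1) return(1L)
  best <- 1L; best_val <- -Inf
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_len(m)) {
      if (i == j) next
      s <- s + tanimoto_oracle(fp_matrix[i, ], fp_matrix[j, ])
    }
    val <- s / (m - 1)
    if (val > best_val + 1e-12) { best <- i; best_val <- val }
  }
  best
}

with_seed_shuffle <- function(x, seed) {
  withr::with_seed(seed, sample(x))
}

# shared synthetic fixtures, built once per test run
.fixtures <- new.env()

bench_small <- function() {
  if (is.null(.fixtures$bench_small)) {
    cfg <- synthetic_config(30, 30, label_noise = 0, seed = 7)
    .fixtures$bench_small <- gen_benchmark_set(cfg)
  }
  .fixtures$bench_small
}

bench_fps <- function(type = "morgan1024") {
  key <- paste0("fps_", type)
  if (is.null(.fixtures[[key]])) {
    b <- bench_small()
    fp <- fingerprint_matrix(b$smiles, type)
    rownames(fp) <- b$id
    .fixtures[[key]] <- fp
  }
  .fixtures[[key]]
}
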