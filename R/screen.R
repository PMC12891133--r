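# Library screening with a trained model, and prioritization of predicted
# hits from tabulated docking scores and MM-PBSA binding-energy components.

#' Screen a compound library with a trained model
#'
#' Featurizes the library with the model's fingerprint type, scores every
#' molecule and assigns the positive class at the given threshold. Hits are
#' returned sorted by descending score.
#'
#' @param tuned A \code{tuned_model} (or \code{ligandscreen_model}) carrying
#'   a \code{fingerprint_type} attribute, from the training pipeline.
#' @param library_records Molecule table with \code{id} and a SMILES column
#'   (\code{std_smiles} preferred, else \code{smiles}).
#' @param threshold Score threshold for the positive class (default 0.5).
#' @param fingerprint_type Override for the fingerprint type; must match the
#'   model metadata when both are present.
#' @return data.frame of class \code{screening_hits}: \code{id},
#'   \code{score}, \code{class} (\code{positive}/\code{negative}),
#'   \code{rank}.
#' @export
screen_library <- function(tuned, library_records, threshold = 0.5,
                           fingerprint_type = NULL) {
  model <- if (inherits(tuned, "tuned_model")) tuned$model else tuned
  meta_fp <- attr(tuned, "fingerprint_type") %||% attr(model, "fingerprint_type")
  fp_type <- fingerprint_type %||% meta_fp
  if (is.null(fp_type)) ls_stop("fp_type_missing", "no fingerprint type on model or argument")
  if (!is.null(meta_fp) && !identical(fp_type, meta_fp)) {
    ls_stop("fp_type_mismatch", "library fingerprint %s does not match model fingerprint %s",
            fp_type, meta_fp)
  }
  smi <- library_records$std_smiles %||% library_records$smiles
  X <- fingerprint_matrix(smi, fp_type)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  scores <- predict(model, X)
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(id = library_records$id[ord], score = scores[ord],
                    class = ifelse(scores[ord] >= threshold, "positive", "negative"),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  class(out) <- c("screening_hits", "data.frame")
  out
}

#' Train the screening model end to end
#'
#' Convenience wrapper: computes the requested fingerprint on the training
#' partition, runs grid-search CV and refits, and stamps the fingerprint
#' type on the result so \code{\link{screen_library}} can check it.
#'
#' @param dataset data.frame with \code{id}, \code{std_smiles}, \code{label}.
#' @param split A \code{dataset_split}.
#' @param fingerprint_type Fingerprint used for modeling.
#' @param family Model family.
#' @param grid Optional reduced grid.
#' @param folds CV folds.
#' @param seed Integer seed.
#' @return A \code{tuned_model} with attributes \code{fingerprint_type} and
#'   \code{test_report} (held-out metric report).
#' @export
train_screening_model <- function(dataset, split, fingerprint_type = "morgan1024",
                                  family = "gradient_boosting", grid = NULL,
                                  folds = 5, seed = 42) {
  lab <- as.integer(dataset$label == "active")
  fp <- fingerprint_matrix(dataset$std_smiles, fingerprint_type)
  rownames(fp) <- dataset$id
  colnames(fp) <- paste0("b", seq_len(ncol(fp)))
  tr <- match(split$train, dataset$id); te <- match(split$test, dataset$id)
  tuned <- tune_and_train(fp[tr, , drop = FALSE], lab[tr], family,
                          grid = grid, folds = folds, seed = seed)
  sc <- predict(tuned$model, fp[te, , drop = FALSE])
  rep <- compute_metrics(confusion_counts(lab[te], as.integer(sc >= 0.5)), sc, lab[te])
  attr(tuned, "fingerprint_type") <- fingerprint_type
  attr(tuned, "test_report") <- rep
  tuned
}

#' Write screening hits as CSV (`id,score,class,rank`)
#' @param hits A \code{screening_hits} table.
#' @param path Output path.
#' @export
write_hits_csv <- function(hits, path) {
  utils::write.csv(as.data.frame(hits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
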