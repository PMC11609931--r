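# Six-way modality ablation. Each subset gets its own model trained FROM
# SCRATCH with only those modality branches instantiated (the fusion head
# then attends over, and renormalises its weights across, the present
# modalities only); all subsets share the same seeds so differences come
# from the modality mask alone.

#' The six studied modality combinations
#'
#' Image alone, series alone, image + series, text + series, text + image,
#' and all three.
#'
#' @return named list of character vectors.
#' @export
ablation_subsets <- function() {
  list(
    image = "image",
    series = "series",
    image_series = c("image", "series"),
    text_series = c("text", "series"),
    text_image = c("text", "image"),
    text_image_series = c("text", "image", "series")
  )
}

subset_key <- function(mods) paste(sort(mods), collapse = "+")

#' Run the modality-ablation experiment
#'
#' For each modality subset, trains a fresh model restricted to those
#' branches (same training seed for every subset) and evaluates it on the
#' test split.
#'
#' @param dataset list with `samples` and `manifest`.
#' @param config base [model_config()] (its `modalities` field is replaced
#'   by each subset in turn).
#' @param tc a [train_config()].
#' @param subsets list of character vectors; defaults to the six studied
#'   combinations from [ablation_subsets()].
#' @return list with `reports` (named list of [metric_report()]s),
#'   `ranking` (subset names ordered by decreasing AUC), and `summary`
#'   (data frame of the headline metrics).
#' @export
ablate <- function(dataset, config = model_config(), tc = train_config(),
                   subsets = ablation_subsets()) {
  if (length(subsets) == 0L) stopf("ablate: no modality subsets given")
  if (is.null(names(subsets))) {
    names(subsets) <- vapply(subsets, subset_key, "")
  }
  reports <- list()
  for (nm in names(subsets)) {
    mods <- subsets[[nm]]
    if (length(mods) == 0L) stopf("ablate: empty modality subset '%s'", nm)
    cfg_s <- config
    cfg_s$modalities <- mods
    validate_model_config(cfg_s)
    model <- train_model(dataset, cfg_s, tc)
    reports[[nm]] <- evaluate_model(model, dataset)
  }
  aucs <- vapply(reports, `[[`, numeric(1), "auc")
  summary <- data.frame(
    subset = names(reports),
    modalities = vapply(subsets, paste, "", collapse = ","),
    precision = vapply(reports, `[[`, numeric(1), "precision"),
    recall = vapply(reports, `[[`, numeric(1), "recall"),
    f1 = vapply(reports, `[[`, numeric(1), "f1"),
    auc = aucs,
    row.names = NULL
  )
  list(reports = reports, ranking = names(sort(aucs, decreasing = TRUE)),
       summary = summary)
}
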