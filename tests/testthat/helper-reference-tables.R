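# Published per-class results of an external three-class osteosarcoma
# histology benchmark (viable tumor / non-viable tumor / non-tumor), used to
# cross-check the metric arithmetic: the printed F-scores must follow from
# the printed precision/recall pairs and the printed Average rows from the
# per-class cells, all at two-decimal presentation.
reference_tables <- function() {
  cols <- c("class", "accuracy", "precision", "recall", "f_score", "mcc",
            "g_mean")
  mk <- function(...) {
    df <- as.data.frame(matrix(c(...), ncol = 7, byrow = TRUE),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    df[-1] <- lapply(df[-1], as.numeric)
    df
  }
  list(
    split_80_train = mk(
      "VT",      99.45, 98.49, 99.62, 99.05, 98.67, 99.50,
      "NVT",     98.91, 97.71, 97.71, 97.71, 96.99, 98.49,
      "NT",      98.36, 98.61, 97.93, 98.27, 96.71, 98.34,
      "Average", 98.91, 98.27, 98.42, 98.34, 97.46, 98.78),
    split_80_test = mk(
      "VT",      100.00, 100.00, 100.00, 100.00, 100.00, 100.00,
      "NVT",     99.56,  97.83, 100.00,  98.90,  98.64,  99.73,
      "NT",      99.56, 100.00,  99.01,  99.50,  99.12,  99.50,
      "Average", 99.71,  99.28,  99.67,  99.47,  99.25,  99.74),
    split_70_train = mk(
      "VT",      99.00, 98.30, 98.30, 98.30, 97.59, 98.79,
      "NVT",     99.25, 99.43, 97.19, 98.30, 97.83, 98.51,
      "NT",      99.00, 98.47, 99.48, 98.97, 98.00, 99.01,
      "Average", 99.08, 98.73, 98.32, 98.52, 97.81, 98.77),
    split_70_test = mk(
      "VT",      99.42, 99.09, 99.09, 99.09, 98.66, 99.33,
      "NVT",     99.13, 98.81, 97.65, 98.22, 97.65, 98.63,
      "NT",      99.13, 98.67, 99.33, 99.00, 98.23, 99.15,
      "Average", 99.22, 98.86, 98.69, 98.77, 98.18, 99.04))
}
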