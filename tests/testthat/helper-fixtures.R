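# small in-code fixtures shared across test files

writeSimTSV <- function(values, labels, path = tempfile(fileext = ".tsv")) {
  df <- as.data.frame(values)
  rownames(df) <- labels
  colnames(df) <- labels[seq_len(ncol(values))]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  path
}

# 3 miRNAs x 2 diseases toy problem with hand-set similarities
toyData <- function() {
  simM <- SimilarityMatrix(
    matrix(c(1, .5, .1,
             .5, 1, .2,
             .1, .2, 1), 3, 3, byrow = TRUE),
    c("m1", "m2", "m3"))
  simD <- SimilarityMatrix(matrix(c(1, .3, .3, 1), 2, 2), c("d1", "d2"))
  screenData(data.frame(mirna = c("m1", "m2"), disease = c("d1", "d1")),
             simM, simD)
}
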