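#' Construct a SimilarityMatrix
#'
#' Validates and wraps a square similarity matrix. Values must be finite and
#' within \code{[0, 1]}; out-of-range values are rejected rather than clipped,
#' because they indicate malformed input and silent clipping would shift every
#' centroid computed from the rows. Diagonal entries different from 1 trigger
#' a warning only: the matrices are used exactly as supplied.
#'
#' @param values numeric square matrix.
#' @param labels character vector of entity names; defaults to the matrix
#'   rownames.
#' @return a \code{\linkS4class{SimilarityMatrix}}.
#' @examples
#' sim <- SimilarityMatrix(diag(3), labels = c("a", "b", "c"))
#' simLabels(sim)
#' @export
SimilarityMatrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(labels)) {
    labels <- as.character(seq_len(nrow(values)))
  }
  obj <- new("SimilarityMatrix", labels = as.character(labels),
             values = unname(values))
  dg <- diag(obj@values)
  if (any(abs(dg - 1) > 1e-8)) {
    warning(sprintf(
      "%d diagonal entries differ from 1 (e.g. '%s' = %s); kept as given",
      sum(abs(dg - 1) > 1e-8),
      obj@labels[which(abs(dg - 1) > 1e-8)[1L]],
      format(dg[which(abs(dg - 1) > 1e-8)[1L]])), call. = FALSE)
  }
  obj
}

#' Load a similarity matrix from a labelled TSV file
#'
#' Expected dialect: first row = tab-separated entity labels, first column =
#' the same labels, cells = decimal similarity scores.
#'
#' @param path file path.
#' @param kind \code{"mirna"} or \code{"disease"}; recorded only for error
#'   messages, both kinds share the same format.
#' @return a \code{\linkS4class{SimilarityMatrix}}.
#' @seealso \code{\link{writeSimilarityMatrix}} for the inverse.
#' @export
loadSimilarityMatrix <- function(path, kind = c("mirna", "disease")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df)
  if (nrow(v) != ncol(v)) {
    stop(sprintf("%s similarity file '%s' is not square: %d rows x %d columns",
                 kind, path, nrow(v), ncol(v)))
  }
  if (!identical(rownames(v), colnames(v))) {
    stop(sprintf("%s similarity file '%s': row labels differ from column labels",
                 kind, path))
  }
  if (!is.numeric(v)) {
    stop(sprintf("%s similarity file '%s' contains non-numeric cells",
                 kind, path))
  }
  SimilarityMatrix(v, labels = rownames(v))
}

#' Write a SimilarityMatrix as labelled TSV
#'
#' Round-trips bit-exactly with \code{\link{loadSimilarityMatrix}} for the
#' supported dialect (up to 15 significant digits).
#'
#' @param sim a \code{SimilarityMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  stopifnot(is(sim, "SimilarityMatrix"))
  v <- simValues(sim)
  # 17 significant digits keep the binary doubles bit-exact on re-load
  df <- as.data.frame(apply(v, 2L, sprintf, fmt = "%.17g"),
                      check.names = FALSE)
  rownames(df) <- rownames(v)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Read an association edge list
#'
#' Two columns, miRNA label then disease label; delimiter is sniffed from the
#' first line (comma or tab). Duplicate pairs are dropped with a warning.
#'
#' @param path file path.
#' @param header logical; does the file carry a header line?
#' @return data.frame with character columns \code{mirna}, \code{disease}.
#' @export
readAssociations <- function(path, header = TRUE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- if (header) {
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, quote = "\"")
  } else {
    utils::read.table(path, header = FALSE, sep = sep,
                      stringsAsFactors = FALSE, quote = "\"",
                      col.names = c("mirna", "disease"))
  }
  if (ncol(df) < 2L) stop(sprintf("association file '%s' needs two columns", path))
  df <- df[, 1:2]
  names(df) <- c("mirna", "disease")
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate association pairs", sum(dup)),
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Assemble a ScreenData object
#'
#' Resolves association labels against both similarity matrices and freezes
#' the canonical pair indexing (row-major over miRNA index then disease
#' index, in matrix label order).
#'
#' @param assoc data.frame with columns \code{mirna}, \code{disease}: either
#'   character labels (resolved against the matrices) or 1-based integer
#'   indices.
#' @param simM miRNA \code{SimilarityMatrix}.
#' @param simD disease \code{SimilarityMatrix}.
#' @return a \code{\linkS4class{ScreenData}}.
#' @examples
#' simM <- SimilarityMatrix(diag(3), c("m1", "m2", "m3"))
#' simD <- SimilarityMatrix(diag(2), c("d1", "d2"))
#' sd <- screenData(data.frame(mirna = "m1", disease = "d2"), simM, simD)
#' nMirna(sd)
#' @export
screenData <- function(assoc, simM, simD) {
  stopifnot(is(simM, "SimilarityMatrix"), is(simD, "SimilarityMatrix"))
  assoc <- as.data.frame(assoc)
  if (!all(c("mirna", "disease") %in% names(assoc))) {
    names(assoc)[1:2] <- c("mirna", "disease")
  }
  resolve <- function(x, labels, what) {
    if (is.numeric(x)) return(as.integer(x))
    idx <- match(as.character(x), labels)
    if (anyNA(idx)) {
      stop(sprintf("%s label '%s' not found in its similarity matrix",
                   what, as.character(x)[which(is.na(idx))[1L]]))
    }
    idx
  }
  assoc2 <- data.frame(
    mirna = resolve(assoc$mirna, simM@labels, "miRNA"),
    disease = resolve(assoc$disease, simD@labels, "disease"))
  new("ScreenData", simM = simM, simD = simD, assoc = assoc2)
}

#' Canonical pair indexing
#'
#' All staged sample sets store pairs under one canonical order: row-major
#' over (miRNA index, disease index), i.e. pair \code{(i, j)} has index
#' \code{(i - 1) * nDisease + j}.
#'
#' @param mirnaIndex,diseaseIndex 1-based entity indices (vectorised).
#' @param nDisease number of diseases.
#' @return \code{pairIndex}: integer pair indices. \code{pairEntities}: a
#'   data.frame with columns \code{mirna}, \code{disease} of entity indices.
#' @export
pairIndex <- function(mirnaIndex, diseaseIndex, nDisease) {
  as.integer((mirnaIndex - 1L) * nDisease + diseaseIndex)
}

#' @rdname pairIndex
#' @param pair canonical pair indices.
#' @export
pairEntities <- function(pair, nDisease) {
  pair <- as.integer(pair)
  data.frame(mirna = (pair - 1L) %/% nDisease + 1L,
             disease = (pair - 1L) %% nDisease + 1L)
}

#' Build the similarity-profile feature vector of one pair
#'
#' The feature vector concatenates the pair's miRNA similarity profile (its
#' row of the miRNA matrix, first) with its disease similarity profile (its
#' row of the disease matrix, second), giving length m + d. With the
#' benchmark dimensions of 495 miRNAs and 383 diseases this is the familiar
#' 878-dimensional representation.
#'
#' @param mirnaIndex,diseaseIndex 1-based indices into the two matrices.
#' @param simM,simD the two \code{SimilarityMatrix} objects.
#' @return numeric vector of length \code{m + d}.
#' @export
buildFeatureVector <- function(mirnaIndex, diseaseIndex, simM, simD) {
  stopifnot(is(simM, "SimilarityMatrix"), is(simD, "SimilarityMatrix"))
  m <- length(simM@labels); d <- length(simD@labels)
  if (mirnaIndex < 1L || mirnaIndex > m) {
    stop(sprintf("miRNA index %d out of range [1, %d]", mirnaIndex, m))
  }
  if (diseaseIndex < 1L || diseaseIndex > d) {
    stop(sprintf("disease index %d out of range [1, %d]", diseaseIndex, d))
  }
  c(simM@values[mirnaIndex, ], simD@values[diseaseIndex, ])
}

#' Feature matrix for a set of pairs
#'
#' Vectorised form of \code{\link{buildFeatureVector}}: one row per pair, in
#' the order given.
#'
#' @param data a \code{ScreenData}.
#' @param pairs canonical pair indices; default all \code{m * d} pairs.
#' @return numeric matrix, \code{length(pairs)} rows x \code{m + d} columns,
#'   rownames = pair indices.
#' @export
pairFeatures <- function(data, pairs = seq_len(nMirna(data) * nDisease(data))) {
  stopifnot(is(data, "ScreenData"))
  ent <- pairEntities(pairs, nDisease(data))
  if (any(ent$mirna < 1L | ent$mirna > nMirna(data)) ||
      any(pairs < 1L)) {
    stop("pair index out of range")
  }
  X <- cbind(data@simM@values[ent$mirna, , drop = FALSE],
             data@simD@values[ent$disease, , drop = FALSE])
  rownames(X) <- as.character(pairs)
  X
}

#' Partition all pairs into positive and unlabelled sets
#'
#' Known associations become the positive set P; every other cell of the
#' miRNA x disease grid becomes the unlabelled set U. Sizes always satisfy
#' |P| + |U| = m * d.
#'
#' @param data a \code{ScreenData} (or pass \code{assoc}, \code{simM},
#'   \code{simD} to build one first via \code{\link{screenData}}).
#' @return a \code{\linkS4class{SampleSets}} with \code{P} and \code{U}
#'   filled.
#' @export
partitionSamples <- function(data) {
  stopifnot(is(data, "ScreenData"))
  m <- nMirna(data); d <- nDisease(data)
  P <- sort(pairIndex(data@assoc$mirna, data@assoc$disease, d))
  U <- setdiff(seq_len(m * d), P)
  new("SampleSets", nMirna = m, nDisease = d,
      P = as.integer(P), U = as.integer(U))
}

#' Export staged sample sets as CSV
#'
#' Writes one row per pair with its entity labels and deepest stage reached,
#' stage in \code{P, LP1, LN1, LN2, RN, RP} (a reliable negative is written
#' as RN, not also as LN1/LN2; reliable positives as RP).
#'
#' @param result a \code{ScreenResult}.
#' @param data the \code{ScreenData} the result came from (for labels).
#' @param path output CSV path.
#' @return the exported data.frame, invisibly.
#' @export
writeStages <- function(result, data, path) {
  stopifnot(is(result, "ScreenResult"), is(data, "ScreenData"))
  sets <- stageSets(result)
  stage <- character(0); pair <- integer(0)
  add <- function(idx, lab) {
    pair <<- c(pair, idx); stage <<- c(stage, rep(lab, length(idx)))
  }
  add(sets@P, "P")
  add(sets@RN, "RN")
  rp <- setdiff(sets@RP, sets@RN)
  add(rp, "RP")
  add(setdiff(sets@LN2, union(sets@RN, rp)), "LN2")
  add(setdiff(sets@LN1, union(sets@LN2, union(sets@RN, rp))), "LN1")
  add(setdiff(sets@LP1, rp), "LP1")
  ent <- pairEntities(pair, sets@nDisease)
  df <- data.frame(mirna = data@simM@labels[ent$mirna],
                   disease = data@simD@labels[ent$disease],
                   stage = stage)
  df <- df[order(pair), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
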