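#' Accessors for PUScreen classes
#'
#' Small accessor functions so user code never touches slots directly.
#'
#' @param x a \code{SimilarityMatrix}, \code{ScreenData},
#'   \code{ScreenResult} or \code{SampleSets} object (see each accessor).
#' @name accessors
NULL

#' @describeIn accessors labels of a \code{SimilarityMatrix}.
#' @export
simLabels <- function(x) {
  stopifnot(is(x, "SimilarityMatrix"))
  x@labels
}

#' @describeIn accessors value matrix of a \code{SimilarityMatrix}
#'   (with labels as dimnames).
#' @export
simValues <- function(x) {
  stopifnot(is(x, "SimilarityMatrix"))
  v <- x@values
  dimnames(v) <- list(x@labels, x@labels)
  v
}

#' @describeIn accessors number of miRNAs in a \code{ScreenData}.
#' @export
nMirna <- function(x) {
  stopifnot(is(x, "ScreenData"))
  length(x@simM@labels)
}

#' @describeIn accessors number of diseases in a \code{ScreenData}.
#' @export
nDisease <- function(x) {
  stopifnot(is(x, "ScreenData"))
  length(x@simD@labels)
}

#' @describeIn accessors the staged \code{SampleSets} of a
#'   \code{ScreenResult}.
#' @export
stageSets <- function(x) {
  stopifnot(is(x, "ScreenResult"))
  x@sets
}

#' @describeIn accessors pair indices of the final reliable negative set.
#' @export
reliableNegatives <- function(x) {
  stopifnot(is(x, "ScreenResult"))
  x@sets@RN
}

#' @describeIn accessors pair indices of the reliable positive set.
#' @export
reliablePositives <- function(x) {
  stopifnot(is(x, "ScreenResult"))
  x@sets@RP
}

#' @describeIn accessors named numeric margins of the reliable negatives.
#' @export
rnScores <- function(x) {
  stopifnot(is(x, "ScreenResult"))
  x@rnScores
}

#' @describeIn accessors the config snapshot of a \code{ScreenResult}.
#' @export
configSnapshot <- function(x) {
  stopifnot(is(x, "ScreenResult"))
  x@config
}

#' @describeIn accessors named stage sizes of a \code{ScreenResult}.
#' @export
stageSizes <- function(x) {
  stopifnot(is(x, "ScreenResult"))
  x@stageSizes
}

#' Extract one staged set from SampleSets
#'
#' @param sets a \code{SampleSets} object.
#' @param stage one of \code{"P"}, \code{"U"}, \code{"LP1"}, \code{"LN1"},
#'   \code{"LN2"}, \code{"RN"}, \code{"RP"}.
#' @return integer vector of canonical pair indices.
#' @export
sampleSet <- function(sets, stage) {
  stopifnot(is(sets, "SampleSets"))
  stage <- match.arg(stage, c("P", "U", "LP1", "LN1", "LN2", "RN", "RP"))
  slot(sets, stage)
}
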