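#' @import methods
NULL

#' SimilarityMatrix: a labelled square similarity matrix
#'
#' Holds a square matrix of pairwise similarity scores in \code{[0, 1]} with a
#' single ordered label set shared by rows and columns. Used for both the
#' miRNA functional-similarity matrix and the disease semantic-similarity
#' matrix; each row is the similarity profile of one entity and becomes one
#' half of a pair's feature vector.
#'
#' Validity requires a square, finite matrix with values in \code{[0, 1]} and
#' identical, duplicate-free row/column labels. A diagonal entry different
#' from 1 is tolerated (the matrices are used as given) but
#' \code{\link{SimilarityMatrix}} warns about it at construction.
#'
#' @slot labels character vector of entity names, in matrix order.
#' @slot values numeric square matrix of similarity scores.
#'
#' @seealso \code{\link{SimilarityMatrix}}, \code{\link{loadSimilarityMatrix}}
#' @export
setClass("SimilarityMatrix",
  representation(labels = "character", values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (nrow(v) != ncol(v)) {
      return(sprintf("matrix must be square, got %d x %d", nrow(v), ncol(v)))
    }
    if (length(object@labels) != nrow(v)) {
      return("label count must equal matrix dimension")
    }
    if (anyDuplicated(object@labels)) {
      return(sprintf("duplicated label: %s",
                     object@labels[duplicated(object@labels)][1L]))
    }
    bad <- which(!is.finite(v) | v < 0 | v > 1, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      i <- bad[1L, 1L]; j <- bad[1L, 2L]
      return(sprintf(
        "similarity value %s at row '%s', column '%s' is not in [0, 1]",
        format(v[i, j]), object@labels[i], object@labels[j]))
    }
    TRUE
  })

#' ScreenData: inputs of one screening problem
#'
#' Bundles the two validated similarity matrices with the table of known
#' (positive) associations after label resolution. All pair indexing
#' downstream is row-major over (miRNA index, disease index) in the label
#' order of the two matrices.
#'
#' @slot simM \code{SimilarityMatrix} over miRNAs.
#' @slot simD \code{SimilarityMatrix} over diseases.
#' @slot assoc data.frame with integer columns \code{mirna}, \code{disease}
#'   (1-based indices into the matrices) — the known positive pairs.
#'
#' @seealso \code{\link{screenData}}, \code{\link{pairFeatures}}
#' @export
setClass("ScreenData",
  representation(simM = "SimilarityMatrix", simD = "SimilarityMatrix",
                 assoc = "data.frame"),
  validity = function(object) {
    a <- object@assoc
    if (!all(c("mirna", "disease") %in% names(a))) {
      return("assoc must have columns 'mirna' and 'disease'")
    }
    m <- length(object@simM@labels); d <- length(object@simD@labels)
    if (nrow(a) > 0L) {
      if (any(a$mirna < 1L | a$mirna > m)) return("miRNA index out of range")
      if (any(a$disease < 1L | a$disease > d)) return("disease index out of range")
      if (anyDuplicated(a[c("mirna", "disease")])) {
        return("duplicate association pair")
      }
    }
    TRUE
  })

#' SampleSets: the staged partition of all miRNA-disease pairs
#'
#' Records the evolving sample sets of the two-stage screen as canonical pair
#' indices (row-major over miRNA x disease). \code{P} and \code{U} always
#' partition the full grid. The staged sets are filled as the pipeline runs:
#' \code{LP1}/\code{LN1} (likely positive/negative after the semi-supervised
#' K-means), \code{LN2} (after Rocchio round 1), \code{RN} (final reliable
#' negatives after Rocchio round 2) and \code{RP} (reliable positives).
#'
#' Validity enforces the containment chain
#' \code{RN <= LN2 <= LN1 <= U}, the partitions
#' \code{P + U = all pairs} and \code{LP1 + LN1 = U}, and
#' \code{RP} disjoint from \code{RN}.
#'
#' @slot nMirna,nDisease grid dimensions.
#' @slot P,U,LP1,LN1,LN2,RN,RP integer vectors of pair indices (staged sets
#'   may be empty before their stage has run).
#'
#' @export
setClass("SampleSets",
  representation(nMirna = "integer", nDisease = "integer",
                 P = "integer", U = "integer", LP1 = "integer",
                 LN1 = "integer", LN2 = "integer", RN = "integer",
                 RP = "integer"),
  prototype(LP1 = integer(), LN1 = integer(), LN2 = integer(),
            RN = integer(), RP = integer()),
  validity = function(object) {
    nAll <- object@nMirna * object@nDisease
    if (length(intersect(object@P, object@U)) > 0L) return("P and U overlap")
    if (length(object@P) + length(object@U) != nAll) {
      return("P and U must cover all miRNA x disease pairs")
    }
    filled <- length(object@LP1) + length(object@LN1) > 0L
    if (filled) {
      if (length(intersect(object@LP1, object@LN1)) > 0L) {
        return("LP1 and LN1 overlap")
      }
      if (!setequal(c(object@LP1, object@LN1), object@U)) {
        return("LP1 and LN1 must partition U")
      }
    }
    if (!all(object@LN2 %in% object@LN1) && length(object@LN1) > 0L) {
      return("LN2 must be a subset of LN1")
    }
    if (!all(object@RN %in% object@LN2) && length(object@LN2) > 0L) {
      return("RN must be a subset of LN2")
    }
    if (length(intersect(object@RP, object@RN)) > 0L) {
      return("RP and RN overlap")
    }
    TRUE
  })

#' ScreenResult: output of a full screening run
#'
#' @slot sets \code{SampleSets} with all stages filled.
#' @slot rnScores named numeric; per reliable negative, the minimum over
#'   prototype pairs of cosine(x, negative prototype) - cosine(x, positive
#'   prototype). Larger = more confidently negative; used for ranked
#'   balanced sampling.
#' @slot rpScores named numeric; per reliable positive,
#'   cosine(x, positive prototype) - cosine(x, negative prototype) from the
#'   round-1 prototypes.
#' @slot config list snapshot of every parameter and seed used, sufficient to
#'   re-run the screen identically.
#' @slot stageSizes named integer vector of |U|, |LP1|, |LN1|, |LN2|, |RN|,
#'   |RP|.
#'
#' @seealso \code{\link{krNSSM}}
#' @export
setClass("ScreenResult",
  representation(sets = "SampleSets", rnScores = "numeric",
                 rpScores = "numeric", config = "list",
                 stageSizes = "integer"),
  validity = function(object) {
    if (length(object@rnScores) && !all(is.finite(object@rnScores))) {
      return("rnScores must be finite")
    }
    if (length(object@rpScores) && !all(is.finite(object@rpScores))) {
      return("rpScores must be finite")
    }
    TRUE
  })

#' SyntheticTruth: hidden ground-truth labels for generated data
#'
#' The generator plants true positive pairs; a fraction of them is hidden
#' from the observed association table and so sits inside the unlabelled set
#' U. This object keeps the complete truth so that the purity of any selected
#' negative set can be counted exactly.
#'
#' @slot nMirna,nDisease grid dimensions.
#' @slot truePositive pair indices that are truly positive (observed or not).
#' @slot observedPositive pair indices in the observed association table (P).
#' @slot hiddenPositive truly positive pairs hidden inside U.
#'
#' @seealso \code{\link{generateSynthetic}}, \code{\link{negativePurity}}
#' @export
setClass("SyntheticTruth",
  representation(nMirna = "integer", nDisease = "integer",
                 truePositive = "integer", observedPositive = "integer",
                 hiddenPositive = "integer"),
  validity = function(object) {
    if (!all(object@observedPositive %in% object@truePositive)) {
      return("every observed association must be a true positive")
    }
    if (!setequal(object@hiddenPositive,
                  setdiff(object@truePositive, object@observedPositive))) {
      return("hiddenPositive must be the unobserved true positives")
    }
    TRUE
  })

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix with %d entities\n", length(object@labels)))
  cat("  labels: ", paste(utils::head(object@labels, 4L), collapse = ", "),
      if (length(object@labels) > 4L) ", ..." else "", "\n", sep = "")
  cat(sprintf("  values in [%.3f, %.3f]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "ScreenData", function(object) {
  cat(sprintf("ScreenData: %d miRNAs x %d diseases, %d known associations\n",
              length(object@simM@labels), length(object@simD@labels),
              nrow(object@assoc)))
})

setMethod("show", "SampleSets", function(object) {
  cat(sprintf("SampleSets on a %d x %d pair grid\n",
              object@nMirna, object@nDisease))
  for (s in c("P", "U", "LP1", "LN1", "LN2", "RN", "RP")) {
    cat(sprintf("  |%s| = %d\n", s, length(slot(object, s))))
  }
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult (two-stage reliable negative screen)\n")
  sz <- object@stageSizes
  cat("  stage sizes: ",
      paste(sprintf("%s=%d", names(sz), sz), collapse = ", "), "\n", sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d true positives (%d observed, %d hidden in U) on %d x %d grid\n",
    length(object@truePositive), length(object@observedPositive),
    length(object@hiddenPositive), object@nMirna, object@nDisease))
})
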