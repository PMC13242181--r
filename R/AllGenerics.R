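#' @rdname monoisotopicMass
#' @export
setGeneric("monoisotopicMass", function(x) standardGeneric("monoisotopicMass"))

#' @rdname averageMass
#' @export
setGeneric("averageMass", function(x) standardGeneric("averageMass"))

#' @rdname isotopePattern
#' @export
setGeneric("isotopePattern",
           function(x, minAbundance = 1e-4) standardGeneric("isotopePattern"))

#' @rdname applyRtAlignment
#' @export
setGeneric("applyRtAlignment",
           function(x, model) standardGeneric("applyRtAlignment"))

#' Number of rows of an MzTable
#' @param x An [MzTable-class].
#' @return Integer row count.
#' @export
setGeneric("numRows", function(x) standardGeneric("numRows"))

#' Column names of an MzTable
#' @param x An [MzTable-class].
#' @return Character vector.
#' @export
setGeneric("columnNames", function(x) standardGeneric("columnNames"))

#' Column types of an MzTable
#' @param x An [MzTable-class].
#' @return Character vector of type names, parallel to [columnNames()].
#' @export
setGeneric("columnTypes", function(x) standardGeneric("columnTypes"))

#' Storage mode of an MzTable
#' @param x An [MzTable-class].
#' @return `"memory"` or `"disk"`.
#' @export
setGeneric("storageMode", function(x) standardGeneric("storageMode"))
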