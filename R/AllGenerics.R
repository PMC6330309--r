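#' @include AllClasses.R
NULL

#' @export
setGeneric("germlineNames", function(x) standardGeneric("germlineNames"))
#' @export
setGeneric("segmentType", function(x) standardGeneric("segmentType"))
#' @export
setGeneric("isDecoy", function(x) standardGeneric("isDecoy"))
#' @export
setGeneric("regionBounds", function(x, gene) standardGeneric("regionBounds"))
#' @export
setGeneric("fr4MotifOffset", function(x) standardGeneric("fr4MotifOffset"))

#' @export
setGeneric("sequenceIds", function(x) standardGeneric("sequenceIds"))
#' @export
setGeneric("aaSequences", function(x) standardGeneric("aaSequences"))
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @export
setGeneric("vCall", function(x) standardGeneric("vCall"))
#' @export
setGeneric("jCall", function(x) standardGeneric("jCall"))
#' @export
setGeneric("cdr3", function(x) standardGeneric("cdr3"))
#' @export
setGeneric("shmCount", function(x) standardGeneric("shmCount"))
#' @export
setGeneric("fr4Residue", function(x) standardGeneric("fr4Residue"))
#' @export
setGeneric("passFilter", function(x) standardGeneric("passFilter"))

#' @export
setGeneric("familyTable", function(x) standardGeneric("familyTable"))
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))
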