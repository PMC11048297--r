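#' @rdname EditingExperiment-accessors
#' @export
setGeneric("altReads", function(x, ...) standardGeneric("altReads"))

#' @rdname EditingExperiment-accessors
#' @export
setGeneric("totalReads", function(x, ...) standardGeneric("totalReads"))

#' @rdname EditingExperiment-accessors
#' @export
setGeneric("refReads", function(x, ...) standardGeneric("refReads"))

#' @rdname EditingExperiment-accessors
#' @export
setGeneric("editingLevels", function(x, ...) standardGeneric("editingLevels"))

#' @rdname EditingExperiment-accessors
#' @export
setGeneric("isObserved", function(x, ...) standardGeneric("isObserved"))

#' @rdname EditingExperiment-accessors
#' @export
setGeneric("siteIds", function(x, ...) standardGeneric("siteIds"))
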