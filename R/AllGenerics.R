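#' Wavelength grid of a spectral object
#'
#' @param x a [SpectralFrames] object.
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Acquisition times of a spectral stream
#'
#' @param x a [SpectralFrames] object.
#' @return numeric vector of frame times in seconds.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Intensity matrix of a spectral stream
#'
#' @param x a [SpectralFrames] object.
#' @return numeric matrix, wavelengths in rows, frames in columns (RFU).
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' Sensitivity of a classification result
#'
#' @param x a [ConfusionMatrix].
#' @return fraction of true positives among condition positives.
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' Specificity of a classification result
#'
#' @param x a [ConfusionMatrix].
#' @return fraction of true negatives among condition negatives.
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
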