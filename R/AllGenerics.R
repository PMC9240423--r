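#' @import methods
#' @importFrom stats fft lm coef median sd rnorm runif shapiro.test t.test
#'   wilcox.test complete.cases setNames
#' @importFrom utils write.csv read.csv head tail modifyList
NULL

#' Number of acquisitions in a series
#'
#' @param object a \linkS4class{FIDSeries}
#' @return integer count of free induction decays
#' @export
setGeneric("nAcquisitions", function(object) standardGeneric("nAcquisitions"))

#' Raw complex FID matrix
#'
#' @param object a \linkS4class{FIDSeries}
#' @return complex matrix, one row per acquisition
#' @export
setGeneric("fidMatrix", function(object) standardGeneric("fidMatrix"))

#' Acquisition protocol of an object
#'
#' @param object an object carrying an \linkS4class{AcquisitionProtocol}
#' @return the protocol
#' @export
setGeneric("protocol", function(object) standardGeneric("protocol"))

#' Phase labels (rest / exercise / recovery)
#'
#' @param object a \linkS4class{FIDSeries} or \linkS4class{MetaboliteTimeSeries}
#' @return character vector of phase labels
#' @export
setGeneric("phaseLabels", function(object) standardGeneric("phaseLabels"))

#' Echo times of a multi-echo stack
#'
#' @param object an \linkS4class{EchoImageStack}
#' @return numeric vector of echo times (ms)
#' @export
setGeneric("echoTimes", function(object) standardGeneric("echoTimes"))

#' Fitted per-pixel T2 values
#'
#' @param object a \linkS4class{T2Map}
#' @return numeric array of T2 (ms), NA where the fit was invalid
#' @export
setGeneric("t2Values", function(object) standardGeneric("t2Values"))

#' Tabular view of a container
#'
#' @param object a \linkS4class{MetaboliteTimeSeries}, \linkS4class{TwitchTable}
#'   or \linkS4class{KineticsResult}
#' @param ... unused
#' @return a data.frame, one row per bin / twitch / scalar summary
#' @export
setGeneric("asTable", function(object, ...) standardGeneric("asTable"))
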