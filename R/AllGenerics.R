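#' @rdname ages
#' @export
setGeneric("ages", function(x, ...) standardGeneric("ages"))

#' @rdname ages
#' @export
setGeneric("ages<-", function(x, value) standardGeneric("ages<-"))

#' @rdname methLevels
#' @export
setGeneric("methLevels", function(x, ...) standardGeneric("methLevels"))

#' @rdname SiteParameters-accessors
#' @export
setGeneric("rates", function(x, ...) standardGeneric("rates"))

#' @rdname SiteParameters-accessors
#' @export
setGeneric("startStates", function(x, ...) standardGeneric("startStates"))

#' @rdname EPMFit-accessors
#' @export
setGeneric("eAges", function(x, ...) standardGeneric("eAges"))

#' @rdname EPMFit-accessors
#' @export
setGeneric("rssTrace", function(x, ...) standardGeneric("rssTrace"))

#' @rdname EPMFit-accessors
#' @export
setGeneric("ageAcceleration", function(x, ...) standardGeneric("ageAcceleration"))

#' @rdname EPMFit-accessors
#' @export
setGeneric("siteParameters", function(x, ...) standardGeneric("siteParameters"))

#' @rdname siteStep
#' @export
setGeneric("siteStep", function(x, ages, ...) standardGeneric("siteStep"))

#' @rdname timeStep
#' @export
setGeneric("timeStep", function(x, params, ...) standardGeneric("timeStep"))

#' @rdname rss
#' @export
setGeneric("rss", function(x, params, ages, ...) standardGeneric("rss"))

#' @rdname fitMC
#' @export
setGeneric("fitMC", function(x, ...) standardGeneric("fitMC"))

#' @rdname fitEPM
#' @export
setGeneric("fitEPM", function(x, ...) standardGeneric("fitEPM"))

#' @rdname selectSites
#' @export
setGeneric("selectSites", function(x, ages, k, ...) standardGeneric("selectSites"))

#' @rdname compareModels
#' @export
setGeneric("compareModels", function(x, ...) standardGeneric("compareModels"))
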