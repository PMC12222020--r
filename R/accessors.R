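# Accessors and show() methods for the S4 containers.

#' @name EpochSet-accessors
#' @title Accessors for EpochSet objects
#' @param x an \code{EpochSet}.
#' @param subject subject identifier (name in \code{subjectIds(x)}).
#' @return \code{epochData}: the trials x channels x samples array of one
#'   subject. \code{epochDesign}: the design \code{data.frame}.
#'   \code{channelNames}: character vector. \code{samplingRate}, \code{epochT0}:
#'   scalars. \code{timeAxis}: sample times in ms. \code{nTrials}: named
#'   integer vector of per-subject trial counts. \code{epochLog}: provenance
#'   list.
NULL

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochData", function(x, subject) standardGeneric("epochData"))

#' @rdname EpochSet-accessors
#' @export
setMethod("epochData", "EpochSet", function(x, subject) {
  subject <- as.character(subject)
  if (!subject %in% names(x@data))
    stop("unknown subject: ", subject)
  x@data[[subject]]
})

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochDesign", function(x) standardGeneric("epochDesign"))

#' @rdname EpochSet-accessors
#' @export
setMethod("epochDesign", "EpochSet", function(x) x@design)

#' @rdname EpochSet-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EpochSet-accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)

#' @rdname EpochSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EpochSet-accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@srate)

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochT0", function(x) standardGeneric("epochT0"))

#' @rdname EpochSet-accessors
#' @export
setMethod("epochT0", "EpochSet", function(x) x@t0)

#' @rdname EpochSet-accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname EpochSet-accessors
#' @export
setMethod("timeAxis", "EpochSet", function(x) {
  n <- if (length(x@data)) dim(x@data[[1]])[3] else 0L
  sampleTimes(x@t0, x@srate, n)
})

#' @rdname EpochSet-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname EpochSet-accessors
#' @export
setMethod("subjectIds", "EpochSet", function(x) names(x@data))

#' @rdname EpochSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname EpochSet-accessors
#' @export
setMethod("nTrials", "EpochSet", function(x)
  vapply(x@data, function(a) dim(a)[1], integer(1)))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochLog", function(x) standardGeneric("epochLog"))

#' @rdname EpochSet-accessors
#' @export
setMethod("epochLog", "EpochSet", function(x) x@log)

setMethod("show", "EpochSet", function(object) {
  nt <- nTrials(object)
  ns <- if (length(object@data)) dim(object@data[[1]])[3] else 0L
  cat("EpochSet with", length(object@data), "subject(s),",
      sum(nt), "trial(s) total\n")
  cat("  channels:", length(object@channels), " srate:", object@srate,
      "Hz  samples:", ns, sprintf("(t0 = %g ms)\n", object@t0))
  if (length(object@log))
    cat("  log:", paste(vapply(object@log, `[[`, "", "op"),
                        collapse = " -> "), "\n")
})

#' @name StatMap-accessors
#' @title Accessors for StatMap objects
#' @param x a \code{StatMap}.
#' @return \code{statT}, \code{statP}, \code{statPadj}: numeric matrices;
#'   \code{statMask}: logical matrix.
NULL

#' @rdname StatMap-accessors
#' @export
setGeneric("statT", function(x) standardGeneric("statT"))
#' @rdname StatMap-accessors
#' @export
setMethod("statT", "StatMap", function(x) x@t)
#' @rdname StatMap-accessors
#' @export
setGeneric("statP", function(x) standardGeneric("statP"))
#' @rdname StatMap-accessors
#' @export
setMethod("statP", "StatMap", function(x) x@p)
#' @rdname StatMap-accessors
#' @export
setGeneric("statPadj", function(x) standardGeneric("statPadj"))
#' @rdname StatMap-accessors
#' @export
setMethod("statPadj", "StatMap", function(x) x@padj)
#' @rdname StatMap-accessors
#' @export
setGeneric("statMask", function(x) standardGeneric("statMask"))
#' @rdname StatMap-accessors
#' @export
setMethod("statMask", "StatMap", function(x) x@mask)

setMethod("show", "StatMap", function(object) {
  cat("StatMap:", nrow(object@t), "x", ncol(object@t),
      "cells, df =", object@df, "\n")
  cat("  ", sum(object@mask, na.rm = TRUE), "cell(s) significant after",
      object@correction, "at alpha =", object@alpha, "\n")
})

#' @name TFCoherenceMap-accessors
#' @title Accessors for TFCoherenceMap objects
#' @param x a \code{TFCoherenceMap}.
#' @return \code{cohValues}: the frequency x time coherence matrix;
#'   \code{cohFreqs}, \code{cohTimes}: grid axes.
NULL

#' @rdname TFCoherenceMap-accessors
#' @export
setGeneric("cohValues", function(x) standardGeneric("cohValues"))
#' @rdname TFCoherenceMap-accessors
#' @export
setMethod("cohValues", "TFCoherenceMap", function(x) x@coh)
#' @rdname TFCoherenceMap-accessors
#' @export
setGeneric("cohFreqs", function(x) standardGeneric("cohFreqs"))
#' @rdname TFCoherenceMap-accessors
#' @export
setMethod("cohFreqs", "TFCoherenceMap", function(x) x@freqs)
#' @rdname TFCoherenceMap-accessors
#' @export
setGeneric("cohTimes", function(x) standardGeneric("cohTimes"))
#' @rdname TFCoherenceMap-accessors
#' @export
setMethod("cohTimes", "TFCoherenceMap", function(x) x@times)

setMethod("show", "TFCoherenceMap", function(object) {
  cat("TFCoherenceMap", object@roiPair, "- subject", object@subject,
      "fnmes", object@fnmes, "choice", object@choice, "\n")
  cat("  grid:", length(object@freqs), "freqs x", length(object@times),
      "times,", object@nTrials, "trial(s); mean coh =",
      signif(mean(object@coh, na.rm = TRUE), 3), "\n")
})

#' @name ClusterResult-accessors
#' @title Accessors for ClusterResult objects
#' @param x a \code{ClusterResult}.
#' @param alpha significance level for \code{significantClusters}.
#' @return \code{clusterTable}: \code{data.frame} with one row per cluster
#'   (size, mass, p); \code{significantClusters}: the subset of the cluster
#'   list with Monte-Carlo p <= alpha.
NULL

#' @rdname ClusterResult-accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname ClusterResult-accessors
#' @export
setMethod("clusterTable", "ClusterResult", function(x) {
  if (!length(x@clusters))
    return(data.frame(cluster = integer(0), size = integer(0),
                      mass = numeric(0), p = numeric(0)))
  data.frame(cluster = seq_along(x@clusters),
             size = vapply(x@clusters, function(cl) nrow(cl$cells), integer(1)),
             mass = vapply(x@clusters, `[[`, numeric(1), "mass"),
             p = vapply(x@clusters, `[[`, numeric(1), "p"))
})

#' @rdname ClusterResult-accessors
#' @export
setGeneric("significantClusters",
           function(x, alpha) standardGeneric("significantClusters"))
#' @rdname ClusterResult-accessors
#' @export
setMethod("significantClusters", "ClusterResult", function(x, alpha) {
  if (missing(alpha)) alpha <- x@params$alpha
  Filter(function(cl) cl$p <= alpha, x@clusters)
})

setMethod("show", "ClusterResult", function(object) {
  tab <- clusterTable(object)
  cat("ClusterResult on a", length(object@freqs), "x",
      length(object@times), "grid;", nrow(tab), "cluster(s),",
      sum(tab$p <= object@params$alpha), "significant at alpha =",
      object@params$alpha, "\n")
  if (nrow(tab)) print(head(tab[order(tab$p), ], 5))
})

#' @name ModelFit-accessors
#' @title Accessors for ModelFit objects
#' @param x a \code{ModelFit}.
#' @return \code{modelTerms}: the coefficient \code{data.frame};
#'   \code{modelObject}: the underlying fit; \code{isSingular}: logical.
NULL

#' @rdname ModelFit-accessors
#' @export
setGeneric("modelTerms", function(x) standardGeneric("modelTerms"))
#' @rdname ModelFit-accessors
#' @export
setMethod("modelTerms", "ModelFit", function(x) x@terms)
#' @rdname ModelFit-accessors
#' @export
setGeneric("modelObject", function(x) standardGeneric("modelObject"))
#' @rdname ModelFit-accessors
#' @export
setMethod("modelObject", "ModelFit", function(x) x@fit)
#' @rdname ModelFit-accessors
#' @export
setGeneric("isSingular", function(x) standardGeneric("isSingular"))
#' @rdname ModelFit-accessors
#' @export
setMethod("isSingular", "ModelFit", function(x) x@singular)

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit:", object@formula, "\n")
  cat("  n =", object@nObs, "obs,", object@nSubjects, "subject(s)",
      if (!object@converged) " [NOT CONVERGED]" else "",
      if (object@singular) " [singular]" else "", "\n", sep = "")
  if (nzchar(object@simplified))
    cat("  random structure simplified:", object@simplified, "\n")
  tt <- object@terms
  tt[-1] <- lapply(tt[-1], function(v) signif(v, 3))
  print(tt, row.names = FALSE)
})
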