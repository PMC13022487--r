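#' @rdname ProteinMatrix-class
#' @param x an object.
#' @export
setGeneric("npx", function(x) standardGeneric("npx"))

#' @rdname ProteinMatrix-class
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' @rdname ProteinMatrix-class
#' @export
setGeneric("participantIds", function(x) standardGeneric("participantIds"))

#' @rdname ProteinMatrix-class
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname ProteinMatrix-class
#' @export
setGeneric("nParticipants", function(x) standardGeneric("nParticipants"))

#' @rdname ProteinMatrix-class
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname PhenotypeTable-class
#' @param x an object.
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname PhenotypeTable-class
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))

#' @rdname PhenotypeTable-class
#' @export
setGeneric("icd10Codes", function(x) standardGeneric("icd10Codes"))

#' @rdname PhenotypeTable-class
#' @param code a 3-character ICD-10 code.
#' @export
setGeneric("hasCode", function(x, code) standardGeneric("hasCode"))

#' @rdname ClusterAssignment-class
#' @param x an object.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterAssignment-class
#' @export
setGeneric("clusterMethod", function(x) standardGeneric("clusterMethod"))

#' @rdname ClusterAssignment-class
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname ClusterAssignment-class
#' @param label a cluster label.
#' @export
setGeneric("clusterMembers", function(x, label) standardGeneric("clusterMembers"))

#' @rdname MissingnessGrouping-class
#' @param x an object.
#' @export
setGeneric("groupProteins", function(x) standardGeneric("groupProteins"))

#' @rdname MissingnessGrouping-class
#' @export
setGeneric("retainedParticipants", function(x) standardGeneric("retainedParticipants"))

#' @rdname MissingnessGrouping-class
#' @export
setGeneric("discardedProteins", function(x) standardGeneric("discardedProteins"))

#' @rdname EmbeddingResult-class
#' @param x an object.
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @rdname EmbeddingResult-class
#' @export
setGeneric("stabilityReport", function(x) standardGeneric("stabilityReport"))

#' @rdname RecreationCurve-class
#' @param x an object.
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' @rdname RecreationCurve-class
#' @export
setGeneric("looTables", function(x) standardGeneric("looTables"))

#' @rdname AbundanceCall-class
#' @param x an object.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname DiffCorrResult-class
#' @param x an object.
#' @export
setGeneric("deltaMatrix", function(x) standardGeneric("deltaMatrix"))

#' @rdname AxisTransform-class
#' @param x an object.
#' @export
setGeneric("axisLoadings", function(x) standardGeneric("axisLoadings"))
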