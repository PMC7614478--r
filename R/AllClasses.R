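#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   findOverlaps pintersect reduce disjoin granges sort.GenomicRanges
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom stats setNames
NULL

# Recognised growth-pattern labels (canonical lower-case) and their grades.
GROWTH_PATTERNS <- c("lepidic", "papillary", "acinar", "cribriform",
                     "micropapillary", "solid", "unknown")
GRADE_OF_PATTERN <- c(lepidic = "low", papillary = "mid", acinar = "mid",
                      cribriform = "high", micropapillary = "high",
                      solid = "high", unknown = "unknown")
GRADE_LEVELS <- c("low", "mid", "high")
SEEDING_LABELS <- c("seeding", "non_seeding", "metastasis", "unknown")

#' Clone tree of mutation clusters
#'
#' A rooted tree of mutation clusters for one tumour, with per-region cancer
#' cell fractions (CCFs) and per-cluster mutation counts. The root cluster
#' holds the truncal mutations present in all cancer cells; every other
#' cluster is subclonal at the tumour level.
#'
#' @slot tumourID single tumour identifier.
#' @slot clusters character vector of cluster ids.
#' @slot parent named character vector: parent cluster id per cluster,
#'   \code{NA} for the root.
#' @slot ccf numeric matrix, clusters x regions, entries in \[0, 1\].
#' @slot nMutations named integer vector of mutation counts per cluster.
#' @exportClass CloneTree
setClass("CloneTree", representation(
  tumourID = "character",
  clusters = "character",
  parent = "character",
  ccf = "matrix",
  nMutations = "integer"
))

setValidity("CloneTree", function(object) {
  msg <- character()
  k <- object@clusters
  if (length(k) == 0) msg <- c(msg, "no clusters")
  if (!identical(names(object@parent), k))
    msg <- c(msg, "parent vector names must equal clusters")
  roots <- k[is.na(object@parent)]
  if (length(roots) != 1) msg <- c(msg, "tree must have exactly one root")
  if (!all(object@parent[!is.na(object@parent)] %in% k))
    msg <- c(msg, "parent ids must be clusters")
  if (!identical(rownames(object@ccf), k))
    msg <- c(msg, "ccf rownames must equal clusters")
  if (length(msg)) msg else TRUE
})

#' Multi-region tumour bundle
#'
#' Container tying together everything known about one tumour: per-region
#' metadata (purity, ploidy, growth pattern, seeding label), phased
#' allele-specific copy-number segment profiles (one \code{GRanges} with
#' \code{cnA}/\code{cnB} metadata columns per region), the clone tree, the
#' mutation catalog, and tumour-level annotations.
#'
#' @slot tumourID single tumour identifier.
#' @slot regions data.frame with columns region_id, purity, ploidy,
#'   growth_pattern, grade, seeding_label.
#' @slot segments named list of \code{GRanges} (one per region) carrying
#'   numeric metadata columns \code{cnA} and \code{cnB}.
#' @slot tree a \code{\linkS4class{CloneTree}}.
#' @slot mutations data.frame with columns mutation_id, cluster_id and one
#'   CCF column per region (named as the region ids).
#' @slot annotations list of tumour-level annotations (predominant subtype,
#'   pattern percentage vector, STAS/necrosis flags, relapse status).
#' @exportClass TumourBundle
setClass("TumourBundle", representation(
  tumourID = "character",
  regions = "data.frame",
  segments = "list",
  tree = "CloneTree",
  mutations = "data.frame",
  annotations = "list"
))

setValidity("TumourBundle", function(object) {
  msg <- character()
  req <- c("region_id", "purity", "ploidy", "growth_pattern", "grade",
           "seeding_label")
  if (!all(req %in% names(object@regions)))
    msg <- c(msg, paste("regions must have columns:", paste(req, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn TumourBundle-class tumour identifier
#' @param object a \code{TumourBundle} or \code{CloneTree}
#' @export
setGeneric("tumourID", function(object) standardGeneric("tumourID"))
setMethod("tumourID", "TumourBundle", function(object) object@tumourID)
setMethod("tumourID", "CloneTree", function(object) object@tumourID)

#' @describeIn TumourBundle-class region ids
#' @export
setGeneric("regionIDs", function(object) standardGeneric("regionIDs"))
setMethod("regionIDs", "TumourBundle", function(object) object@regions$region_id)
setMethod("regionIDs", "CloneTree", function(object) colnames(object@ccf))

#' @describeIn TumourBundle-class per-region metadata data.frame
#' @export
setGeneric("regionTable", function(object) standardGeneric("regionTable"))
setMethod("regionTable", "TumourBundle", function(object) object@regions)

#' @describeIn TumourBundle-class named list of per-region segment GRanges
#' @export
setGeneric("segmentProfiles", function(object) standardGeneric("segmentProfiles"))
setMethod("segmentProfiles", "TumourBundle", function(object) object@segments)

#' @describeIn TumourBundle-class the clone tree
#' @export
setGeneric("cloneTree", function(object) standardGeneric("cloneTree"))
setMethod("cloneTree", "TumourBundle", function(object) object@tree)

#' @describeIn TumourBundle-class the mutation catalog data.frame
#' @export
setGeneric("mutationCatalog", function(object) standardGeneric("mutationCatalog"))
setMethod("mutationCatalog", "TumourBundle", function(object) object@mutations)

#' @describeIn TumourBundle-class tumour-level annotations list
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
setMethod("annotations", "TumourBundle", function(object) object@annotations)

#' @describeIn CloneTree-class cluster ids
#' @param object a \code{CloneTree}
#' @export
setGeneric("clusterIDs", function(object) standardGeneric("clusterIDs"))
setMethod("clusterIDs", "CloneTree", function(object) object@clusters)

#' @describeIn CloneTree-class root cluster id
#' @export
setGeneric("rootCluster", function(object) standardGeneric("rootCluster"))
setMethod("rootCluster", "CloneTree",
          function(object) object@clusters[is.na(object@parent)])

#' @describeIn CloneTree-class leaf cluster ids (no children)
#' @export
setGeneric("leafClusters", function(object) standardGeneric("leafClusters"))
setMethod("leafClusters", "CloneTree", function(object)
  setdiff(object@clusters, unique(object@parent[!is.na(object@parent)])))

#' @describeIn CloneTree-class clusters x regions CCF matrix
#' @export
setGeneric("ccfMatrix", function(object) standardGeneric("ccfMatrix"))
setMethod("ccfMatrix", "CloneTree", function(object) object@ccf)

#' @describeIn CloneTree-class named parent vector (NA at the root)
#' @export
setGeneric("parentVector", function(object) standardGeneric("parentVector"))
setMethod("parentVector", "CloneTree", function(object) object@parent)

#' @describeIn CloneTree-class named mutation counts per cluster
#' @export
setGeneric("mutationCounts", function(object) standardGeneric("mutationCounts"))
setMethod("mutationCounts", "CloneTree", function(object) object@nMutations)

setMethod("show", "CloneTree", function(object) {
  cat("CloneTree for tumour", object@tumourID, "\n")
  cat("  ", length(object@clusters), "clusters (root:", rootCluster(object),
      "),", length(leafClusters(object)), "leaves\n")
  cat("  ", ncol(object@ccf), "regions;",
      sum(object@nMutations), "mutations\n")
})

setMethod("show", "TumourBundle", function(object) {
  cat("TumourBundle", object@tumourID, "\n")
  cat("  regions  :", nrow(object@regions),
      paste0("(", paste(object@regions$region_id, collapse = ", "), ")"), "\n")
  cat("  segments :", sum(vapply(object@segments, length, 1L)),
      "across", length(object@segments), "profiles\n")
  cat("  tree     :", length(object@tree@clusters), "clusters,",
      sum(object@tree@nMutations), "mutations\n")
})

#' Construct a CloneTree
#'
#' @param tumourID tumour id.
#' @param parent named character vector mapping each cluster to its parent
#'   (\code{NA} for the root).
#' @param ccf clusters x regions CCF matrix; rownames must match the names
#'   of \code{parent}.
#' @param nMutations named integer vector of mutation counts per cluster.
#' @return a \code{\linkS4class{CloneTree}}.
#' @export
CloneTree <- function(tumourID, parent, ccf, nMutations = NULL) {
  clusters <- names(parent)
  ccf <- as.matrix(ccf)[clusters, , drop = FALSE]
  if (is.null(nMutations))
    nMutations <- setNames(rep(0L, length(clusters)), clusters)
  nMutations <- setNames(as.integer(nMutations[clusters]), clusters)
  new("CloneTree", tumourID = as.character(tumourID), clusters = clusters,
      parent = parent, ccf = ccf, nMutations = nMutations)
}

#' Construct a TumourBundle
#'
#' @param tumourID tumour id.
#' @param regions per-region metadata data.frame (region_id, purity, ploidy,
#'   growth_pattern, seeding_label; grade is derived if absent).
#' @param segments named list of per-region \code{GRanges} with \code{cnA},
#'   \code{cnB} metadata columns.
#' @param tree a \code{CloneTree}.
#' @param mutations mutation catalog data.frame (mutation_id, cluster_id,
#'   one CCF column per region).
#' @param annotations tumour-level annotations list.
#' @return a \code{\linkS4class{TumourBundle}}.
#' @export
TumourBundle <- function(tumourID, regions, segments, tree, mutations,
                         annotations = list()) {
  regions$growth_pattern <- tolower(as.character(regions$growth_pattern))
  if (is.null(regions$grade))
    regions$grade <- deriveGrade(regions$growth_pattern)
  if (is.null(regions$seeding_label)) regions$seeding_label <- "unknown"
  new("TumourBundle", tumourID = as.character(tumourID), regions = regions,
      segments = segments, tree = tree, mutations = mutations,
      annotations = annotations)
}
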