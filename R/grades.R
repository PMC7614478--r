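#' Map growth patterns to architectural grade
#'
#' Lung adenocarcinoma growth patterns are grouped into three architectural
#' grades: lepidic is low-grade; papillary and acinar are mid-grade;
#' cribriform, micropapillary and solid are high-grade. Labels are matched
#' case-insensitively; \code{"unknown"} maps to \code{"unknown"}.
#'
#' @param pattern character vector of growth-pattern labels.
#' @return character vector of grades (\code{"low"}, \code{"mid"},
#'   \code{"high"} or \code{"unknown"}).
#' @examples
#' deriveGrade(c("lepidic", "micropapillary", "unknown"))
#' @export
deriveGrade <- function(pattern) {
  p <- tolower(as.character(pattern))
  bad <- setdiff(unique(p), GROWTH_PATTERNS)
  if (length(bad))
    stop("unrecognised growth pattern(s): ", paste(bad, collapse = ", "),
         "; accepted labels are: ", paste(GROWTH_PATTERNS, collapse = ", "))
  unname(GRADE_OF_PATTERN[p])
}

#' Numeric grade score maps
#'
#' Two presets are provided: \code{"figure"} scores low/mid/high as 1/2/3,
#' \code{"methods"} scores them 0/1/3. Both are strictly increasing in
#' grade order.
#'
#' @param preset \code{"figure"} (default) or \code{"methods"}.
#' @return named numeric vector over \code{c("low", "mid", "high")}.
#' @export
gradeScoreMap <- function(preset = c("figure", "methods")) {
  preset <- match.arg(preset)
  if (preset == "figure") c(low = 1, mid = 2, high = 3)
  else c(low = 0, mid = 1, high = 3)
}

#' Classify tumour growth-pattern homogeneity
#'
#' A tumour is morphologically homogeneous when its predominant subtype
#' occupies at least 90 per cent of the diagnostic slide area AND at least
#' 90 per cent of the annotated regional patterns; otherwise it is mixed.
#' When no regional annotations are available the area criterion alone is
#' evaluated and the result is flagged indeterminate.
#'
#' @param bundle a \code{\linkS4class{TumourBundle}} whose annotations carry
#'   \code{pattern_pct} (named percentage vector summing to 100) and whose
#'   regions carry growth patterns.
#' @param areaMin,regionMin thresholds (fractions, default 0.9).
#' @return list with \code{class} (\code{"homogeneous"}/\code{"mixed"}),
#'   \code{predominant}, \code{area_fraction}, \code{region_fraction}, and
#'   \code{indeterminate} flag.
#' @export
classifyHomogeneity <- function(bundle, areaMin = 0.9, regionMin = 0.9) {
  pct <- annotations(bundle)$pattern_pct
  if (is.null(pct) || !length(pct))
    stop("bundle has no pattern_pct annotation")
  pct <- pct[pct > 0]
  predominant <- names(pct)[which.max(pct)]
  areaFrac <- unname(pct[predominant] / sum(pct))
  pats <- tolower(regionTable(bundle)$growth_pattern)
  pats <- pats[pats != "unknown"]
  if (!length(pats)) {
    cls <- if (areaFrac >= areaMin) "homogeneous" else "mixed"
    return(list(class = cls, predominant = predominant,
                area_fraction = areaFrac, region_fraction = NA_real_,
                indeterminate = TRUE))
  }
  regionFrac <- mean(pats == predominant)
  ok <- areaFrac >= areaMin && regionFrac >= regionMin
  list(class = if (ok) "homogeneous" else "mixed", predominant = predominant,
       area_fraction = areaFrac, region_fraction = regionFrac,
       indeterminate = FALSE)
}
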