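#' Validate a tumour bundle
#'
#' Checks every structural invariant of a \code{\linkS4class{TumourBundle}}
#' and returns all violations found (empty data.frame = valid): purity and
#' ploidy ranges, grade consistency, segment ordering/overlap and
#' non-negative allele copy numbers, single-rooted clone tree, per-region
#' child-CCF-below-parent and root-CCF-near-one constraints, mutation
#' cluster membership and presence flags, cross-table region id
#' consistency, and pattern-percentage totals.
#'
#' @param bundle a \code{TumourBundle}.
#' @param ccfTol tolerance for CCF constraints (default 0.05).
#' @param pctTol tolerance for pattern percentages summing to 100
#'   (default 0.5).
#' @return data.frame with columns \code{rule}, \code{location},
#'   \code{detail}; zero rows when the bundle is valid.
#' @export
validateBundle <- function(bundle, ccfTol = 0.05, pctTol = 0.5) {
  v <- list()
  add <- function(rule, location, detail)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, location = location,
                                       detail = detail)
  reg <- regionTable(bundle)
  bad <- reg$region_id[reg$purity < 0 | reg$purity > 1]
  for (r in bad) add("purity_range", r, "purity outside [0,1]")
  bad <- reg$region_id[reg$ploidy <= 0]
  for (r in bad) add("ploidy_positive", r, "ploidy must be > 0")
  expect <- deriveGrade(reg$growth_pattern)
  bad <- reg$region_id[reg$grade != expect]
  for (r in bad) add("grade_consistency", r,
                     "grade does not match growth pattern")

  segIDs <- names(segmentProfiles(bundle))
  if (!setequal(segIDs, reg$region_id))
    add("region_consistency", tumourID(bundle),
        paste0("segment profiles for {",
               paste(segIDs, collapse = ","), "} vs regions {",
               paste(reg$region_id, collapse = ","), "}"))
  for (rid in segIDs) {
    gr <- segmentProfiles(bundle)[[rid]]
    if (any(mcols(gr)$cnA < 0 | mcols(gr)$cnB < 0))
      add("cn_nonnegative", rid, "negative allele copy number")
    for (ch in unique(as.character(seqnames(gr)))) {
      g <- gr[seqnames(gr) == ch]
      o <- order(start(g))
      if (is.unsorted(start(g)))
        add("segments_sorted", paste0(rid, ":", ch), "segments not sorted")
      g <- g[o]
      if (length(g) > 1 && any(start(g)[-1] <= end(g)[-length(g)]))
        add("segments_nonoverlap", paste0(rid, ":", ch),
            "overlapping segments")
    }
  }

  tr <- cloneTree(bundle)
  roots <- clusterIDs(tr)[is.na(parentVector(tr))]
  if (length(roots) != 1)
    add("single_root", tumourID(bundle),
        paste0("multiple roots (", length(roots), ")"))
  ccf <- ccfMatrix(tr)
  if (any(ccf < -1e-9 | ccf > 1 + 1e-9, na.rm = TRUE))
    add("ccf_range", tumourID(bundle), "CCF outside [0,1]")
  par <- parentVector(tr)
  for (cl in clusterIDs(tr)) {
    p <- par[[cl]]
    if (is.na(p) || !(p %in% rownames(ccf))) next
    for (rid in colnames(ccf)) {
      if (!is.na(ccf[cl, rid]) && !is.na(ccf[p, rid]) &&
          ccf[cl, rid] > ccf[p, rid] + ccfTol)
        add("ccf_child_leq_parent", paste0(cl, "@", rid),
            sprintf("child CCF %.3f exceeds parent %.3f + %.2f",
                    ccf[cl, rid], ccf[p, rid], ccfTol))
    }
  }
  if (length(roots) == 1 && roots %in% rownames(ccf)) {
    for (rid in colnames(ccf)) {
      rc <- ccf[roots, rid]
      if (!is.na(rc) && abs(rc - 1) > ccfTol)
        add("root_ccf_one", paste0(roots, "@", rid),
            sprintf("root CCF %.3f not 1 within %.2f", rc, ccfTol))
    }
  }
  if (!setequal(colnames(ccf), reg$region_id))
    add("region_consistency", tumourID(bundle),
        "clone-tree regions differ from region table")

  mut <- mutationCatalog(bundle)
  if (nrow(mut)) {
    orphan <- unique(mut$cluster_id[!(mut$cluster_id %in% clusterIDs(tr))])
    for (cl in orphan)
      add("mutation_cluster_membership", cl,
          "mutation cluster absent from clone tree")
  }

  pct <- annotations(bundle)$pattern_pct
  if (!is.null(pct) && length(pct) && abs(sum(pct) - 100) > pctTol)
    add("pattern_pct_total", tumourID(bundle),
        sprintf("pattern percentages sum to %.2f", sum(pct)))

  if (!length(v))
    return(data.frame(rule = character(), location = character(),
                      detail = character()))
  do.call(rbind, v)
}

#' Validate every bundle of a cohort
#' @param cohort list as returned by \code{\link{readCohort}} or
#'   \code{\link{simulateCohort}}.
#' @param ... passed to \code{\link{validateBundle}}.
#' @return data.frame of violations with a leading \code{tumour_id} column.
#' @export
validateCohort <- function(cohort, ...) {
  out <- lapply(cohort$bundles, function(b) {
    r <- validateBundle(b, ...)
    if (nrow(r)) cbind(tumour_id = tumourID(b), r) else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(tumour_id = character(), rule = character(),
                      location = character(), detail = character()))
  do.call(rbind, out)
}
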