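#' @importFrom utils read.delim write.table
NULL

# Tab-separated readers/writers for the bundle file set. Segment tables are
# 1-based inclusive (seg convention); cytoband maps are BED 0-based
# half-open and converted to 1-based GRanges on read.

.readTSV <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': file not found")
  tryCatch(
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               check.names = FALSE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e)))
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

#' Read a cytoband map
#'
#' Reads a BED-style file (chrom, start, end, band name, arm) into a
#' \code{GRanges} with metadata columns \code{band} and \code{arm}.
#' Coordinates are converted from BED 0-based half-open to 1-based
#' inclusive.
#'
#' @param path path to a cytobands BED file with columns chrom, start, end,
#'   band, arm (no header).
#' @return \code{GRanges} with mcols \code{band}, \code{arm}.
#' @export
readCytobands <- function(path) {
  df <- tryCatch(
    read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 5)
    stop("parse error in '", path, "': expected 5 columns (BED4 + arm)")
  names(df)[1:5] <- c("chrom", "start", "end", "band", "arm")
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr)$band <- df$band
  mcols(gr)$arm <- df$arm
  gr
}

#' Write a cytoband map
#' @param cytobands \code{GRanges} with mcols \code{band}, \code{arm}.
#' @param path output path (BED 0-based half-open, no header).
#' @export
writeCytobands <- function(cytobands, path) {
  df <- data.frame(chrom = as.character(seqnames(cytobands)),
                   start = start(cytobands) - 1L, end = end(cytobands),
                   band = mcols(cytobands)$band, arm = mcols(cytobands)$arm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

.segmentsToGRangesList <- function(segdf) {
  # split a per-tumour segments table into a named list of GRanges by region
  out <- lapply(split(segdf, segdf$region_id), function(d) {
    d <- d[order(d$chrom, d$start), ]
    gr <- GRanges(d$chrom, IRanges(d$start, d$end))
    mcols(gr)$cnA <- as.numeric(d$cnA)
    mcols(gr)$cnB <- as.numeric(d$cnB)
    gr
  })
  out[unique(segdf$region_id)]
}

.ccfColumns <- function(df, fixed) {
  setdiff(names(df), fixed)
}

#' Read a cohort directory into tumour bundles
#'
#' Expects \code{regions.tsv}, \code{segments.tsv}, \code{clusters.tsv},
#' \code{mutations.tsv}, \code{cytobands.bed} and optionally
#' \code{tumours.tsv} under \code{dir} (formats documented in the package
#' vignette). Region CCF columns absent for a tumour (all-NA) are dropped
#' for that tumour.
#'
#' @param dir directory containing the bundle files.
#' @return list with \code{bundles} (named list of
#'   \code{\linkS4class{TumourBundle}}) and \code{cytobands}
#'   (\code{GRanges}).
#' @export
readCohort <- function(dir) {
  need <- c("regions.tsv", "segments.tsv", "clusters.tsv", "mutations.tsv",
            "cytobands.bed")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing input file(s) in '", dir, "': ",
         paste(missing, collapse = ", "))
  regions <- .readTSV(file.path(dir, "regions.tsv"))
  segments <- .readTSV(file.path(dir, "segments.tsv"))
  clusters <- .readTSV(file.path(dir, "clusters.tsv"))
  mutations <- .readTSV(file.path(dir, "mutations.tsv"))
  cytobands <- readCytobands(file.path(dir, "cytobands.bed"))
  annot <- if (file.exists(file.path(dir, "tumours.tsv")))
    .readTSV(file.path(dir, "tumours.tsv")) else NULL

  bundles <- lapply(unique(regions$tumour_id), function(tid) {
    reg <- regions[regions$tumour_id == tid,
                   setdiff(names(regions), "tumour_id"), drop = FALSE]
    reg$growth_pattern <- tolower(reg$growth_pattern)
    reg$grade <- deriveGrade(reg$growth_pattern)
    seg <- segments[segments$tumour_id == tid, , drop = FALSE]
    cl <- clusters[clusters$tumour_id == tid, , drop = FALSE]
    ccfCols <- .ccfColumns(cl, c("tumour_id", "cluster_id", "parent_id",
                                 "n_mutations"))
    ccfCols <- ccfCols[colSums(!is.na(cl[, ccfCols, drop = FALSE])) > 0]
    ccf <- as.matrix(cl[, ccfCols, drop = FALSE])
    rownames(ccf) <- as.character(cl$cluster_id)
    parent <- setNames(as.character(cl$parent_id), as.character(cl$cluster_id))
    parent[parent == "NA" | parent == ""] <- NA_character_
    tree <- CloneTree(tid, parent, ccf,
                      setNames(cl$n_mutations, as.character(cl$cluster_id)))
    mut <- mutations[mutations$tumour_id == tid,
                     setdiff(names(mutations), "tumour_id"), drop = FALSE]
    mut$cluster_id <- as.character(mut$cluster_id)
    keep <- c("mutation_id", "cluster_id",
              intersect(.ccfColumns(mut, c("mutation_id", "cluster_id")),
                        ccfCols))
    mut <- mut[, keep, drop = FALSE]
    ann <- list()
    if (!is.null(annot) && tid %in% annot$tumour_id) {
      row <- annot[annot$tumour_id == tid, , drop = FALSE]
      pctCols <- grep("^pct_", names(row), value = TRUE)
      pct <- unlist(row[1, pctCols])
      names(pct) <- sub("^pct_", "", pctCols)
      ann <- list(predominant = row$predominant[1],
                  pattern_pct = pct[!is.na(pct) & pct > 0],
                  stas = as.logical(row$stas[1]),
                  necrosis = as.logical(row$necrosis[1]),
                  relapse = row$relapse[1])
    }
    TumourBundle(tid, reg, .segmentsToGRangesList(seg), tree, mut, ann)
  })
  names(bundles) <- unique(regions$tumour_id)
  list(bundles = bundles, cytobands = cytobands)
}

#' Write a cohort of tumour bundles to a directory
#'
#' Inverse of \code{\link{readCohort}}; writes the six tab-separated bundle
#' files. Floats survive a write/read round trip to better than 1e-9.
#'
#' @param bundles named list of \code{\linkS4class{TumourBundle}}.
#' @param cytobands \code{GRanges} cytoband map.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(bundles, cytobands, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regs <- do.call(rbind, lapply(bundles, function(b)
    cbind(tumour_id = tumourID(b),
          regionTable(b)[c("region_id", "purity", "ploidy", "growth_pattern",
                           "seeding_label")])))
  .writeTSV(regs, file.path(dir, "regions.tsv"))

  segs <- do.call(rbind, lapply(bundles, function(b) {
    do.call(rbind, lapply(names(segmentProfiles(b)), function(rid) {
      gr <- segmentProfiles(b)[[rid]]
      data.frame(tumour_id = tumourID(b), region_id = rid,
                 chrom = as.character(seqnames(gr)), start = start(gr),
                 end = end(gr), cnA = mcols(gr)$cnA, cnB = mcols(gr)$cnB)
    }))
  }))
  .writeTSV(segs, file.path(dir, "segments.tsv"))

  allRegions <- unique(unlist(lapply(bundles, regionIDs)))
  cls <- do.call(rbind, lapply(bundles, function(b) {
    tr <- cloneTree(b)
    ccf <- ccfMatrix(tr)
    out <- data.frame(tumour_id = tumourID(b), cluster_id = clusterIDs(tr),
                      parent_id = ifelse(is.na(parentVector(tr)), "NA",
                                         parentVector(tr)),
                      n_mutations = mutationCounts(tr))
    full <- matrix(NA_real_, nrow(out), length(allRegions),
                   dimnames = list(NULL, allRegions))
    full[, colnames(ccf)] <- ccf
    cbind(out, as.data.frame(full, check.names = FALSE))
  }))
  .writeTSV(cls, file.path(dir, "clusters.tsv"))

  muts <- do.call(rbind, lapply(bundles, function(b) {
    m <- mutationCatalog(b)
    out <- data.frame(tumour_id = rep(tumourID(b), nrow(m)),
                      mutation_id = m$mutation_id, cluster_id = m$cluster_id)
    full <- matrix(NA_real_, nrow(m), length(allRegions),
                   dimnames = list(NULL, allRegions))
    present <- intersect(allRegions, names(m))
    full[, present] <- as.matrix(m[, present, drop = FALSE])
    cbind(out, as.data.frame(full, check.names = FALSE))
  }))
  .writeTSV(muts, file.path(dir, "mutations.tsv"))

  writeCytobands(cytobands, file.path(dir, "cytobands.bed"))

  pats <- setdiff(GROWTH_PATTERNS, "unknown")
  tum <- do.call(rbind, lapply(bundles, function(b) {
    ann <- annotations(b)
    pct <- setNames(rep(0, length(pats)), pats)
    if (!is.null(ann$pattern_pct))
      pct[names(ann$pattern_pct)] <- ann$pattern_pct
    row <- data.frame(tumour_id = tumourID(b),
                      predominant = ann$predominant %||% names(which.max(pct)),
                      stas = ann$stas %||% NA,
                      necrosis = ann$necrosis %||% NA,
                      relapse = ann$relapse %||% NA)
    cbind(row, setNames(as.data.frame(as.list(pct)), paste0("pct_", pats)))
  }))
  .writeTSV(tum, file.path(dir, "tumours.tsv"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
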