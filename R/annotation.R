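#' Annotation index for neutral-site classification
#'
#' A sorted set of genomic feature intervals, stored 1-based inclusive
#' (the VCF convention used throughout the package). GFF3 input is already
#' 1-based inclusive; BED input is converted from 0-based half-open at the
#' boundary by [read_annotation()].
#'
#' @param features data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return An `annotation_index` object.
#' @export
annotation_index <- function(features) {
  stopifnot(all(c("chrom", "start", "end") %in% names(features)))
  if (any(features$start > features$end))
    stop("annotation intervals must satisfy start <= end")
  features <- features[order(features$chrom, features$start, features$end),
                       c("chrom", "start", "end")]
  rownames(features) <- NULL
  structure(list(features = features, coordinates = "1-based inclusive"),
            class = "annotation_index")
}

#' Read feature annotation from GFF3 or BED
#'
#' Uses rtracklayer, which performs the BED 0-based half-open to 1-based
#' inclusive conversion; both formats describing the same intervals yield
#' identical indices.
#'
#' @param path file path; format from extension (`.gff`, `.gff3`, `.bed`)
#'   unless `format` is given.
#' @param format optional `"gff3"` or `"bed"`.
#' @return An [annotation_index()].
#' @export
read_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed",
                     stop("cannot infer annotation format from extension: ",
                          path))
  }
  gr <- rtracklayer::import(path, format = format)
  annotation_index(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)))
}

#' Classify sites as genic, neutral, or intermediate
#'
#' A site inside any annotated feature is `genic`; a site whose distance to
#' the nearest feature edge is at least `min_dist` bp is `neutral`
#' (inclusive boundary: exactly `min_dist` away counts as neutral); the
#' remainder is `intermediate`. Sites on chromosomes absent from the
#' annotation are classed neutral with a warning. The partition is
#' exhaustive, disjoint, and invariant to feature ordering in the input.
#'
#' @param gm a [genotype_matrix()].
#' @param ann an [annotation_index()].
#' @param min_dist minimum distance in bp for the neutral class
#'   (default 5000, "at least 5 kb from an annotated feature").
#' @return factor of length `n_sites` with levels `genic`, `neutral`,
#'   `intermediate`.
#' @export
classify_neutral <- function(gm, ann, min_dist = 5000) {
  stopifnot(inherits(ann, "annotation_index"))
  out <- rep(NA_character_, length(gm$pos))
  feats <- split(ann$features, ann$features$chrom)
  missing_chroms <- setdiff(unique(gm$chrom), names(feats))
  if (length(missing_chroms))
    warning("chromosome(s) absent from annotation, sites classed neutral: ",
            paste(missing_chroms, collapse = ", "))
  for (ch in unique(gm$chrom)) {
    i <- which(gm$chrom == ch)
    f <- feats[[ch]]
    if (is.null(f)) { out[i] <- "neutral"; next }
    pos <- gm$pos[i]
    # distance to nearest feature: 0 if inside, gap to nearest edge else
    d <- vapply(pos, function(x)
      min(pmax(f$start - x, x - f$end, 0)), numeric(1))
    out[i] <- ifelse(d == 0, "genic",
                     ifelse(d >= min_dist, "neutral", "intermediate"))
  }
  factor(out, levels = c("genic", "neutral", "intermediate"))
}
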