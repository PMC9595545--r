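# Region sets: named collections of 0-based half-open intervals with an
# optional per-interval label (e.g. the gieStain column of a cytoband file).
# Interval arithmetic is delegated to IRanges.

#' Construct a region set
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds; `start < end`.
#' @param label optional per-interval label (e.g. gieStain value).
#' @param name name of the set.
#' @return a `region_set` (a data frame with attributes `name`, `flattened`).
#' @export
#' @examples
#' region_set("chr1", 0, 1000, label = "gneg", name = "bands")
region_set <- function(chrom, start, end, label = NA_character_,
                       name = "regions") {
  n <- length(start)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(end) == n)
  if (n && any(start < 0)) .stopf("negative region start")
  if (n && any(end <= start)) {
    i <- which(end <= start)[1]
    .stopf("region with end <= start: %s:[%d,%d)", chrom[i], start[i], end[i])
  }
  label <- rep_len(as.character(label), n)
  structure(
    data.frame(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), label = label, stringsAsFactors = FALSE),
    name = name, flattened = FALSE,
    class = c("region_set", "data.frame")
  )
}

#' Read a BED file as a region set
#'
#' BED3 or wider; column 4, when present, becomes the per-interval label.
#'
#' @param path BED file.
#' @param name name for the set (defaults to the file name).
#' @return a [region_set()].
#' @export
read_bed_regions <- function(path, name = basename(path)) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "", fill = TRUE)
  if (ncol(df) < 3L) .stopf("BED needs at least 3 columns, got %d", ncol(df))
  lab <- if (ncol(df) >= 4L) as.character(df[[4]]) else NA_character_
  region_set(df[[1]], df[[2]], df[[3]], label = lab, name = name)
}

#' Read a UCSC-style cytoband table
#'
#' Expects tab-separated columns `chrom, start, end, band, gieStain`
#' (0-based starts, no header). The gieStain value becomes the interval
#' label, from which chromatin classes are derived via [stain_to_class()].
#'
#' @param path cytoband TSV.
#' @return a [region_set()] named `"cytoband"`.
#' @export
read_cytoband <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 5L) {
    .stopf("cytoband file must have 5 columns (missing gieStain?): got %d",
           ncol(df))
  }
  region_set(df[[1]], df[[2]], df[[3]], label = as.character(df[[5]]),
             name = "cytoband")
}

#' Write a region set as BED
#' @param regions a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  out <- regions[, c("chrom", "start", "end")]
  if (any(!is.na(regions$label))) {
    lab <- regions$label
    lab[is.na(lab)] <- "."
    out$label <- lab
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.rs_iranges <- function(rs) {
  # 0-based half-open -> IRanges (1-based closed)
  split(IRanges::IRanges(start = rs$start + 1L, end = rs$end), rs$chrom)
}

.iranges_rs <- function(irl, name) {
  chrom <- rep(names(irl), vapply(irl, length, integer(1)))
  starts <- unlist(lapply(irl, IRanges::start), use.names = FALSE)
  ends <- unlist(lapply(irl, IRanges::end), use.names = FALSE)
  if (length(chrom) == 0L) {
    out <- region_set(character(0), integer(0), integer(0), name = name)
  } else {
    out <- region_set(chrom, starts - 1L, ends, name = name)
  }
  out
}

#' Flatten a region set
#'
#' Merges overlapping or abutting intervals per chromosome into disjoint
#' sorted intervals. Labels are dropped.
#'
#' @param regions a `region_set`.
#' @return a flattened `region_set`.
#' @export
flatten_regions <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  irl <- lapply(.rs_iranges(regions), IRanges::reduce)
  out <- .iranges_rs(irl, attr(regions, "name"))
  attr(out, "flattened") <- TRUE
  out
}

#' Intersect two region sets
#'
#' Returns all maximal intervals shared by `a` and `b`; overlap requires
#' strictly positive shared length (half-open abutment does not overlap).
#'
#' @param a,b `region_set` objects.
#' @return a flattened `region_set` of the overlaps.
#' @export
#' @examples
#' a <- region_set("chr1", 0, 10)
#' b <- region_set("chr1", 5, 15)
#' intersect_regions(a, b)
intersect_regions <- function(a, b) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  ia <- .rs_iranges(a)
  ib <- .rs_iranges(b)
  common <- intersect(names(ia), names(ib))
  irl <- lapply(common, function(ch) {
    x <- IRanges::reduce(ia[[ch]])
    y <- IRanges::reduce(ib[[ch]])
    ov <- IRanges::findOverlaps(x, y, minoverlap = 1L)
    if (length(ov) == 0L) return(IRanges::IRanges())
    IRanges::reduce(IRanges::pintersect(x[S4Vectors::queryHits(ov)],
                                        y[S4Vectors::subjectHits(ov)]))
  })
  names(irl) <- common
  irl <- irl[vapply(irl, length, integer(1)) > 0L]
  out <- .iranges_rs(irl, paste0(attr(a, "name"), "&", attr(b, "name")))
  attr(out, "flattened") <- TRUE
  out
}

# logical: is each (chrom, pos) point inside some interval of `regions`?
.positions_in_regions <- function(regions, chrom, pos) {
  out <- logical(length(pos))
  irl <- .rs_iranges(regions)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (is.null(irl[[ch]])) next
    q <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    out[sel] <- IRanges::countOverlaps(q, irl[[ch]]) > 0L
  }
  out
}

#' Total number of bases covered by a region set
#' @param regions a `region_set`.
#' @return numeric base count (after flattening).
#' @export
region_bases <- function(regions) {
  fl <- flatten_regions(regions)
  sum(as.numeric(fl$end - fl$start))
}
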