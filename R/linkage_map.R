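#' Linkage map objects
#'
#' A linkage map is an ordered set of chromosomes, each carrying named
#' markers at strictly increasing positions in centiMorgans.  Maps are
#' expected to have been constructed by dedicated mapping software; this
#' package only consumes them.
#'
#' @param chrom character vector of chromosome names (one entry per marker,
#'   chromosomes contiguous and in display order).
#' @param marker character vector of marker names, unique across the map.
#' @param pos numeric vector of positions in cM, strictly increasing within
#'   each chromosome, first position >= 0.
#' @return an object of class \code{linkage_map}: a data frame with columns
#'   \code{chrom}, \code{marker}, \code{pos}.
#' @examples
#' m <- linkage_map(rep("chr1", 3), c("M1", "M2", "M3"), c(0, 10, 20))
#' n_markers(m)
#' @export
linkage_map <- function(chrom, marker, pos) {
  if (length(chrom) != length(marker) || length(marker) != length(pos)) {
    stop("chrom, marker and pos must have equal length")
  }
  chrom <- as.character(chrom)
  marker <- as.character(marker)
  pos <- as.numeric(pos)
  map <- data.frame(chrom = chrom, marker = marker, pos = pos,
                    stringsAsFactors = FALSE)
  validate_linkage_map(map)
}

validate_linkage_map <- function(map) {
  if (nrow(map) == 0) stop("linkage map is empty")
  # chromosomes must be contiguous blocks
  rl <- rle(map$chrom)
  if (anyDuplicated(rl$values)) {
    stop("markers of one chromosome must be listed contiguously")
  }
  if (anyDuplicated(map$marker)) {
    dup <- map$marker[duplicated(map$marker)][1]
    stop("duplicate marker name in map: ", dup)
  }
  for (ch in rl$values) {
    p <- map$pos[map$chrom == ch]
    if (p[1] < 0) stop("first marker position on ", ch, " is negative")
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("marker positions on ", ch, " are not strictly increasing")
    }
  }
  class(map) <- c("linkage_map", "data.frame")
  map
}

#' @rdname linkage_map
#' @param map a \code{linkage_map}.
#' @export
n_markers <- function(map) nrow(map)

#' @rdname linkage_map
#' @export
chromosomes <- function(map) unique(map$chrom)

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("Linkage map: %d chromosomes, %d markers\n",
              length(unique(x$chrom)), nrow(x)))
  tab <- do.call(rbind, lapply(split(x, factor(x$chrom, unique(x$chrom))),
    function(d) data.frame(chrom = d$chrom[1], markers = nrow(d),
                           length_cM = max(d$pos) - min(d$pos))))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Scan-position grid for one-dimensional QTL scans
#'
#' Positions are laid on a regular grid of \code{step} cM starting at each
#' chromosome's first marker, and every marker position is always included,
#' so the scan visits markers exactly and intermediate points in between.
#'
#' @param map a \code{linkage_map}.
#' @param step grid step in cM (default 1).
#' @return data frame with columns \code{chrom} and \code{pos}, sorted by
#'   chromosome then position.
#' @export
scan_positions <- function(map, step = 1) {
  if (!inherits(map, "linkage_map")) map <- validate_linkage_map(map)
  if (step <= 0) stop("scan step must be positive")
  out <- lapply(split(map, factor(map$chrom, unique(map$chrom))), function(d) {
    grid <- seq(d$pos[1], d$pos[nrow(d)], by = step)
    p <- sort(unique(round(c(grid, d$pos), 8)))
    data.frame(chrom = d$chrom[1], pos = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read a linkage-map (MHP) input file
#'
#' The file has three parts, in order, with '#' comments ignored:
#' \enumerate{
#'   \item general information: number of chromosomes, marker space type
#'     (1 = positions, 2 = intervals between adjacent markers), marker
#'     space unit (1 = cM, 2 = Morgan);
#'   \item marker numbers: one \code{name count} pair per chromosome;
#'   \item the map itself: for each chromosome, \code{count} lines of
#'     \code{marker value}.
#' }
#' Interval-style input is accumulated into positions; Morgan units are
#' converted to cM.  Positions are stored internally in cM.
#'
#' @param file path to the input file.
#' @return a \code{linkage_map}.
#' @export
read_mhp <- function(file) {
  tk <- token_reader(file)
  n_chrom <- tk$take_int(what = "number of chromosomes")
  space_type <- tk$take_int(what = "marker space type")
  space_unit <- tk$take_int(what = "marker space unit")
  if (!space_type %in% 1:2) stop("marker space type must be 1 (positions) or 2 (intervals)")
  if (!space_unit %in% 1:2) stop("marker space unit must be 1 (cM) or 2 (Morgan)")
  chrom_names <- character(n_chrom)
  n_mark <- integer(n_chrom)
  for (i in seq_len(n_chrom)) {
    chrom_names[i] <- tk$take(what = "chromosome name")
    n_mark[i] <- tk$take_int(what = paste0("marker count of ", chrom_names[i]))
  }
  chrom <- marker <- character(0)
  pos <- numeric(0)
  for (i in seq_len(n_chrom)) {
    nm <- character(n_mark[i])
    pv <- numeric(n_mark[i])
    for (j in seq_len(n_mark[i])) {
      nm[j] <- tk$take(what = sprintf("marker name (%s #%d)", chrom_names[i], j))
      pv[j] <- tk$take_num(what = sprintf("marker position (%s #%d)", chrom_names[i], j))
    }
    if (space_unit == 2) pv <- pv * 100
    if (space_type == 2) pv <- cumsum(pv)
    chrom <- c(chrom, rep(chrom_names[i], n_mark[i]))
    marker <- c(marker, nm)
    pos <- c(pos, pv)
  }
  if (!tk$exhausted()) {
    stop(sprintf("'%s': trailing content after line %d (marker counts in part 2 may be too small)",
                 file, tk$line()), call. = FALSE)
  }
  linkage_map(chrom, marker, pos)
}

#' Write and read the plain-text linkage-map table
#'
#' \code{write_linkage_map_txt()} writes the tab-separated
#' chromosome/marker/position table ('LinkageMap.txt');
#' \code{read_linkage_map_txt()} parses it back.
#'
#' @param map a \code{linkage_map}.
#' @param file output path.
#' @return \code{write_linkage_map_txt()} returns \code{file} invisibly.
#' @export
write_linkage_map_txt <- function(map, file) {
  df <- as.data.frame(map)[, c("chrom", "marker", "pos")]
  names(df) <- c("Chromosome", "Marker", "Position_cM")
  write_tsv(df, file)
  invisible(file)
}

#' @rdname write_linkage_map_txt
#' @export
read_linkage_map_txt <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  linkage_map(df$Chromosome, df$Marker, df$Position_cM)
}

#' Draw a linkage map
#'
#' Each chromosome is drawn as a vertical bar with marker ticks; marker
#' names and positions are labelled.  \code{render_map()} exports the
#' drawing headlessly to a PNG or SVG file.
#'
#' @param x,map a \code{linkage_map}.
#' @param chromosomes optional subset of chromosome names to draw.
#' @param show_labels draw marker names/positions (default TRUE).
#' @param ... further arguments (ignored).
#' @export
plot.linkage_map <- function(x, chromosomes = NULL, show_labels = TRUE, ...) {
  chs <- unique(x$chrom)
  if (!is.null(chromosomes)) {
    missing_ch <- setdiff(chromosomes, chs)
    if (length(missing_ch)) stop("unknown chromosome(s): ", paste(missing_ch, collapse = ", "))
    chs <- chromosomes
  }
  maxpos <- max(x$pos[x$chrom %in% chs])
  nc <- length(chs)
  graphics::plot(NULL, xlim = c(0.5, nc + 0.7), ylim = c(maxpos * 1.05, -maxpos * 0.05),
                 xlab = "", ylab = "Position (cM)", xaxt = "n", bty = "n", ...)
  graphics::axis(1, at = seq_len(nc), labels = chs, tick = FALSE)
  for (i in seq_len(nc)) {
    d <- x[x$chrom == chs[i], ]
    graphics::rect(i - 0.06, min(d$pos), i + 0.06, max(d$pos),
                   col = "grey85", border = "grey40")
    graphics::segments(i - 0.06, d$pos, i + 0.06, d$pos, col = "grey20")
    if (show_labels) {
      graphics::text(i + 0.1, d$pos, d$marker, cex = 0.55, adj = 0)
      graphics::text(i - 0.1, d$pos, formatC(d$pos, format = "fg"), cex = 0.5, adj = 1)
    }
  }
  invisible(x)
}

#' @rdname plot.linkage_map
#' @param file output image path; format from extension (.png or .svg).
#' @param width,height device size in inches.
#' @export
render_map <- function(map, file, chromosomes = NULL, width = 7, height = 6, ...) {
  ext <- tolower(tools::file_ext(file))
  dev <- switch(ext,
    png = function() grDevices::png(file, width = width, height = height,
                                    units = "in", res = 150),
    svg = function() grDevices::svg(file, width = width, height = height),
    stop("unsupported image format: .", ext, " (use .png or .svg)")
  )
  dev()
  on.exit(grDevices::dev.off())
  plot.linkage_map(map, chromosomes = chromosomes, ...)
  invisible(file)
}
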