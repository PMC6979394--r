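#' Construct a genetic map
#'
#' A genetic map ties physical marker coordinates (bp, 1-based) to genetic
#' positions (cM) per chromosome. Within a chromosome physical positions must
#' be strictly increasing and genetic positions non-decreasing.
#'
#' @param map data.frame with columns `chrom`, `marker_id`, `pos_bp`, `pos_cM`.
#'   `marker_id` is generated when absent.
#' @param chrom_len optional named vector of chromosome lengths in bp; defaults
#'   to the last marker position per chromosome.
#' @return A `genetic_map` object (data.frame with a `chrom_len` attribute).
#' @export
genetic_map <- function(map, chrom_len = NULL) {
  stopifnot(is.data.frame(map), all(c("chrom", "pos_bp", "pos_cM") %in% names(map)))
  if (is.null(map$marker_id)) {
    map$marker_id <- paste0(map$chrom, "_", map$pos_bp)
  }
  map$chrom <- as.character(map$chrom)
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos_bp)
  map <- map[ord, c("chrom", "marker_id", "pos_bp", "pos_cM")]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    if (anyDuplicated(m$pos_bp)) {
      stop("duplicated pos_bp on chromosome ", ch)
    }
    if (any(diff(m$pos_cM) < 0)) {
      stop("decreasing cM on chromosome ", ch)
    }
    if (m$pos_cM[1] < 0 || m$pos_bp[1] < 1) {
      stop("negative cM or bp < 1 on chromosome ", ch)
    }
  }
  if (is.null(chrom_len)) {
    chrom_len <- vapply(split(map$pos_bp, map$chrom), max, numeric(1))
    chrom_len <- chrom_len[unique(map$chrom)]
  } else {
    stopifnot(all(unique(map$chrom) %in% names(chrom_len)))
    chrom_len <- chrom_len[unique(map$chrom)]
    last <- vapply(split(map$pos_bp, map$chrom), max, numeric(1))[unique(map$chrom)]
    if (any(chrom_len < last)) stop("chrom_len shorter than last marker")
  }
  structure(map, chrom_len = chrom_len, class = c("genetic_map", "data.frame"))
}

#' Read a genetic map from a TSV file
#'
#' Expects tab-separated columns `chrom`, `pos_bp`, `cM` (a `marker_id` column
#' is honoured when present).
#'
#' @param path file path.
#' @return A [genetic_map()] object.
#' @export
read_genetic_map <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos_bp")
  if (!all(need %in% names(tab)) || !any(c("cM", "pos_cM") %in% names(tab))) {
    stop("genetic map must have columns chrom, pos_bp, cM")
  }
  if (!"pos_cM" %in% names(tab)) tab$pos_cM <- tab$cM
  genetic_map(tab[, c("chrom", "pos_bp", "pos_cM",
                      intersect("marker_id", names(tab)))])
}

#' Write a genetic map to TSV
#' @param map a [genetic_map()] object.
#' @param path output file path.
#' @export
write_genetic_map <- function(map, path) {
  out <- data.frame(chrom = map$chrom, marker_id = map$marker_id,
                    pos_bp = map$pos_bp, cM = map$pos_cM)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolate genetic positions at arbitrary physical positions
#'
#' Piecewise-linear interpolation of cM against bp, clamped at the first and
#' last marker of each chromosome (positions before the first marker map to
#' its cM, positions past the last marker to the last marker's cM).
#'
#' @param map a [genetic_map()] object.
#' @param chrom chromosome name (scalar).
#' @param pos_bp numeric vector of physical positions.
#' @return numeric vector of genetic positions in cM.
#' @export
interp_cM <- function(map, chrom, pos_bp) {
  m <- map[map$chrom == chrom, ]
  if (nrow(m) == 0L) stop("chromosome ", chrom, " absent from map")
  if (nrow(m) == 1L) return(rep(m$pos_cM, length(pos_bp)))
  stats::approx(m$pos_bp, m$pos_cM, xout = pos_bp, rule = 2, ties = "ordered")$y
}

#' Interpolate physical positions at arbitrary genetic positions
#'
#' Inverse of [interp_cM()]: piecewise-linear interpolation of bp against cM,
#' clamped at the chromosome ends. Plateaus in the map (zero recombination)
#' resolve to their left edge.
#'
#' @inheritParams interp_cM
#' @param pos_cM numeric vector of genetic positions in cM.
#' @return numeric vector of physical positions (bp).
#' @export
interp_bp <- function(map, chrom, pos_cM) {
  m <- map[map$chrom == chrom, ]
  if (nrow(m) == 0L) stop("chromosome ", chrom, " absent from map")
  if (nrow(m) == 1L) return(rep(m$pos_bp, length(pos_cM)))
  stats::approx(m$pos_cM, m$pos_bp, xout = pos_cM, rule = 2, ties = "min")$y
}

#' Chromosome map lengths in centimorgans
#' @param map a [genetic_map()] object.
#' @return named numeric vector, cM span per chromosome.
#' @export
map_lengths_cM <- function(map) {
  vapply(split(map$pos_cM, map$chrom), function(x) max(x) - min(x),
         numeric(1))[unique(map$chrom)]
}

#' Chromosome physical lengths in bp
#' @param map a [genetic_map()] object.
#' @return named numeric vector of chromosome lengths.
#' @export
chrom_lengths <- function(map) attr(map, "chrom_len")

#' Build a uniform synthetic genetic map
#'
#' Convenience generator for simulation studies: `n_chr` chromosomes, each of
#' genetic length `chr_cM` and physical length `chr_bp`, with `n_markers`
#' evenly spaced markers and a linear bp-to-cM relation.
#'
#' @param n_chr number of chromosomes.
#' @param chr_cM genetic length per chromosome (cM).
#' @param chr_bp physical length per chromosome (bp).
#' @param n_markers markers per chromosome.
#' @return A [genetic_map()] object.
#' @export
synthetic_map <- function(n_chr = 2, chr_cM = 100, chr_bp = 1e7, n_markers = 5000) {
  pos <- round(seq(1, chr_bp, length.out = n_markers))
  maps <- lapply(seq_len(n_chr), function(ch) {
    data.frame(chrom = paste0("chr", ch), pos_bp = pos,
               pos_cM = (pos - 1) / (chr_bp - 1) * chr_cM)
  })
  cl <- rep(chr_bp, n_chr)
  names(cl) <- paste0("chr", seq_len(n_chr))
  genetic_map(do.call(rbind, maps), chrom_len = cl)
}
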