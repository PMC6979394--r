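#' Collapse mosaics into recombination bins
#'
#' A bin is a genomic span within which no recombination breakpoint occurs in
#' any line: bin boundaries are the union of all segment boundaries across
#' lines, and each line's state in a bin is inherited from its covering
#' segment (UNKNOWN propagates).
#'
#' @param mosaic a [mosaic_set()] over a common genome.
#' @return A `bin_map` object: list with `bins` (data.frame bin_id, chrom,
#'   start_bp, end_bp, n_states), `states` (lines x bins integer matrix, NA =
#'   UNKNOWN) and `samples`.
#' @export
build_bins <- function(mosaic) {
  chrom_len <- attr(mosaic, "chrom_len")
  lines <- unique(mosaic$line)
  bin_rows <- list()
  state_cols <- list()
  k <- 1L
  for (ch in names(chrom_len)) {
    seg <- mosaic[mosaic$chrom == ch, ]
    if (nrow(seg) == 0L) stop("chromosome ", ch, " missing from mosaic")
    starts <- sort(unique(seg$start_bp))
    if (starts[1] != 1) stop("mosaic does not tile chromosome ", ch)
    ends <- c(starts[-1] - 1, chrom_len[[ch]])
    st <- matrix(NA_integer_, length(lines), length(starts))
    for (i in seq_along(lines)) {
      s <- seg[seg$line == lines[i], ]
      st[i, ] <- s$founder[findInterval(starts, s$start_bp)]
    }
    bin_rows[[k]] <- data.frame(chrom = ch, start_bp = starts, end_bp = ends)
    state_cols[[k]] <- st
    k <- k + 1L
  }
  bins <- do.call(rbind, bin_rows)
  bins$bin_id <- sprintf("bin%05d", seq_len(nrow(bins)))
  states <- do.call(cbind, state_cols)
  dimnames(states) <- list(lines, bins$bin_id)
  bins$n_states <- apply(states, 2, function(v) length(unique(v[!is.na(v)])))
  bins <- bins[, c("bin_id", "chrom", "start_bp", "end_bp", "n_states")]
  structure(list(bins = bins, states = states, samples = lines),
            class = "bin_map")
}

#' @export
print.bin_map <- function(x, ...) {
  cat(sprintf("bin_map: %d lines x %d bins\n",
              length(x$samples), nrow(x$bins)))
  invisible(x)
}

#' Bin-haplotype kinship matrix
#'
#' Bins are reformatted as founder-state dummy variables; the kinship between
#' two lines is the fraction of bins at which they carry the same founder
#' state (K = Z Z' / n_bins for the line x (bin, state) indicator matrix Z).
#' UNKNOWN states match nothing, so the diagonal equals the fraction of
#' non-UNKNOWN bins per line.
#'
#' @param bins a [build_bins()] result.
#' @param weight_by_length weight bins by their bp length instead of equally
#'   (off by default).
#' @return symmetric N x N matrix.
#' @export
bin_kinship <- function(bins, weight_by_length = FALSE) {
  st <- bins$states
  n <- nrow(st)
  B <- ncol(st)
  w <- if (weight_by_length) {
    len <- bins$bins$end_bp - bins$bins$start_bp + 1
    len / sum(len)
  } else {
    rep(1 / B, B)
  }
  K <- matrix(0, n, n, dimnames = list(rownames(st), rownames(st)))
  buf <- vector("list", B)
  nc <- 0L
  flush_at <- 4000L
  pending <- integer(0)
  for (b in seq_len(B)) {
    sb <- st[, b]
    lev <- unique(sb[!is.na(sb)])
    if (length(lev) == 0L) next
    Z <- matrix(0, n, length(lev))
    for (j in seq_along(lev)) Z[!is.na(sb) & sb == lev[j], j] <- sqrt(w[b])
    buf[[b]] <- Z
    pending <- c(pending, b)
    nc <- nc + length(lev)
    if (nc >= flush_at || b == B) {
      K <- K + tcrossprod(do.call(cbind, buf[pending]))
      buf[pending] <- list(NULL)
      pending <- integer(0)
      nc <- 0L
    }
  }
  if (length(pending)) K <- K + tcrossprod(do.call(cbind, buf[pending]))
  K
}

#' Founder states of each bin at marker resolution
#'
#' Consistency helper: returns the bin state of the bin covering each marker.
#'
#' @param bins a [build_bins()] result.
#' @param markers marker table with `chrom`, `pos_bp`.
#' @return lines x markers integer matrix.
#' @export
bin_states_at <- function(bins, markers) {
  out <- matrix(NA_integer_, length(bins$samples), nrow(markers),
                dimnames = list(bins$samples, markers$marker_id))
  for (ch in unique(markers$chrom)) {
    cols <- which(markers$chrom == ch)
    bidx <- which(bins$bins$chrom == ch)
    j <- findInterval(markers$pos_bp[cols], bins$bins$start_bp[bidx])
    out[, cols] <- bins$states[, bidx[j], drop = FALSE]
  }
  out
}

#' Write a bin table (with per-line states) to TSV
#' @param bins a [build_bins()] result.
#' @param path output path.
#' @export
write_bins <- function(bins, path) {
  st <- t(bins$states)
  st_chr <- apply(st, 2, function(v) ifelse(is.na(v), "UNKNOWN", v))
  out <- cbind(bins$bins, as.data.frame(st_chr, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
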