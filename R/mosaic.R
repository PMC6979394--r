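#' Construct a mosaic set
#'
#' A mosaic set records, for every line and chromosome, an ordered tiling of
#' founder-labelled identity-by-descent segments. Coordinates are 1-based
#' inclusive; `founder` is an integer index into the founder panel, `NA`
#' meaning the segment could not be traced (UNKNOWN). Segments must tile each
#' chromosome exactly and adjacent segments must carry different labels.
#'
#' @param segments data.frame with columns `line`, `chrom`, `start_bp`,
#'   `end_bp`, `founder`.
#' @param chrom_len named vector of chromosome lengths (bp).
#' @param n_founders number of founders the labels refer to.
#' @param validate verify the tiling invariants (default TRUE).
#' @return A `mosaic_set` object (data.frame with attributes).
#' @export
mosaic_set <- function(segments, chrom_len, n_founders, validate = TRUE) {
  stopifnot(all(c("line", "chrom", "start_bp", "end_bp", "founder")
                %in% names(segments)))
  segments$chrom <- as.character(segments$chrom)
  segments <- segments[order(segments$line,
                             match(segments$chrom, names(chrom_len)),
                             segments$start_bp), ]
  rownames(segments) <- NULL
  if (validate) {
    sp <- split(seq_len(nrow(segments)),
                list(segments$line, segments$chrom), drop = TRUE)
    for (idx in sp) {
      s <- segments[idx, ]
      L <- chrom_len[[s$chrom[1]]]
      if (s$start_bp[1] != 1 || s$end_bp[nrow(s)] != L ||
          (nrow(s) > 1 && any(s$start_bp[-1] != s$end_bp[-nrow(s)] + 1))) {
        stop("segments do not tile chromosome ", s$chrom[1],
             " for line ", s$line[1])
      }
      if (nrow(s) > 1) {
        same <- s$founder[-1] == s$founder[-nrow(s)]
        same[is.na(same)] <- is.na(s$founder[-1])[is.na(same)] &
          is.na(s$founder[-nrow(s)])[is.na(same)]
        if (any(same, na.rm = TRUE)) {
          stop("adjacent segments share a label for line ", s$line[1])
        }
      }
    }
  }
  structure(segments, chrom_len = chrom_len, n_founders = n_founders,
            class = c("mosaic_set", "data.frame"))
}

#' @export
print.mosaic_set <- function(x, ...) {
  cat(sprintf("mosaic_set: %d lines, %d segments, %d chromosomes, %d founders\n",
              length(unique(x$line)), nrow(x),
              length(attr(x, "chrom_len")), attr(x, "n_founders")))
  invisible(x)
}

#' Founder state of every line at every map marker
#'
#' @param mosaic a [mosaic_set()].
#' @param map a [genetic_map()] whose markers to evaluate.
#' @return integer matrix lines x markers of founder indices (NA = UNKNOWN),
#'   lines ordered as `sort(unique(mosaic$line))` unless `lines` given.
#' @param lines optional character vector fixing line order.
#' @export
mosaic_states_at <- function(mosaic, map, lines = NULL) {
  if (is.null(lines)) lines <- unique(mosaic$line)
  S <- nrow(map)
  out <- matrix(NA_integer_, length(lines), S,
                dimnames = list(lines, map$marker_id))
  for (ch in unique(map$chrom)) {
    mcols <- which(map$chrom == ch)
    pos <- map$pos_bp[mcols]
    seg <- mosaic[mosaic$chrom == ch, ]
    for (i in seq_along(lines)) {
      s <- seg[seg$line == lines[i], ]
      if (nrow(s) == 0L) stop("line ", lines[i], " missing on chromosome ", ch)
      j <- findInterval(pos, s$start_bp)
      out[i, mcols] <- s$founder[j]
    }
  }
  out
}

#' Project SNP genotypes from founder alleles through a mosaic
#'
#' Each line's dosage at a marker is twice the allele of the founder whose
#' segment covers the marker (fully homozygous projection); markers falling in
#' UNKNOWN segments become missing.
#'
#' @param mosaic a [mosaic_set()].
#' @param founders a [founder_panel()].
#' @return A [genotype_matrix()].
#' @export
project_genotypes <- function(mosaic, founders) {
  map <- founders$map
  states <- mosaic_states_at(mosaic, map)
  S <- ncol(states)
  idx <- cbind(as.vector(states), rep(seq_len(S), each = nrow(states)))
  dos <- matrix(2 * founders$alleles[idx], nrow(states), S)
  genotype_matrix(dos, map_to_markers(map), samples = rownames(states))
}

map_to_markers <- function(map) {
  data.frame(marker_id = map$marker_id, chrom = map$chrom,
             pos_bp = map$pos_bp, stringsAsFactors = FALSE)
}

#' Write a mosaic set to TSV
#'
#' Columns: line, chrom, start_bp, end_bp, founder (founder ID or "UNKNOWN").
#'
#' @param mosaic a [mosaic_set()].
#' @param path output path.
#' @param founder_ids optional character vector translating founder indices.
#' @export
write_mosaic <- function(mosaic, path, founder_ids = NULL) {
  lab <- if (is.null(founder_ids)) as.character(mosaic$founder)
         else founder_ids[mosaic$founder]
  lab[is.na(lab)] <- "UNKNOWN"
  out <- data.frame(line = mosaic$line, chrom = mosaic$chrom,
                    start_bp = mosaic$start_bp, end_bp = mosaic$end_bp,
                    founder = lab)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mosaic set from TSV
#' @param path file path (format of [write_mosaic()]).
#' @param chrom_len named chromosome lengths; inferred from segment ends when NULL.
#' @param n_founders number of founders; inferred from labels when NULL.
#' @param founder_ids optional character vector mapping IDs back to indices.
#' @return A [mosaic_set()].
#' @export
read_mosaic <- function(path, chrom_len = NULL, n_founders = NULL,
                        founder_ids = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  f <- tab$founder
  f[f == "UNKNOWN"] <- NA
  tab$founder <- if (is.null(founder_ids)) as.integer(f)
                 else match(f, founder_ids)
  if (is.null(chrom_len)) {
    chrom_len <- vapply(split(tab$end_bp, tab$chrom), max, numeric(1))
  }
  if (is.null(n_founders)) n_founders <- max(tab$founder, na.rm = TRUE)
  mosaic_set(tab, chrom_len = chrom_len, n_founders = n_founders)
}
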