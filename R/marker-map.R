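#' Construct a parental marker map
#'
#' A marker map lists the polymorphic positions (SNPs and InDels) that
#' distinguish the two isogenic parents along one chromosome, the coordinate
#' system in which all events are localized.
#'
#' @param chromosome Chromosome name.
#' @param chromosome_length Chromosome length in bp.
#' @param position Integer vector of strictly increasing 1-based marker
#'   positions.
#' @param kind Character vector, `"SNP"` or `"InDel"`, recycled.
#' @param allele_P1,allele_P2 Parental allele labels; must differ at every
#'   marker.
#' @return An object of class `marker_map`: a list with elements
#'   `chromosome`, `chromosome_length` and `markers` (a data frame with
#'   columns `pos`, `kind`, `allele_P1`, `allele_P2`).
#' @seealso [generate_marker_map()] to draw a synthetic map.
#' @export
marker_map <- function(chromosome, chromosome_length, position,
                       kind = "SNP", allele_P1 = "A", allele_P2 = "T") {
  position <- as.integer(position)
  n <- length(position)
  markers <- data.frame(
    pos = position,
    kind = rep_len(as.character(kind), n),
    allele_P1 = rep_len(as.character(allele_P1), n),
    allele_P2 = rep_len(as.character(allele_P2), n),
    stringsAsFactors = FALSE
  )
  # canonical order: sorting by position makes results invariant to the
  # row order of an input file; duplicates are still rejected
  markers <- markers[order(markers$pos), , drop = FALSE]
  rownames(markers) <- NULL
  map <- structure(
    list(chromosome = as.character(chromosome),
         chromosome_length = as.numeric(chromosome_length),
         markers = markers),
    class = "marker_map"
  )
  validate_marker_map(map)
  map
}

validate_marker_map <- function(map) {
  m <- map$markers
  stop_if(nrow(m) > 0 && any(diff(m$pos) <= 0),
          "marker positions must be strictly increasing")
  stop_if(nrow(m) > 0 && (m$pos[1] < 1 || m$pos[nrow(m)] > map$chromosome_length),
          "marker positions must lie in [1, chromosome_length]")
  stop_if(any(m$allele_P1 == m$allele_P2),
          "parental alleles must differ at every marker")
  stop_if(!all(m$kind %in% c("SNP", "InDel")),
          "marker kind must be 'SNP' or 'InDel'")
  invisible(map)
}

#' Generate a synthetic parental marker map
#'
#' Draws `n_markers` distinct positions on a chromosome.  With
#' `clustering = 0` positions are uniform; with `clustering > 0` a
#' piecewise-constant marker intensity is drawn from a gamma distribution
#' (shape `1/clustering`) over blocks of the chromosome, so the inter-marker
#' gap distribution is over-dispersed relative to uniform, emulating the
#' patchy polymorphism density of real isogenic-line comparisons.
#'
#' Defaults emulate a 22.4-Mb chromosome arm carrying 93,538 polymorphisms
#' (mean gap about 239.5 bp).
#'
#' @param n_markers Number of markers.
#' @param chromosome_length Chromosome length in bp; must be at least
#'   `n_markers`.
#' @param clustering Non-negative dispersion parameter; 0 gives uniform
#'   placement.
#' @param seed Integer seed.
#' @param chromosome Chromosome name.
#' @param n_blocks Number of intensity blocks used when `clustering > 0`.
#' @return A [marker_map()].
#' @examples
#' map <- generate_marker_map(1000, 1e6, clustering = 0, seed = 1)
#' mean(diff(map$markers$pos))
#' @export
generate_marker_map <- function(n_markers = 93538, chromosome_length = 22.4e6,
                                clustering = 0.5, seed = 1,
                                chromosome = "X", n_blocks = 1000) {
  stop_if(n_markers < 0 || chromosome_length < n_markers,
          "need 0 <= n_markers <= chromosome_length")
  stop_if(clustering < 0, "clustering must be >= 0")
  L <- floor(chromosome_length)
  set.seed(seed)
  if (n_markers == 0) {
    pos <- integer(0)
  } else if (clustering == 0) {
    pos <- sort(sample.int(L, n_markers))
  } else {
    nb <- min(n_blocks, max(1L, n_markers %/% 5L))
    bounds <- round(seq(0, L, length.out = nb + 1))
    sizes <- diff(bounds)
    w <- rgamma(nb, shape = 1 / clustering, rate = 1 / clustering) * sizes
    # cap per-block counts at block size, redistributing the excess
    counts <- as.vector(rmultinom(1, n_markers, w / sum(w)))
    over <- counts > sizes
    while (any(over)) {
      excess <- sum(counts[over] - sizes[over])
      counts[over] <- sizes[over]
      room <- sizes - counts
      idx <- which(room > 0)
      add <- as.vector(rmultinom(1, excess, room[idx] / sum(room[idx])))
      counts[idx] <- counts[idx] + add
      over <- counts > sizes
    }
    pos <- unlist(lapply(seq_len(nb), function(b) {
      if (counts[b] == 0) return(integer(0))
      bounds[b] + sort(sample.int(sizes[b], counts[b]))
    }), use.names = FALSE)
  }
  kind <- ifelse(runif(n_markers) < 0.845, "SNP", "InDel")
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, n_markers, replace = TRUE)
  a2 <- bases[(match(a1, bases) + sample(1:3, n_markers, replace = TRUE) - 1L) %% 4L + 1L]
  marker_map(chromosome, chromosome_length, pos, kind, a1, a2)
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("Marker map: %d markers on %s (%.4g bp)\n",
              nrow(x$markers), x$chromosome, x$chromosome_length))
  if (nrow(x$markers) > 1) {
    cat(sprintf("  mean inter-marker gap: %.1f bp\n", mean(diff(x$markers$pos))))
  }
  invisible(x)
}

#' Read or write a marker map as tab-separated text
#'
#' The format has a header line and columns `chrom`, `pos`, `kind`,
#' `allele_P1`, `allele_P2` with 1-based positions.
#'
#' @param map A [marker_map()].
#' @param path File path.
#' @param chromosome_length Chromosome length; when reading, defaults to the
#'   last marker position if not given.
#' @return `read_marker_map` returns a [marker_map()]; `write_marker_map`
#'   returns `path` invisibly.
#' @export
write_marker_map <- function(map, path) {
  df <- data.frame(chrom = map$chromosome, map$markers, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path, chromosome_length = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  len <- chromosome_length %||% (if (nrow(df)) max(df$pos) else 0)
  chrom <- if (nrow(df)) df$chrom[1] else "X"
  marker_map(chrom, len, df$pos, df$kind, df$allele_P1, df$allele_P2)
}
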