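#' Generate a synthetic exon/intron/intergenic annotation
#'
#' Tiles a chromosome with alternating exonic and non-exonic segments whose
#' lengths are exponential, scaled so the expected exonic fraction matches
#' `exon_fraction`; non-exonic segments are labelled intron or intergenic at
#' random.  This emulates the composition of a gene-dense chromosome arm
#' (the Drosophila X is about 23.7\% exonic) for placement-randomization
#' tests; it does not reproduce real gene structure.
#'
#' @param chromosome_length Chromosome length in bp.
#' @param exon_fraction Target exonic fraction of the chromosome.
#' @param mean_exon_length Mean exon segment length in bp.
#' @param seed Integer seed.
#' @return A data frame with 1-based inclusive `start`, `end` and `class`
#'   (`"exon"`, `"intron"` or `"intergenic"`) columns covering the
#'   chromosome.
#' @export
generate_annotation <- function(chromosome_length, exon_fraction = 0.237,
                                mean_exon_length = 400, seed = 1) {
  stop_if(exon_fraction <= 0 || exon_fraction >= 1,
          "exon_fraction must be in (0, 1)")
  set.seed(seed)
  mean_other <- mean_exon_length * (1 - exon_fraction) / exon_fraction
  n_guess <- ceiling(chromosome_length / (mean_exon_length + mean_other) * 2) + 10
  lens <- numeric(0)
  is_exon <- logical(0)
  total <- 0
  start_exon <- runif(1) < 0.5
  while (total < chromosome_length) {
    ex <- xor(rep(c(TRUE, FALSE), n_guess), !start_exon)
    ln <- ceiling(rexp(2 * n_guess, 1 / ifelse(ex, mean_exon_length, mean_other)))
    lens <- c(lens, ln)
    is_exon <- c(is_exon, ex)
    total <- sum(lens)
  }
  ends <- cumsum(lens)
  keep <- seq_len(which(ends >= chromosome_length)[1])
  lens <- lens[keep]; is_exon <- is_exon[keep]
  ends <- cumsum(lens); ends[length(ends)] <- chromosome_length
  starts <- c(1, head(ends, -1) + 1)
  cls <- ifelse(is_exon, "exon",
                sample(c("intron", "intergenic"), length(is_exon), replace = TRUE))
  ok <- starts <= ends
  data.frame(start = starts[ok], end = ends[ok], class = cls[ok],
             stringsAsFactors = FALSE)
}

#' Read or write an annotation as BED
#'
#' The feature class is stored in the BED name column; coordinates are
#' converted between the package's 1-based inclusive data frames and BED's
#' 0-based half-open convention.
#'
#' @param annotation Data frame with `start`, `end`, `class` columns.
#' @param path File path.
#' @param chromosome Chromosome name written to the BED file.
#' @return `read_annotation_bed` returns an annotation data frame;
#'   `write_annotation_bed` returns `path` invisibly.
#' @export
write_annotation_bed <- function(annotation, path, chromosome = "X") {
  df <- data.frame(chrom = chromosome, start = annotation$start - 1,
                   end = annotation$end, name = annotation$class)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  bed <- read_bed(path)
  data.frame(start = bed$start + 1, end = bed$end, class = bed$name,
             stringsAsFactors = FALSE)
}
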